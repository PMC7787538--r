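#' Pipeline configuration
#'
#' Bundles the file paths and parameters of a full end-to-end run. Any field
#' may be overridden; paths set to `NULL` disable the stages that need them.
#'
#' @param corpus,dict,network,pathways,rules,detected input file paths
#'   (corpus JSONL/MEDLINE, dictionary TSV, network SIF/TSV, pathway
#'   membership TSV, optional rule DSL file overriding MPIN-derived rules,
#'   detected-pathway list with one id per line).
#' @param weights optional precomputed weight-matrix TSV; bypasses corpus
#'   counting in the ranking stage.
#' @param disease disease id to extract markers for.
#' @param out_dir output directory (created if missing).
#' @param z_min,min_docs extraction thresholds.
#' @param seed integer seed driving every random tie-break.
#' @param policy rule-generation policy, see [rules_from_mpin()].
#' @param max_size largest enumerated combination size.
#' @param log_level one of `"quiet"`, `"warn"`, `"info"`, `"debug"`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(corpus, dict, network, pathways, detected,
                            disease, out_dir,
                            rules = NULL, weights = NULL,
                            z_min = 1.96, min_docs = 3L, seed = 1L,
                            policy = "generalize", max_size = 3L,
                            log_level = "warn") {
  stopifnot(is.numeric(z_min), is.numeric(min_docs), is.numeric(seed),
            is.numeric(max_size))
  policy <- match.arg(policy, c("generalize", "specialize", "conjunctive"))
  log_level <- match.arg(log_level, names(.log_levels))
  structure(list(corpus = corpus, dict = dict, network = network,
                 pathways = pathways, rules = rules, detected = detected,
                 weights = weights, disease = disease, out_dir = out_dir,
                 z_min = z_min, min_docs = as.integer(min_docs),
                 seed = as.integer(seed), policy = policy,
                 max_size = as.integer(max_size), log_level = log_level),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes extract, build-mct, build-mpin, rules, infer, rank and indicate
#' in order, writing each stage's artifact under `out_dir` and finally the
#' individual's risk indicator. All inputs are validated before any work is
#' done; every stage's output path and record count is collected in a run
#' manifest (written as `manifest.json`). The run is deterministic in
#' `(inputs, seed)`.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (list with `version`, `seed`, `config`,
#'   `stages`, `risk_indicator`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  old <- options(sddp.log_level = config$log_level)
  on.exit(options(old))
  required <- c("corpus", "dict", "network", "pathways", "detected")
  for (f in required) {
    if (is.null(config[[f]]) || !file.exists(config[[f]])) {
      stop("missing input for stage '", f, "': ",
           config[[f]] %||% "<unset>")
    }
  }
  for (f in c("rules", "weights")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      stop("missing input file: ", config[[f]])
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    version = as.character(utils::packageVersion("sddp")),
    seed = config$seed,
    config = unclass(config),
    stages = list()
  )
  stage <- function(name, path, n) {
    manifest$stages[[name]] <<- list(path = path, records = n)
    sddp_log("info", "stage ", name, ": ", n, " record(s) -> ", path)
  }
  out <- function(f) file.path(config$out_dir, f)
  # a stage failure still leaves a manifest recording partial completion
  on.exit({
    if (is.null(manifest$risk_indicator)) {
      manifest$partial <- TRUE
      try(jsonlite::write_json(manifest,
                               file.path(config$out_dir, "manifest.json"),
                               auto_unbox = TRUE, pretty = TRUE,
                               null = "null"), silent = TRUE)
    }
  }, add = TRUE)

  corpus <- read_corpus(config$corpus)
  dict <- read_term_dict(config$dict)
  network <- read_sif(config$network)
  pathways <- read_pathways(config$pathways)
  detected <- readLines(config$detected, warn = FALSE)
  detected <- trimws(detected[nzchar(trimws(detected))])

  # 1. extract
  extraction <- extract_markers(corpus, dict, config$disease,
                                z_min = config$z_min,
                                min_docs = config$min_docs)
  write_extraction(extraction, config$disease, out("associations.tsv"))
  stage("extract", out("associations.tsv"), nrow(extraction))

  # 2. build-mct (forests per pathway)
  forests <- lapply(pathways, function(p) {
    mct_forest(p, network, seed = config$seed)
  })
  forest_json <- lapply(forests, function(fs) {
    lapply(fs, function(t) list(root = t$root, parent = as.list(t$parent),
                                depth = as.list(t$depth)))
  })
  jsonlite::write_json(forest_json, out("mct_forests.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  stage("build-mct", out("mct_forests.json"),
        sum(vapply(forests, length, 1L)))

  # 3. build-mpin
  mpin <- build_mpin(pathways, network, seed = config$seed)
  write_mpin(mpin, out("mpin.tsv"))
  stage("build-mpin", out("mpin.tsv"), nrow(mpin$edges))

  # 4. rules
  rules <- if (!is.null(config$rules)) {
    parse_rules(config$rules, file = TRUE)
  } else {
    rules_from_mpin(mpin, policy = config$policy)
  }
  write_rules(rules, out("rules.txt"))
  stage("rules", out("rules.txt"), length(rules$rules))

  # 5. infer
  result <- forward_chain(rules, detected)
  write_inference(result, out("inference.json"))
  stage("infer", out("inference.json"), length(result$inferred))

  # 6. rank
  combos <- enumerate_combinations(names(pathways), config$max_size)
  individual <- sort(result$combined)
  cx <- NULL
  for (cid in names(combos)) {
    if (setequal(combos[[cid]], individual)) cx <- cid
  }
  if (is.null(cx)) {
    combos[[paste0("c", length(combos) + 1L)]] <- individual
    cx <- names(combos)[length(combos)]
  }
  weights <- if (!is.null(config$weights)) {
    read_weights(config$weights)
  } else {
    combination_weights(corpus, dict, pathways, combos)
  }
  ranking <- dominance_scores(weights)
  write_ranking(ranking, out("ranking.tsv"))
  stage("rank", out("ranking.tsv"), length(ranking$scores))

  # 7. indicate
  indicator <- risk_indicator(ranking, cx)
  jsonlite::write_json(list(combination = cx,
                            pathways = individual,
                            risk_indicator = indicator),
                       out("risk_indicator.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  stage("indicate", out("risk_indicator.json"), 1L)

  manifest$risk_indicator <- indicator
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
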