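#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the literature input of the extractor: abstracts
#' containing planted marker-disease sentences (single-clause templates,
#' judged related), decoy sentences splitting a planted pair across two
#' independent clauses joined by a coordinator (judged unrelated), pronoun
#' relative-clause sentences, and background noise in which terms co-occur
#' under independence so the z-score null is exact. Every sentence is
#' emitted both as raw text and as its bracketed constituency parse, so the
#' text-mining stage needs no external parser. Identical `(config, seed)`
#' yield byte-identical output.
#'
#' @param seed integer RNG seed.
#' @param n_publications number of abstracts.
#' @param sentences_range integer range (min, max) of sentences per abstract.
#' @param n_markers,n_diseases vocabulary sizes.
#' @param n_planted number of planted marker-disease associations (marker k
#'   is paired with disease `(k - 1) %% n_diseases + 1`).
#' @param planted_prob per-abstract probability that a planted pair
#'   contributes a sentence.
#' @param whereas_frac fraction of planted-pair sentences expressed as
#'   cross-clause decoys (coordinator-split, hence unrelated).
#' @param pronoun_frac fraction of planted-pair sentences expressed through
#'   a relative-pronoun clause.
#' @param noise_marker_rate,noise_disease_rate per-sentence probability
#'   that a filler sentence mentions a uniformly random marker / disease
#'   (independently, giving independence-level joint co-occurrence).
#' @param n_molecules,edge_prob random-network size and edge probability.
#' @param n_pathways,pathway_size,overlap_frac,markers_per_pathway pathway
#'   sampling parameters: consecutive pathways share
#'   `round(overlap_frac * pathway_size)` molecules.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_publications = 200L,
                       sentences_range = c(4L, 8L),
                       n_markers = 20L,
                       n_diseases = 2L,
                       n_planted = 10L,
                       planted_prob = 0.15,
                       whereas_frac = 0.2,
                       pronoun_frac = 0.15,
                       noise_marker_rate = 0.08,
                       noise_disease_rate = 0.08,
                       n_molecules = 30L,
                       edge_prob = 0.2,
                       n_pathways = 4L,
                       pathway_size = 10L,
                       overlap_frac = 0.3,
                       markers_per_pathway = 2L) {
  cfg <- as.list(environment())
  probs <- c(cfg$planted_prob, cfg$whereas_frac, cfg$pronoun_frac,
             cfg$noise_marker_rate, cfg$noise_disease_rate, cfg$edge_prob,
             cfg$overlap_frac)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  sizes <- c(cfg$n_publications, cfg$n_markers, cfg$n_diseases,
             cfg$n_molecules, cfg$n_pathways, cfg$pathway_size,
             cfg$markers_per_pathway)
  if (any(sizes <= 0)) stop("sizes must be positive")
  if (cfg$n_planted > cfg$n_markers) stop("n_planted exceeds n_markers")
  structure(cfg, class = "sim_config")
}

sim_dictionary <- function(config) {
  mk_ids <- sprintf("MRK%02d", seq_len(config$n_markers))
  ds_ids <- sprintf("DIS%d", seq_len(config$n_diseases))
  term_dict(
    c(mk_ids, ds_ids),
    c(rep("marker", length(mk_ids)), rep("disease", length(ds_ids))),
    c(lapply(seq_along(mk_ids), function(k) {
        c(sprintf("GENE%d", k), sprintf("g%dvar", k))
      }),
      lapply(seq_along(ds_ids), function(k) sprintf("DISEASE%d", k)))
  )
}

# sentence templates; each returns list(text, post, related = df | NULL)
.sim_templates <- list(
  direct = function(m, d) {
    list(text = sprintf("%s is associated with %s in patients .", m, d),
         post = sprintf(
           "(S (NP %s) (VP is associated (PP with (NP %s)) (PP in (NP patients))) .)",
           m, d))
  },
  pronoun = function(m, d) {
    list(text = sprintf("%s is elevated , which predicts %s .", m, d),
         post = sprintf(
           "(CU (S (NP %s) (VP is elevated)) , (S which (VP predicts (NP %s)) .))",
           m, d))
  },
  decoy = function(m, d, coord = "whereas") {
    list(text = sprintf("%s is elevated , %s %s progresses slowly .",
                        m, coord, d),
         post = sprintf(
           "(CU (S (NP %s) (VP is elevated)) , %s (S (NP %s) (VP progresses slowly) .))",
           m, coord, d))
  },
  joint_noise = function(m, d) {
    list(text = sprintf("%s was observed in %s cohorts .", m, d),
         post = sprintf(
           "(S (NP %s) (VP was observed (PP in (NP %s cohorts))) .)", m, d))
  },
  marker_only = function(m) {
    list(text = sprintf("%s levels were measured .", m),
         post = sprintf("(S (NP %s levels) (VP were measured) .)", m))
  },
  disease_only = function(d) {
    list(text = sprintf("patients with %s were recruited .", d),
         post = sprintf(
           "(S (NP patients (PP with (NP %s))) (VP were recruited) .)", d))
  },
  filler = function() {
    list(text = "samples were analysed in triplicate .",
         post = "(S (NP samples) (VP were analysed (PP in (NP triplicate))) .)")
  }
)

#' Generate a synthetic corpus with ground truth
#'
#' @param config a [sim_config()].
#' @return list with `corpus` (an `sddp_corpus` whose records carry
#'   bracketed parses), `dictionary` (a [term_dict()]),
#'   `truth` (data.frame of planted marker-disease associations: `marker_id`,
#'   `disease_id`) and `sentence_truth` (data.frame `pmid`, `sentence`,
#'   `id_a`, `id_b`, `planted` listing every related pair per sentence).
#' @export
gen_corpus <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  dict <- sim_dictionary(config)
  if (!config$n_markers || !config$n_diseases) stop("empty vocabularies")
  surf <- function(id) dict$surfaces[[id]][[1L]]
  planted <- data.frame(
    marker_id = sprintf("MRK%02d", seq_len(config$n_planted)),
    disease_id = sprintf("DIS%d", (seq_len(config$n_planted) - 1L) %%
                                    config$n_diseases + 1L),
    stringsAsFactors = FALSE
  )
  with_seed(config$seed, {
    records <- vector("list", config$n_publications)
    sent_truth <- list()
    for (p in seq_len(config$n_publications)) {
      pmid <- sprintf("S%05d", p)
      sents <- list()
      note <- function(k, a, b, is_planted) {
        sent_truth[[length(sent_truth) + 1L]] <<- data.frame(
          pmid = pmid, sentence = k, id_a = min(a, b), id_b = max(a, b),
          planted = is_planted, stringsAsFactors = FALSE)
      }
      for (i in seq_len(nrow(planted))) {
        if (stats::runif(1) >= config$planted_prob) next
        m <- planted$marker_id[i]; d <- planted$disease_id[i]
        u <- stats::runif(1)
        if (u < config$whereas_frac) {
          coord <- sample(c("whereas", "while", "but"), 1L)
          sents[[length(sents) + 1L]] <-
            .sim_templates$decoy(surf(m), surf(d), coord)
          # cross-clause: judged unrelated, so no truth entry
        } else if (u < config$whereas_frac + config$pronoun_frac) {
          sents[[length(sents) + 1L]] <- .sim_templates$pronoun(surf(m), surf(d))
          note(length(sents), m, d, TRUE)
        } else {
          sents[[length(sents) + 1L]] <- .sim_templates$direct(surf(m), surf(d))
          note(length(sents), m, d, TRUE)
        }
      }
      n_target <- sample(config$sentences_range[1L]:config$sentences_range[2L], 1L)
      while (length(sents) < n_target) {
        m <- if (stats::runif(1) < config$noise_marker_rate) {
          sample(sprintf("MRK%02d", seq_len(config$n_markers)), 1L)
        } else NA
        d <- if (stats::runif(1) < config$noise_disease_rate) {
          sample(sprintf("DIS%d", seq_len(config$n_diseases)), 1L)
        } else NA
        if (!is.na(m) && !is.na(d)) {
          sents[[length(sents) + 1L]] <- .sim_templates$joint_noise(surf(m), surf(d))
          note(length(sents), m, d, FALSE)
        } else if (!is.na(m)) {
          sents[[length(sents) + 1L]] <- .sim_templates$marker_only(surf(m))
        } else if (!is.na(d)) {
          sents[[length(sents) + 1L]] <- .sim_templates$disease_only(surf(d))
        } else {
          sents[[length(sents) + 1L]] <- .sim_templates$filler()
        }
      }
      records[[p]] <- list(
        pmid = pmid,
        sentences = vapply(sents, `[[`, "", "text"),
        parses = vapply(sents, `[[`, "", "post"))
    }
    truth_sent <- if (length(sent_truth)) do.call(rbind, sent_truth) else {
      data.frame(pmid = character(0), sentence = integer(0),
                 id_a = character(0), id_b = character(0),
                 planted = logical(0))
    }
    list(corpus = as_corpus(records), dictionary = dict, truth = planted,
         sentence_truth = truth_sent)
  })
}

#' Generate a random molecular network and overlapping pathways
#'
#' An Erdos-Renyi interaction network over the molecule vocabulary plus
#' pathway molecule sets with configured pairwise overlaps: consecutive
#' pathways share `round(overlap_frac * pathway_size)` molecules, and each
#' pathway designates `markers_per_pathway` of its molecules as markers
#' (preferring molecules that can reach the rest of the pathway).
#'
#' @param config a [sim_config()].
#' @param marker_ids optional molecule ids to prefer as pathway markers
#'   (e.g. extracted marker ids); defaults to sampled molecules.
#' @return list with `network` (igraph) and `pathways` (named list of
#'   [pathway()]).
#' @export
gen_network_and_pathways <- function(config, marker_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n_overlap <- round(config$overlap_frac * config$pathway_size)
  if (n_overlap >= config$pathway_size) {
    stop("overlap fraction infeasible for pathway size")
  }
  if (config$n_pathways * (config$pathway_size - n_overlap) + n_overlap >
      config$n_molecules) {
    stop("pathway sizes and overlaps infeasible for molecule count")
  }
  with_seed(config$seed + 7L, {
    mols <- sprintf("MOL%03d", seq_len(config$n_molecules))
    if (!is.null(marker_ids)) {
      mols[seq_along(marker_ids)] <- marker_ids
    }
    g <- igraph::sample_gnp(config$n_molecules, config$edge_prob)
    igraph::V(g)$name <- mols
    pool <- sample(mols)
    pathways <- list()
    prev_tail <- character(0)
    for (i in seq_len(config$n_pathways)) {
      fresh_n <- config$pathway_size - length(prev_tail)
      fresh <- pool[seq_len(fresh_n)]
      pool <- pool[-seq_len(fresh_n)]
      members <- c(prev_tail, fresh)
      # prefer well-connected members as markers so trees cover the pathway
      sub <- igraph::induced_subgraph(g, members)
      reach <- vapply(members, function(m) {
        length(igraph::subcomponent(sub, m))
      }, 1L)
      preferred <- members %in% (marker_ids %||% character(0))
      cand <- members[order(-preferred, -reach, members)]
      markers <- cand[seq_len(min(config$markers_per_pathway, length(cand)))]
      pid <- sprintf("MP_P%02d", i)
      pathways[[pid]] <- pathway(pid, members, markers)
      prev_tail <- fresh[seq_len(min(n_overlap, length(fresh)))]
    }
    list(network = g, pathways = pathways)
  })
}

#' Precision, recall and F-value of an extraction
#'
#' Standard confusion counts over predicted versus true association pairs:
#' `recall = TP / (TP + FN)`, `precision = TP / (TP + FP)`,
#' `F = 2 * precision * recall / (precision + recall)`. Undefined ratios
#' (zero denominators) are returned as 0 with the `undefined` flag set.
#'
#' @param predicted,truth data.frames with columns `marker_id`,
#'   `disease_id` (or 2-column matrices of pair ids).
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f_value`,
#'   `undefined`.
#' @export
score_extraction <- function(predicted, truth) {
  key <- function(x) {
    x <- as.data.frame(x)
    if (!nrow(x)) return(character(0))
    unique(paste(x[[1L]], x[[2L]], sep = "\r"))
  }
  p <- key(predicted[, c("marker_id", "disease_id")])
  t <- key(truth[, c("marker_id", "disease_id")])
  tp <- length(intersect(p, t))
  fp <- length(setdiff(p, t))
  fn <- length(setdiff(t, p))
  undefined <- FALSE
  ratio <- function(num, den) {
    if (den == 0) { undefined <<- TRUE; 0 } else num / den
  }
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  f_value <- ratio(2 * precision * recall, precision + recall)
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f_value = f_value, undefined = undefined)
}

#' Worked-example fixtures
#'
#' Small fixtures shipped with the package: `"table2"` (the ten-combination,
#' three-publication co-occurrence weight matrix of the dominance-ranking
#' worked example), `"example1"` (the two-clause coordinator sentence with
#' its bracketed parse and term dictionary) and `"t2d_rules"` (a *synthetic*
#' stand-in specification rule base for the type-2-diabetes pathway
#' illustration — constructed for demonstration, not a published rule set).
#'
#' @param name fixture name.
#' @return the loaded fixture: a `combination_weights`, a list
#'   (`sentence`, `post`, `dictionary`), or a [rule_base()].
#' @export
sddp_example <- function(name = c("table2", "example1", "t2d_rules")) {
  name <- match.arg(name)
  path <- function(f) system.file("extdata", f, package = "sddp",
                                  mustWork = TRUE)
  switch(name,
    table2 = read_weights(path("table2_weights.tsv")),
    example1 = {
      lines <- readLines(path("example1_sentence.txt"), encoding = "UTF-8")
      list(sentence = lines[[1L]], post = lines[[2L]],
           dictionary = read_term_dict(path("example1_dict.tsv")))
    },
    t2d_rules = parse_rules(path("synthetic_t2d.rules"), file = TRUE)
  )
}
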