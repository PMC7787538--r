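#' Co-occurrence z-score of a term pair
#'
#' One-sample binomial z against the independence expectation: with term
#' marginals `n_a`, `n_b` over `n_sentences` sentences, the null probability
#' of a joint related co-occurrence in a sentence is
#' `p = (n_a/n_sentences) * (n_b/n_sentences)`, the expectation is
#' `E = p * n_sentences`, and
#' `z = (n_related - E) / sqrt(E * (1 - p))`. Returns 0 when `E = 0`.
#'
#' @param n_related sentences where the pair co-occurs and is judged related.
#' @param n_a,n_b sentences containing each term (must be positive).
#' @param n_sentences corpus sentence total (must be positive).
#' @return the z-score, a single numeric.
#' @examples
#' pair_zscore(30, 100, 100, 1000) # about 6.36
#' @export
pair_zscore <- function(n_related, n_a, n_b, n_sentences) {
  if (n_sentences <= 0) stop("n_sentences must be positive")
  if (n_a <= 0 || n_b <= 0) stop("n_a and n_b must be positive")
  if (n_related < 0 || n_related > min(n_a, n_b)) {
    stop("n_related must satisfy 0 <= n_related <= min(n_a, n_b)")
  }
  p <- (n_a / n_sentences) * (n_b / n_sentences)
  e <- p * n_sentences
  if (e == 0) return(0)
  (n_related - e) / sqrt(e * (1 - p))
}

#' Sentence-level pair statistics over a corpus
#'
#' Walks every sentence of the corpus, locates dictionary mentions (with
#' pronoun antecedent annotation), judges relatedness with the strict clause
#' rules, and aggregates per unordered term pair: `n_related` (related
#' co-occurring sentences), the term marginals `n_a`/`n_b`,
#' `n_docs_related` (distinct publications with at least one related
#' co-occurrence) and the z-score. Only pairs with at least one related
#' co-occurrence are returned (all others have non-positive evidence).
#'
#' @param corpus an `sddp_corpus`.
#' @param dict a [term_dict()].
#' @param coordinators,pronouns lexicons passed to the sentence analysers.
#' @param extra_rules extra exclusion predicates, see [related_pairs()].
#' @return data.frame with columns `id_a`, `id_b`, `type_a`, `type_b`,
#'   `n_related`, `n_a`, `n_b`, `n_docs_related`, `n_sentences`, `z`.
#' @export
corpus_pair_stats <- function(corpus, dict,
                              coordinators = .default_coordinators,
                              pronouns = .default_pronouns,
                              extra_rules = list()) {
  stopifnot(inherits(corpus, "sddp_corpus"))
  if (!length(dict$ids)) stop("empty dictionary")
  term_n <- new.env(parent = emptyenv())   # id -> sentence count
  pair_n <- new.env(parent = emptyenv())   # key -> related sentence count
  pair_docs <- new.env(parent = emptyenv())# key -> set of pmids (env as set)
  bump <- function(env, key, by = 1L) {
    assign(key, (get0(key, envir = env) %||% 0L) + by, envir = env)
  }
  n_sentences <- 0L
  for (rec in corpus) {
    for (k in seq_along(rec$sentences)) {
      n_sentences <- n_sentences + 1L
      tr <- record_post(rec, k, dict, pronouns, coordinators)
      mentions <- mention_table(tr, dict)
      for (id in unique(mentions$id)) bump(term_n, id)
      rel <- related_pairs(tr, dict, coordinators = coordinators,
                           extra_rules = extra_rules)
      for (i in seq_len(nrow(rel))) {
        key <- pair_key(rel$id_a[i], rel$id_b[i])
        bump(pair_n, key)
        docs <- get0(key, envir = pair_docs) %||% character(0)
        assign(key, union(docs, rec$pmid), envir = pair_docs)
      }
    }
  }
  keys <- sort(ls(pair_n))
  if (!length(keys)) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      type_a = character(0), type_b = character(0),
                      n_related = integer(0), n_a = integer(0),
                      n_b = integer(0), n_docs_related = integer(0),
                      n_sentences = integer(0), z = numeric(0)))
  }
  ids <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  df <- data.frame(
    id_a = ids[, 1L], id_b = ids[, 2L],
    type_a = unname(dict$types[ids[, 1L]]),
    type_b = unname(dict$types[ids[, 2L]]),
    n_related = vapply(keys, get0, 0L, envir = pair_n),
    n_a = vapply(ids[, 1L], get0, 0L, envir = term_n),
    n_b = vapply(ids[, 2L], get0, 0L, envir = term_n),
    n_docs_related = vapply(keys, function(k) length(get(k, envir = pair_docs)), 1L),
    n_sentences = n_sentences,
    stringsAsFactors = FALSE, row.names = NULL
  )
  df$z <- vapply(seq_len(nrow(df)), function(i) {
    pair_zscore(df$n_related[i], df$n_a[i], df$n_b[i], df$n_sentences[i])
  }, 0)
  df
}

#' Extract marker terms associated with a disease
#'
#' Keeps marker-disease pairs that co-occur (a) significantly within
#' sentences (`z >= z_min`) and (b) in a significant number of publications
#' (`n_docs_related >= min_docs`), the two strictness filters of the
#' extractor. Output is deterministically ordered: z descending, then marker
#' id ascending.
#'
#' @param corpus an `sddp_corpus`.
#' @param dict a [term_dict()].
#' @param disease_id canonical disease id to extract markers for.
#' @param z_min z-score threshold (default 1.96, one-sided 2.5\%).
#' @param min_docs minimum distinct publications with related co-occurrence.
#' @param stats optional precomputed [corpus_pair_stats()] table (the corpus
#'   is then not re-scanned).
#' @param ... passed to [corpus_pair_stats()].
#' @return data.frame of pair statistics restricted to the disease's
#'   markers, with a `marker_id` column, sorted by `z` descending.
#' @export
extract_markers <- function(corpus, dict, disease_id, z_min = 1.96,
                            min_docs = 3L, stats = NULL, ...) {
  if (!disease_id %in% dict$ids) {
    stop("disease id not in dictionary: ", disease_id)
  }
  if (dict$types[[disease_id]] != "disease") {
    stop(disease_id, " is not a disease entry")
  }
  if (is.null(stats)) stats <- corpus_pair_stats(corpus, dict, ...)
  hit <- (stats$id_a == disease_id & stats$type_b == "marker") |
         (stats$id_b == disease_id & stats$type_a == "marker")
  df <- stats[hit, , drop = FALSE]
  if (nrow(df)) {
    df$marker_id <- ifelse(df$id_a == disease_id, df$id_b, df$id_a)
    df <- df[df$z >= z_min & df$n_docs_related >= min_docs, , drop = FALSE]
    df <- df[order(-df$z, df$marker_id), , drop = FALSE]
    row.names(df) <- NULL
  } else {
    df$marker_id <- character(0)
  }
  df
}

#' Write an extraction result as TSV
#'
#' Columns: `marker_id`, `disease_id`, `n_related`, `n_docs_related`, `z`.
#'
#' @param extraction result of [extract_markers()].
#' @param disease_id the disease the extraction was run for.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_extraction <- function(extraction, disease_id, path) {
  out <- data.frame(
    marker_id = extraction$marker_id,
    disease_id = rep(disease_id, nrow(extraction)),
    n_related = extraction$n_related,
    n_docs_related = extraction$n_docs_related,
    z = extraction$z
  )
  write_tsv_sddp(out, path)
}
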