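#' Combination weight matrices
#'
#' Weights count, per publication and per pathway combination, the sentences
#' in which the combination's pathways jointly co-occur (one marker term per
#' member pathway, all pairwise semantically related). The container is an
#' integer matrix with publications as rows and combinations as columns,
#' plus the combination definitions.
#'
#' @param W non-negative integer matrix, rows = publications, columns =
#'   combinations (both dimnames required).
#' @param combinations named list mapping combination id to a character
#'   vector of member pathway ids; may be `NULL` when definitions are
#'   unknown (a bare worked-example matrix).
#' @return an object of class `combination_weights`.
#' @export
combination_weights_matrix <- function(W, combinations = NULL) {
  W <- as.matrix(W)
  if (any(W < 0) || any(W != round(W))) {
    stop("weights must be non-negative integers")
  }
  if (is.null(rownames(W)) || is.null(colnames(W))) {
    stop("weight matrix needs publication row names and combination column names")
  }
  if (!is.null(combinations) &&
      !setequal(names(combinations), colnames(W))) {
    stop("combination definitions do not match matrix columns")
  }
  structure(list(W = W, combinations = combinations),
            class = "combination_weights")
}

#' @export
print.combination_weights <- function(x, ...) {
  cat("combination_weights:", nrow(x$W), "publications x", ncol(x$W),
      "combinations\n")
  invisible(x)
}

#' Pairwise dominance outcome of two weight columns
#'
#' Combination i beats combination j if its weight exceeds j's in more
#' publications than the reverse.
#'
#' @param w_i,w_j equal-length numeric weight vectors (one entry per
#'   publication).
#' @return `+1` (i beats j), `-1` (i loses) or `0` (tie).
#' @examples
#' pairwise_outcome(c(3, 0, 3), c(0, 7, 5)) # -1
#' @export
pairwise_outcome <- function(w_i, w_j) {
  if (length(w_i) != length(w_j)) stop("weight columns differ in length")
  wins <- sum(w_i > w_j)
  losses <- sum(w_j > w_i)
  if (wins > losses) 1L else if (losses > wins) -1L else 0L
}

#' Dominance scores and competition ranks of all combinations
#'
#' Fills the antisymmetric beats matrix with [pairwise_outcome()] for every
#' pair, scores each combination as beats minus losses (a Copeland-style
#' score), and assigns competition ranks: tied scores share a rank and the
#' following ranks are skipped (`rank_i = 1 + #\{j : score_j > score_i\}`).
#'
#' @param weights a `combination_weights`, or a bare matrix acceptable to
#'   [combination_weights_matrix()] (with `combinations = NULL`).
#' @return an object of class `dominance_result`: list with `beats` (the
#'   +1/0/-1 matrix), `scores` (named integer) and `ranks` (named integer,
#'   the risk indicators).
#' @export
dominance_scores <- function(weights) {
  if (!inherits(weights, "combination_weights")) {
    weights <- combination_weights_matrix(weights)
  }
  W <- weights$W
  ids <- colnames(W)
  n <- length(ids)
  if (n < 1L) stop("need at least one combination")
  B <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      o <- pairwise_outcome(W[, i], W[, j])
      B[i, j] <- o
      B[j, i] <- -o
    }
  }
  scores <- setNames(as.integer(rowSums(pmax(B, 0L)) - rowSums(pmax(-B, 0L))),
                     ids)
  ranks <- setNames(vapply(scores, function(s) {
    1L + sum(scores > s)
  }, 1L), ids)
  structure(list(beats = B, scores = scores, ranks = ranks,
                 combinations = weights$combinations),
            class = "dominance_result")
}

#' @export
print.dominance_result <- function(x, ...) {
  df <- data.frame(combination = names(x$scores),
                   score = unname(x$scores), rank = unname(x$ranks))
  print(df[order(df$rank, df$combination), ], row.names = FALSE)
  invisible(x)
}

#' Risk indicator of a combination
#'
#' The individual's risk indicator is the competition (dominance) rank of
#' the combination of pathways inferred for them.
#'
#' @param result a `dominance_result`.
#' @param combination combination id present in the result.
#' @return positive integer rank.
#' @export
risk_indicator <- function(result, combination) {
  stopifnot(inherits(result, "dominance_result"))
  if (!combination %in% names(result$ranks)) {
    stop("unknown combination: ", combination)
  }
  unname(result$ranks[[combination]])
}

#' Enumerate pathway combinations up to a size limit
#'
#' @param pathway_ids character vector of pathway ids.
#' @param max_size largest combination size (default 3; the full power set
#'   is exponential).
#' @return named list of combinations (`c1`, `c2`, ...), each a sorted
#'   character vector, ordered by size then lexicographically.
#' @export
enumerate_combinations <- function(pathway_ids, max_size = 3L) {
  pathway_ids <- sort(unique(pathway_ids))
  combos <- list()
  for (k in seq_len(min(max_size, length(pathway_ids)))) {
    cm <- utils::combn(pathway_ids, k, simplify = FALSE)
    combos <- c(combos, cm)
  }
  setNames(combos, paste0("c", seq_along(combos)))
}

#' Count joint related co-occurrence weights over a corpus
#'
#' For every publication and combination, counts the sentences in which at
#' least one marker term of *every* member pathway occurs and a selection of
#' one such mention per pathway is pairwise semantically related (judged by
#' the same strict clause rules as the extractor). A singleton combination
#' degenerates to counting sentences mentioning any of its markers.
#'
#' @param corpus an `sddp_corpus`.
#' @param dict a [term_dict()]; pathway markers must be dictionary ids.
#' @param pathways named list of [pathway()] objects.
#' @param combinations named list of combinations (character vectors of
#'   pathway ids), e.g. from [enumerate_combinations()].
#' @param ... lexicon arguments passed to the sentence analysers.
#' @return a `combination_weights`.
#' @export
combination_weights <- function(corpus, dict, pathways, combinations, ...) {
  stopifnot(inherits(corpus, "sddp_corpus"))
  pw_ids <- vapply(pathways, function(p) p$id, "")
  names(pathways) <- pw_ids
  for (cid in names(combinations)) {
    unknown <- setdiff(combinations[[cid]], pw_ids)
    if (length(unknown)) {
      stop("combination ", cid, " references unknown pathway(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  marker_sets <- lapply(pathways, function(p) intersect(p$markers, dict$ids))
  W <- matrix(0L, nrow = length(corpus), ncol = length(combinations),
              dimnames = list(vapply(corpus, function(r) r$pmid, ""),
                              names(combinations)))
  for (ri in seq_along(corpus)) {
    rec <- corpus[[ri]]
    for (k in seq_along(rec$sentences)) {
      tr <- record_post(rec, k, dict)
      mentions <- mention_table(tr, dict)
      if (!nrow(mentions)) next
      present <- unique(mentions$id)
      rel <- related_pairs(tr, dict, ...)
      rel_key <- pair_key(rel$id_a, rel$id_b)
      related <- function(a, b) a == b || pair_key(a, b) %in% rel_key
      for (ci in seq_along(combinations)) {
        member_ids <- lapply(combinations[[ci]], function(p) {
          intersect(marker_sets[[p]], present)
        })
        if (any(!vapply(member_ids, length, 1L))) next
        picks <- expand.grid(member_ids, stringsAsFactors = FALSE)
        ok <- FALSE
        for (pi in seq_len(nrow(picks))) {
          sel <- unlist(picks[pi, ], use.names = FALSE)
          good <- TRUE
          if (length(sel) > 1L) {
            for (a in seq_len(length(sel) - 1L)) {
              for (b in (a + 1L):length(sel)) {
                if (!related(sel[a], sel[b])) { good <- FALSE; break }
              }
              if (!good) break
            }
          }
          if (good) { ok <- TRUE; break }
        }
        if (ok) W[ri, ci] <- W[ri, ci] + 1L
      }
    }
  }
  combination_weights_matrix(W, combinations)
}

#' Read a weight matrix from TSV
#'
#' Layout written by [write_weights()]: optional `# cid = MP_A+MP_B`
#' definition comment lines, then a header row (`publication` followed by
#' combination ids) and one row per publication.
#'
#' @param path file path.
#' @return a `combination_weights`.
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  defs <- grep("^#\\s*\\S+\\s*=", lines, value = TRUE)
  combos <- NULL
  if (length(defs)) {
    combos <- lapply(defs, function(d) {
      strsplit(sub("^#\\s*\\S+\\s*=\\s*", "", d), "+", fixed = TRUE)[[1L]]
    })
    names(combos) <- sub("^#\\s*(\\S+)\\s*=.*$", "\\1", defs)
  }
  df <- read_tsv_sddp(path)
  if (names(df)[1L] != "publication") {
    stop(path, ": first column must be 'publication'")
  }
  W <- as.matrix(df[, -1L, drop = FALSE])
  rownames(W) <- df$publication
  storage.mode(W) <- "integer"
  combination_weights_matrix(W, combos)
}

#' Write a weight matrix to TSV
#'
#' @param weights a `combination_weights`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  stopifnot(inherits(weights, "combination_weights"))
  df <- data.frame(publication = rownames(weights$W), weights$W,
                   check.names = FALSE)
  comments <- NULL
  if (!is.null(weights$combinations)) {
    comments <- vapply(names(weights$combinations), function(cid) {
      paste0(cid, " = ", paste(weights$combinations[[cid]], collapse = "+"))
    }, "")
  }
  write_tsv_sddp(df, path, comments = comments)
}

#' Write a dominance ranking to TSV
#'
#' Columns: `combination`, `score`, `rank`.
#'
#' @param result a `dominance_result`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(result, path) {
  stopifnot(inherits(result, "dominance_result"))
  write_tsv_sddp(data.frame(combination = names(result$scores),
                            score = unname(result$scores),
                            rank = unname(result$ranks)), path)
}
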