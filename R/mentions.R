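#' Locate dictionary term mentions in a token sequence
#'
#' Case-insensitive longest-match scan: at each position the longest surface
#' form starting there wins, and scanning resumes after it (mentions do not
#' overlap). Spans are 0-based half-open.
#'
#' @param tokens character vector of tokens.
#' @param dict a [term_dict()].
#' @return data.frame with columns `id`, `type`, `start`, `end`.
#' @export
find_mentions <- function(tokens, dict) {
  stopifnot(inherits(dict, "term_dict"))
  if (!length(dict$ids)) stop("empty dictionary")
  idx <- dict_index(dict)
  low <- tolower(tokens)
  n <- length(low)
  hits <- list()
  i <- 1L
  while (i <= n) {
    cand <- idx[[low[i]]]
    best <- NULL
    if (!is.null(cand)) {
      for (e in cand) {
        if (e$n <= n - i + 1L &&
            (is.null(best) || e$n > best$n) &&
            identical(low[i:(i + e$n - 1L)], e$tokens)) {
          best <- e
        }
      }
    }
    if (is.null(best)) {
      i <- i + 1L
    } else {
      hits[[length(hits) + 1L]] <- data.frame(
        id = best$id, type = unname(dict$types[[best$id]]),
        start = i - 1L, end = i - 1L + best$n, stringsAsFactors = FALSE)
      i <- i + best$n
    }
  }
  if (!length(hits)) {
    return(data.frame(id = character(0), type = character(0),
                      start = integer(0), end = integer(0)))
  }
  do.call(rbind, hits)
}

.default_pronouns <- c("whom", "which", "it", "who", "that")

#' Annotate pronouns with their antecedent terms
#'
#' Implements the antecedent rule of the extractor: each pronoun is annotated
#' with the closest dictionary terms of the nearest *preceding* independent
#' clause (closest = smallest token distance from the pronoun to the term's
#' end; equidistant terms are all kept). The tree shape is unchanged; the
#' annotations are stored in the `pronoun_refs` attribute and count as
#' mentions of the antecedent terms during relatedness judgement. A pronoun
#' with no preceding independent clause is left unannotated and logged.
#'
#' @param tree a `post_tree`.
#' @param dict a [term_dict()].
#' @param pronouns pronoun lexicon (lowercase).
#' @return `tree` with a `pronoun_refs` attribute (list of `list(pos, ids)`).
#' @export
resolve_pronouns <- function(tree, dict, pronouns = .default_pronouns) {
  stopifnot(inherits(tree, "post_tree"))
  toks <- tolower(tree$tokens)
  ppos <- which(toks %in% pronouns) # 1-based positions
  if (!length(ppos)) {
    attr(tree, "pronoun_refs") <- list()
    return(tree)
  }
  clauses <- post_clauses(tree)
  mentions <- find_mentions(tree$tokens, dict)
  refs <- list()
  for (p in ppos) {
    p0 <- p - 1L # 0-based token index of the pronoun
    # nearest preceding independent clause: ends at or before the pronoun,
    # does not contain it
    prev <- which(clauses$end <= p0)
    if (!length(prev)) {
      sddp_log("info", "pronoun '", tree$tokens[p],
               "' has no preceding independent clause; left unannotated")
      next
    }
    ci <- prev[which.max(clauses$end[prev])]
    in_clause <- mentions[mentions$start >= clauses$start[ci] &
                          mentions$end <= clauses$end[ci], , drop = FALSE]
    if (!nrow(in_clause)) next
    dist <- p0 - in_clause$end
    ids <- unique(in_clause$id[dist == min(dist)])
    if (length(ids) > 1L) {
      sddp_log("info", "pronoun '", tree$tokens[p],
               "' has equidistant antecedents: ", paste(ids, collapse = ", "))
    }
    refs[[length(refs) + 1L]] <- list(pos = p0, ids = ids)
  }
  attr(tree, "pronoun_refs") <- refs
  tree
}

.default_coordinators <- c("whereas", "while", "but")

# Mention table with clause assignment; pronoun annotations become extra
# mentions of their antecedent ids at the pronoun's position.
mention_table <- function(tree, dict) {
  mentions <- find_mentions(tree$tokens, dict)
  refs <- attr(tree, "pronoun_refs") %||% list()
  for (r in refs) {
    for (id in r$ids) {
      mentions <- rbind(mentions, data.frame(
        id = id, type = unname(dict$types[[id]]),
        start = r$pos, end = r$pos + 1L, stringsAsFactors = FALSE))
    }
  }
  if (!nrow(mentions)) return(cbind(mentions, clause = integer(0)))
  clauses <- post_clauses(tree)
  mentions$clause <- vapply(seq_len(nrow(mentions)), function(i) {
    clause_of_span(clauses, mentions$start[i], mentions$end[i])
  }, 1L)
  mentions
}

# TRUE iff two mentions sit in distinct independent clauses joined by a
# coordinator from `coordinators` (the preposition-modifier exclusion rule).
split_by_coordinator <- function(tree, clauses, ci, cj, coordinators) {
  if (is.na(ci) || is.na(cj) || ci == cj) return(FALSE)
  a <- clauses[min(ci, cj), ]; b <- clauses[max(ci, cj), ]
  if (a$end > b$start) return(FALSE) # nested/overlapping: rule out of scope
  between <- if (a$end < b$start) tree$tokens[(a$end + 1L):b$start] else character(0)
  any(tolower(between) %in% coordinators)
}

#' Semantically related term pairs in a sentence
#'
#' Judges every pair of dictionary mentions in the sentence. Two mentions are
#' related unless an enabled exclusion rule separates them; the built-in rule
#' treats mentions in two distinct independent clauses joined by a
#' preposition-modifier coordinator (`whereas`, `while`, `but`) as unrelated.
#' Pronoun annotations made by [resolve_pronouns()] count as mentions of
#' their antecedent terms. Additional exclusion rules can be plugged in as
#' predicates over a mention pair and the tree.
#'
#' @param tree a `post_tree` (optionally pronoun-annotated).
#' @param dict a [term_dict()].
#' @param coordinators coordinator lexicon for the built-in exclusion rule.
#' @param extra_rules list of functions `f(mention_i, mention_j, tree)`
#'   returning `TRUE` when the pair must be treated as unrelated.
#' @return data.frame with columns `id_a`, `id_b` (`id_a < id_b`), one row
#'   per related unordered pair of distinct ids.
#' @examples
#' d <- term_dict(c("BRCA1", "BC"), c("marker", "disease"),
#'                list("BRCA1", "breast cancer"))
#' related_pairs(sentence_post("BRCA1 is associated with breast cancer"), d)
#' @export
related_pairs <- function(tree, dict,
                          coordinators = .default_coordinators,
                          extra_rules = list()) {
  stopifnot(inherits(tree, "post_tree"))
  if (!length(dict$ids)) stop("empty dictionary")
  mentions <- mention_table(tree, dict)
  out <- list()
  if (nrow(mentions) >= 2L) {
    clauses <- post_clauses(tree)
    for (i in seq_len(nrow(mentions) - 1L)) {
      for (j in (i + 1L):nrow(mentions)) {
        if (mentions$id[i] == mentions$id[j]) next
        if (split_by_coordinator(tree, clauses,
                                 mentions$clause[i], mentions$clause[j],
                                 coordinators)) next
        excluded <- FALSE
        for (f in extra_rules) {
          if (isTRUE(f(mentions[i, ], mentions[j, ], tree))) {
            excluded <- TRUE; break
          }
        }
        if (excluded) next
        out[[length(out) + 1L]] <- c(min(mentions$id[i], mentions$id[j]),
                                     max(mentions$id[i], mentions$id[j]))
      }
    }
  }
  if (!length(out)) {
    return(data.frame(id_a = character(0), id_b = character(0)))
  }
  m <- unique(do.call(rbind, out))
  df <- data.frame(id_a = m[, 1L], id_b = m[, 2L], stringsAsFactors = FALSE)
  df[order(df$id_a, df$id_b), , drop = FALSE]
}
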