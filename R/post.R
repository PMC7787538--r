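#' @name post
#' @title Part-of-sentence trees (POST)
#'
#' @description
#' A sentence is represented as an ordered rooted tree of constituents —
#' clauses, units and groups — whose leaves are the tokens of the sentence.
#' Constituent labels are restricted to `independent-clause`,
#' `adverbial-clause`, `conjoint-clause`, `compound-unit`, `unit`, `group`
#' and `token`; token spans are 0-based and half-open, and the spans of a
#' node's children partition the node's span in order.
NULL

.post_labels <- c("independent-clause", "adverbial-clause", "conjoint-clause",
                  "compound-unit", "unit", "group", "token")

# Penn-treebank-style labels collapsed onto the constituent scheme; anything
# unlisted becomes "unit".
.post_label_map <- c(
  "S" = "independent-clause", "IC" = "independent-clause",
  "SINV" = "independent-clause",
  "SBAR" = "adverbial-clause", "AC" = "adverbial-clause",
  "CJC" = "conjoint-clause",
  "CU" = "compound-unit", "UCP" = "compound-unit",
  "NP" = "group", "VP" = "group", "PP" = "group", "ADJP" = "group",
  "ADVP" = "group", "GRP" = "group",
  "U" = "unit", "FRAG" = "unit"
)

map_post_label <- function(label) {
  if (label %in% .post_labels) return(label)
  m <- unname(.post_label_map[label])
  if (is.na(m)) "unit" else m
}

#' Tokenize raw text
#'
#' Whitespace splitting with leading/trailing punctuation peeled off into
#' separate tokens; internal punctuation (hyphens, slashes) stays inside the
#' token, so identifiers such as `5-HIT` survive intact.
#'
#' @param text a single string.
#' @return character vector of tokens.
#' @export
tokenize_text <- function(text) {
  stopifnot(length(text) == 1L)
  chunks <- strsplit(trimws(text), "\\s+")[[1L]]
  chunks <- chunks[nzchar(chunks)]
  out <- character(0)
  for (ch in chunks) {
    lead <- character(0); trail <- character(0)
    while (nchar(ch) > 1L && grepl("^[[:punct:]]", ch) &&
           !grepl("^[[:alnum:]]", ch)) {
      lead <- c(lead, substr(ch, 1L, 1L)); ch <- substr(ch, 2L, nchar(ch))
    }
    while (nchar(ch) > 1L && grepl("[[:punct:]]$", ch) &&
           !grepl("[[:alnum:]]$", ch)) {
      trail <- c(substr(ch, nchar(ch), nchar(ch)), trail)
      ch <- substr(ch, 1L, nchar(ch) - 1L)
    }
    out <- c(out, lead, ch, trail)
  }
  out
}

post_node <- function(label, children = NULL, token = NULL,
                      start = NA_integer_, end = NA_integer_) {
  list(label = label, children = children, token = token,
       start = start, end = end)
}

#' Parse a bracketed constituency parse into a POST
#'
#' Reads a Penn-style bracketed parse, e.g.
#' `"(S (NP BRCA1) (VP is associated with (NP breast cancer)))"`. Labels are
#' mapped onto the constituent scheme; unmappable labels collapse to
#' `"unit"`. Leaves become `token` nodes; spans are assigned 0-based,
#' half-open.
#'
#' @param text a single bracketed-parse string.
#' @return an object of class `post_tree` with elements `root` (nested node
#'   list) and `tokens` (character vector).
#' @examples
#' tr <- post_parse("(S (NP BRCA1) (VP is associated with (NP breast cancer)))")
#' post_tokens(tr)
#' @export
post_parse <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "")[[1L]]
  n <- length(chars)
  pos <- 1L
  perr <- function(msg, at) {
    stop(sprintf("parse error at offset %d: %s", at - 1L, msg), call. = FALSE)
  }
  skip_ws <- function() {
    while (pos <= n && grepl("^\\s$", chars[pos])) pos <<- pos + 1L
  }
  read_atom <- function() {
    start <- pos
    while (pos <= n && !grepl("^[\\s()]$", chars[pos], perl = TRUE)) {
      pos <<- pos + 1L
    }
    if (pos == start) perr("expected a label or token", start)
    paste(chars[start:(pos - 1L)], collapse = "")
  }
  tokens <- character(0)
  parse_node <- function() {
    skip_ws()
    if (pos > n) perr("unexpected end of input", pos)
    if (chars[pos] == "(") {
      open_at <- pos
      pos <<- pos + 1L
      skip_ws()
      if (pos > n || chars[pos] %in% c("(", ")")) {
        perr("missing constituent label", open_at)
      }
      label <- map_post_label(read_atom())
      children <- list()
      repeat {
        skip_ws()
        if (pos > n) perr("unbalanced '(': missing ')'", open_at)
        if (chars[pos] == ")") { pos <<- pos + 1L; break }
        children[[length(children) + 1L]] <- parse_node()
      }
      if (!length(children)) perr("empty constituent", open_at)
      post_node(label, children = children,
                start = children[[1L]]$start,
                end = children[[length(children)]]$end)
    } else if (chars[pos] == ")") {
      perr("unexpected ')'", pos)
    } else {
      tok <- read_atom()
      tokens[[length(tokens) + 1L]] <<- tok
      post_node("token", token = tok,
                start = length(tokens) - 1L, end = length(tokens))
    }
  }
  root <- parse_node()
  skip_ws()
  if (pos <= n) perr("trailing input after parse", pos)
  structure(list(root = root, tokens = tokens), class = "post_tree")
}

#' Tokens of a POST
#' @param tree a `post_tree`.
#' @return character vector of leaf tokens in order.
#' @export
post_tokens <- function(tree) {
  stopifnot(inherits(tree, "post_tree"))
  tree$tokens
}

#' @export
print.post_tree <- function(x, ...) {
  rec <- function(node, indent) {
    if (node$label == "token") {
      cat(indent, node$token, " [", node$start, ",", node$end, ")\n", sep = "")
    } else {
      cat(indent, node$label, " [", node$start, ",", node$end, ")\n", sep = "")
      for (ch in node$children) rec(ch, paste0(indent, "  "))
    }
  }
  rec(x$root, "")
  invisible(x)
}

# All independent clauses as a data.frame (start, end, depth), document order.
post_clauses <- function(tree) {
  res <- list()
  rec <- function(node, depth) {
    if (node$label == "independent-clause") {
      res[[length(res) + 1L]] <<-
        data.frame(start = node$start, end = node$end, depth = depth)
    }
    for (ch in node$children %||% list()) rec(ch, depth + 1L)
  }
  rec(tree$root, 0L)
  if (!length(res)) {
    return(data.frame(start = integer(0), end = integer(0), depth = integer(0)))
  }
  do.call(rbind, res)
}

# Index (row) of the deepest independent clause containing [s, e), or NA.
clause_of_span <- function(clauses, s, e) {
  hit <- which(clauses$start <= s & clauses$end >= e)
  if (!length(hit)) return(NA_integer_)
  hit[which.max(clauses$depth[hit])]
}

#' Heuristic POST for a raw sentence
#'
#' When no external constituency parse is available, a sentence is split into
#' independent clauses at coordinating tokens (`whereas`, `while`, `but` by
#' default) and, after a comma, at relative pronouns, producing a flat
#' compound-unit-of-clauses tree. This is a deliberately coarse stand-in for
#' a full parser: it preserves exactly the clause boundaries the strict
#' extraction rules consume.
#'
#' @param text a single sentence string.
#' @param coordinators tokens that close an independent clause.
#' @param pronouns relative pronouns that open a clause when comma-preceded.
#' @return a `post_tree`.
#' @export
sentence_post <- function(text,
                          coordinators = c("whereas", "while", "but"),
                          pronouns = c("whom", "which", "it", "who", "that")) {
  toks <- tokenize_text(text)
  if (!length(toks)) stop("empty sentence")
  low <- tolower(toks)
  clause_start <- 1L
  parts <- list() # each: list(kind = "clause"/"coord", idx = indices)
  i <- 1L
  flush_clause <- function(upto) {
    if (upto >= clause_start) {
      parts[[length(parts) + 1L]] <<-
        list(kind = "clause", idx = clause_start:upto)
    }
  }
  while (i <= length(toks)) {
    if (low[i] %in% coordinators) {
      flush_clause(i - 1L)
      parts[[length(parts) + 1L]] <- list(kind = "coord", idx = i)
      clause_start <- i + 1L
    } else if (i > clause_start && low[i] %in% pronouns &&
               low[i - 1L] == ",") {
      flush_clause(i - 1L)
      clause_start <- i
    }
    i <- i + 1L
  }
  flush_clause(length(toks))
  mk_leaf <- function(j) post_node("token", token = toks[j],
                                   start = j - 1L, end = j)
  children <- lapply(parts, function(p) {
    leaves <- lapply(p$idx, mk_leaf)
    if (p$kind == "coord") {
      leaves[[1L]]
    } else {
      post_node("independent-clause", children = leaves,
                start = p$idx[1L] - 1L, end = p$idx[length(p$idx)])
    }
  })
  root <- if (length(children) == 1L) {
    children[[1L]]
  } else {
    post_node("compound-unit", children = children,
              start = 0L, end = length(toks))
  }
  structure(list(root = root, tokens = toks), class = "post_tree")
}
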