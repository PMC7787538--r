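#' Term dictionary for dictionary-based entity matching
#'
#' A term dictionary maps canonical identifiers to their surface forms. Each
#' entry is typed as either a molecular marker (`"marker"`) or a disease
#' (`"disease"`); mentions in text are located by case-insensitive
#' longest-match lookup of the surface forms.
#'
#' @param ids character vector of unique canonical identifiers.
#' @param types character vector, one of `"marker"`/`"disease"` per id.
#' @param surfaces list of character vectors, one per id, each with at least
#'   one surface form (the first is treated as the primary term).
#' @return an object of class `term_dict`.
#' @examples
#' d <- term_dict(c("BRCA1", "BRCA"), c("marker", "disease"),
#'                list("BRCA1", c("breast cancer", "BRCA")))
#' @export
term_dict <- function(ids, types, surfaces) {
  ids <- as.character(ids)
  types <- as.character(types)
  if (anyDuplicated(ids)) stop("dictionary ids must be unique")
  if (length(types) != length(ids) || length(surfaces) != length(ids)) {
    stop("ids, types and surfaces must have equal length")
  }
  if (!all(types %in% c("marker", "disease"))) {
    stop("types must be 'marker' or 'disease'")
  }
  surfaces <- lapply(surfaces, as.character)
  if (any(vapply(surfaces, length, 1L) == 0L)) {
    stop("every entry needs at least one surface form")
  }
  structure(
    list(ids = ids, types = setNames(types, ids),
         surfaces = setNames(surfaces, ids)),
    class = "term_dict"
  )
}

#' @export
print.term_dict <- function(x, ...) {
  cat("term_dict:", length(x$ids), "entries (",
      sum(x$types == "marker"), "markers,",
      sum(x$types == "disease"), "diseases )\n")
  invisible(x)
}

#' @export
length.term_dict <- function(x) length(x$ids)

#' Read a term dictionary from 4-column TSV
#'
#' Columns: `id`, `type`, `primary_term`, `synonyms` (pipe-separated, may be
#' empty). `#` lines are comments.
#'
#' @param path file path.
#' @return a [term_dict()].
#' @export
read_term_dict <- function(path) {
  df <- read_tsv_sddp(path)
  need <- c("id", "type", "primary_term", "synonyms")
  if (!all(need %in% names(df))) {
    stop("dictionary TSV must have columns: ", paste(need, collapse = ", "))
  }
  syn <- strsplit(ifelse(is.na(df$synonyms), "", as.character(df$synonyms)),
                  "|", fixed = TRUE)
  surfaces <- Map(function(p, s) unique(c(p, s[nzchar(s)])),
                  as.character(df$primary_term), syn)
  term_dict(df$id, df$type, unname(surfaces))
}

#' Write a term dictionary to 4-column TSV
#'
#' @param dict a [term_dict()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_term_dict <- function(dict, path) {
  stopifnot(inherits(dict, "term_dict"))
  df <- data.frame(
    id = dict$ids,
    type = unname(dict$types[dict$ids]),
    primary_term = vapply(dict$surfaces[dict$ids], `[[`, "", 1L),
    synonyms = vapply(dict$surfaces[dict$ids],
                      function(s) paste(s[-1L], collapse = "|"), ""),
    stringsAsFactors = FALSE
  )
  write_tsv_sddp(df, path)
}

# Tokenized surface-form index used by the longest-match scanner: a list of
# (tokens, id, n) entries sorted by decreasing token length, grouped by first
# token (lowercased).
dict_index <- function(dict) {
  idx <- attr(dict, ".index")
  if (!is.null(idx)) return(idx)
  entries <- list()
  for (id in dict$ids) {
    for (s in dict$surfaces[[id]]) {
      toks <- tolower(tokenize_text(s))
      if (!length(toks)) next
      entries[[length(entries) + 1L]] <-
        list(tokens = toks, id = id, n = length(toks))
    }
  }
  first <- vapply(entries, function(e) e$tokens[[1L]], "")
  split(entries, first)
}
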