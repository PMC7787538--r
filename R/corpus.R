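#' Abstract corpora
#'
#' A corpus is a list of publication records, each with a `pmid`, a character
#' vector of `sentences` and, optionally, a parallel vector of bracketed
#' constituency `parses`. When a record carries parses they are consumed via
#' [post_parse()]; otherwise sentences fall back on the heuristic
#' [sentence_post()] splitter.
#'
#' @param records list of `list(pmid, sentences, parses = NULL)` entries, or
#'   `list(pmid, abstract)` entries (abstracts are sentence-split).
#' @return an object of class `sddp_corpus`.
#' @export
as_corpus <- function(records) {
  recs <- lapply(records, function(r) {
    if (is.null(r$pmid)) stop("corpus record without pmid")
    sent <- r$sentences
    if (is.null(sent)) {
      if (is.null(r$abstract)) stop("corpus record needs sentences or abstract")
      sent <- split_sentences(r$abstract)
    }
    parses <- r$parses
    if (!is.null(parses) && length(parses) != length(sent)) {
      stop("record ", r$pmid, ": parses and sentences differ in length")
    }
    list(pmid = as.character(r$pmid), sentences = as.character(sent),
         parses = parses)
  })
  structure(recs, class = "sddp_corpus")
}

#' @export
print.sddp_corpus <- function(x, ...) {
  ns <- sum(vapply(x, function(r) length(r$sentences), 1L))
  cat("sddp_corpus:", length(x), "publications,", ns, "sentences\n")
  invisible(x)
}

#' Split an abstract into sentences
#'
#' Splits at `.`, `!` or `?` followed by whitespace and an uppercase letter,
#' digit or opening bracket — a simple rule adequate for abstract prose.
#'
#' @param text a single string.
#' @return character vector of sentences.
#' @export
split_sentences <- function(text) {
  parts <- strsplit(text, "(?<=[.!?])\\s+(?=[A-Z0-9(\"])", perl = TRUE)[[1L]]
  trimws(parts[nzchar(trimws(parts))])
}

#' Read a corpus from JSONL or MEDLINE flat file
#'
#' JSONL records are `{"pmid": ..., "abstract": ...}` or
#' `{"pmid": ..., "sentences": [...], "parses": [...]}` (one object per
#' line). MEDLINE flat files use `PMID- ` and `AB  - ` fields with indented
#' continuation lines, records separated by blank lines. `format = "auto"`
#' sniffs the first non-empty line.
#'
#' @param path file path.
#' @param format `"auto"`, `"jsonl"` or `"medline"`.
#' @return an `sddp_corpus`.
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "medline")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (format == "auto") {
    first <- lines[nzchar(trimws(lines))][1L] %||% ""
    format <- if (startsWith(trimws(first), "{")) "jsonl" else "medline"
  }
  if (format == "jsonl") {
    recs <- lapply(which(nzchar(trimws(lines))), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                      error = function(e) {
                        stop(path, ", line ", i, ": malformed JSON record (",
                             conditionMessage(e), ")", call. = FALSE)
                      })
      if (is.null(rec$pmid)) {
        stop(path, ", line ", i, ": record lacks field 'pmid'", call. = FALSE)
      }
      rec
    })
    return(as_corpus(recs))
  }
  # MEDLINE flat file
  recs <- list(); cur <- NULL; field <- NULL
  line_no <- 0L
  flush <- function() {
    if (!is.null(cur)) {
      if (is.null(cur$pmid)) {
        stop(path, ": record ending at line ", line_no,
             " lacks field 'PMID'", call. = FALSE)
      }
      recs[[length(recs) + 1L]] <<- cur
    }
    cur <<- NULL; field <<- NULL
  }
  for (ln in lines) {
    line_no <- line_no + 1L
    if (!nzchar(trimws(ln))) { flush(); next }
    if (grepl("^[A-Z]{1,4}\\s*- ", ln)) {
      tag <- trimws(sub("-.*$", "", ln))
      val <- sub("^[A-Z]{1,4}\\s*- ", "", ln)
      if (is.null(cur)) cur <- list()
      if (tag == "PMID") { cur$pmid <- trimws(val); field <- NULL }
      else if (tag == "AB") { cur$abstract <- val; field <- "abstract" }
      else field <- NULL
    } else if (grepl("^\\s", ln) && !is.null(field)) {
      cur[[field]] <- paste(cur[[field]], trimws(ln))
    } else {
      stop(path, ", line ", line_no, ": malformed MEDLINE line", call. = FALSE)
    }
  }
  flush()
  as_corpus(recs)
}

#' Write a corpus as JSONL
#'
#' Records with parses keep them; plain records are written as
#' `{"pmid", "abstract"}`.
#'
#' @param corpus an `sddp_corpus`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "sddp_corpus"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (r in corpus) {
    obj <- if (is.null(r$parses)) {
      list(pmid = r$pmid, abstract = paste(r$sentences, collapse = " "))
    } else {
      list(pmid = r$pmid, sentences = r$sentences, parses = r$parses)
    }
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), con)
  }
  invisible(path)
}

# Parse sentence k of record r into a pronoun-annotated POST.
record_post <- function(rec, k, dict, pronouns = .default_pronouns,
                        coordinators = .default_coordinators) {
  tr <- if (!is.null(rec$parses)) {
    post_parse(rec$parses[[k]])
  } else {
    sentence_post(rec$sentences[[k]], coordinators = coordinators,
                  pronouns = pronouns)
  }
  resolve_pronouns(tr, dict, pronouns = pronouns)
}
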