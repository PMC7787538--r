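#' @importFrom stats setNames
#' @importFrom utils read.delim write.table head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded tie-breaks never perturb the global random stream.
#' With `seed = NULL` the code runs on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Log levels in increasing verbosity; default "warn" keeps outputs quiet so
# logging can never alter artifacts.
.log_levels <- c(quiet = 0L, warn = 1L, info = 2L, debug = 3L)

sddp_log <- function(level, ...) {
  threshold <- getOption("sddp.log_level", "warn")
  if (.log_levels[[level]] <= .log_levels[[threshold]]) {
    message("[sddp ", level, "] ", ...)
  }
  invisible(NULL)
}

#' Read a tab-separated file in the package dialect
#'
#' Tab-separated, UTF-8, `#` comment lines, no quoting.
#'
#' @param path file path.
#' @param col_names logical, does the first non-comment line hold column names?
#' @return a data.frame.
#' @export
read_tsv_sddp <- function(path, col_names = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, header = col_names, sep = "\t", quote = "",
             comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE, fileEncoding = "UTF-8")
}

#' Write a tab-separated file in the package dialect
#'
#' @param x data.frame.
#' @param path file path.
#' @param comments optional character vector written as leading `#` lines.
#' @return `path`, invisibly.
#' @export
write_tsv_sddp <- function(x, path, comments = NULL) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

# stable unordered-pair key
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}
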