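#' Read a molecular interaction network from SIF or 2-column TSV
#'
#' SIF lines are `a relation b` (whitespace-separated); 2-column TSV lines
#' are `a<TAB>b`. The result is an undirected simple igraph: self-loops are
#' dropped and duplicate edges deduplicated with a warning.
#'
#' @param path file path.
#' @return an undirected simple `igraph` with node names.
#' @export
read_sif <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  edges <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "[\t ]+")[[1L]]
    if (length(f) == 2L) f[c(1L, 2L)]
    else if (length(f) >= 3L) f[c(1L, 3L)]
    else stop(path, ", line ", i, ": expected 2 (TSV) or 3 (SIF) fields",
              call. = FALSE)
  })
  em <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  loops <- sum(igraph::which_loop(g))
  multi <- sum(igraph::which_multiple(g))
  if (loops) warning(loops, " self-loop(s) dropped from ", path)
  if (multi) warning(multi, " duplicate edge(s) deduplicated in ", path)
  igraph::simplify(g)
}

#' Write a network as SIF
#'
#' @param network an igraph with node names.
#' @param path file path.
#' @param relation relation label written in the middle column.
#' @return `path`, invisibly.
#' @export
write_sif <- function(network, path, relation = "interacts") {
  el <- igraph::as_edgelist(network)
  writeLines(paste(el[, 1L], relation, el[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Molecular pathway
#'
#' A pathway is a set of molecule ids with a designated non-empty subset of
#' marker molecules (the traceable biomarkers of the pathway).
#'
#' @param id pathway identifier.
#' @param molecules character vector of molecule ids (non-empty).
#' @param markers character vector, subset of `molecules`.
#' @return an object of class `pathway`.
#' @export
pathway <- function(id, molecules, markers = character(0)) {
  molecules <- unique(as.character(molecules))
  markers <- unique(as.character(markers))
  if (!length(molecules)) stop("pathway ", id, ": empty molecule set")
  if (!all(markers %in% molecules)) {
    stop("pathway ", id, ": markers must be a subset of molecules")
  }
  structure(list(id = as.character(id), molecules = molecules,
                 markers = markers), class = "pathway")
}

#' @export
print.pathway <- function(x, ...) {
  cat("pathway", x$id, "-", length(x$molecules), "molecules,",
      length(x$markers), "markers\n")
  invisible(x)
}

#' Read pathway membership from TSV
#'
#' Columns: `pathway_id`, `molecule_id`, `is_marker` (0/1).
#'
#' @param path file path.
#' @return named list of [pathway()] objects.
#' @export
read_pathways <- function(path) {
  df <- read_tsv_sddp(path)
  need <- c("pathway_id", "molecule_id", "is_marker")
  if (!all(need %in% names(df))) {
    stop("pathway TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(df$is_marker %in% c(0L, 1L))) {
    stop(path, ": is_marker must be 0 or 1")
  }
  out <- lapply(split(df, df$pathway_id), function(d) {
    pathway(d$pathway_id[1L], d$molecule_id,
            d$molecule_id[d$is_marker == 1L])
  })
  out[order(names(out))]
}

#' Write pathway membership to TSV
#'
#' @param pathways list of [pathway()] objects.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_pathways <- function(pathways, path) {
  rows <- lapply(pathways, function(p) {
    data.frame(pathway_id = p$id, molecule_id = p$molecules,
               is_marker = as.integer(p$molecules %in% p$markers))
  })
  write_tsv_sddp(do.call(rbind, rows), path)
}
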