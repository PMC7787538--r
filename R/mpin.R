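#' Build the molecular pathway interrelationships network (MPIN)
#'
#' Pathways become nodes; two pathways are linked iff they share at least
#' one molecule. For a linked pair the *lowest common molecule* `n_com` is
#' the shared molecule minimising the sum of its hierarchical levels in the
#' two pathways' forests (ties broken by smallest id); with `x_bar` and
#' `y_bar` the levels of `n_com` in the two forests, an arrow runs from the
#' more general pathway to the more specific one: `x_bar < y_bar` draws the
#' arrow from y to x (x is more specific). Equal levels leave the edge
#' undirected.
#'
#' @param pathways list of [pathway()] objects (at least 2).
#' @param network an undirected `igraph` with node names.
#' @param seed integer seed for MCT parent tie-breaks.
#' @param deterministic lexicographic tie-break, see [build_mct()].
#' @return an object of class `mpin`: list with `nodes` (pathway ids),
#'   `edges` (data.frame `x`, `y`, `n_com`, `x_bar`, `y_bar`, `direction`
#'   with direction in `"x->y"`, `"y->x"`, `"undirected"`) and `forests`.
#' @export
build_mpin <- function(pathways, network, seed = NULL, deterministic = FALSE) {
  if (length(pathways) < 2L) stop("need at least 2 pathways")
  ids <- vapply(pathways, function(p) p$id, "")
  if (anyDuplicated(ids)) stop("duplicate pathway ids")
  names(pathways) <- ids
  forests <- lapply(seq_along(pathways), function(i) {
    mct_forest(pathways[[i]], network,
               seed = if (is.null(seed)) NULL else seed + 1000L * i,
               deterministic = deterministic)
  })
  names(forests) <- ids
  rows <- list()
  # pairs follow input order: x is the earlier pathway, so swapping two
  # pathways in the input swaps the x/y roles (and hence the arrow notation)
  for (a in seq_along(ids)) {
    for (b in seq_along(ids)) {
      if (b <= a) next
      px <- pathways[[a]]; py <- pathways[[b]]
      shared <- intersect(px$molecules, py$molecules)
      if (!length(shared)) next
      fx <- forests[[px$id]]; fy <- forests[[py$id]]
      lev <- function(m, f) {
        d <- unlist(lapply(f, function(t) t$depth[m]))
        d <- d[!is.na(d)]
        if (length(d)) min(d) else NA_integer_
      }
      lx <- vapply(shared, lev, 0L, f = fx)
      ly <- vapply(shared, lev, 0L, f = fy)
      ok <- !is.na(lx) & !is.na(ly)
      if (!any(ok)) {
        rows[[length(rows) + 1L]] <- data.frame(
          x = px$id, y = py$id, n_com = NA_character_,
          x_bar = NA_integer_, y_bar = NA_integer_,
          direction = "undirected", stringsAsFactors = FALSE)
        next
      }
      cand <- sort(shared[ok])
      tot <- lx[cand] + ly[cand]
      ncom <- cand[which.min(tot)] # sort() above makes ties lexicographic
      xb <- lx[[ncom]]; yb <- ly[[ncom]]
      dir <- if (xb < yb) "y->x" else if (yb < xb) "x->y" else "undirected"
      rows[[length(rows) + 1L]] <- data.frame(
        x = px$id, y = py$id, n_com = ncom, x_bar = xb, y_bar = yb,
        direction = dir, stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(x = character(0), y = character(0), n_com = character(0),
               x_bar = integer(0), y_bar = integer(0),
               direction = character(0))
  }
  structure(list(nodes = sort(ids), edges = edges, forests = forests),
            class = "mpin")
}

#' @export
print.mpin <- function(x, ...) {
  cat("mpin:", length(x$nodes), "pathways,", nrow(x$edges), "edges (",
      sum(x$edges$direction != "undirected"), "directed )\n")
  invisible(x)
}

# Directed edges as (general -> specific) pairs: arrow "y->x" means x is the
# more specific side.
mpin_arrows <- function(mpin) {
  e <- mpin$edges[mpin$edges$direction != "undirected", , drop = FALSE]
  if (!nrow(e)) {
    return(data.frame(general = character(0), specific = character(0)))
  }
  data.frame(
    general = ifelse(e$direction == "y->x", e$y, e$x),
    specific = ifelse(e$direction == "y->x", e$x, e$y),
    stringsAsFactors = FALSE
  )
}

#' Write an MPIN edge list as TSV
#'
#' Columns: `x`, `y`, `direction`, `n_com`, `x_bar`, `y_bar`.
#'
#' @param mpin an `mpin`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_mpin <- function(mpin, path) {
  stopifnot(inherits(mpin, "mpin"))
  write_tsv_sddp(mpin$edges[, c("x", "y", "direction", "n_com",
                                "x_bar", "y_bar")], path)
}

#' Read an MPIN edge list from TSV
#'
#' Rebuilds an `mpin` object (without forests) from a [write_mpin()] file,
#' sufficient for rule generation.
#'
#' @param path file path.
#' @return an `mpin` (with empty `forests`).
#' @export
read_mpin <- function(path) {
  df <- read_tsv_sddp(path)
  need <- c("x", "y", "direction", "n_com", "x_bar", "y_bar")
  if (!all(need %in% names(df))) {
    stop("MPIN TSV must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[, c("x", "y", "n_com", "x_bar", "y_bar", "direction")]
  structure(list(nodes = sort(unique(c(df$x, df$y))), edges = df,
                 forests = list()),
            class = "mpin")
}

#' Export an MPIN as GraphML
#'
#' @param mpin an `mpin`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_mpin_graphml <- function(mpin, path) {
  e <- mpin$edges
  from <- ifelse(e$direction == "y->x", e$y, e$x)
  to <- ifelse(e$direction == "y->x", e$x, e$y)
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to,
               n_com = e$n_com, directed = e$direction != "undirected"),
    directed = TRUE,
    vertices = data.frame(name = mpin$nodes))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
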