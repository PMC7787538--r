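#' Build a molecular characteristic tree (MCT)
#'
#' Transforms the molecular interaction network into a single-parent,
#' shortest-path tree rooted at a marker molecule: multiple parentage is
#' removed by keeping, for every node, only the edge that maintains a
#' shortest path to the root. When several neighbours lie on a shortest
#' path, one is selected at random (seeded) — or lexicographically with
#' `deterministic = TRUE`. The tree spans exactly the connected component of
#' the root; depths equal breadth-first distances from the root by
#' construction (the BFS is implemented directly here; `igraph` distances
#' serve as an independent check in the test-suite).
#'
#' @param network an undirected `igraph` with node names.
#' @param root molecule id to root the tree at.
#' @param seed integer seed for the random parent tie-break, or `NULL` to
#'   use the current RNG stream.
#' @param deterministic if `TRUE`, break parent ties by smallest id instead
#'   of at random.
#' @return an object of class `mct`: list with `root`, `parent` (named
#'   character, one entry per non-root node) and `depth` (named integer).
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c, a - c)
#' build_mct(g, "a", seed = 1)
#' @export
build_mct <- function(network, root, seed = NULL, deterministic = FALSE) {
  vn <- igraph::V(network)$name
  if (is.null(vn)) stop("network vertices must be named")
  if (!root %in% vn) stop("root molecule not in network: ", root)
  adj <- igraph::as_adj_list(network)
  names(adj) <- vn
  depth <- setNames(rep(NA_integer_, length(vn)), vn)
  parent <- character(0)
  depth[[root]] <- 0L
  frontier <- root
  candidates <- list() # node -> neighbours at depth(node) - 1
  while (length(frontier)) {
    nxt <- character(0)
    for (u in frontier) {
      for (v in vn[as.integer(adj[[u]])]) {
        if (is.na(depth[[v]])) {
          depth[[v]] <- depth[[u]] + 1L
          nxt <- c(nxt, v)
          candidates[[v]] <- u
        } else if (depth[[v]] == depth[[u]] + 1L) {
          candidates[[v]] <- c(candidates[[v]], u)
        }
      }
    }
    frontier <- nxt
  }
  reached <- names(depth)[!is.na(depth)]
  pick <- function(v) {
    cand <- sort(unique(candidates[[v]]))
    if (length(cand) == 1L || deterministic) cand[[1L]]
    else cand[[sample.int(length(cand), 1L)]]
  }
  non_root <- setdiff(reached, root)
  parent <- with_seed(seed, vapply(non_root, pick, ""))
  structure(list(root = root, parent = parent,
                 depth = depth[reached][order(depth[reached],
                                              names(depth[reached]))]),
            class = "mct")
}

#' @export
print.mct <- function(x, ...) {
  cat("mct rooted at", x$root, "-", length(x$depth), "molecules, max depth",
      max(x$depth), "\n")
  kids <- split(names(x$parent), x$parent)
  rec <- function(node, indent) {
    cat(indent, node, "\n", sep = "")
    for (ch in sort(kids[[node]] %||% character(0))) {
      rec(ch, paste0(indent, "  "))
    }
  }
  rec(x$root, "")
  invisible(x)
}

#' @export
as.data.frame.mct <- function(x, ...) {
  nodes <- names(x$depth)
  data.frame(molecule = nodes,
             parent = ifelse(nodes == x$root, NA_character_,
                             unname(x$parent[nodes])),
             depth = unname(x$depth[nodes]),
             stringsAsFactors = FALSE)
}

#' Build the MCT forest of a pathway
#'
#' One characteristic tree per marker of the pathway, each rooted at that
#' marker and built over the subnetwork induced by the pathway's molecules.
#' Pathway molecules unreachable from every marker are excluded from the
#' forest and logged.
#'
#' @param pw a [pathway()].
#' @param network an undirected `igraph` with node names.
#' @param seed integer seed; each tree draws its tie-breaks from a stream
#'   derived from it.
#' @param deterministic lexicographic parent tie-break, see [build_mct()].
#' @return named list of `mct` objects (one per marker).
#' @export
mct_forest <- function(pw, network, seed = NULL, deterministic = FALSE) {
  stopifnot(inherits(pw, "pathway"))
  if (!length(pw$markers)) stop("pathway ", pw$id, ": no markers")
  vn <- igraph::V(network)$name
  missing <- setdiff(pw$markers, vn)
  if (length(missing)) {
    stop("pathway ", pw$id, ": marker(s) absent from network: ",
         paste(missing, collapse = ", "))
  }
  sub <- igraph::induced_subgraph(network,
                                  intersect(vn, pw$molecules))
  forest <- lapply(seq_along(pw$markers), function(i) {
    build_mct(sub, pw$markers[i],
              seed = if (is.null(seed)) NULL else seed + i - 1L,
              deterministic = deterministic)
  })
  names(forest) <- pw$markers
  covered <- unique(unlist(lapply(forest, function(t) names(t$depth))))
  dropped <- setdiff(intersect(pw$molecules, vn), covered)
  dropped <- union(dropped, setdiff(pw$molecules, vn))
  if (length(dropped)) {
    sddp_log("info", "pathway ", pw$id, ": ", length(dropped),
             " molecule(s) unreachable from any marker, excluded: ",
             paste(dropped, collapse = ", "))
  }
  forest
}

#' Hierarchical level of a molecule within a pathway's forest
#'
#' The level is the minimum depth of the molecule across the pathway's
#' characteristic trees (0 for a marker root).
#'
#' @param molecule molecule id.
#' @param forest a list of `mct` objects, e.g. from [mct_forest()].
#' @return non-negative integer level.
#' @export
molecule_level <- function(molecule, forest) {
  depths <- unlist(lapply(forest, function(t) t$depth[molecule]))
  depths <- depths[!is.na(depths)]
  if (!length(depths)) stop("molecule not in any tree of the forest: ", molecule)
  min(depths)
}
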