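#' Cyst lineage trees
#'
#' A `cyst_tree` represents a germline cyst as an unrooted tree: nodes are
#' cells, edges are ring canals (intercellular bridges left by incomplete
#' cytokinesis). Because every division is incomplete, a cyst formed by `k`
#' synchronous divisions has `2^k` cells and `2^k - 1` ring canals, and the
#' connectivity graph is always a tree.
#'
#' @param canals two-column integer matrix (or list of length-2 vectors) of
#'   unordered cell pairs joined by a ring canal.
#' @param cells optional integer vector of cell identifiers; defaults to the
#'   identifiers appearing in `canals` (or `1` for a single-cell cyst).
#' @param labels optional named integer vector mapping cells to canonical
#'   cell numbers `1..n`.
#' @return an object of class `cyst_tree` with elements `cells`, `canals`
#'   (sorted two-column matrix) and `labels`.
#' @examples
#' cyst_tree(rbind(c(1, 2), c(1, 3), c(2, 4)))  # the 4-cell chain 3-1-2-4
#' @export
cyst_tree <- function(canals = NULL, cells = NULL, labels = NULL) {
  if (is.null(canals) || length(canals) == 0L) {
    canals <- matrix(integer(0), ncol = 2)
  }
  if (is.list(canals)) canals <- do.call(rbind, canals)
  canals <- matrix(as.integer(canals), ncol = 2)
  canals <- cbind(pmin(canals[, 1], canals[, 2]),
                  pmax(canals[, 1], canals[, 2]))
  if (is.null(cells)) {
    cells <- if (nrow(canals)) sort(unique(as.integer(canals))) else 1L
  }
  cells <- sort(unique(as.integer(cells)))
  tr <- structure(list(cells = cells, canals = canals, labels = labels),
                  class = "cyst_tree")
  validate_cyst_tree(tr)
  tr
}

validate_cyst_tree <- function(tr) {
  n <- length(tr$cells)
  m <- nrow(tr$canals)
  if (m != n - 1L)
    stop("not a tree: ", n, " cells but ", m, " canals", call. = FALSE)
  if (m > 0L) {
    if (!all(tr$canals %in% tr$cells))
      stop("canal endpoint not among cells", call. = FALSE)
    if (any(tr$canals[, 1] == tr$canals[, 2]))
      stop("self-loop canal", call. = FALSE)
    if (anyDuplicated(paste(tr$canals[, 1], tr$canals[, 2])))
      stop("duplicate canal", call. = FALSE)
    # connectivity: |E| = |V| - 1 + acyclic <=> connected; check via BFS
    if (length(reachable_cells(tr, tr$cells[1])) != n)
      stop("not a tree: disconnected", call. = FALSE)
  }
  invisible(tr)
}

# adjacency list keyed by cell id (as character)
adjacency_list <- function(tr) {
  adj <- stats::setNames(vector("list", length(tr$cells)),
                         as.character(tr$cells))
  if (nrow(tr$canals)) {
    for (i in seq_len(nrow(tr$canals))) {
      a <- as.character(tr$canals[i, 1]); b <- as.character(tr$canals[i, 2])
      adj[[a]] <- c(adj[[a]], tr$canals[i, 2])
      adj[[b]] <- c(adj[[b]], tr$canals[i, 1])
    }
  }
  adj
}

reachable_cells <- function(tr, start) {
  adj <- adjacency_list(tr)
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Ring-canal count (degree) of every cell
#'
#' @param tr a [cyst_tree()].
#' @return named integer vector of degrees, one per cell.
#' @export
cyst_degrees <- function(tr) {
  d <- stats::setNames(integer(length(tr$cells)), as.character(tr$cells))
  if (nrow(tr$canals)) {
    tab <- table(as.integer(tr$canals))
    d[names(tab)] <- as.integer(tab)
  }
  d
}

#' @export
print.cyst_tree <- function(x, ...) {
  n <- length(x$cells)
  cat(sprintf("<cyst_tree> %d cell%s, %d ring canal%s\n",
              n, if (n == 1) "" else "s",
              nrow(x$canals), if (nrow(x$canals) == 1) "" else "s"))
  if (nrow(x$canals)) {
    deg <- sort(cyst_degrees(x), decreasing = TRUE)
    cat("  degree sequence:", paste(deg, collapse = " "), "\n")
  }
  if (!is.null(x$labels))
    cat("  canonical labels assigned\n")
  invisible(x)
}

#' @export
plot.cyst_tree <- function(x, ...) {
  g <- as_igraph_tree(x)
  set.seed(1L)
  igraph::plot.igraph(g, vertex.size = 18, vertex.color = "lightsteelblue",
                      vertex.label = igraph::V(g)$name, ...)
  invisible(x)
}

as_igraph_tree <- function(tr) {
  igraph::graph_from_data_frame(
    d = data.frame(from = as.character(tr$canals[, 1]),
                   to = as.character(tr$canals[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(tr$cells)))
}

#' Serialise / deserialise cyst trees as JSON
#'
#' The JSON dialect is `{"cells": [...], "canals": [[i,j], ...],
#' "labels": {...}}`.
#'
#' @param tr a [cyst_tree()].
#' @param path file path; for `tree_from_json`, a path or JSON string.
#' @return `tree_to_json` returns `path` invisibly; `tree_from_json` a
#'   [cyst_tree()].
#' @export
tree_to_json <- function(tr, path) {
  obj <- list(cells = tr$cells,
              canals = unname(lapply(seq_len(nrow(tr$canals)),
                                     function(i) tr$canals[i, ])))
  if (!is.null(tr$labels)) obj$labels <- as.list(tr$labels)
  jsonlite::write_json(obj, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname tree_to_json
#' @export
tree_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  labels <- if (!is.null(obj$labels)) unlist(obj$labels) else NULL
  canals <- obj$canals
  if (is.list(canals)) canals <- do.call(rbind, canals)
  cyst_tree(canals = canals, cells = obj$cells, labels = labels)
}

#' Rooted Newick-like export for display
#'
#' Roots the tree at `root` (canonical cell 1 by default) and writes nested
#' parentheses with cell identifiers as tip/node labels.
#'
#' @param tr a [cyst_tree()].
#' @param root cell id to root at.
#' @return a single string ending in `";"`.
#' @export
tree_to_newick <- function(tr, root = min(tr$cells)) {
  stopifnot(root %in% tr$cells)
  adj <- adjacency_list(tr)
  rec <- function(v, parent) {
    kids <- setdiff(adj[[as.character(v)]], parent)
    if (!length(kids)) return(as.character(v))
    paste0("(", paste(vapply(kids, rec, "", parent = v), collapse = ","),
           ")", v)
  }
  paste0(rec(root, NA_integer_), ";")
}
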