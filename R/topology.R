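#' The canonical maximally branched cyst tree
#'
#' In the female germline every division adds a new terminal cell, producing
#' a unique "maximally branched" topology at every stage. Labels follow the
#' convention that cell `i` divides at division `k` to produce cell
#' `i + 2^(k-1)`, with the mother retaining all of its prior ring canals; the
#' two cells that end up with four ring canals in the 16-cell cyst (the
#' pro-oocytes) are cells 1 and 2.
#'
#' @param n_cells cyst size, a power of 2 between 1 and 16.
#' @return a [cyst_tree()] with canonical labels.
#' @examples
#' canonical_max_branched(4)   # the chain 3-1-2-4
#' sort(cyst_degrees(canonical_max_branched(16)), decreasing = TRUE)
#' @export
canonical_max_branched <- function(n_cells) {
  if (length(n_cells) != 1L || is.na(n_cells) ||
      !(n_cells %in% c(1L, 2L, 4L, 8L, 16L)))
    stop("n_cells must be one of 1, 2, 4, 8, 16", call. = FALSE)
  n_cells <- as.integer(n_cells)
  canals <- NULL
  n <- 1L
  while (n < n_cells) {
    # division round: every cell i buds a new terminal daughter i + n
    canals <- rbind(canals, cbind(seq_len(n), seq_len(n) + n))
    n <- 2L * n
  }
  cells <- seq_len(n_cells)
  cyst_tree(canals = canals, cells = cells,
            labels = stats::setNames(cells, as.character(cells)))
}

#' Division choices of a cell
#'
#' At an incomplete division a cell's existing ring canals are partitioned
#' between the two daughters; the new canal always joins them. A degree-`d`
#' cell therefore has `2^(d-1)` distinct (unordered) choices. The choice
#' handing no existing canal to the new daughter is the "branching" choice
#' (the daughter is terminal); every other choice is an in-line division.
#'
#' @param tr a [cyst_tree()].
#' @param cell a cell id in `tr`.
#' @return list of integer vectors: neighbours handed to the new daughter.
#'   The empty vector (branching) is always first.
#' @export
division_choices <- function(tr, cell) {
  adj <- adjacency_list(tr)
  nb <- sort(adj[[as.character(cell)]])
  d <- length(nb)
  if (d == 0L) return(list(integer(0)))
  # subsets of neighbours up to complement: fix that the lowest neighbour
  # stays with the old cell, enumerate subsets of the rest
  rest <- nb[-1]
  subs <- list(integer(0))
  for (x in rest) subs <- c(subs, lapply(subs, function(s) c(s, x)))
  subs[order(lengths(subs))]
}

#' Synchronous division of every cell
#'
#' Replaces each cell `i` by two daughters — `i` (retaining the neighbours
#' not listed in its choice) and `i + N` (receiving the listed neighbours),
#' where `N` is the current cell count — joined by a new ring canal. With the
#' all-branching choice at every cell this reproduces
#' [canonical_max_branched()] stage by stage.
#'
#' @param tr a [cyst_tree()] whose cells are `1..N`.
#' @param choices list of integer vectors, one per cell in cell order: the
#'   neighbours handed to that cell's new daughter (see [division_choices()]).
#' @return a [cyst_tree()] with `2N` cells.
#' @export
divide_all <- function(tr, choices) {
  n <- length(tr$cells)
  if (!identical(tr$cells, seq_len(n)))
    stop("divide_all requires cells numbered 1..N", call. = FALSE)
  if (length(choices) != n)
    stop("need exactly one division choice per cell", call. = FALSE)
  adj <- adjacency_list(tr)
  for (i in seq_len(n)) {
    bad <- setdiff(choices[[i]], adj[[as.character(i)]])
    if (length(bad))
      stop("inconsistent choice: canal ", i, "-", bad[1],
           " is not incident to cell ", i, call. = FALSE)
  }
  new_canals <- cbind(seq_len(n), seq_len(n) + n)  # mother-daughter canals
  old <- tr$canals
  if (nrow(old)) {
    remap <- function(endpoint, other) {
      # endpoint keeps its id unless `other` was handed to its new daughter
      ifelse(mapply(function(e, o) o %in% choices[[e]], endpoint, other),
             endpoint + n, endpoint)
    }
    old <- cbind(remap(old[, 1], old[, 2]), remap(old[, 2], old[, 1]))
  }
  cyst_tree(canals = rbind(old, new_canals), cells = seq_len(2L * n))
}

# ---- canonical form (AHU encoding rooted at the centroid) ----------------

tree_centroids <- function(tr) {
  n <- length(tr$cells)
  if (n == 1L) return(tr$cells)
  adj <- adjacency_list(tr)
  deg <- cyst_degrees(tr)
  alive <- stats::setNames(rep(TRUE, n), as.character(tr$cells))
  remaining <- n
  leaves <- tr$cells[deg[as.character(tr$cells)] <= 1L]
  while (remaining > 2L) {
    remaining <- remaining - length(leaves)
    nxt <- integer(0)
    for (v in leaves) {
      alive[as.character(v)] <- FALSE
      for (u in adj[[as.character(v)]]) {
        cu <- as.character(u)
        if (alive[cu]) {
          deg[cu] <- deg[cu] - 1L
          if (deg[cu] == 1L) nxt <- c(nxt, u)
        }
      }
    }
    leaves <- nxt
  }
  sort(tr$cells[alive[as.character(tr$cells)]])
}

ahu_encode <- function(adj, root, parent = NA_integer_) {
  kids <- setdiff(adj[[as.character(root)]], parent)
  if (!length(kids)) return("()")
  enc <- vapply(kids, function(k) ahu_encode(adj, k, root), "")
  paste0("(", paste(sort(enc), collapse = ""), ")")
}

#' Canonical string encoding of an unrooted tree
#'
#' AHU encoding rooted at the tree centroid; with two centroids both
#' rootings are encoded and the lexicographically smaller string is kept.
#' Two trees are isomorphic iff their canonical strings are equal.
#'
#' @param tr a [cyst_tree()].
#' @return a single string.
#' @export
tree_canonical_form <- function(tr) {
  adj <- adjacency_list(tr)
  enc <- vapply(tree_centroids(tr), function(c0) ahu_encode(adj, c0), "")
  min(enc)
}

#' Test two cyst trees for isomorphism
#'
#' @param a,b [cyst_tree()] objects.
#' @return logical.
#' @export
trees_isomorphic <- function(a, b) {
  if (length(a$cells) != length(b$cells)) return(FALSE)
  identical(tree_canonical_form(a), tree_canonical_form(b))
}

#' Is a cyst maximally branched?
#'
#' @param tr a [cyst_tree()] with a power-of-2 cell count at most 16.
#' @return logical: is `tr` isomorphic to
#'   [canonical_max_branched()] of the same size?
#' @export
is_max_branched <- function(tr) {
  trees_isomorphic(tr, canonical_max_branched(length(tr$cells)))
}

#' Enumerate cyst topologies reachable by one synchronous division
#'
#' Applies [divide_all()] over the Cartesian product of every cell's
#' division choices and collapses the products to isomorphism classes.
#' Reproduces the field's counts: 1 four-cell topology from the 2-cell cyst,
#' 3 eight-cell topologies from the 4-cell chain (1 maximally branched), and
#' 36 sixteen-cell topologies from the maximally branched 8-cell cyst
#' (1 maximally branched).
#'
#' @param start a [cyst_tree()] with at most 8 cells (product-space guard).
#' @return list with `classes` (one representative [cyst_tree()] per
#'   isomorphism class), `n_classes`, `n_max_branched`, and `n_products`
#'   (size of the labelled choice product).
#' @examples
#' enumerate_topologies(canonical_max_branched(4))$n_classes  # 3
#' @export
enumerate_topologies <- function(start) {
  n <- length(start$cells)
  if (n > 8L)
    stop("enumeration limited to starts of at most 8 cells", call. = FALSE)
  per_cell <- lapply(start$cells, function(c0) division_choices(start, c0))
  idx <- do.call(expand.grid, lapply(per_cell, seq_along))
  reps <- list(); keys <- character(0)
  for (r in seq_len(nrow(idx))) {
    ch <- lapply(seq_len(n), function(i) per_cell[[i]][[idx[r, i]]])
    child <- divide_all(start, ch)
    key <- tree_canonical_form(child)
    if (!key %in% keys) {
      keys <- c(keys, key)
      reps <- c(reps, list(child))
    }
  }
  list(classes = reps,
       n_classes = length(reps),
       n_max_branched = sum(vapply(reps, is_max_branched, logical(1))),
       n_products = nrow(idx))
}

# ---- subtree embeddability ----------------------------------------------

# maximum bipartite matching by augmenting paths; ok[i, j] marks admissible
# pairs. Returns the matching size.
bipartite_match_size <- function(ok) {
  nl <- nrow(ok); nr <- ncol(ok)
  if (nl == 0L) return(0L)
  match_r <- rep(0L, nr)
  try_kuhn <- function(i, seen) {
    for (j in seq_len(nr)) {
      if (ok[i, j] && !seen[j]) {
        seen[j] <- TRUE
        if (match_r[j] == 0L) {
          match_r[j] <<- i
          return(list(found = TRUE, seen = seen))
        }
        res <- try_kuhn(match_r[j], seen)
        seen <- res$seen
        if (res$found) {
          match_r[j] <<- i
          return(list(found = TRUE, seen = seen))
        }
      }
    }
    list(found = FALSE, seen = seen)
  }
  size <- 0L
  for (i in seq_len(nl)) {
    if (try_kuhn(i, rep(FALSE, nr))$found) size <- size + 1L
  }
  size
}

#' Can a fragment's topology be embedded in a host cyst?
#'
#' Tests whether `fragment_tree` is isomorphic to a connected subtree of
#' `host` — e.g. whether the tree traced by a partially fragmented fusome is
#' consistent with a maximally branched cyst. Uses the classic rooted
#' dynamic programme over (fragment node, host node, excluded host parent)
#' with a bipartite matching of children at each step.
#'
#' @param fragment_tree,host [cyst_tree()] objects.
#' @return logical.
#' @examples
#' is_embeddable(canonical_max_branched(8), canonical_max_branched(16))
#' @export
is_embeddable <- function(fragment_tree, host) {
  nf <- length(fragment_tree$cells); nh <- length(host$cells)
  if (nf > nh) return(FALSE)
  if (nf <= 1L) return(TRUE)
  fadj <- adjacency_list(fragment_tree)
  hadj <- adjacency_list(host)
  root_f <- fragment_tree$cells[1]
  memo <- new.env(parent = emptyenv())
  # can the fragment subtree at f (entered from fparent) embed at host node h
  # (entered from hparent)?
  embeds <- function(f, fparent, h, hparent) {
    key <- paste(f, fparent, h, hparent)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    fk <- setdiff(fadj[[as.character(f)]], fparent)
    hk <- setdiff(hadj[[as.character(h)]], hparent)
    res <- if (length(fk) > length(hk)) {
      FALSE
    } else if (!length(fk)) {
      TRUE
    } else {
      ok <- matrix(FALSE, length(fk), length(hk))
      for (i in seq_along(fk)) for (j in seq_along(hk))
        ok[i, j] <- embeds(fk[i], f, hk[j], h)
      bipartite_match_size(ok) == length(fk)
    }
    memo[[key]] <- res
    res
  }
  for (h in host$cells)
    if (embeds(root_f, NA_integer_, h, NA_integer_)) return(TRUE)
  FALSE
}
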