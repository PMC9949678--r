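test_that("canonical maximally branched trees have the stereotyped shape", {
  t2 <- canonical_max_branched(2)
  expect_equal(t2$canals, cbind(1L, 2L))

  # 4-cell cyst is the linear chain 3-1-2-4
  t4 <- canonical_max_branched(4)
  expect_true(trees_isomorphic(t4, path_tree(4)))
  expect_equal(sort(cyst_degrees(t4)[c("3", "1", "2", "4")]),
               sort(c(`3` = 1L, `1` = 2L, `2` = 2L, `4` = 1L)))

  t16 <- canonical_max_branched(16)
  expect_equal(nrow(t16$canals), 15L)
  deg <- cyst_degrees(t16)
  expect_equal(sort(as.integer(deg), decreasing = TRUE),
               c(4, 4, 3, 3, 2, 2, 2, 2, rep(1, 8)))
  # the pro-oocytes (degree 4) are cells 1 and 2
  expect_setequal(names(deg)[deg == 4L], c("1", "2"))

  expect_error(canonical_max_branched(6), "one of")
  expect_error(canonical_max_branched(32), "one of")
})

test_that("division choices follow the 2^(d-1) rule", {
  t8 <- canonical_max_branched(8)
  deg <- cyst_degrees(t8)
  for (cell in t8$cells) {
    ch <- division_choices(t8, cell)
    expect_length(ch, 2^(deg[[as.character(cell)]] - 1L))
    expect_identical(ch[[1]], integer(0))  # branching choice first
  }
  # terminal cell: exactly one (forced branching) choice
  expect_length(division_choices(t8, 8L), 1L)
})

test_that("synchronous division grows trees correctly", {
  # 1-cell -> 2-cell
  t1 <- cyst_tree(cells = 1L)
  t2 <- divide_all(t1, list(integer(0)))
  expect_equal(length(t2$cells), 2L)

  # 2-cell, both forced -> the unique 4-cell path
  t4 <- divide_all(t2, list(integer(0), integer(0)))
  expect_true(trees_isomorphic(t4, path_tree(4)))

  # terminal cell division yields one internal and one terminal daughter
  deg4 <- cyst_degrees(t4)
  expect_equal(sort(as.integer(deg4)), c(1, 1, 2, 2))

  # all-branching choices reproduce the canonical tree at every stage
  tr <- cyst_tree(cells = 1L)
  for (k in 1:4) {
    tr <- divide_all(tr, rep(list(integer(0)), length(tr$cells)))
    expect_true(trees_isomorphic(tr, canonical_max_branched(2^k)))
  }

  # inconsistent choice: canal not incident to the cell
  expect_error(divide_all(t2, list(c(5L), integer(0))), "inconsistent")
})

test_that("tree isomorphism matches the igraph oracle", {
  t4 <- path_tree(4)
  expect_true(trees_isomorphic(t4, t4))
  expect_false(trees_isomorphic(path_tree(4), star_tree(4)))

  # on the chain a-b-c-d, 'b branches, c in-line' and 'b in-line, c
  # branches' give isomorphic 8-cell products (mirror symmetry)
  chain <- canonical_max_branched(4)  # 3-1-2-4 with internal cells 1, 2
  mk <- function(inline_cell) {
    ch <- rep(list(integer(0)), 4)
    nb <- sort(fusomekit:::adjacency_list(chain)[[as.character(inline_cell)]])
    ch[[inline_cell]] <- nb[2]  # hand one canal over: in-line division
    divide_all(chain, ch)
  }
  expect_true(trees_isomorphic(mk(1L), mk(2L)))
  expect_true(iso_oracle(mk(1L), mk(2L)))

  # property: agree with igraph on random tree pairs
  for (s in 1:20) {
    a <- random_tree(7, s)
    b <- random_tree(7, s + 100)
    expect_identical(trees_isomorphic(a, b), as.logical(iso_oracle(a, b)),
                     info = paste("seed", s))
  }
})

test_that("topology enumeration reproduces the 1 / 3 / 36 counts", {
  e2 <- enumerate_topologies(canonical_max_branched(2))
  expect_equal(e2$n_classes, 1L)

  e4 <- enumerate_topologies(canonical_max_branched(4))
  expect_equal(e4$n_classes, 3L)
  expect_equal(e4$n_max_branched, 1L)

  e8 <- enumerate_topologies(canonical_max_branched(8))
  expect_equal(e8$n_classes, 36L)
  expect_equal(e8$n_max_branched, 1L)
  # labelled product space: 2^(sum(d_i - 1)) combinations
  expect_equal(e8$n_products,
               2^sum(cyst_degrees(canonical_max_branched(8)) - 1L))

  expect_error(enumerate_topologies(canonical_max_branched(16)), "at most 8")
})

test_that("enumeration classes agree with a brute-force igraph partition", {
  for (start in list(canonical_max_branched(2), canonical_max_branched(4))) {
    res <- enumerate_topologies(start)
    # oracle: walk the labelled product again, classify purely with igraph
    per_cell <- lapply(start$cells, function(c0) division_choices(start, c0))
    idx <- do.call(expand.grid, lapply(per_cell, seq_along))
    reps <- list()
    for (r in seq_len(nrow(idx))) {
      ch <- lapply(seq_along(start$cells),
                   function(i) per_cell[[i]][[idx[r, i]]])
      child <- divide_all(start, ch)
      if (!any(vapply(reps, iso_oracle, logical(1), b = child)))
        reps <- c(reps, list(child))
    }
    expect_equal(res$n_classes, length(reps))
  }
})

test_that("edge counts follow 2^k - 1 through synchronous divisions", {
  tr <- cyst_tree(cells = 1L)
  for (k in 1:4) {
    tr <- divide_all(tr, rep(list(integer(0)), length(tr$cells)))
    expect_equal(nrow(tr$canals), 2^k - 1)
  }
})

test_that("subtree embeddability is correct and matches brute force", {
  t16 <- canonical_max_branched(16)
  expect_true(is_embeddable(canonical_max_branched(8), t16))
  expect_true(is_embeddable(canonical_max_branched(4), t16))

  # longest path in the canonical 16-cell tree has 8 nodes (diameter 7)
  expect_equal(igraph::diameter(fusomekit:::as_igraph_tree(t16)), 7)
  expect_true(is_embeddable(path_tree(8), t16))
  expect_false(is_embeddable(path_tree(9), t16))

  # max degree of the host is 4, so a 5-star cannot embed
  expect_false(is_embeddable(star_tree(6), t16))

  # reflexivity on random trees
  for (s in 1:10) {
    tr <- random_tree(9, s)
    expect_true(is_embeddable(tr, tr), info = paste("seed", s))
  }

  # brute-force oracle: enumerate connected vertex subsets of the host and
  # compare by igraph isomorphism
  brute_embeddable <- function(frag, host) {
    n <- length(host$cells)
    k <- length(frag$cells)
    subsets <- utils::combn(host$cells, k, simplify = FALSE)
    for (ss in subsets) {
      keep <- host$canals[host$canals[, 1] %in% ss &
                            host$canals[, 2] %in% ss, , drop = FALSE]
      if (nrow(keep) != k - 1) next  # not a connected subtree
      sub <- tryCatch(cyst_tree(keep, cells = ss), error = function(e) NULL)
      if (!is.null(sub) && iso_oracle(frag, sub)) return(TRUE)
    }
    FALSE
  }
  host <- canonical_max_branched(8)
  for (s in 1:12) {
    frag <- random_tree(5, s + 300)
    expect_identical(is_embeddable(frag, host),
                     brute_embeddable(frag, host),
                     info = paste("seed", s))
  }

  # monotone under taking connected subtrees of the fragment: dropping a
  # leaf preserves embeddability
  for (s in 1:8) {
    frag <- random_tree(6, s + 600)
    if (!is_embeddable(frag, host)) next
    deg <- cyst_degrees(frag)
    leaf <- as.integer(names(deg)[deg == 1L][1])
    keep <- setdiff(frag$cells, leaf)
    sub <- cyst_tree(frag$canals[frag$canals[, 1] != leaf &
                                   frag$canals[, 2] != leaf, , drop = FALSE],
                     cells = keep)
    expect_true(is_embeddable(sub, host), info = paste("seed", s))
  }
})

test_that("trees serialise to JSON and Newick and back", {
  tr <- canonical_max_branched(8)
  p <- withr::local_tempfile(fileext = ".json")
  tree_to_json(tr, p)
  back <- tree_from_json(p)
  expect_equal(back$canals, tr$canals)
  expect_true(trees_isomorphic(back, tr))

  nwk <- tree_to_newick(tr, root = 1L)
  expect_match(nwk, ";$")
  # every cell appears in the string
  for (c0 in tr$cells) expect_match(nwk, as.character(c0))
})
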