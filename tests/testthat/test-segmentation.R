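test_that("probability thresholding behaves", {
  z <- array(0, c(4, 4, 4))
  expect_error(threshold_probabilities(voxel_grid(z), 0.5), "empty class")

  z[1, 1, 1] <- 0.4; z[2, 2, 2] <- 0.6
  m <- threshold_probabilities(voxel_grid(z), 0.5)
  expect_equal(sum(m$values), 1L)
  expect_equal(m$values[2, 2, 2], 1L)

  # blurred render thresholded at 0.5 recovers the solid within 10%
  img <- render_cyst(render_config(canonical_max_branched(2),
                                   blur_sigma_nm = 150, seed = 3))
  mask <- threshold_probabilities(img$fusome_prob, 0.5)
  expect_lt(abs(sum(mask$values) - sum(img$fusome$values)) /
              sum(img$fusome$values), 0.10)
})

test_that("fusome extraction picks components by mode", {
  z <- array(0L, c(30, 10, 10))
  z[2:25, 2:6, 2:6] <- 1L      # 2400 voxels
  z[28:29, 8:9, 8:9] <- 1L     # 8 voxels, disjoint
  g <- voxel_grid(z)
  fem <- extract_fusome(g, "female")
  expect_length(fem, 1L)
  expect_length(fem[[1]]$indices, sum(z) - 8L)

  male <- extract_fusome(g, "male", min_voxels = 5L)
  expect_length(male, 2L)
  expect_gte(length(male[[1]]$indices), length(male[[2]]$indices))
  expect_length(extract_fusome(g, "male", min_voxels = 50L), 1L)
})

test_that("closed loops are recognised by their Euler characteristic", {
  # solid box: chi = 1, not a ring
  box <- as.matrix(expand.grid(1:4, 1:4, 1:4))
  expect_equal(fusomekit:::euler_characteristic(box), 1L)
  # box with a through-hole: a handle, chi = 0
  holed <- box[!(box[, 1] %in% 2:3 & box[, 2] %in% 2:3), ]
  expect_equal(fusomekit:::euler_characteristic(holed), 0L)

  z <- array(0L, c(12, 12, 6))
  for (r in seq_len(nrow(holed))) z[holed[r, 1], holed[r, 2], holed[r, 3]] <- 1L
  rings <- detect_rings(voxel_grid(z, c(100, 100, 100)))
  expect_length(rings, 1L)

  solid <- array(0L, c(8, 8, 8)); solid[2:6, 2:6, 2:6] <- 1L
  expect_warning(r0 <- detect_rings(voxel_grid(solid)), "no closed-loop")
  expect_length(r0, 0L)
})

test_that("rendered tori are detected with the right geometry", {
  img <- render_cyst(render_config(canonical_max_branched(2), seed = 4))
  rings <- detect_rings(img$rings)
  expect_length(rings, 1L)
  r <- rings[[1]]
  # radius within a voxel of the configured ring radius
  expect_lt(abs(r$radius_nm - 550), 220)
  # centroid at the configured ring position
  expect_lt(sqrt(sum((r$centroid_nm - img$truth$ring_centers_nm[1, ])^2)),
            300)
  # plane normal parallel (up to sign) to the bridge direction
  expect_gt(abs(sum(r$normal * img$truth$ring_normals[1, ])), 0.95)

  img4 <- render_cyst(render_config(canonical_max_branched(4), seed = 4))
  expect_length(detect_rings(img4$rings), 3L)
})

test_that("splitting at rings conserves volume and counts fragments", {
  img <- render_cyst(render_config(canonical_max_branched(2),
                                   cell_volumes = c(7, 3), seed = 2))
  comp <- extract_fusome(threshold_probabilities(img$fusome), "female")[[1]]
  rings <- detect_rings(img$rings)
  sp <- split_at_rings(comp, rings)
  expect_length(sp$fragments, 2L)
  expect_equal(sum(lengths(lapply(sp$fragments, `[[`, "indices"))),
               length(comp$indices))  # exact voxel conservation

  # no rings: the whole component is one fragment
  sp0 <- split_at_rings(comp, list())
  expect_length(sp0$fragments, 1L)

  # 4-cell chain: 4 fragments within 5% of ground truth
  img4 <- render_cyst(render_config(canonical_max_branched(4),
                                    cell_volumes = c(4.75, 2.75, 1.25, 1.25),
                                    seed = 6))
  comp4 <- extract_fusome(threshold_probabilities(img4$fusome), "female")[[1]]
  rings4 <- detect_rings(img4$rings)
  sp4 <- split_at_rings(comp4, rings4)
  expect_length(sp4$fragments, 4L)
  gt <- sort(img4$truth$cell_volumes_um3, decreasing = TRUE)
  got <- sort(vapply(sp4$fragments, fusomekit:::component_volume_um3,
                     numeric(1)), decreasing = TRUE)
  expect_equal(got, unname(gt), tolerance = 0.05)

  # recursion-order invariance: shuffled ring order leaves the fragment
  # volume multiset unchanged within 2% per fragment
  base <- sort(got)
  for (s in 1:10) {
    set.seed(s)
    perm <- sample(seq_along(rings4))
    rings_p <- lapply(seq_along(perm), function(i) {
      r <- rings4[[perm[i]]]; r$id <- i; r
    })
    sp_p <- split_at_rings(comp4, rings_p)
    got_p <- sort(vapply(sp_p$fragments, fusomekit:::component_volume_um3,
                         numeric(1)))
    expect_equal(got_p, base, tolerance = 0.02)
  }
})

test_that("adjacency recovery and canonical labelling work end to end", {
  pl <- solve_plug_volumes(0.7, 0.5)
  img8 <- render_cyst(render_config(canonical_max_branched(8),
                                    cell_volumes = predict_fractions(pl, 8),
                                    seed = 8))
  out <- reconstruct_cyst(img8$fusome, img8$rings, mode = "female")
  expect_true(trees_isomorphic(out$adjacency, canonical_max_branched(8)))

  fr <- out$fragments
  # cell 1: maximal ring-canal count and the larger of the central pair
  expect_equal(fr$n_rings[fr$label == 1], max(fr$n_rings))
  expect_gte(fr$volume_um3[fr$label == 1], fr$volume_um3[fr$label == 2])
  # labels are a bijection consistent with the canonical topology
  expect_setequal(fr$label, 1:8)
  relab <- out$tree
  mapped <- cbind(out$label_map[as.character(relab$canals[, 1])],
                  out$label_map[as.character(relab$canals[, 2])])
  canon <- canonical_max_branched(8)$canals
  expect_setequal(paste(pmin(mapped[, 1], mapped[, 2]),
                        pmax(mapped[, 1], mapped[, 2])),
                  paste(canon[, 1], canon[, 2]))
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-12)

  # 2-cell cyst with volumes 70/30
  img2 <- render_cyst(render_config(canonical_max_branched(2),
                                    cell_volumes = c(7, 3), seed = 2))
  out2 <- reconstruct_cyst(img2$fusome, img2$rings, mode = "female")
  expect_equal(out2$fragments$label[order(out2$fragments$volume_um3,
                                          decreasing = TRUE)], 1:2)
  expect_lt(abs(out2$fragments$fraction[out2$fragments$label == 1] - 0.70),
            0.02)

  # exact volume tie: deterministic tie-break on fragment id, flagged
  tie <- assign_labels(canonical_max_branched(2), c(5, 5))
  expect_true(tie$tie)
  expect_equal(tie$label_map[["1"]], 1L)

  # non-canonical topology refuses labelling
  expect_error(assign_labels(path_tree(16), rep(1, 16)),
               "labelling unavailable")
})

test_that("the Hungarian solver matches brute force on random instances", {
  set.seed(77)
  for (n in c(2, 3, 4, 5)) {
    for (rep in 1:5) {
      cost <- matrix(runif(n * n), n, n)
      asg <- fusomekit:::hungarian_assignment(cost)
      expect_setequal(asg, seq_len(n))
      expect_equal(sum(cost[cbind(seq_len(n), asg)]),
                   brute_assignment_cost(cost), tolerance = 1e-12)
    }
  }
})

test_that("fusome-connected cell counts follow traversed rings", {
  img <- render_cyst(render_config(canonical_max_branched(4), seed = 4))
  comp <- extract_fusome(threshold_probabilities(img$fusome), "female")[[1]]
  rings <- detect_rings(img$rings)
  cc <- fusome_connected_cells(comp, rings)
  expect_equal(cc$n_cells, 4L)
  expect_true(cc$power_of_2)

  # an isolated blob away from all rings counts as one cell
  z <- array(0L, dim(img$fusome$values))
  z[2:4, 2:4, 2:4] <- 1L
  blob <- extract_fusome(voxel_grid(z, img$fusome$voxel_size_nm), "female")[[1]]
  cc0 <- fusome_connected_cells(blob, rings)
  expect_equal(cc0$n_cells, 1L)
  expect_true(cc0$power_of_2)

  # fragmented male render: census counts match the planted fragmentation
  imgm <- render_cyst(render_config(canonical_max_branched(8), p_frag = 0.4,
                                    seed = 21))
  res <- reconstruct_cyst(imgm$fusome, imgm$rings, mode = "male")
  dropped <- imgm$truth$fragmented_edges
  keep <- canonical_max_branched(8)$canals[setdiff(1:7, dropped), ,
                                           drop = FALSE]
  g <- igraph::graph_from_edgelist(apply(keep, 2, as.character),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, 8 - igraph::vcount(g))
  gt_largest <- max(igraph::components(g)$csize)
  expect_equal(res[[1]]$n_cells, gt_largest)
})
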