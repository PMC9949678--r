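#' Configuration for model-drawn volume tables
#'
#' States the simulated world for the growth-model data generator: true
#' parameters, groupwise ratio, replication and multiplicative noise.
#' Defaults follow the measured setting — `alpha = 0.7` (the larger 2-cell
#' fragment holds ~70% of the fusome), `beta = 0.5` (plugs shared evenly),
#' ratio 2:1:1:1, 12 cysts per stage, lognormal noise sigma = 0.05.
#'
#' @param alpha_true,beta_true generating parameters (feasible:
#'   `beta_true < alpha_true`).
#' @param group_ratios 16-cell groupwise ratio (see [solve_plug_volumes()]).
#' @param n_cysts_per_stage replicates per stage.
#' @param noise_sigma sdlog of the multiplicative lognormal volume noise.
#' @param seed integer; fully determines the output.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(alpha_true = 0.7, beta_true = 0.5,
                              group_ratios = c(2, 1, 1, 1),
                              n_cysts_per_stage = 12, noise_sigma = 0.05,
                              seed = 1L) {
  stopifnot(noise_sigma >= 0, n_cysts_per_stage >= 1)
  structure(list(alpha_true = alpha_true, beta_true = beta_true,
                 group_ratios = group_ratios,
                 n_cysts_per_stage = as.integer(n_cysts_per_stage),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a per-cell fusome volume table
#'
#' Draws, for each stage `n` in 2/4/8/16 and each replicate cyst, per-cell
#' volumes `T_k * f_i(alpha*, beta*) * exp(N(0, sigma))` with `v0 = 1`
#' (volumes are in spectrosome units; only fractions enter the fit). The
#' generating fractions are recorded alongside as ground truth.
#'
#' @param config a [simulation_config()].
#' @return data frame with columns `cyst_id`, `stage`, `cell_label`,
#'   `volume_um3`, `true_fraction`.
#' @examples
#' tab <- simulate_volume_table(simulation_config(seed = 42))
#' aggregate(volume_um3 ~ stage, tab, length)
#' @export
simulate_volume_table <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  plugs <- solve_plug_volumes(config$alpha_true, config$beta_true,
                              config$group_ratios)
  if (!plugs$feasible)
    stop("infeasible generating parameters: negative plug volume",
         call. = FALSE)
  set.seed(config$seed)
  rows <- list()
  for (k in 1:4) {
    n <- 2L^k
    f <- predict_fractions(plugs, n)
    Tk <- plugs$total[k]
    for (r in seq_len(config$n_cysts_per_stage)) {
      noise <- if (config$noise_sigma > 0)
        stats::rlnorm(n, 0, config$noise_sigma) else rep(1, n)
      rows[[length(rows) + 1L]] <- data.frame(
        cyst_id = sprintf("s%d_c%02d", n, r),
        stage = n, cell_label = seq_len(n),
        volume_um3 = Tk * f * noise,
        true_fraction = f)
    }
  }
  do.call(rbind, rows)
}

#' Configuration for rendered voxel cysts
#'
#' States the geometry of the synthetic microscopy world: a cyst tree is
#' embedded in 3D, each cell's fusome is a ball of prescribed volume, each
#' ring canal a torus encircling the cylindrical fusome bridge between
#' sister cells. Defaults keep every structure resolved at the default
#' anisotropic voxel size (the tube and torus minor radii exceed the z
#' step), with length scales loosely matching germarium cysts (cell bodies
#' a few microns apart, ring canals ~1 um across).
#'
#' @param tree a [cyst_tree()].
#' @param cell_volumes relative per-cell fusome volumes in cell-id order
#'   (default: equal). Only ratios matter; balls are scaled to
#'   `mean_cell_radius_nm`.
#' @param cell_spacing_nm distance between adjacent cell centres.
#' @param mean_cell_radius_nm radius of a cell ball at the mean volume.
#' @param tube_radius_nm radius of the fusome bridge cylinders.
#' @param ring_radius_nm major radius of the ring-canal tori.
#' @param ring_minor_nm minor (tube) radius of the tori.
#' @param voxel_size_nm `(dx, dy, dz)`; default `(100, 100, 200)`
#'   (anisotropic, as in confocal stacks).
#' @param blur_sigma_nm optional Gaussian blur to emit probability maps.
#' @param p_frag probability of deleting each bridge mid-segment (male-style
#'   fusome fragmentation); 0 keeps the fusome fully connected.
#' @param seed integer seed (layout and fragmentation).
#' @return a list of class `render_config`.
#' @export
render_config <- function(tree, cell_volumes = NULL,
                          cell_spacing_nm = 3600,
                          mean_cell_radius_nm = 950,
                          tube_radius_nm = 250,
                          ring_radius_nm = 550,
                          ring_minor_nm = 220,
                          voxel_size_nm = c(100, 100, 200),
                          blur_sigma_nm = 0,
                          p_frag = 0,
                          seed = 1L) {
  stopifnot(inherits(tree, "cyst_tree"), length(voxel_size_nm) == 3L,
            all(voxel_size_nm > 0), p_frag >= 0, p_frag <= 1)
  n <- length(tree$cells)
  if (!identical(tree$cells, seq_len(n)))
    stop("render_config requires cells numbered 1..n", call. = FALSE)
  if (is.null(cell_volumes)) cell_volumes <- rep(1, n)
  stopifnot(length(cell_volumes) == n, all(cell_volumes > 0))
  structure(list(tree = tree, cell_volumes = cell_volumes,
                 cell_spacing_nm = cell_spacing_nm,
                 mean_cell_radius_nm = mean_cell_radius_nm,
                 tube_radius_nm = tube_radius_nm,
                 ring_radius_nm = ring_radius_nm,
                 ring_minor_nm = ring_minor_nm,
                 voxel_size_nm = voxel_size_nm,
                 blur_sigma_nm = blur_sigma_nm,
                 p_frag = p_frag, seed = as.integer(seed)),
            class = "render_config")
}

# seeded 3D force-directed embedding of the tree, rescaled so the closest
# adjacent cells sit cell_spacing apart; rejects layouts whose non-adjacent
# cells collide, whose edges stretch too unevenly, or whose ring sites
# (edge midpoints) crowd each other
layout_tree_3d <- function(tree, spacing, seed, ring_clearance = 0,
                           max_tries = 40L) {
  n <- length(tree$cells)
  if (n == 1L) return(matrix(0, 1, 3))
  g <- as_igraph_tree(tree)
  adj_pairs <- tree$canals
  for (try in seq_len(max_tries)) {
    set.seed(seed + 1000L * (try - 1L))
    xyz <- igraph::layout_with_fr(g, dim = 3, niter = 1000)
    xyz <- xyz[match(as.character(tree$cells), igraph::V(g)$name), ,
               drop = FALSE]
    d_adj <- sqrt(rowSums((xyz[adj_pairs[, 1], , drop = FALSE] -
                           xyz[adj_pairs[, 2], , drop = FALSE])^2))
    xyz <- xyz * spacing / min(d_adj)
    # inflate, within reason, until ring sites (edge midpoints) are clear
    if (nrow(adj_pairs) > 1L && ring_clearance > 0) {
      mids <- (xyz[adj_pairs[, 1], , drop = FALSE] +
                 xyz[adj_pairs[, 2], , drop = FALSE]) / 2
      needed <- ring_clearance / min(stats::dist(mids))
      if (needed > 1.8) next
      if (needed > 1) xyz <- xyz * needed
    }
    dm <- as.matrix(stats::dist(xyz))
    adj_mask <- matrix(FALSE, n, n)
    adj_mask[adj_pairs] <- TRUE
    adj_mask <- adj_mask | t(adj_mask)
    diag(dm) <- Inf
    if (any(dm[!adj_mask] < spacing)) next
    if (any(dm[adj_mask] > 3.6 * spacing)) next
    return(xyz)
  }
  stop("layout failure: could not place cells without overlap; ",
       "increase cell_spacing_nm", call. = FALSE)
}

# paint a predicate-defined solid into an integer array restricted to a
# physical bounding box; pred takes physical coordinate matrix, returns mask
paint_region <- function(arr, vs, lo, hi, pred, value, only_empty = FALSE) {
  dims <- dim(arr)
  i1 <- pmax(1L, floor(lo / vs + 0.5))
  i2 <- pmin(dims, ceiling(hi / vs + 0.5))
  if (any(i1 > i2)) return(arr)
  ix <- i1[1]:i2[1]; iy <- i1[2]:i2[2]; iz <- i1[3]:i2[3]
  cx <- (ix - 0.5) * vs[1]; cy <- (iy - 0.5) * vs[2]; cz <- (iz - 0.5) * vs[3]
  co <- as.matrix(expand.grid(x = cx, y = cy, z = cz))
  sel <- pred(co)
  if (!any(sel)) return(arr)
  sub <- arr[ix, iy, iz, drop = FALSE]
  if (only_empty) sel <- sel & (sub == 0L)
  sub[sel] <- value
  arr[ix, iy, iz] <- sub
  arr
}

#' Render a cyst as voxel images with ground truth
#'
#' Produces a fusome channel (each voxel labelled by the ground-truth cell
#' owning it), a ring-canal channel (tori), and an answer key sufficient to
#' score segmentation with no human input. Cells are balls of prescribed
#' relative volume joined by cylinders along each ring canal; each cylinder
#' half belongs to its end cell. Set `blur_sigma_nm > 0` to also obtain
#' probability maps.
#'
#' @param config a [render_config()].
#' @return list with `fusome` (binary [voxel_grid()]), `rings` (binary
#'   [voxel_grid()]), `fusome_prob`/`rings_prob` (only when blurred),
#'   `truth`: list with `tree`, `label_array` (integer array of ground-truth
#'   cell per voxel), `cell_volumes_um3` (named, voxel-measured),
#'   `ring_centers_nm`, `ring_normals`, `centers_nm`, and `config`.
#' @examples
#' rc <- render_config(canonical_max_branched(2), cell_volumes = c(7, 3))
#' img <- render_cyst(rc)
#' img$truth$cell_volumes_um3 / sum(img$truth$cell_volumes_um3)
#' @export
render_cyst <- function(config) {
  stopifnot(inherits(config, "render_config"))
  tr <- config$tree
  n <- length(tr$cells)
  vs <- config$voxel_size_nm
  xyz <- layout_tree_3d(tr, config$cell_spacing_nm, config$seed,
                        ring_clearance = 2.2 * (config$ring_radius_nm +
                                                  config$ring_minor_nm))
  # ball radii from relative volumes
  relv <- config$cell_volumes / mean(config$cell_volumes)
  radii <- config$mean_cell_radius_nm * relv^(1 / 3)
  pad <- max(radii) + config$ring_radius_nm + config$ring_minor_nm +
    4 * max(vs)
  xyz <- sweep(xyz, 2, apply(xyz, 2, min)) + pad  # shift into positive octant
  ext <- apply(xyz, 2, max) + pad
  dims <- pmax(ceiling(ext / vs), 8L)
  label <- array(0L, dims)
  rings <- array(0L, dims)

  set.seed(config$seed + 7L)
  m <- nrow(tr$canals)
  frag_drop <- if (m) stats::runif(m) < config$p_frag else logical(0)

  # bridges first (cylinder halves owned by their end cells), balls override
  ring_centers <- matrix(0, m, 3); ring_normals <- matrix(0, m, 3)
  if (m) for (e in seq_len(m)) {
    a <- tr$canals[e, 1]; b <- tr$canals[e, 2]
    pa <- xyz[a, ]; pb <- xyz[b, ]
    u <- (pb - pa) / sqrt(sum((pb - pa)^2))
    len <- sqrt(sum((pb - pa)^2))
    mid <- (pa + pb) / 2
    ring_centers[e, ] <- mid; ring_normals[e, ] <- u
    rt <- config$tube_radius_nm
    lo <- pmin(pa, pb) - rt; hi <- pmax(pa, pb) + rt
    gap <- if (frag_drop[e]) 0.18 * len else -1  # half-width of removed mid
    cyl <- function(co, owner_a) {
      w <- sweep(co, 2, pa)
      t_ax <- as.vector(w %*% u)
      r2 <- rowSums(w^2) - t_ax^2
      inside <- r2 <= rt^2 & t_ax >= 0 & t_ax <= len
      if (gap > 0) inside <- inside & abs(t_ax - len / 2) > gap
      if (owner_a) inside & t_ax <= len / 2 else inside & t_ax > len / 2
    }
    label <- paint_region(label, vs, lo, hi, function(co) cyl(co, TRUE), a)
    label <- paint_region(label, vs, lo, hi, function(co) cyl(co, FALSE), b)
    # ring torus, normal along the bridge
    R <- config$ring_radius_nm; rm <- config$ring_minor_nm
    tlo <- mid - (R + rm); thi <- mid + (R + rm)
    torus <- function(co) {
      w <- sweep(co, 2, mid)
      h <- as.vector(w %*% u)
      rho <- sqrt(pmax(rowSums(w^2) - h^2, 0))
      (rho - R)^2 + h^2 <= rm^2
    }
    rings <- paint_region(rings, vs, tlo, thi, torus, e)
  }
  for (i in seq_len(n)) {
    p <- xyz[i, ]; r <- radii[i]
    ball <- function(co) rowSums(sweep(co, 2, p)^2) <= r^2
    label <- paint_region(label, vs, p - r, p + r, ball, tr$cells[i])
  }

  voxel_um3 <- prod(vs) / 1e9
  counts <- tabulate(label[label > 0L], nbins = max(tr$cells))
  cell_vol <- stats::setNames(counts[tr$cells] * voxel_um3,
                              as.character(tr$cells))
  out <- list(
    fusome = voxel_grid(array(as.integer(label > 0L), dims), vs),
    rings = voxel_grid(array(as.integer(rings > 0L), dims), vs),
    truth = list(tree = tr, label_array = label,
                 cell_volumes_um3 = cell_vol,
                 ring_centers_nm = ring_centers,
                 ring_normals = ring_normals,
                 ring_edges = tr$canals,
                 centers_nm = xyz,
                 fragmented_edges = which(frag_drop)),
    config = config)
  if (config$blur_sigma_nm > 0) {
    out$fusome_prob <- voxel_grid(
      gaussian_blur_3d(label > 0L, vs, config$blur_sigma_nm), vs)
    out$rings_prob <- voxel_grid(
      gaussian_blur_3d(rings > 0L, vs, config$blur_sigma_nm), vs)
  }
  out
}

# separable 3D Gaussian blur in physical units (small kernels; used only to
# turn binary renders into probability-map stand-ins)
gaussian_blur_3d <- function(x, vs, sigma_nm) {
  x <- array(as.numeric(x), dim(x))
  for (ax in 1:3) {
    s <- sigma_nm / vs[ax]
    if (s < 1e-6) next
    half <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-half, half), sd = s)
    k <- k / sum(k)
    x <- convolve_axis(x, k, ax)
  }
  x
}

convolve_axis <- function(x, k, axis) {
  d <- dim(x)
  half <- (length(k) - 1L) / 2L
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  m <- matrix(xp, nrow = dp[1])
  n1 <- dp[1]
  out <- matrix(0, n1, ncol(m))
  for (j in seq_along(k)) {
    off <- j - half - 1L
    src <- pmin(pmax(seq_len(n1) + off, 1L), n1)  # replicate edges
    out <- out + k[j] * m[src, , drop = FALSE]
  }
  array(out, dp) |> aperm(order(perm))
}
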