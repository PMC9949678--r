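# ---- components ----------------------------------------------------------

# a connected voxel set inside a grid: linear indices + grid geometry
new_component <- function(indices, dims, voxel_size_nm) {
  structure(list(indices = as.integer(indices), dims = dims,
                 voxel_size_nm = voxel_size_nm),
            class = "fusome_component")
}

#' @export
print.fusome_component <- function(x, ...) {
  cat(sprintf("<fusome_component> %d voxels (%.3f um^3)\n",
              length(x$indices),
              length(x$indices) * prod(x$voxel_size_nm) / 1e9))
  invisible(x)
}

component_coords_nm <- function(comp) {
  ind <- arrayInd(comp$indices, comp$dims)
  sweep(ind - 0.5, 2, comp$voxel_size_nm, `*`)
}

component_volume_um3 <- function(comp) {
  length(comp$indices) * prod(comp$voxel_size_nm) / 1e9
}

# label all 26-connected components of a binary voxel_grid
label_components <- function(mask) {
  lab <- label_components_26(as.logical(mask$values), dim(mask$values))
  array(lab, dim(mask$values))
}

#' Extract fusome components from a binary mask
#'
#' In females the fusome is a single connected organelle, so `mode =
#' "female"` returns only the largest 26-connected component. Male fusomes
#' fragment; `mode = "male"` returns every component above a minimum-volume
#' floor, largest first.
#'
#' @param mask binary [voxel_grid()].
#' @param mode `"female"` or `"male"`.
#' @param min_voxels male-mode floor on component size (voxels).
#' @return list of components.
#' @export
extract_fusome <- function(mask, mode = c("female", "male"),
                           min_voxels = 50L) {
  mode <- match.arg(mode)
  stopifnot(inherits(mask, "voxel_grid"))
  if (!any(mask$values > 0)) stop("empty fusome mask", call. = FALSE)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- if (mode == "female") which.max(sizes) else
    which(sizes >= min_voxels)
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  lapply(keep, function(k)
    new_component(which(lab == k), dim(mask$values), mask$voxel_size_nm))
}

# ---- ring detection ------------------------------------------------------

# Euler characteristic of the cubical complex spanned by unit cubes at the
# given integer voxel coordinates (n x 3). chi = V - E + F - C; a solid
# ball gives 1, a solid torus 0 (one handle).
euler_characteristic <- function(coords) {
  n <- nrow(coords)
  if (!n) return(0L)
  key <- function(m) m[, 1] + 2048 * m[, 2] + 2048^2 * m[, 3]
  corner_offsets <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  corners <- do.call(rbind, lapply(seq_len(8), function(i)
    sweep(coords, 2, corner_offsets[i, ], `+`)))
  nV <- length(unique(key(corners)))
  # edges: 12 per cube, identified by (min corner, axis)
  ek <- numeric(0)
  for (ax in 1:3) {
    fix <- setdiff(1:3, ax)
    offs <- as.matrix(expand.grid(0:1, 0:1))
    for (i in 1:4) {
      base <- coords
      base[, fix[1]] <- base[, fix[1]] + offs[i, 1]
      base[, fix[2]] <- base[, fix[2]] + offs[i, 2]
      ek <- c(ek, key(base) * 4 + ax)
    }
  }
  nE <- length(unique(ek))
  # faces: 6 per cube, identified by (min corner, normal axis)
  fk <- numeric(0)
  for (ax in 1:3) {
    for (s in 0:1) {
      base <- coords
      base[, ax] <- base[, ax] + s
      fk <- c(fk, key(base) * 4 + ax)
    }
  }
  nF <- length(unique(fk))
  nV - nE + nF - n
}

#' Detect ring canals as closed loops
#'
#' Ring canals appear in their own channel as closed loops encircling the
#' fusome. Each 26-connected component of the ring mask is kept iff it
#' contains a cycle — its cubical-complex Euler characteristic is <= 0 (a
#' solid torus has 0, any blob without a handle has 1). Non-loop debris is
#' discarded. Each ring is reported with its centroid, best-fit plane
#' normal (least-variance principal axis, in physical coordinates) and mean
#' in-plane loop radius.
#'
#' @param mask binary [voxel_grid()] of the ring-canal channel.
#' @param min_voxels discard components smaller than this before the loop
#'   test.
#' @return list of `ring_canal` objects (fields `id`, `indices`,
#'   `centroid_nm`, `normal`, `radius_nm`, `n_voxels`); zero length (with a
#'   warning) when no loop is found, in which case the cyst is treated as
#'   single-celled.
#' @export
detect_rings <- function(mask, min_voxels = 8L) {
  stopifnot(inherits(mask, "voxel_grid"))
  if (!any(mask$values > 0)) stop("empty ring mask", call. = FALSE)
  lab <- label_components(mask)
  ncomp <- max(lab)
  rings <- list()
  vs <- mask$voxel_size_nm
  for (k in seq_len(ncomp)) {
    idx <- which(lab == k)
    if (length(idx) < min_voxels) next
    ind <- arrayInd(idx, dim(mask$values))
    if (euler_characteristic(ind) > 0L) next
    xyz <- sweep(ind - 0.5, 2, vs, `*`)
    ctr <- colMeans(xyz)
    w <- sweep(xyz, 2, ctr)
    ev <- eigen(crossprod(w) / nrow(w), symmetric = TRUE)
    normal <- ev$vectors[, 3]                    # least-variance axis
    h <- as.vector(w %*% normal)
    rad <- mean(sqrt(pmax(rowSums(w^2) - h^2, 0)))
    rings[[length(rings) + 1L]] <- structure(
      list(id = length(rings) + 1L, indices = idx, centroid_nm = ctr,
           normal = normal, radius_nm = rad, n_voxels = length(idx)),
      class = "ring_canal")
  }
  if (!length(rings))
    warning("no closed-loop ring detected: treating cyst as 1-cell")
  rings
}

#' @export
print.ring_canal <- function(x, ...) {
  cat(sprintf("<ring_canal %d> %d voxels, radius %.0f nm\n",
              x$id, x$n_voxels, x$radius_nm))
  invisible(x)
}

# ---- recursive splitting -------------------------------------------------

# connected components among a subset of voxels (rows of coords/indices),
# computed on the bounding-box crop
subset_components <- function(indices, dims) {
  ind <- arrayInd(indices, dims)
  lo <- apply(ind, 2, min); hi <- apply(ind, 2, max)
  sub_dims <- hi - lo + 1L
  sub <- array(FALSE, sub_dims)
  shifted <- sweep(ind, 2, lo - 1L)
  sub_lin <- shifted[, 1] + sub_dims[1] * (shifted[, 2] - 1L) +
    sub_dims[1] * sub_dims[2] * (shifted[, 3] - 1L)
  sub[sub_lin] <- TRUE
  lab <- label_components_26(as.logical(sub), sub_dims)
  lab[sub_lin]   # component id per input voxel, in input order
}

min_dist2_to_set <- function(point, coords) {
  min(rowSums(sweep(coords, 2, point)^2))
}

#' Split a fusome component at its ring canals
#'
#' Recursive bisection as in the reconstruction pipeline: at each step one
#' unused ring canal defines a cutting disk (the ring's best-fit plane, a
#' slab two voxels thick, disk radius 1.25 x the measured ring radius);
#' fusome voxels inside the disk are removed, which must disconnect the
#' component into exactly two sides. Remaining rings are dealt to the side
#' whose voxels lie nearest their centroid, and each side is split
#' recursively. Removed voxels are finally reassigned to the nearest
#' resulting fragment (physical distance), so the fragment volumes sum
#' exactly to the component volume.
#'
#' @param component a component from [extract_fusome()].
#' @param rings list of rings from [detect_rings()].
#' @param disk_factor cutting-disk radius as a multiple of the ring radius.
#' @return list with `fragments` (list of components), `edges` (matrix with
#'   columns `from`, `to`, `ring`: fragments separated by each ring) and
#'   `ring_ids` used. With no rings, the whole component is the single
#'   fragment.
#' @export
split_at_rings <- function(component, rings, disk_factor = 1.25) {
  stopifnot(inherits(component, "fusome_component"))
  vs <- component$voxel_size_nm
  dims <- component$dims
  coords <- component_coords_nm(component)
  # slab half-thickness: one voxel step projected on the cut normal (a
  # thinner slab cannot sever 26-connected paths on anisotropic grids)
  slab_half_for <- function(normal) 0.55 * sum(abs(normal) * vs)
  st <- new.env(parent = emptyenv())
  st$fragments <- list(); st$edges <- NULL; st$deleted <- list()

  # `rows` are positions into component$indices / coords, not grid indices
  rec <- function(rows, ring_ids) {
    if (!length(ring_ids)) {
      st$fragments[[length(st$fragments) + 1L]] <- rows
      return(length(st$fragments))
    }
    e <- ring_ids[1]
    ring <- rings[[e]]
    w <- sweep(coords[rows, , drop = FALSE], 2, ring$centroid_nm)
    h <- as.vector(w %*% ring$normal)
    rho2 <- pmax(rowSums(w^2) - h^2, 0)
    cut <- abs(h) <= slab_half_for(ring$normal) &
      rho2 <= (disk_factor * ring$radius_nm)^2
    if (!any(cut) || all(cut))
      stop("cut failure at ring ", e, ": disk removes none/all voxels",
           call. = FALSE)
    rem <- rows[!cut]
    comp_id <- subset_components(component$indices[rem], dims)
    ncc <- max(comp_id)
    if (ncc == 1L)
      stop("cut failure at ring ", e,
           ": component did not split", call. = FALSE)
    if (ncc > 2L) {
      # tolerate tiny debris shaved off the tube wall by the disk: fold any
      # component far smaller than the two principal sides into the cut set
      sizes <- tabulate(comp_id)
      main <- order(sizes, decreasing = TRUE)[1:2]
      if (sum(sizes[-main]) > 0.02 * sum(sizes))
        stop("ambiguous cut at ring ", e, ": ", ncc, " components",
             call. = FALSE)
      keep_idx <- which(!cut)
      cut[keep_idx[!(comp_id %in% main)]] <- TRUE
      rem <- rows[!cut]
      comp_id <- subset_components(component$indices[rem], dims)
      if (max(comp_id) != 2L)
        stop("ambiguous cut at ring ", e, call. = FALSE)
    }
    st$deleted[[length(st$deleted) + 1L]] <- rows[cut]
    side_a <- rem[comp_id == 1L]
    side_b <- rem[comp_id == 2L]
    rest <- ring_ids[-1]
    to_a <- logical(length(rest))
    if (length(rest)) {
      ca <- coords[side_a, , drop = FALSE]
      cb <- coords[side_b, , drop = FALSE]
      for (i in seq_along(rest)) {
        ctr <- rings[[rest[i]]]$centroid_nm
        to_a[i] <- min_dist2_to_set(ctr, ca) <= min_dist2_to_set(ctr, cb)
      }
    }
    ids_a <- rec(side_a, rest[to_a])
    ids_b <- rec(side_b, rest[!to_a])
    near_frag <- function(ids) {
      d <- vapply(ids, function(fid)
        min_dist2_to_set(ring$centroid_nm,
                         coords[st$fragments[[fid]], , drop = FALSE]),
        numeric(1))
      ids[which.min(d)]
    }
    st$edges <- rbind(st$edges,
                      c(from = near_frag(ids_a), to = near_frag(ids_b),
                        ring = e))
    c(ids_a, ids_b)
  }

  rows0 <- seq_along(component$indices)
  # only rings that actually touch this component participate
  use <- which(vapply(rings, function(r) {
    w <- sweep(coords, 2, r$centroid_nm)
    h <- as.vector(w %*% r$normal)
    rho2 <- pmax(rowSums(w^2) - h^2, 0)
    any(abs(h) <= 2 * slab_half_for(r$normal) &
          rho2 <= (disk_factor * r$radius_nm)^2)
  }, logical(1)))
  rec(rows0, use)

  # reassign deleted voxels to the nearest final fragment
  frags_lin <- lapply(st$fragments, function(rows) component$indices[rows])
  deleted_lin <- component$indices[unlist(st$deleted)]
  if (length(deleted_lin)) {
    frag_of <- integer(prod(dims))
    for (fid in seq_along(frags_lin)) frag_of[frags_lin[[fid]]] <- fid
    assign_to <- nearest_labelled(deleted_lin, frag_of, dims, vs)
    for (fid in seq_along(frags_lin))
      frags_lin[[fid]] <- sort(c(frags_lin[[fid]],
                                 deleted_lin[assign_to == fid]))
  }
  list(fragments = lapply(frags_lin, new_component, dims = dims,
                          voxel_size_nm = vs),
       edges = st$edges,
       ring_ids = use)
}

# nearest labelled voxel (physical distance) for each query index, searched
# over growing Chebyshev shells; queries sit within a voxel or two of a
# labelled fragment by construction
nearest_labelled <- function(queries, label_of, dims, vs, max_r = 12L) {
  ind <- arrayInd(queries, dims)
  out <- integer(length(queries))
  for (q in seq_along(queries)) {
    best <- 0L; best_d <- Inf
    for (r in seq_len(max_r)) {
      lo <- pmax(ind[q, ] - r, 1L); hi <- pmin(ind[q, ] + r, dims)
      box <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
      lin <- box[, 1] + dims[1] * (box[, 2] - 1L) +
        dims[1] * dims[2] * (box[, 3] - 1L)
      lab <- label_of[lin]
      hit <- lab > 0L
      if (any(hit)) {
        dd <- sweep(box[hit, , drop = FALSE], 2, ind[q, ])
        d2 <- as.vector((dd^2) %*% (vs^2))
        j <- which.min(d2)
        if (d2[j] < best_d) { best_d <- d2[j]; best <- lab[hit][j] }
        # a hit at shell r guarantees the true nearest lies within r+1
        if (r >= 2L || sqrt(best_d) <= r * min(vs)) break
      }
    }
    out[q] <- best
  }
  if (any(out == 0L))
    stop("internal: deleted voxel too far from any fragment", call. = FALSE)
  out
}

#' Build the cyst adjacency tree from a split
#'
#' @param split result of [split_at_rings()].
#' @return a [cyst_tree()] whose cells are fragment ids; edge `i-j` means
#'   fragments `i` and `j` were the two sides of one ring canal.
#' @export
build_adjacency <- function(split) {
  n <- length(split$fragments)
  canals <- if (is.null(split$edges)) NULL else split$edges[, 1:2,
                                                            drop = FALSE]
  tr <- tryCatch(cyst_tree(canals = canals, cells = seq_len(n)),
                 error = function(e)
                   stop("topology violation: fragment adjacency is not ",
                        "a tree (", conditionMessage(e), ")", call. = FALSE))
  tr
}

# ---- canonical labelling -------------------------------------------------

hop_distances <- function(tr, from) {
  adj <- adjacency_list(tr)
  d <- stats::setNames(rep(NA_integer_, length(tr$cells)),
                       as.character(tr$cells))
  d[as.character(from)] <- 0L
  frontier <- from
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (u in adj[[as.character(v)]]) {
        cu <- as.character(u)
        if (is.na(d[cu])) { d[cu] <- d[as.character(v)] + 1L
          nxt <- c(nxt, u) }
      }
    }
    frontier <- nxt
  }
  d
}

structural_signature <- function(tr, anchor) {
  deg <- cyst_degrees(tr)
  dist <- hop_distances(tr, anchor)
  lapply(tr$cells, function(v) {
    nb_deg <- sort(deg[as.character(adjacency_list(tr)[[as.character(v)]])],
                   decreasing = TRUE)
    list(deg = deg[[as.character(v)]], dist = dist[[as.character(v)]],
         profile = as.integer(nb_deg))
  })
}

signature_cost <- function(s1, s2) {
  p1 <- s1$profile; p2 <- s2$profile
  len <- max(length(p1), length(p2))
  pad <- function(p) c(p, rep(0L, len - length(p)))
  1000 * abs(s1$deg - s2$deg) + 100 * abs(s1$dist - s2$dist) +
    sum(abs(pad(p1) - pad(p2)))
}

# deterministic backtracking isomorphism tree -> canonical tree anchored at
# root_f -> cell 1; assumes the anchored rooted trees are isomorphic
anchored_isomorphism <- function(tr, canon, root_f) {
  adj_f <- adjacency_list(tr); adj_c <- adjacency_list(canon)
  shape_f <- function(v, parent) ahu_encode(adj_f, v, parent)
  shape_c <- function(v, parent) ahu_encode(adj_c, v, parent)
  mapping <- stats::setNames(rep(NA_integer_, length(tr$cells)),
                             as.character(tr$cells))
  rec <- function(v, pv, c, pc) {
    mapping[[as.character(v)]] <<- c
    kids_v <- sort(setdiff(adj_f[[as.character(v)]], pv))
    kids_c <- sort(setdiff(adj_c[[as.character(c)]], pc))
    if (length(kids_v) != length(kids_c)) return(FALSE)
    if (!length(kids_v)) return(TRUE)
    sh_v <- vapply(kids_v, function(k) shape_f(k, v), "")
    sh_c <- vapply(kids_c, function(k) shape_c(k, c), "")
    used <- logical(length(kids_c))
    for (i in seq_along(kids_v)) {
      placed <- FALSE
      for (j in seq_along(kids_c)) {
        if (!used[j] && sh_v[i] == sh_c[j]) {
          used[j] <- TRUE
          if (rec(kids_v[i], v, kids_c[j], c)) { placed <- TRUE; break }
          used[j] <- FALSE
        }
      }
      if (!placed) return(FALSE)
    }
    TRUE
  }
  if (!rec(root_f, NA_integer_, 1L, NA_integer_)) return(NULL)
  mapping
}

#' Assign canonical cell labels to reconstructed fragments
#'
#' Female cysts have an invariant topology, so fragments can be matched to
#' canonical cell numbers: the larger-volume fragment among those of
#' maximal ring-canal count is the founder (cell 1), and the remaining
#' labels are found by minimum-cost linear assignment (Hungarian algorithm)
#' on structural signatures — degree, hop distance to cell 1 and the sorted
#' neighbour-degree profile. The assignment is verified to be a graph
#' isomorphism onto the canonical topology; if equal-cost ties produced a
#' non-isomorphic map, a deterministic anchored backtracking search
#' replaces it.
#'
#' @param tree fragment adjacency from [build_adjacency()].
#' @param volumes_um3 per-fragment volumes in fragment-id order.
#' @return list of class `reconstructed_cyst`: `fragments` data frame
#'   (`fragment`, `label`, `volume_um3`, `fraction`, `n_rings`), `tree`
#'   (with labels), `label_map` (fragment -> canonical cell), `tie`
#'   (logical: pro-oocyte volume tie broken by fragment id).
#' @export
assign_labels <- function(tree, volumes_um3) {
  n <- length(tree$cells)
  stopifnot(length(volumes_um3) == n)
  canon <- canonical_max_branched(n)
  if (!trees_isomorphic(tree, canon))
    stop("labelling unavailable: cyst topology is not the maximally ",
         "branched ", n, "-cell tree", call. = FALSE)
  deg <- cyst_degrees(tree)
  maxdeg <- tree$cells[deg == max(deg)]
  vols <- volumes_um3[match(maxdeg, tree$cells)]
  tie <- isTRUE(length(maxdeg) > 1L &&
                  sort(vols, decreasing = TRUE)[1] ==
                  sort(vols, decreasing = TRUE)[2])
  cand <- maxdeg[order(-vols, maxdeg)]
  root_f <- cand[1]

  label_map <- NULL
  if (n > 1L) {
    sig_f <- structural_signature(tree, root_f)
    sig_c <- structural_signature(canon, 1L)
    cost <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      cost[i, j] <- signature_cost(sig_f[[i]], sig_c[[j]])
    big <- 1e6
    cost[match(root_f, tree$cells), ] <- big
    cost[match(root_f, tree$cells), 1] <- 0
    cost[-match(root_f, tree$cells), 1] <- big
    asg <- hungarian_assignment(cost)
    label_map <- stats::setNames(asg, as.character(tree$cells))
    # verify the map is edge-preserving; backtrack if ties misled it
    canon_keys <- paste(canon$canals[, 1], canon$canals[, 2])
    mapped <- cbind(label_map[as.character(tree$canals[, 1])],
                    label_map[as.character(tree$canals[, 2])])
    mapped_keys <- paste(pmin(mapped[, 1], mapped[, 2]),
                         pmax(mapped[, 1], mapped[, 2]))
    if (!all(mapped_keys %in% canon_keys)) {
      label_map <- anchored_isomorphism(tree, canon, root_f)
      if (is.null(label_map))
        stop("internal: anchored isomorphism search failed", call. = FALSE)
    }
  } else {
    label_map <- stats::setNames(1L, as.character(tree$cells))
  }
  fr <- volumes_um3 / sum(volumes_um3)
  fragments <- data.frame(fragment = tree$cells,
                          label = as.integer(label_map[as.character(tree$cells)]),
                          volume_um3 = volumes_um3,
                          fraction = fr,
                          n_rings = as.integer(deg[as.character(tree$cells)]))
  fragments <- fragments[order(fragments$label), ]
  rownames(fragments) <- NULL
  tree$labels <- label_map
  structure(list(fragments = fragments, tree = tree,
                 label_map = label_map, tie = tie),
            class = "reconstructed_cyst")
}

#' @export
print.reconstructed_cyst <- function(x, ...) {
  cat(sprintf("<reconstructed_cyst> %d cells\n", nrow(x$fragments)))
  print(x$fragments, digits = 3)
  invisible(x)
}

# ---- male-mode census ----------------------------------------------------

#' Count fusome-connected cells of a component
#'
#' The number of cells joined by one connected fusome fragment equals the
#' number of ring canals the fragment traverses plus one. A ring is
#' traversed when the component has voxels inside the ring's disk.
#'
#' @param component a component from [extract_fusome()].
#' @param rings list from [detect_rings()].
#' @param disk_factor disk radius multiple (as in [split_at_rings()]).
#' @return list with `n_cells`, `n_rings`, `power_of_2`.
#' @export
fusome_connected_cells <- function(component, rings, disk_factor = 1.25) {
  coords <- component_coords_nm(component)
  vs <- component$voxel_size_nm
  traversed <- vapply(rings, function(r) {
    w <- sweep(coords, 2, r$centroid_nm)
    h <- as.vector(w %*% r$normal)
    rho2 <- pmax(rowSums(w^2) - h^2, 0)
    any(abs(h) <= 1.1 * sum(abs(r$normal) * vs) &
          rho2 <= (disk_factor * r$radius_nm)^2)
  }, logical(1))
  n_cells <- sum(traversed) + 1L
  list(n_cells = n_cells, n_rings = sum(traversed),
       power_of_2 = bitwAnd(n_cells, n_cells - 1L) == 0L)
}

# ---- end-to-end reconstruction ------------------------------------------

#' Reconstruct a cyst from fusome and ring-canal channels
#'
#' Full female-mode pipeline: threshold both channels, take the fusome as
#' the largest connected component, detect closed-loop ring canals, split
#' the fusome recursively at each ring, build the adjacency tree and assign
#' canonical cell labels with per-cell volume fractions. In male mode each
#' fusome component above the size floor is analysed separately: connected
#' cell census, fragment adjacency, and embeddability of its topology into
#' the canonical maximally branched 16-cell tree.
#'
#' @param fusome,rings [voxel_grid()]s (probability or binary).
#' @param mode `"female"` or `"male"`.
#' @param cutoff probability threshold.
#' @param min_voxels male-mode component floor.
#' @return female mode: a `reconstructed_cyst` (see [assign_labels()]) with
#'   an additional `adjacency` element. Male mode: list of per-component
#'   records (`n_cells`, `n_rings`, `power_of_2`, `tree`, `embeddable`,
#'   `volume_um3`).
#' @export
reconstruct_cyst <- function(fusome, rings, mode = c("female", "male"),
                             cutoff = 0.5, min_voxels = 50L) {
  mode <- match.arg(mode)
  fmask <- threshold_probabilities(fusome, cutoff)
  rmask <- threshold_probabilities(rings, cutoff)
  ring_list <- detect_rings(rmask)
  comps <- extract_fusome(fmask, mode, min_voxels)
  if (mode == "female") {
    comp <- comps[[1]]
    sp <- split_at_rings(comp, ring_list)
    tr <- build_adjacency(sp)
    vols <- vapply(sp$fragments, component_volume_um3, numeric(1))
    rc <- assign_labels(tr, vols)
    rc$adjacency <- tr
    rc$split <- sp
    rc$rings <- ring_list
    rc
  } else {
    lapply(comps, function(comp) {
      census <- fusome_connected_cells(comp, ring_list)
      sp <- split_at_rings(comp, ring_list)
      tr <- build_adjacency(sp)
      list(n_cells = census$n_cells, n_rings = census$n_rings,
           power_of_2 = census$power_of_2, tree = tr,
           embeddable = is_embeddable(tr, canonical_max_branched(16L)),
           volume_um3 = component_volume_um3(comp))
    })
  }
}
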