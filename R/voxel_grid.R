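#' 3D voxel grids with physical voxel size
#'
#' Minimal container for volumetric image data: a 3D array of per-voxel
#' class probabilities (in `[0, 1]`) or binary occupancy, plus the physical
#' voxel edge lengths in nm. Confocal stacks are anisotropic (z step several
#' times the xy pixel size), so all geometry downstream is computed in
#' physical coordinates; voxel `(i, j, k)` is centred at
#' `((i - 0.5) dx, (j - 0.5) dy, (k - 0.5) dz)`.
#'
#' @param values 3D numeric/integer/logical array.
#' @param voxel_size_nm positive `(dx, dy, dz)` in nm; default
#'   `(70, 70, 210)` as in typical high-resolution confocal acquisitions.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, voxel_size_nm = c(70, 70, 210)) {
  stopifnot(length(dim(values)) == 3L, length(voxel_size_nm) == 3L,
            all(voxel_size_nm > 0))
  if (is.logical(values)) values <- array(as.integer(values), dim(values))
  rng <- range(values)
  if (rng[1] < 0 || rng[2] > 1)
    stop("voxel values must be probabilities or occupancy in [0, 1]",
         call. = FALSE)
  structure(list(values = values, voxel_size_nm = as.numeric(voxel_size_nm)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, voxel %g x %g x %g nm\n",
              d[1], d[2], d[3],
              x$voxel_size_nm[1], x$voxel_size_nm[2], x$voxel_size_nm[3]))
  cat(sprintf("  occupied (> 0): %d voxels (%.3f um^3)\n",
              sum(x$values > 0),
              sum(x$values > 0) * prod(x$voxel_size_nm) / 1e9))
  invisible(x)
}

voxel_volume_um3 <- function(grid) prod(grid$voxel_size_nm) / 1e9

#' Threshold a probability map
#'
#' @param grid a [voxel_grid()] of class probabilities.
#' @param cutoff probability cutoff in (0, 1); voxels at or above it are
#'   retained.
#' @return a binary [voxel_grid()].
#' @export
threshold_probabilities <- function(grid, cutoff = 0.5) {
  stopifnot(inherits(grid, "voxel_grid"), cutoff > 0, cutoff < 1)
  mask <- grid$values >= cutoff
  if (!any(mask))
    stop("empty class: no voxel reaches the probability cutoff",
         call. = FALSE)
  voxel_grid(array(as.integer(mask), dim(grid$values)), grid$voxel_size_nm)
}

#' Write / read a voxel grid as plain text
#'
#' Serialisation used in place of TIFF (no TIFF reader is available here):
#' a one-line JSON header carrying `dims` and `voxel_size_nm`, followed by
#' one `index,value` CSV row per occupied voxel (linear, column-major,
#' 1-based).
#'
#' @param grid a [voxel_grid()].
#' @param path file path.
#' @return `write_voxel_grid` returns `path` invisibly; `read_voxel_grid` a
#'   [voxel_grid()].
#' @export
write_voxel_grid <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  idx <- which(grid$values > 0)
  hdr <- jsonlite::toJSON(list(dims = dim(grid$values),
                               voxel_size_nm = grid$voxel_size_nm),
                          auto_unbox = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(hdr), con)
  writeLines("index,value", con)
  if (length(idx))
    writeLines(paste(idx, grid$values[idx], sep = ","), con)
  invisible(path)
}

#' @rdname write_voxel_grid
#' @export
read_voxel_grid <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1])
  values <- array(0, unlist(hdr$dims))
  if (length(lines) > 2L) {
    body <- utils::read.csv(text = lines[-1])
    values[body$index] <- body$value
  }
  voxel_grid(values, unlist(hdr$voxel_size_nm))
}
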