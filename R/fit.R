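# cache of grid model predictions keyed by (range, step, ratios); a grid of
# ~10^4 points costs a fraction of a second but is reused heavily by
# simulation studies
.fusome_cache <- new.env(parent = emptyenv())

#' Model fractions over a parameter grid
#'
#' Computes, for every feasible `(alpha, beta)` grid point, the predicted
#' per-cell volume fractions at all four stages, concatenated in canonical
#' cell order (stage 2 cells 1-2, stage 4 cells 1-4, stage 8 cells 1-8,
#' stage 16 cells 1-16; 30 columns). Infeasible points (`alpha - beta`
#' below `feas_gap`, or any negative solved plug volume) get `NA` rows.
#'
#' @param grid_alpha,grid_beta numeric vectors of grid values.
#' @param group_ratios see [solve_plug_volumes()].
#' @param feas_gap minimum `alpha - beta` admitted (default 0.01).
#' @return list with `alpha`, `beta` (per grid point, row order =
#'   `expand.grid(grid_alpha, grid_beta)`), and `fractions` (matrix, one row
#'   per grid point).
#' @export
grid_predictions <- function(grid_alpha, grid_beta,
                             group_ratios = c(2, 1, 1, 1),
                             feas_gap = 0.01) {
  key <- paste(c(signif(range(grid_alpha), 12), length(grid_alpha),
                 signif(range(grid_beta), 12), length(grid_beta),
                 signif(group_ratios, 12), feas_gap), collapse = "|")
  hit <- .fusome_cache[[key]]
  if (!is.null(hit)) return(hit)
  pts <- expand.grid(alpha = grid_alpha, beta = grid_beta,
                     KEEP.OUT.ATTRS = FALSE)
  frac <- matrix(NA_real_, nrow(pts), 30L)
  for (r in seq_len(nrow(pts))) {
    a <- pts$alpha[r]; b <- pts$beta[r]
    if (a - b < feas_gap) next
    pl <- tryCatch(solve_plug_volumes(a, b, group_ratios),
                   error = function(e) NULL)
    if (is.null(pl) || !pl$feasible) next
    frac[r, ] <- c(predict_fractions(pl, 2), predict_fractions(pl, 4),
                   predict_fractions(pl, 8), predict_fractions(pl, 16))
  }
  out <- list(alpha = pts$alpha, beta = pts$beta, fractions = frac)
  .fusome_cache[[key]] <- out
  out
}

# per-cyst volume fractions in canonical order with the pro-oocyte pair
# sorted descending; returns a list of per-stage matrices (cyst x cell)
stage_fraction_matrices <- function(volumes) {
  need <- c("cyst_id", "stage", "cell_label", "volume_um3")
  if (!all(need %in% names(volumes)))
    stop("volume table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  stages <- c(2L, 4L, 8L, 16L)
  out <- stats::setNames(vector("list", 4), as.character(stages))
  for (s in stages) {
    sub <- volumes[volumes$stage == s, , drop = FALSE]
    if (!nrow(sub)) next
    ids <- unique(sub$cyst_id)
    m <- matrix(NA_real_, length(ids), s)
    for (i in seq_along(ids)) {
      cy <- sub[sub$cyst_id == ids[i], , drop = FALSE]
      if (nrow(cy) != s || anyDuplicated(cy$cell_label) ||
          !all(sort(cy$cell_label) == seq_len(s)))
        stop("cyst ", ids[i], " at stage ", s,
             " does not carry cell labels 1..", s, call. = FALSE)
      f <- cy$volume_um3[order(cy$cell_label)]
      f <- f / sum(f)
      if (f[2] > f[1]) f[1:2] <- f[2:1]  # cell 1 = larger pro-oocyte
      m[i, ] <- f
    }
    rownames(m) <- as.character(ids)
    out[[as.character(s)]] <- m
  }
  out
}

#' Fit the fusome growth model by grid search
#'
#' Fits the two model parameters — `alpha`, the founder cell's fusome
#' fraction at the 2-cell stage, and `beta`, the mother's share of each new
#' plug — to measured per-cell volume fractions by minimising the summed
#' squared residuals between measured and predicted fractions over every
#' cell at every cyst size, on a regular `(alpha, beta)` grid. By default
#' residuals are taken against the stage-wise mean measured fraction per
#' cell (one residual per cell per stage); `per_sample = TRUE` instead sums
#' residuals over every individual cyst.
#'
#' @param volumes data frame with columns `cyst_id`, `stage` (2/4/8/16),
#'   `cell_label` (1..stage) and `volume_um3`.
#' @param grid_range,grid_step grid specification for both parameters
#'   (defaults: `[0.25, 0.75]` at step 0.005).
#' @param group_ratios 16-cell groupwise ratio closing the plug-volume
#'   system; see [solve_plug_volumes()].
#' @param per_sample sum residuals over individual cysts instead of
#'   stage-wise means.
#' @param feas_gap minimum admitted `alpha - beta`.
#' @return an object of class `fusome_fit`: list with `alpha`, `beta`
#'   (the minimising grid point), `surface` (error matrix, alpha x beta),
#'   `grid_alpha`, `grid_beta`, `region5` (data frame of grid points within
#'   5% of the minimum error, with its `alpha_range`/`beta_range`
#'   attributes), `plugs` (plug volumes at the optimum), `means`
#'   (stage-wise mean measured fractions), `n_cysts`, `per_sample`, `call`.
#' @examples
#' tab <- simulate_volume_table(simulation_config(seed = 1))
#' fit <- fit_fusome_growth(tab, grid_step = 0.025)
#' coef(fit)
#' @export
fit_fusome_growth <- function(volumes, grid_range = c(0.25, 0.75),
                              grid_step = 0.005,
                              group_ratios = c(2, 1, 1, 1),
                              per_sample = FALSE, feas_gap = 0.01) {
  cl <- match.call()
  grid_alpha <- seq(grid_range[1], grid_range[2], by = grid_step)
  grid_beta <- grid_alpha
  gp <- grid_predictions(grid_alpha, grid_beta, group_ratios, feas_gap)
  mats <- stage_fraction_matrices(volumes)
  if (all(vapply(mats, is.null, logical(1))))
    stop("no cysts found at any stage", call. = FALSE)
  stages <- c(2L, 4L, 8L, 16L)
  offsets <- c(0L, 2L, 6L, 14L)  # column offsets of each stage in fractions
  sse <- numeric(nrow(gp$fractions))
  means <- stats::setNames(vector("list", 4), as.character(stages))
  for (si in seq_along(stages)) {
    m <- mats[[si]]
    if (is.null(m)) next
    cols <- offsets[si] + seq_len(stages[si])
    mu <- colMeans(m)
    means[[si]] <- mu
    pred <- gp$fractions[, cols, drop = FALSE]
    if (per_sample) {
      for (r in seq_len(nrow(m)))
        sse <- sse + rowSums((pred - rep(m[r, ], each = nrow(pred)))^2)
    } else {
      sse <- sse + rowSums((pred - rep(mu, each = nrow(pred)))^2)
    }
  }
  sse[is.na(sse)] <- Inf
  if (!any(is.finite(sse)))
    stop("no feasible grid point: empty grid after feasibility mask",
         call. = FALSE)
  best <- which.min(sse)
  alpha_hat <- gp$alpha[best]; beta_hat <- gp$beta[best]
  surface <- matrix(sse, length(grid_alpha), length(grid_beta),
                    dimnames = list(format(grid_alpha), format(grid_beta)))
  in5 <- is.finite(sse) & sse <= 1.05 * sse[best]
  region5 <- data.frame(alpha = gp$alpha[in5], beta = gp$beta[in5],
                        error = sse[in5])
  attr(region5, "alpha_range") <- range(region5$alpha)
  attr(region5, "beta_range") <- range(region5$beta)
  structure(list(
    alpha = alpha_hat, beta = beta_hat, error = sse[best],
    surface = surface, grid_alpha = grid_alpha, grid_beta = grid_beta,
    region5 = region5,
    plugs = solve_plug_volumes(alpha_hat, beta_hat, group_ratios),
    group_ratios = group_ratios, means = means,
    n_cysts = vapply(mats, function(m) if (is.null(m)) 0L else nrow(m),
                     integer(1)),
    per_sample = per_sample, call = cl), class = "fusome_fit")
}

#' @export
print.fusome_fit <- function(x, digits = 3, ...) {
  cat("Fusome growth model (grid-search least squares)\n")
  cat(sprintf("  alpha = %.3f  (cell 1 fraction at the 2-cell stage)\n",
              x$alpha))
  cat(sprintf("  beta  = %.3f  (mother's share of each new plug)\n", x$beta))
  cat(sprintf("  SSR   = %.*g over %d cysts (stages 2/4/8/16: %s)\n",
              digits, x$error, sum(x$n_cysts),
              paste(x$n_cysts, collapse = "/")))
  invisible(x)
}

#' @export
coef.fusome_fit <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta)
}

#' @export
summary.fusome_fit <- function(object, ...) {
  ar <- attr(object$region5, "alpha_range")
  br <- attr(object$region5, "beta_range")
  out <- list(coef = coef(object), error = object$error,
              alpha_range5 = ar, beta_range5 = br,
              ratio = ratio_trajectory(object$plugs),
              pair_share = pair_share_trajectory(object$plugs),
              plugs = object$plugs$v, n_cysts = object$n_cysts)
  class(out) <- "summary.fusome_fit"
  out
}

#' @export
print.summary.fusome_fit <- function(x, ...) {
  cat("Fusome growth model fit\n")
  cat(sprintf("  alpha = %.3f, 5%%-of-minimum range (%.3f, %.3f)\n",
              x$coef["alpha"], x$alpha_range5[1], x$alpha_range5[2]))
  cat(sprintf("  beta  = %.3f, 5%%-of-minimum range (%.3f, %.3f)\n",
              x$coef["beta"], x$beta_range5[1], x$beta_range5[2]))
  cat(sprintf("  SSR at optimum: %.4g\n", x$error))
  cat("  plug volumes (v0..v4):",
      paste(sprintf("%.3f", x$plugs), collapse = " "), "\n")
  cat("  cell1:cell2 ratio by stage:",
      paste(sprintf("%.2f", x$ratio), collapse = " "), "\n")
  cat("  pro-oocyte pair share by stage:",
      paste(sprintf("%.3f", x$pair_share), collapse = " "), "\n")
  invisible(x)
}

#' Predicted volume fractions from a fitted model
#'
#' @param object a `fusome_fit`.
#' @param stage cyst size(s) among 2, 4, 8, 16; default all four.
#' @param ... unused.
#' @return named list of per-cell fraction vectors, one per stage.
#' @export
predict.fusome_fit <- function(object, stage = c(2L, 4L, 8L, 16L), ...) {
  stats::setNames(lapply(stage, function(s) predict_fractions(object$plugs, s)),
                  as.character(stage))
}

#' Residuals of a fitted fusome growth model
#'
#' Stage-wise mean measured fractions minus model predictions, in canonical
#' cell order.
#'
#' @param object a `fusome_fit`.
#' @param ... unused.
#' @return named list of per-cell residual vectors, one per stage with data.
#' @export
residuals.fusome_fit <- function(object, ...) {
  stages <- c(2L, 4L, 8L, 16L)
  out <- list()
  for (si in seq_along(stages)) {
    mu <- object$means[[si]]
    if (is.null(mu)) next
    out[[as.character(stages[si])]] <-
      mu - predict_fractions(object$plugs, stages[si])
  }
  out
}

#' Simulate volume tables from a fitted model
#'
#' @param object a `fusome_fit`.
#' @param nsim number of tables.
#' @param seed integer seed.
#' @param n_cysts_per_stage,noise_sigma forwarded to [simulation_config()].
#' @param ... unused.
#' @return a volume table (`nsim = 1`) or list of tables.
#' @export
simulate.fusome_fit <- function(object, nsim = 1, seed = NULL,
                                n_cysts_per_stage = 12, noise_sigma = 0.05,
                                ...) {
  if (is.null(seed)) seed <- 1L
  tabs <- lapply(seq_len(nsim), function(i) {
    cfg <- simulation_config(alpha_true = object$alpha,
                             beta_true = object$beta,
                             group_ratios = object$group_ratios,
                             n_cysts_per_stage = n_cysts_per_stage,
                             noise_sigma = noise_sigma,
                             seed = as.integer(seed) + i - 1L)
    simulate_volume_table(cfg)
  })
  if (nsim == 1) tabs[[1]] else tabs
}

#' Plot the grid-search error surface
#'
#' Shows `log10` SSR over the `(alpha, beta)` grid with the 5%-of-minimum
#' region and the optimum marked.
#'
#' @param x a `fusome_fit`.
#' @param ... passed to [graphics::image()].
#' @export
plot.fusome_fit <- function(x, ...) {
  z <- log10(x$surface)
  z[!is.finite(z)] <- NA
  graphics::image(x$grid_alpha, x$grid_beta, z,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = expression(alpha), ylab = expression(beta),
                  main = "Grid-search error surface (log10 SSR)", ...)
  graphics::points(x$region5$alpha, x$region5$beta, pch = ".", col = "white")
  graphics::points(x$alpha, x$beta, pch = 4, col = "red", lwd = 2)
  invisible(x)
}
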