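#' Solve for the fusome plug volumes
#'
#' The additive growth model tracks the fusome as a spectrosome of volume
#' `v0` (normalised to 1) plus a "plug" of volume `v_k` added in every ring
#' canal formed at division `k`; a fraction `beta` of each plug is retained
#' by the mother and `1 - beta` goes to the daughter. `alpha` is cell 1's
#' volume fraction at the 2-cell stage, which fixes
#' `v1 = v0 (1 - alpha) / (alpha - beta)`. Imposing the measured 16-cell
#' groupwise volume-fraction ratio (cells 1-2 : 3-4 : 5-8 : 9-16, default
#' 2:1:1:1) closes a linear system for `v2, v3, v4`.
#'
#' @param alpha cell 1's fusome volume fraction at the 2-cell stage, in (0,1).
#' @param beta fraction of each new plug retained by the mother, in (0,1);
#'   feasibility requires `beta < alpha`.
#' @param group_ratios positive length-4 vector of 16-cell groupwise
#'   volume-fraction shares for cells {1-2}, {3-4}, {5-8}, {9-16}.
#' @param v0 spectrosome volume (all plug volumes are reported as multiples
#'   of it).
#' @return list with `v` (named numeric `v0..v4`), `alpha`, `beta`,
#'   `group_ratios`, `total` (named totals `T1..T4` of the 2-, 4-, 8- and
#'   16-cell fusome), and `feasible` (all plug volumes non-negative).
#' @examples
#' solve_plug_volumes(0.7, 0.5)$v   # v1 = 1.5, v2 = 1.25, v3 = v4 = 0.625
#' @export
solve_plug_volumes <- function(alpha, beta, group_ratios = c(2, 1, 1, 1),
                               v0 = 1) {
  stopifnot(length(alpha) == 1L, length(beta) == 1L,
            length(group_ratios) == 4L, all(group_ratios > 0), v0 > 0)
  if (!(alpha > 0 && alpha < 1) || !(beta > 0 && beta < 1))
    stop("alpha and beta must lie in (0, 1)", call. = FALSE)
  if (alpha <= beta)
    stop("infeasible parameters: alpha must exceed beta (v1 > 0 requires it)",
         call. = FALSE)
  g <- group_ratios / sum(group_ratios)
  v1 <- v0 * (1 - alpha) / (alpha - beta)
  # groupwise 16-cell fractions, numerators linear in (v2, v3, v4):
  #   cells 3-4 : 2(1-b)v2 + 2b v3 + 2b v4 = g2 * T4
  #   cells 5-8 : 4(1-b)v3 + 4b v4         = g3 * T4
  #   cells 9-16: 8(1-b)v4                 = g4 * T4
  # with T4 = v0 + v1 + 2 v2 + 4 v3 + 8 v4 (the 1-2 group equation is the
  # complement and holds automatically).
  A <- rbind(
    c(2 * (1 - beta) - 2 * g[2], 2 * beta - 4 * g[2], 2 * beta - 8 * g[2]),
    c(-2 * g[3], 4 * (1 - beta) - 4 * g[3], 4 * beta - 8 * g[3]),
    c(-2 * g[4], -4 * g[4], 8 * (1 - beta) - 8 * g[4]))
  b <- c(g[2], g[3], g[4]) * (v0 + v1)
  v234 <- tryCatch(solve(A, b), error = function(e)
    stop("plug-volume system is singular at these parameters",
         call. = FALSE))
  v <- c(v0 = v0, v1 = v1, v2 = v234[1], v3 = v234[2], v4 = v234[3])
  total <- cumsum(c(v0, v[2:5] * 2^(0:3)))[-1]
  names(total) <- paste0("T", 1:4)
  list(v = v, alpha = alpha, beta = beta, group_ratios = group_ratios,
       total = total, feasible = all(v >= -1e-12))
}

# division at which canonical cell i was born (0 for the founder, cell 1)
birth_division <- function(i) ifelse(i == 1L, 0L, ceiling(log2(i)))

#' Predicted per-cell fusome volume fractions
#'
#' At the `2^k`-cell stage, cell 1 holds `v0 + beta * (v1 + ... + vk)`;
#' a cell born at division `b` holds `(1-beta) * v_b` from its birth plug
#' plus `beta * (v_{b+1} + ... + v_k)` retained from later divisions.
#' Fractions divide by the stage total and sum to one.
#'
#' @param plugs result of [solve_plug_volumes()].
#' @param stage cyst size, one of 2, 4, 8, 16.
#' @return numeric vector of length `stage`: fractions for canonical cells
#'   `1..stage`.
#' @examples
#' predict_fractions(solve_plug_volumes(0.7, 0.5), 4)  # 0.475 0.275 0.125 0.125
#' @export
predict_fractions <- function(plugs, stage) {
  if (!(stage %in% c(2L, 4L, 8L, 16L)))
    stop("stage must be one of 2, 4, 8, 16", call. = FALSE)
  k <- as.integer(log2(stage))
  beta <- plugs$beta
  v <- plugs$v            # v0..v4
  cells <- seq_len(stage)
  b <- birth_division(cells)
  later <- vapply(b, function(bi)
    if (bi < k) sum(v[(bi + 2):(k + 1)]) else 0, numeric(1))
  vol <- ifelse(cells == 1L,
                v[1] + beta * later,
                (1 - beta) * v[b + 1] + beta * later)
  Tk <- sum(v[1:(k + 1)] * c(1, 2^(0:(k - 1))))
  vol / Tk
}

#' Pro-oocyte volume ratio across stages
#'
#' The ratio of cell 1's to cell 2's predicted fusome volume at the 2-, 4-,
#' 8- and 16-cell stages; strictly decreasing for feasible parameters, from
#' `alpha / (1 - alpha)` at the 2-cell stage towards parity.
#'
#' @param plugs result of [solve_plug_volumes()].
#' @return named numeric vector `r2, r4, r8, r16`.
#' @examples
#' ratio_trajectory(solve_plug_volumes(0.7, 0.5))
#' @export
ratio_trajectory <- function(plugs) {
  r <- vapply(c(2L, 4L, 8L, 16L), function(n) {
    f <- predict_fractions(plugs, n)
    f[1] / f[2]
  }, numeric(1))
  stats::setNames(r, paste0("r", c(2, 4, 8, 16)))
}

#' Pro-oocyte pair share across stages
#'
#' Combined predicted fraction of cells 1 and 2 at each stage (1 at the
#' 2-cell stage by definition).
#'
#' @param plugs result of [solve_plug_volumes()].
#' @return named numeric vector over stages 2, 4, 8, 16.
#' @export
pair_share_trajectory <- function(plugs) {
  s <- vapply(c(2L, 4L, 8L, 16L), function(n)
    sum(predict_fractions(plugs, n)[1:2]), numeric(1))
  stats::setNames(s, paste0("stage", c(2, 4, 8, 16)))
}
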