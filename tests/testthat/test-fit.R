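test_that("noise-free data recovers the generating parameters exactly", {
  tab <- simulate_volume_table(
    simulation_config(alpha_true = 0.7, beta_true = 0.5, noise_sigma = 0,
                      n_cysts_per_stage = 2, seed = 1))
  fit <- fit_fusome_growth(tab)
  expect_equal(unname(coef(fit)), c(0.700, 0.500), tolerance = 1e-9)
  expect_s3_class(fit, "fusome_fit")

  # region5 contains the optimum; optimum beats its 8 grid neighbours
  expect_true(any(fit$region5$alpha == fit$alpha &
                    fit$region5$beta == fit$beta))
  ia <- match(fit$alpha, fit$grid_alpha)
  ib <- match(fit$beta, fit$grid_beta)
  for (da in -1:1) for (db in -1:1) {
    a <- ia + da; b <- ib + db
    if (a >= 1 && a <= nrow(fit$surface) && b >= 1 && b <= ncol(fit$surface))
      expect_gte(fit$surface[a, b], fit$error)
  }
})

test_that("fit modes, methods and failure modes behave", {
  tab <- simulate_volume_table(simulation_config(seed = 5))
  fit <- fit_fusome_growth(tab)
  fit_ps <- fit_fusome_growth(tab, per_sample = TRUE)
  # both modes land near the generator on well-behaved data
  expect_lt(abs(fit$alpha - 0.7), 0.03)
  expect_lt(abs(fit_ps$alpha - 0.7), 0.03)
  expect_lt(abs(fit$beta - 0.5), 0.06)

  expect_named(coef(fit), c("alpha", "beta"))
  s <- summary(fit)
  expect_s3_class(s, "summary.fusome_fit")
  expect_output(print(s), "alpha")
  pr <- predict(fit)
  expect_length(pr, 4)
  expect_equal(vapply(pr, sum, numeric(1)), rep(1, 4),
               tolerance = 1e-9, ignore_attr = TRUE)
  res <- residuals(fit)
  expect_length(res[["16"]], 16)
  expect_lt(max(abs(unlist(res))), 0.05)

  sim <- simulate(fit, seed = 9)
  expect_true(all(c("cyst_id", "stage", "cell_label", "volume_um3") %in%
                    names(sim)))

  # pro-oocyte sorting: swapping labels 1 and 2 in the input changes nothing
  tab_sw <- tab
  one <- tab_sw$cell_label == 1L
  two <- tab_sw$cell_label == 2L
  tab_sw$cell_label[one] <- 2L; tab_sw$cell_label[two] <- 1L
  expect_equal(coef(fit_fusome_growth(tab_sw)), coef(fit))

  bad <- tab[tab$stage == 2, ][1, , drop = FALSE]
  expect_error(fit_fusome_growth(bad), "labels 1")
  expect_error(fit_fusome_growth(tab[0, ]), "no cysts")
})

test_that("grid predictions are cached and feasibility-masked", {
  gp <- grid_predictions(seq(0.25, 0.75, 0.05), seq(0.25, 0.75, 0.05))
  infeas <- gp$alpha - gp$beta < 0.01
  expect_true(all(is.na(gp$fractions[infeas, 1])))
  ok <- which(!is.na(gp$fractions[, 1]))
  expect_equal(rowSums(gp$fractions[ok, 1:2, drop = FALSE]), rep(1, length(ok)),
               tolerance = 1e-9)
  # second call hits the cache and returns the identical object
  gp2 <- grid_predictions(seq(0.25, 0.75, 0.05), seq(0.25, 0.75, 0.05))
  expect_identical(gp, gp2)
})

test_that("moderate-noise fits recover parameters within tolerance", {
  # reduced-size version of the recovery study (full version in the
  # acceptance suite): one parameter pair, 10 replicates
  hits <- 0L
  for (r in 1:10) {
    tab <- simulate_volume_table(
      simulation_config(alpha_true = 0.7, beta_true = 0.5,
                        n_cysts_per_stage = 12, noise_sigma = 0.05,
                        seed = 1000 + r))
    fit <- fit_fusome_growth(tab)
    if (abs(fit$alpha - 0.7) <= 0.02 && abs(fit$beta - 0.5) <= 0.05)
      hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
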