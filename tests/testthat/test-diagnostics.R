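test_that("GOF on an exactly fitted dataset has zero residuals", {
  p <- ref_params()
  ds <- generate_dataset(p, default_design(), prop_error(0), seed = 1)
  fit <- fit_cascade(ds, init = p, n_starts = 1)
  g <- gof(fit, ds)
  expect_lt(max(abs(g$residual) / pmax(g$predicted, 1e-12)), 1e-5)
  s <- attr(g, "summary")
  expect_equal(s$slope_origin, rep(1, 4), tolerance = 1e-5)
})

test_that("GOF residuals on a well-specified fit are calibrated", {
  g <- gof(fixture_fit(), fixture_dataset())
  s <- attr(g, "summary")
  expect_equal(s$slope_origin, rep(1, 4), tolerance = 0.1)
  # mean standardized residual within +/- 3/sqrt(N) of zero per analyte
  expect_true(all(abs(s$mean_std_residual) <= 3 / sqrt(s$n)))
  expect_equal(g$residual, g$observed - g$predicted)
})

test_that("shuffled observations destroy the obs-vs-pred agreement", {
  ds <- fixture_dataset()
  set.seed(17)
  i <- ds$analyte == "TNF"
  ds$value[i] <- sample(ds$value[i])
  g <- gof(fixture_fit(), ds)
  s <- attr(g, "summary")
  expect_gt(abs(s$slope_origin[s$analyte == "TNF"] - 1), 0.1)
})

test_that("VPC envelope collapses at zero noise and widens with sigma", {
  p <- ref_params()
  d <- default_design()
  v0 <- vpc(p, prop_error(0), d, n_sim = 20, seed = 1)
  expect_equal(v0$q5, v0$predicted)
  expect_equal(v0$q50, v0$predicted)
  expect_equal(v0$q95, v0$predicted)
  v_small <- vpc(p, prop_error(0.05), d, n_sim = 100, seed = 2)
  v_large <- vpc(p, prop_error(0.2), d, n_sim = 100, seed = 2)
  expect_true(all(v_large$q95 - v_large$q5 >=
                    v_small$q95 - v_small$q5 - 1e-12))
})

test_that("VPC covers observed medians at close to nominal rate", {
  p <- ref_params()
  d <- default_design()
  ds <- generate_dataset(p, d, prop_error(0.1), seed = 71)
  v <- vpc(p, prop_error(0.1), d, n_sim = 200, seed = 3, dataset = ds)
  cover <- mean(v$obs_median >= v$q5 & v$obs_median <= v$q95)
  # 80 cells at nominal 90%: binomial 3-sigma band
  expect_gte(cover, 0.9 - 3 * sqrt(0.9 * 0.1 / nrow(v)))
})

test_that("timecourse tables are an exact view of the solver output", {
  p <- ref_params()
  grid <- seq(0, 12, by = 0.5)
  tab <- timecourse_plot_data(p, arms = c(0, 10, 20, 40), grid = grid)
  expect_setequal(unique(tab$baicalein_uM), c(0, 10, 20, 40))
  expect_true("LPS" %in% tab$arm_id)  # control arm present
  tr <- simulate_cascade(p, 20, grid)
  got <- tab[tab$baicalein_uM == 20 & tab$analyte == "IL6", "value"]
  expect_identical(got, unname(tr$states[, "il6"]))
})
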