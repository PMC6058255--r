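test_that("pooled NLL matches its closed forms and a brute-force sum", {
  p <- ref_params()
  d <- default_design()
  noise_free <- predict_design(p, d)
  # zero residuals, additive sigma: NLL = (N/2) log(2 pi sigma^2)
  em <- error_model("additive", sigma_add = 2)
  N <- nrow(noise_free)
  expect_equal(neg_log_likelihood(p, em, noise_free),
               N / 2 * log(2 * pi * 4), tolerance = 1e-7)
  # single record with residual 2 at additive sigma 1
  one <- noise_free[noise_free$analyte == "TNF" &
                      noise_free$baicalein_uM == 0 &
                      noise_free$time_h == 2, ][1, ]
  one$value <- one$value + 2
  expect_equal(neg_log_likelihood(p, error_model("additive", sigma_add = 1),
                                  one),
               0.5 * log(2 * pi) + 2, tolerance = 1e-7)
  # noisy dataset: straight-line per-record summation as oracle
  ds <- generate_dataset(p, d, prop_error(0.1), seed = 31)
  em2 <- prop_error(0.12)
  brute <- 0
  for (i in seq_len(nrow(ds))) {
    tr <- simulate_cascade(p, ds$baicalein_uM[i],
                           times = c(0, ds$time_h[i]))
    col <- c(TNF = "tnf", IL6 = "il6", iNOS = "inos", NO = "no")
    pred <- tr$states[2, col[[ds$analyte[i]]]]
    brute <- brute - dnorm(ds$value[i], pred, 0.12 * pred, log = TRUE)
  }
  expect_equal(neg_log_likelihood(p, em2, ds), brute, tolerance = 1e-6)
})

test_that("information criteria obey their defining identities", {
  expect_equal(information_criteria(0, 1, 1), c(aic = 2, bic = 0))
  set.seed(8)
  for (i in 1:25) {
    m2ll <- runif(1, 0, 5000); p <- sample(1:30, 1); n <- sample(1:500, 1)
    ic <- information_criteria(m2ll, p, n)
    expect_equal(unname(ic["aic"]), m2ll + 2 * p)
    expect_equal(unname(ic["bic"]), m2ll + p * log(n))
  }
  # a -2LL of 2818.03 with 24 free parameters gives AIC 2866.03
  expect_equal(unname(information_criteria(2818.03, 24, 288)["aic"]),
               2866.03)
})

test_that("fitting noise-free data from the truth is a fixed point", {
  p <- ref_params()
  ds <- generate_dataset(p, default_design(), prop_error(0), seed = 1)
  fit <- fit_cascade(ds, init = p, n_starts = 1)
  est <- unlist(fit$estimates[fit$free])
  expect_equal(est, unlist(p[fit$free]), tolerance = 1e-4)
})

test_that("noise-free fit recovers the truth from distant starts", {
  p <- ref_params()
  ds <- generate_dataset(p, default_design(), prop_error(0), seed = 1)
  init <- do.call(pd_params, modifyList(
    unclass(p),
    lapply(unclass(p)[setdiff(pd_param_names(),
                              c("k_out_inos", "k_out_no", "tnf0", "il6_0",
                                "inos0", "no0", "alpha"))],
           function(v) v * 2)))
  init$alpha <- min(p$alpha * 2, 0.26)
  fit <- suppressWarnings(fit_cascade(ds, init = init, n_starts = 8,
                                      seed = 2))
  est <- unlist(fit$estimates[fit$free])
  expect_equal(est, unlist(p[fit$free]), tolerance = 1e-3)
})

test_that("fixed parameters are honored bit-exactly", {
  ds <- fixture_dataset()
  p <- ref_params()
  fit <- suppressWarnings(
    fit_cascade(ds, init = p,
                fixed = c("alpha", "k_out_inos", "k_out_no",
                          "tnf0", "il6_0", "inos0", "no0"),
                n_starts = 2, seed = 3))
  expect_identical(fit$estimates$alpha, p$alpha)
  expect_false("alpha" %in% fit$free)
})

test_that("the optimum improves on the start and resists perturbation", {
  fit <- fixture_fit()
  est <- unlist(fit$estimates[fit$free])
  nll_est <- fit$objective_natural(est)
  nll_init <- fit$objective_natural(unlist(ref_params()[fit$free]))
  expect_lte(nll_est, nll_init + 1e-8)
  expect_equal(2 * nll_est, fit$minus2LL, tolerance = 1e-10)
  # profile sanity: +/-20% single-parameter perturbations never improve
  for (nm in c("alpha", "k_out_tnf", "tau1", "delta")) {
    for (fac in c(0.8, 1.2)) {
      v <- est; v[nm] <- v[nm] * fac
      expect_gte(fit$objective_natural(v), nll_est - 1e-8)
    }
  }
})

test_that("the two likelihood code paths agree at the optimum", {
  fit <- fixture_fit()
  # neg_log_likelihood with the fitted sigmas must equal the profiled
  # objective value used during optimization
  em <- error_model("proportional", sigma_prop = fit$sigma)
  expect_equal(neg_log_likelihood(fit$estimates, em, fixture_dataset()),
               fit$minus2LL / 2, tolerance = 1e-6)
  # and the reported criteria obey their identities
  ic <- information_criteria(fit$minus2LL, fit$p, fit$n_obs)
  expect_equal(unname(ic["aic"]), fit$aic)
  expect_equal(unname(ic["bic"]), fit$bic)
})

test_that("CV% excludes fixed parameters and shrinks with sample size", {
  fit <- fixture_fit()
  cv <- parameter_cv(fit)
  expect_setequal(names(cv), fit$free)
  expect_true(all(is.finite(cv) & cv > 0))
  # quadrupling replicates should halve the CVs (1/sqrt(n) scaling)
  p <- ref_params()
  d4 <- study_design(arms = c(0, 10, 20, 40), times = c(1, 2, 4, 8, 12),
                     replicates = c(TNF = 12, IL6 = 12, iNOS = 24, NO = 12))
  ds4 <- generate_dataset(p, d4, prop_error(0.1), seed = 101)
  fit4 <- suppressWarnings(fit_cascade(ds4, init = p, n_starts = 2,
                                       seed = 4))
  cv4 <- parameter_cv(fit4)
  ratio <- cv[fit$free] / cv4[fit$free]
  expect_gt(median(ratio), 1.5)
  expect_lt(median(ratio), 2.7)
})

test_that("hessian and bootstrap CV% agree within a factor of two", {
  fit <- fixture_fit()
  cv_h <- parameter_cv(fit)
  cv_b <- suppressWarnings(
    parameter_cv(fit, fixture_dataset(), method = "bootstrap", B = 40,
                 seed = 5, n_starts = 1))
  ratio <- cv_b / cv_h
  expect_true(all(ratio > 0.5 & ratio < 2))
})

test_that("recovery with one noiseless replicate returns the truth", {
  p <- ref_params()
  rec <- recover_parameters(p, default_design(), prop_error(0),
                            n_sim = 1, seed = 50, n_starts = 1,
                            compute_coverage = FALSE)
  expect_equal(rec$summary$median, unname(unlist(p[rec$summary$parameter])),
               tolerance = 1e-4)
  expect_equal(rec$n_failed, 0L)
})

test_that("doubling replicates reduces recovery RMSE", {
  p <- ref_params()
  d1 <- default_design()
  d2 <- study_design(arms = d1$arms, times = d1$times,
                     replicates = c(TNF = 6, IL6 = 6, iNOS = 12, NO = 6))
  r1 <- recover_parameters(p, d1, prop_error(0.1), n_sim = 3, seed = 60,
                           n_starts = 2, compute_coverage = FALSE)
  r2 <- recover_parameters(p, d2, prop_error(0.1), n_sim = 3, seed = 60,
                           n_starts = 2, compute_coverage = FALSE)
  rel1 <- r1$summary$rmse / r1$summary$truth
  rel2 <- r2$summary$rmse / r2$summary$truth
  expect_lt(mean(rel2), mean(rel1))
})
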