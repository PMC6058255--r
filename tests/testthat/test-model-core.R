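test_that("drug effect is log-linear with clamping below 1 uM", {
  # 8.32% inhibition per e-fold of concentration at the reference alpha
  expect_equal(drug_effect(0.0832, exp(1)), 0.0832)
  expect_equal(drug_effect(0.0832, 1), 0)
  expect_equal(drug_effect(0.0832, 0), 0)    # control arm, no drug
  expect_equal(drug_effect(0.0832, 0.5), 0)  # clamp: no predicted stimulation
  expect_equal(drug_effect(0, 40), 0)
  expect_equal(drug_effect(0.0832, 40), 0.30691477, tolerance = 1e-7)
  expect_equal(drug_effect(0.0832, c(1, exp(1), 40)),
               c(0, 0.0832, 0.0832 * log(40)))
})

test_that("drug effect rejects total production shutdown", {
  expect_error(drug_effect(0.3, 40), "shutdown")
  expect_error(drug_effect(-0.1, 40), "alpha")
  expect_error(drug_effect(0.1, -5), "conc")
})

test_that("TNF-alpha closed form satisfies its boundary cases", {
  p <- ref_params()
  expect_equal(tnf_closed_form(p, conc = 0, t = 0), p$tnf0)
  expect_equal(tnf_closed_form(p, conc = 0, t = -3), p$tnf0)  # history
  # zero-elimination limit: pure zero-order accumulation
  p0 <- pd_params(alpha = 0.0832, k_in_tnf = 3740, k_out_tnf = 0,
                  k_in_il6 = 0.353, k_out_il6 = 0.143, tau1 = 1.38,
                  k_in_inos = 0.00169, tau2 = 1.41, k_in_no = 0.0605,
                  delta = 1.35)
  expect_equal(tnf_closed_form(p0, conc = 0, t = 2), 100 + 2 * 3740)
  # frozen constant evaluated independently from S/k + (T0 - S/k) e^{-kt}
  expect_equal(tnf_closed_form(p, conc = 0, t = 1), 3750.215458,
               tolerance = 1e-9)
})

test_that("delayed lookup returns history before the lag elapses", {
  p <- ref_params()
  tr <- simulate_cascade(p, conc = 0, times = seq(0, 12, by = 0.05))
  expect_equal(delayed_tnf(tr, t = 1, tau = 1.38), p$tnf0)
  expect_equal(delayed_tnf(tr, t = 1.38, tau = 1.38), p$tnf0)  # boundary
  expect_equal(delayed_tnf(tr, t = 4, tau = 1.41),
               tnf_closed_form(p, 0, 2.59), tolerance = 1e-5)
  expect_error(delayed_tnf(tr, t = 20, tau = 1), "extrapolation")
})

test_that("cascade solver matches the TNF closed form and the lsoda route", {
  p <- ref_params()
  times <- c(0, 1, 2, 4, 8, 12)
  for (conc in c(0, 40)) {
    tr <- simulate_cascade(p, conc, times)
    cf <- tnf_closed_form(p, conc, times)
    expect_equal(tr$states[, "tnf"], cf, tolerance = 1e-7)
    tr2 <- simulate_cascade(p, conc, times, solver = "lsoda")
    expect_equal(tr2$states, tr$states, tolerance = 1e-6)
  }
})

test_that("iNOS without elimination equals the quadrature of delayed TNF", {
  p <- ref_params()  # k_out_inos = 0
  for (conc in c(0, 20)) {
    tr <- simulate_cascade(p, conc, times = c(0, 1, 2, 4, 8, 12))
    for (t in c(2, 8, 12)) {
      quad <- stats::integrate(function(s) tnf_closed_form(p, conc, s - p$tau2),
                               0, t, rel.tol = 1e-10)$value
      expected <- p$inos0 + p$k_in_inos * quad
      got <- unname(tr$states[tr$time == t, "inos"])
      expect_equal(got, expected, tolerance = 1e-6)
    }
  }
})

test_that("all production switched off leaves every state at baseline", {
  p <- pd_params(alpha = 0, k_in_tnf = 0, k_out_tnf = 0,
                 k_in_il6 = 0, k_out_il6 = 0, tau1 = 1,
                 k_in_inos = 0, tau2 = 1, k_in_no = 0, delta = 1,
                 tnf0 = 7, il6_0 = 3, inos0 = 1, no0 = 2)
  tr <- simulate_cascade(p, conc = 0, times = c(0, 2, 6, 12))
  expect_equal(tr$states,
               matrix(rep(c(7, 3, 1, 2), each = 4), 4,
                      dimnames = list(NULL, c("tnf", "il6", "inos", "no"))))
})

test_that("higher dose never raises any state (monotone inhibition)", {
  set.seed(42)
  times <- c(0, 1, 2, 4, 8, 12)
  for (i in 1:20) {
    p <- random_params()
    c1 <- runif(1, 1, 20)
    c2 <- runif(1, c1, 40)
    t1 <- simulate_cascade(p, c1, times)
    t2 <- simulate_cascade(p, c2, times)
    slack <- 1e-6 * abs(t1$states[-1, ]) + 1e-9  # integrator tolerance
    expect_true(all(t2$states[-1, ] <= t1$states[-1, ] + slack))
  }
})

test_that("iNOS and NO accumulate monotonically when not eliminated", {
  p <- ref_params()
  tr <- simulate_cascade(p, conc = 10, times = seq(0, 12, by = 0.5))
  expect_true(all(diff(tr$states[, "inos"]) >= -1e-10))
  expect_true(all(diff(tr$states[, "no"]) >= -1e-10))
})

test_that("zero concentration and zero alpha give identical trajectories", {
  p <- ref_params()
  p0 <- do.call(pd_params, modifyList(unclass(p), list(alpha = 0)))
  a <- simulate_cascade(p, conc = 0, times = c(0, 1, 4, 12))
  b <- simulate_cascade(p0, conc = 40, times = c(0, 1, 4, 12))
  expect_identical(a$states, b$states)
})

test_that("solution is insensitive to output-grid refinement", {
  p <- ref_params()
  coarse <- simulate_cascade(p, 20, seq(0, 12, by = 1))
  fine <- simulate_cascade(p, 20, seq(0, 12, by = 0.5))
  idx <- match(coarse$time, fine$time)
  rel <- abs(fine$states[idx, ] - coarse$states) /
    pmax(abs(coarse$states), 1e-12)
  expect_lt(max(rel[-1, ]), 1e-6)
})

test_that("time grids must start at zero and increase", {
  p <- ref_params()
  expect_error(simulate_cascade(p, 0, c(1, 2, 4)), "start at 0")
  expect_error(simulate_cascade(p, 0, c(0, 2, 2)), "increasing")
})

test_that("relative iNOS ratio normalizes blot intensities", {
  expect_equal(inos_relative_ratio(1.7, 2.2, 1.7, 2.2), 1)
  expect_equal(inos_relative_ratio(2, 1, 1, 1), 2)
  expect_equal(inos_relative_ratio(3.0, 1.5, 0.8, 1.6), 4.0)
  expect_error(inos_relative_ratio(0, 1, 1, 1), "> 0")
  expect_error(inos_relative_ratio(2, 1, -1, 1), "> 0")
})
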