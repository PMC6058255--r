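test_that("default design reproduces the four-arm time-course layout", {
  d <- default_design()
  expect_equal(d$arms, c(0, 10, 20, 40))
  expect_equal(d$times, c(1, 2, 4, 8, 12))
  expect_equal(unname(d$replicates), c(3, 3, 6, 3))
  expect_equal(default_design(include_24h = TRUE)$times,
               c(1, 2, 4, 8, 12, 24))
  # 4 arms x 5 times x (3+3+3 ELISA/Griess + 6 blot) records
  expect_equal(nrow(predict_design(ref_params(), d)), 300)
})

test_that("design construction rejects malformed inputs", {
  expect_error(study_design(c(0, 10), times = c(2, 1)))
  expect_error(study_design(c(0, 10), times = c(1, 2),
                            replicates = c(TNF = 3)), "named")
  expect_error(study_design(c(0, 0), times = c(1, 2)))
})

test_that("noise-free predictions equal the model states", {
  p <- ref_params()
  d <- default_design()
  pred <- predict_design(p, d)
  # TNF records match the closed form, arm by arm
  tnf <- pred[pred$analyte == "TNF", ]
  for (conc in d$arms) {
    arm <- tnf[tnf$baicalein_uM == conc, ]
    expect_equal(arm$value, tnf_closed_form(p, conc, arm$time_h),
                 tolerance = 1e-7)
  }
  # replicates within a cell are identical
  spread <- tapply(pred$value,
                   paste(pred$arm_id, pred$analyte, pred$time_h),
                   function(v) diff(range(v)))
  expect_true(all(spread == 0))
  # before the lag elapses iNOS integrates the constant history
  inos1 <- pred[pred$analyte == "iNOS" & pred$time_h == 1 &
                  pred$baicalein_uM == 0, "value"][1]
  expect_equal(inos1, p$inos0 + p$k_in_inos * p$tnf0 * 1, tolerance = 1e-6)
})

test_that("baseline-only model predicts the baselines everywhere", {
  p <- pd_params(alpha = 0, k_in_tnf = 0, k_out_tnf = 0, k_in_il6 = 0,
                 k_out_il6 = 0, tau1 = 1, k_in_inos = 0, tau2 = 1,
                 k_in_no = 0, delta = 1,
                 tnf0 = 11, il6_0 = 5, inos0 = 1, no0 = 2)
  pred <- predict_design(p, default_design())
  bases <- c(TNF = 11, IL6 = 5, iNOS = 1, NO = 2)
  expect_equal(pred$value, unname(bases[pred$analyte]))
})

test_that("error models perturb values as specified", {
  em <- prop_error(0)
  v <- c(10, 100, 1000)
  expect_identical(apply_error(v, em), v)  # zero sigma is a no-op
  set.seed(7); a <- apply_error(v, prop_error(0.1))
  set.seed(7); b <- apply_error(v, prop_error(0.1))
  expect_identical(a, b)  # determinism under the same RNG state
  # additive and power forms
  set.seed(7); eps <- rnorm(3)
  set.seed(7)
  expect_equal(apply_error(v, error_model("additive", sigma_add = 2)),
               v + 2 * eps)
  set.seed(7)
  expect_equal(apply_error(v, error_model("power", sigma_add = 0.5,
                                          power_exponent = 0.5)),
               v + 0.5 * sqrt(v) * eps)
})

test_that("proportional noise has the configured coefficient of variation", {
  set.seed(99)
  x <- apply_error(rep(100, 1e5), prop_error(0.1))
  expect_equal(sd(x) / mean(x), 0.1, tolerance = 0.02)
  expect_true(all(x >= 0))
})

test_that("zero-sigma generation round-trips to the noise-free surface", {
  p <- ref_params()
  d <- default_design()
  expect_equal(generate_dataset(p, d, prop_error(0), seed = 5),
               predict_design(p, d), ignore_attr = TRUE)
})

test_that("generation is seed-deterministic down to the serialized bytes", {
  p <- ref_params()
  d <- default_design()
  a <- generate_dataset(p, d, prop_error(0.1), seed = 11)
  b <- generate_dataset(p, d, prop_error(0.1), seed = 11)
  expect_identical(a$value, b$value)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_dataset(a, f1); write_dataset(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  c2 <- generate_dataset(p, d, prop_error(0.1), seed = 12)
  expect_false(identical(a$value, c2$value))
})

test_that("replicate means concentrate on the noise-free value", {
  p <- ref_params()
  d <- study_design(arms = c(0, 40), times = c(2, 8),
                    replicates = c(TNF = 200, IL6 = 200, iNOS = 200,
                                   NO = 200))
  ds <- generate_dataset(p, d, prop_error(0.1), seed = 21)
  truth <- predict_design(p, d)
  key <- function(x) paste(x$arm_id, x$analyte, x$time_h)
  mu <- tapply(ds$value, key(ds), mean)
  ref <- tapply(truth$value, key(truth), mean)
  se <- 0.1 * ref / sqrt(200)
  within3 <- abs(mu - ref[names(mu)]) <= 3 * se[names(mu)]
  expect_gte(mean(within3), 0.95)
})
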