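# Shared fixtures: the reference generating truth, a fast reduced design,
# and a cached noisy fit reused by estimation and diagnostic tests.

ref_params <- function(...) baicalein_reference_params(...)

prop_error <- function(sigma = 0.1) {
  error_model("proportional", sigma_prop = sigma)
}

# small random-but-valid parameter sets for property tests
random_params <- function() {
  pd_params(
    alpha = runif(1, 0, 0.2),
    k_in_tnf = exp(runif(1, log(10), log(1e4))),
    k_out_tnf = exp(runif(1, log(0.01), log(1))),
    k_in_il6 = exp(runif(1, log(0.01), log(1))),
    k_out_il6 = exp(runif(1, log(0.01), log(1))),
    tau1 = runif(1, 0, 3),
    k_in_inos = exp(runif(1, log(1e-4), log(0.01))),
    k_out_inos = runif(1, 0, 0.5),
    tau2 = runif(1, 0, 3),
    k_in_no = exp(runif(1, log(0.01), log(0.5))),
    k_out_no = runif(1, 0, 0.5),
    delta = runif(1, 0.5, 2),
    tnf0 = runif(1, 10, 200), il6_0 = runif(1, 10, 100),
    inos0 = 1, no0 = runif(1, 0.5, 2))
}

# one noisy dataset + its pooled-ML fit, computed once per test run
fixture_env <- new.env(parent = emptyenv())

fixture_dataset <- function() {
  if (is.null(fixture_env$dataset))
    fixture_env$dataset <- generate_dataset(ref_params(), default_design(),
                                            prop_error(0.1), seed = 101)
  fixture_env$dataset
}

fixture_fit <- function() {
  if (is.null(fixture_env$fit))
    fixture_env$fit <- suppressWarnings(
      fit_cascade(fixture_dataset(), init = ref_params(), n_starts = 4,
                  seed = 1))
  fixture_env$fit
}
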