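#' Pooled Gaussian negative log-likelihood of a dataset
#'
#' Naive-pooled likelihood: every record is an independent Gaussian
#' observation centred on the cascade-model prediction for its arm and
#' time, with standard deviation given by the residual-error model
#' (additive: \eqn{\sigma}; proportional: \eqn{\sigma \hat y}; power:
#' \eqn{\sigma \hat y^{\gamma}}).  No random effects — this is the
#' population-level analogue of a mixed-effects fit, used because only
#' population estimates are reported for this experiment.
#'
#' @param params A [pd_params()] object.
#' @param em A [error_model()] with strictly positive sigma(s).
#' @param dataset Long-format dataset (see [predict_design()]).
#' @param rtol Integration tolerance passed to [simulate_cascade()].
#' @return The scalar NLL; `+Inf` for parameter sets violating model
#'   invariants (e.g. inhibition fraction \eqn{\ge} 1), so optimizers can
#'   step through invalid regions.
#' @export
neg_log_likelihood <- function(params, em, dataset, rtol = 1e-8) {
  stopifnot(is_pd_params(params), inherits(em, "pd_error_model"))
  validate_dataset(dataset)
  times <- sort(unique(dataset$time_h))
  total <- 0
  for (conc in sort(unique(dataset$baicalein_uM))) {
    tr <- try(simulate_cascade(params, conc, times = c(0, times),
                               rtol = rtol), silent = TRUE)
    if (inherits(tr, "try-error")) return(Inf)
    sub <- dataset[dataset$baicalein_uM == conc, ]
    state_col <- c(TNF = "tnf", IL6 = "il6", iNOS = "inos", NO = "no")
    pred <- tr$states[cbind(match(sub$time_h, tr$time),
                            match(state_col[sub$analyte],
                                  colnames(tr$states)))]
    sd <- numeric(nrow(sub))
    for (a in unique(sub$analyte)) {
      i <- sub$analyte == a
      sd[i] <- error_sd_at(em, a, pred[i])
    }
    if (any(sd <= 0)) return(Inf)
    total <- total +
      sum(0.5 * log(2 * pi * sd^2) + (sub$value - pred)^2 / (2 * sd^2))
  }
  total
}

#' Akaike and Bayesian information criteria
#'
#' `aic = minus2LL + 2p`, `bic = minus2LL + p * log(n_obs)`, with `p` the
#' number of free parameters (structural plus residual-error) and `n_obs`
#' the number of fitted records.
#'
#' @param minus2LL Twice the negative log-likelihood at the optimum.
#' @param p Number of free parameters (>= 1).
#' @param n_obs Number of observations (>= 1).
#' @return Named numeric vector `c(aic, bic)`.
#' @export
#' @examples
#' information_criteria(2818.03, p = 24, n_obs = 288)
information_criteria <- function(minus2LL, p, n_obs) {
  stopifnot(is.numeric(minus2LL), p >= 1, n_obs >= 1)
  c(aic = minus2LL + 2 * p, bic = minus2LL + p * log(n_obs))
}

# ---- internal machinery for profiled-sigma pooled ML ----------------------

# Sufficient statistics per (arm, analyte, time) cell: replicate count,
# sum and sum of squares.  The Gaussian NLL only needs these, which makes
# each likelihood evaluation a handful of vectorized operations per arm.
dataset_suffstats <- function(dataset) {
  validate_dataset(dataset)
  times <- sort(unique(dataset$time_h))
  concs <- sort(unique(dataset$baicalein_uM))
  cells <- list()
  for (ci in seq_along(concs)) {
    for (a in analyte_levels()) {
      sub <- dataset[dataset$baicalein_uM == concs[ci] &
                       dataset$analyte == a, ]
      if (!nrow(sub)) next
      n <- tapply(sub$value, factor(sub$time_h, levels = times), length)
      s1 <- tapply(sub$value, factor(sub$time_h, levels = times), sum)
      s2 <- tapply(sub$value^2, factor(sub$time_h, levels = times), sum)
      keep <- !is.na(n)
      cells[[length(cells) + 1]] <-
        list(conc = concs[ci], analyte = a, times = times[keep],
             n = unname(n[keep]), s1 = unname(s1[keep]),
             s2 = unname(s2[keep]))
    }
  }
  list(times = times, concs = concs, cells = cells,
       analytes = intersect(analyte_levels(), unique(dataset$analyte)))
}

# Profiled pooled NLL: per-analyte residual scale sigma_a maximized out in
# closed form (its MLE given the predictions), leaving only structural
# parameters.  `weight(pred)` is the variance-model weight w with
# sd = sigma * w: 1 (additive), pred (proportional), pred^gamma (power).
# A floor on the profiled sigma^2 keeps the objective finite on
# noise-free data.
profiled_nll <- function(params, ss, kind, power_exponent = 0.5,
                         rtol = 1e-8, sigma2_floor = 1e-20,
                         return_sigma = FALSE) {
  state_idx <- c(TNF = 1L, IL6 = 2L, iNOS = 3L, NO = 4L)
  preds <- vector("list", length(ss$concs))
  pv <- solver_param_vector(params)
  for (ci in seq_along(ss$concs)) {
    f <- tryCatch(drug_effect(params$alpha, ss$concs[ci]),
                  error = function(e) NA_real_)
    if (!is.finite(f)) return(Inf)
    m <- tryCatch(cascade_solve_cpp(pv, f, c(0, ss$times), rtol, rtol),
                  error = function(e) NULL)
    if (is.null(m) || any(!is.finite(m))) return(Inf)
    preds[[ci]] <- m
  }
  acc <- list()
  for (cell in ss$cells) {
    ci <- match(cell$conc, ss$concs)
    p <- preds[[ci]][match(cell$times, c(0, ss$times)),
                     state_idx[[cell$analyte]]]
    w <- switch(kind, additive = rep_len(1, length(p)), proportional = p,
                power = p^power_exponent)
    if (any(w <= 0) || any(p < 0)) return(Inf)
    rss_w <- sum((cell$s2 - 2 * p * cell$s1 + cell$n * p^2) / w^2)
    a <- cell$analyte
    if (is.null(acc[[a]])) acc[[a]] <- c(rss = 0, logw = 0, N = 0)
    acc[[a]] <- acc[[a]] + c(rss_w, sum(cell$n * log(w)), sum(cell$n))
  }
  total <- 0
  sigma <- numeric(0)
  for (a in names(acc)) {
    N <- acc[[a]][["N"]]
    s2 <- max(acc[[a]][["rss"]] / N, sigma2_floor)
    total <- total + N / 2 * (log(2 * pi) + 1 + log(s2)) +
      acc[[a]][["logw"]]
    sigma[a] <- sqrt(s2)
  }
  if (return_sigma) list(nll = total, sigma = sigma) else total
}
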