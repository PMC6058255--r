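#' Default box bounds for free structural parameters
#'
#' Natural-scale bounds used by [fit_cascade()].  `alpha` is capped at
#' 0.26 so the inhibition fraction stays below 1 at the highest designed
#' concentration (40 \eqn{\mu}M: \eqn{0.26 \ln 40 \approx 0.96}); lag
#' times are restricted to \[0, 6\] h (half the sampling window); `delta`
#' to \[0.05, 5\].  Positive rate constants get wide log-scale-friendly
#' ranges.
#'
#' @return List with named numeric vectors `lower` and `upper`.
#' @export
default_bounds <- function() {
  lower <- c(alpha = 0, k_in_tnf = 1e-3, k_out_tnf = 1e-5,
             k_in_il6 = 1e-6, k_out_il6 = 1e-5, tau1 = 0,
             k_in_inos = 1e-8, k_out_inos = 0, tau2 = 0,
             k_in_no = 1e-6, k_out_no = 0, delta = 0.05,
             tnf0 = 0, il6_0 = 0, inos0 = 0, no0 = 0)
  upper <- c(alpha = 0.26, k_in_tnf = 1e7, k_out_tnf = 10,
             k_in_il6 = 100, k_out_il6 = 10, tau1 = 6,
             k_in_inos = 10, k_out_inos = 10, tau2 = 6,
             k_in_no = 10, k_out_no = 10, delta = 5,
             tnf0 = 1e7, il6_0 = 1e7, inos0 = 1e4, no0 = 1e4)
  list(lower = lower, upper = upper)
}

# parameters optimized on log scale when free with positive init;
# alpha and the lag times stay on the natural scale (their bounds
# include 0)
log_scale_params <- function() {
  c("k_in_tnf", "k_out_tnf", "k_in_il6", "k_out_il6", "k_in_inos",
    "k_out_inos", "k_in_no", "k_out_no", "delta",
    "tnf0", "il6_0", "inos0", "no0")
}

#' Fit the cascade model by pooled maximum likelihood
#'
#' Bounded multi-start local optimization ([stats::nlminb()]) of the
#' pooled Gaussian likelihood with the per-analyte residual scale
#' profiled out in closed form.  By default the two late-phase
#' elimination constants `k_out_inos`, `k_out_no` and all four baselines
#' are fixed at their `init` values (baselines are time-0 control values,
#' not free parameters), leaving 10 free structural parameters plus one
#' residual sigma per analyte.
#'
#' Positive rate constants and `delta` are optimized on the log scale;
#' `alpha` and the lag times on the natural scale.  Because the cascade
#' is block-triangular (the TNF-\eqn{\alpha} parameters are informed only
#' by TNF-\eqn{\alpha} records, the IL-6 block adds three parameters, and
#' so on), an extra staged start is computed by default: each block is
#' fitted on its own analyte with a small multi-start, conditioning on
#' the upstream blocks, and the result seeds the joint optimization.
#' The remaining starts are `init` itself and copies of `init` jittered
#' by independent log-uniform factors in `jitter_range`, clamped to
#' `bounds`.  The fit is deterministic given (`dataset`, `init`, options,
#' `seed`).
#'
#' @param dataset Long-format dataset (see [predict_design()]).
#' @param init A [pd_params()] object: starting values, and the values at
#'   which fixed parameters are held.
#' @param fixed Character vector of parameter names to hold fixed.
#' @param error_kind Residual-error weighting: `"proportional"`,
#'   `"additive"` or `"power"`.
#' @param power_exponent Fixed exponent of the power weighting.
#' @param bounds List with `lower`/`upper` named vectors
#'   ([default_bounds()]).
#' @param n_starts Number of optimization starts (>= 1).
#' @param jitter_range Multiplicative jitter range for starts 2..n.
#' @param seed Seed for the start jitter.
#' @param rtol Integration tolerance for the model solves.
#' @param staged_start Prepend the block-wise staged start (see Details).
#' @param control Passed to [stats::nlminb()].
#' @return An object of class `pd_fit`: the estimates, free/fixed flags,
#'   per-analyte residual sigma estimates, `minus2LL`, `aic`, `bic`
#'   (`p` = free structural + residual sigmas), and convergence metadata.
#'   Errors if no start converges; warns when the best NLL is not
#'   reproduced by at least two starts.
#' @export
#' @examples
#' truth <- baicalein_reference_params()
#' d <- generate_dataset(truth, default_design(),
#'                       error_model("proportional", sigma_prop = 0.1),
#'                       seed = 101)
#' \donttest{
#' fit <- fit_cascade(d, init = truth, n_starts = 2)
#' fit$estimates$alpha
#' }
fit_cascade <- function(dataset, init,
                        fixed = c("k_out_inos", "k_out_no",
                                  "tnf0", "il6_0", "inos0", "no0"),
                        error_kind = c("proportional", "additive", "power"),
                        power_exponent = 0.5,
                        bounds = default_bounds(),
                        n_starts = 8, jitter_range = c(0.5, 2),
                        seed = 1, rtol = 1e-8, staged_start = TRUE,
                        control = list(eval.max = 4000, iter.max = 800)) {
  stopifnot(is_pd_params(init))
  error_kind <- match.arg(error_kind)
  unknown <- setdiff(fixed, pd_param_names())
  if (length(unknown))
    stop("unknown parameter(s) in `fixed`: ", paste(unknown, collapse = ", "))
  ss <- dataset_suffstats(dataset)
  free <- setdiff(pd_param_names(), fixed)
  if (!length(free)) stop("no free parameters")
  init_v <- unlist(init[pd_param_names()])
  lower <- bounds$lower[free]
  upper <- bounds$upper[free]
  if (any(init_v[free] < lower | init_v[free] > upper))
    stop("init outside bounds for: ",
         paste(free[init_v[free] < lower | init_v[free] > upper],
               collapse = ", "))

  if (!is.null(seed)) set.seed(seed)
  staged <- if (staged_start)
    staged_init(ss, init_v, free, bounds, error_kind, power_exponent, rtol,
                control)
  use_log <- free %in% log_scale_params() & init_v[free] > 0 & lower > 0
  to_t <- function(v) ifelse(use_log, log(v), v)
  from_t <- function(x) ifelse(use_log, exp(x), x)
  params_at <- function(v_free) {
    p <- as.list(init_v)
    p[free] <- v_free
    structure(p, class = "pd_params")
  }
  obj_nat <- function(v_free)
    profiled_nll(params_at(v_free), ss, error_kind, power_exponent, rtol)
  obj_t <- function(x) obj_nat(from_t(x))

  starts <- vector("list", n_starts)
  starts[[1]] <- init_v[free]
  if (n_starts > 1) {
    for (m in 2:n_starts) {
      fac <- exp(stats::runif(length(free), log(jitter_range[1]),
                              log(jitter_range[2])))
      starts[[m]] <- pmin(pmax(init_v[free] * fac, lower), upper)
    }
  }
  if (staged_start) starts <- c(list(staged[free]), starts)
  results <- vector("list", length(starts))
  for (m in seq_along(starts)) {
    results[[m]] <- tryCatch(
      stats::nlminb(to_t(starts[[m]]), obj_t,
                    lower = to_t(lower), upper = to_t(upper),
                    control = control),
      error = function(e) list(convergence = 1L, objective = Inf,
                               message = conditionMessage(e)))
  }
  # nlminb reports "false convergence" (code 1) on objectives that go
  # flat near the optimum, e.g. when the profiled sigma^2 hits its floor
  # on noise-free data; such endpoints are kept as candidate optima
  conv <- vapply(results, function(r)
    is.finite(r$objective) &&
      (identical(r$convergence, 0L) ||
         grepl("false convergence", r$message %||% "")), logical(1))
  if (!any(conv))
    stop("no optimization start converged (messages: ",
         paste(unique(vapply(results, function(r)

         as.character(r$message %||% "?"), character(1))), collapse = "; "),
         ")")
  nlls <- vapply(results, function(r) r$objective, numeric(1))
  nlls[!conv] <- Inf
  best_i <- which.min(nlls)
  best <- results[[best_i]]
  if (n_starts >= 2 && sum(nlls <= best$objective + 0.1) < 2)
    warning("best NLL reached by only one start; ",
            "consider more starts or wider jitter")

  est_free <- from_t(best$par)
  names(est_free) <- free
  estimates <- params_at(est_free)
  prof <- profiled_nll(estimates, ss, error_kind, power_exponent, rtol,
                       return_sigma = TRUE)
  n_obs <- sum(vapply(ss$cells, function(c) sum(c$n), numeric(1)))
  p_total <- length(free) + length(prof$sigma)
  ic <- information_criteria(2 * prof$nll, p_total, n_obs)
  em_hat <- error_model(error_kind,
                        sigma_add = if (error_kind != "proportional")
                          prof$sigma else 0,
                        sigma_prop = if (error_kind == "proportional")
                          prof$sigma else 0,
                        power_exponent = power_exponent)
  structure(list(
    estimates = estimates, free = free, fixed = fixed,
    error_kind = error_kind, power_exponent = power_exponent,
    sigma = prof$sigma, error_model = em_hat,
    minus2LL = 2 * prof$nll, n_obs = n_obs, p = p_total,
    aic = unname(ic["aic"]), bic = unname(ic["bic"]),
    convergence = list(status = best$convergence,
                       message = best$message,
                       iterations = best$iterations,
                       best_start = best_i,
                       n_converged = sum(conv),
                       start_nll = nlls),
    init = init, seed = seed, rtol = rtol,
    objective_natural = obj_nat), class = "pd_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Block-wise staged initialization.  Exploits the cascade's triangular
# structure: each block of structural parameters is fitted against its
# own analyte's records only, conditioning on the blocks upstream, with a
# small multi-start per block (the 3-D subproblems are cheap and the
# IL-6 block in particular has a fast-turnover local optimum that a
# single start can fall into).  Returns a full parameter vector.
staged_init <- function(ss, init_v, free, bounds, kind, power_exponent,
                        rtol, control, n_block_starts = 6) {
  blocks <- list(list(pars = c("alpha", "k_in_tnf", "k_out_tnf"),
                      analyte = "TNF"),
                 list(pars = c("k_in_il6", "k_out_il6", "tau1"),
                      analyte = "IL6"),
                 list(pars = c("k_in_inos", "k_out_inos", "tau2"),
                      analyte = "iNOS"),
                 list(pars = c("k_in_no", "k_out_no", "delta"),
                      analyte = "NO"))
  cur <- init_v
  for (bl in blocks) {
    fr <- intersect(bl$pars, free)
    if (!length(fr)) next
    ssb <- ss
    ssb$cells <- Filter(function(cell) cell$analyte == bl$analyte, ss$cells)
    if (!length(ssb$cells)) next
    lower <- bounds$lower[fr]
    upper <- bounds$upper[fr]
    use_log <- fr %in% log_scale_params() & cur[fr] > 0 & lower > 0
    to_t <- function(v) ifelse(use_log, log(v), v)
    from_t <- function(x) ifelse(use_log, exp(x), x)
    obj <- function(x) {
      v <- as.list(cur)
      v[fr] <- from_t(x)
      profiled_nll(structure(v, class = "pd_params"), ssb, kind,
                   power_exponent, rtol)
    }
    best <- NULL
    for (m in seq_len(n_block_starts)) {
      s0 <- if (m == 1) cur[fr]
            else pmin(pmax(cur[fr] * exp(stats::runif(length(fr),
                                                      log(0.25), log(4))),
                           lower), upper)
      r <- tryCatch(stats::nlminb(to_t(s0), obj, lower = to_t(lower),
                                  upper = to_t(upper), control = control),
                    error = function(e) NULL)
      if (!is.null(r) && is.finite(r$objective) &&
          (is.null(best) || r$objective < best$objective)) best <- r
    }
    if (!is.null(best)) cur[fr] <- from_t(best$par)
  }
  cur
}

#' @export
print.pd_fit <- function(x, ...) {
  cat("Pooled-ML cascade fit (", x$error_kind, " error)\n", sep = "")
  cat("Free parameters:\n")
  est <- unlist(x$estimates[x$free])
  tab <- data.frame(estimate = signif(est, 4))
  if (!is.null(x$cv_percent))
    tab$cv_percent <- signif(x$cv_percent[x$free], 3)
  print(tab)
  cat("Residual sigma:", paste(names(x$sigma), signif(x$sigma, 3),
                               sep = "=", collapse = ", "), "\n")
  cat(sprintf("-2LL %.2f | AIC %.2f | BIC %.2f | n_obs %d | p %d\n",
              x$minus2LL, x$aic, x$bic, x$n_obs, x$p))
  cat("Converged starts:", x$convergence$n_converged, "(best: start",
      x$convergence$best_start, ")\n")
  invisible(x)
}

#' Coefficient of variation of fitted parameters
#'
#' `CV% = 100 * SE / estimate` per free structural parameter.  Method
#' `"hessian"` takes standard errors from the inverse numerical observed
#' information of the profiled likelihood at the optimum
#' ([pracma::hessian()]); `"bootstrap"` resamples records with
#' replacement within each (arm, analyte, time) cell and refits.
#'
#' @param fit A `pd_fit` from [fit_cascade()].
#' @param dataset The fitted dataset (required for `"bootstrap"`).
#' @param method `"hessian"` or `"bootstrap"`.
#' @param B Bootstrap replicate count.
#' @param seed Bootstrap seed.
#' @param n_starts Starts per bootstrap refit (inits at the original
#'   estimate, so few are needed).
#' @return Named CV% vector over the free parameters (fixed parameters
#'   are excluded).  Errors if the information matrix is singular,
#'   naming the parameters in its numerical null space.
#' @export
parameter_cv <- function(fit, dataset = NULL,
                         method = c("hessian", "bootstrap"),
                         B = 200, seed = 1, n_starts = 2) {
  stopifnot(inherits(fit, "pd_fit"))
  method <- match.arg(method)
  est <- unlist(fit$estimates[fit$free])
  if (method == "hessian") {
    # observed information on the relative scale u = (x - est)/est, which
    # conditions the Hessian (raw parameters span many orders of
    # magnitude) and gives CV% = 100 * SE(u) directly
    scale <- ifelse(est != 0, abs(est), 1)
    obj_u <- function(u) fit$objective_natural(est + scale * u)
    H <- pracma::hessian(obj_u, rep(0, length(est)))
    ev <- eigen(H, symmetric = TRUE)
    thresh <- .Machine$double.eps^0.5 * max(abs(ev$values))
    if (any(ev$values < thresh)) {
      null_dirs <- ev$vectors[, ev$values < thresh, drop = FALSE]
      culprits <- fit$free[apply(abs(null_dirs) > 0.3, 1, any)]
      stop("information matrix is singular; null space involves: ",
           paste(culprits, collapse = ", "))
    }
    se_u <- sqrt(diag(solve(H)))
    cv <- 100 * se_u * scale / abs(est)
  } else {
    if (is.null(dataset)) stop("bootstrap CV needs the fitted dataset")
    key <- with(dataset, paste(arm_id, analyte, time_h))
    boots <- matrix(NA_real_, B, length(fit$free),
                    dimnames = list(NULL, fit$free))
    for (b in seq_len(B)) {
      set.seed(seed + b)
      idx <- unlist(lapply(split(seq_len(nrow(dataset)), key),
                           function(i) sample(i, length(i), replace = TRUE)))
      bd <- dataset[idx, ]
      bd$replicate <- stats::ave(bd$value, with(bd, paste(arm_id, analyte,
                                                          time_h)),
                                 FUN = seq_along)
      f <- tryCatch(suppressWarnings(
        fit_cascade(bd, init = fit$estimates, fixed = fit$fixed,
                    error_kind = fit$error_kind,
                    power_exponent = fit$power_exponent,
                    n_starts = n_starts, seed = seed + b,
                    rtol = fit$rtol)),
        error = function(e) NULL)
      if (!is.null(f)) boots[b, ] <- unlist(f$estimates[fit$free])
    }
    if (sum(stats::complete.cases(boots)) < B / 2)
      warning("more than half of bootstrap refits failed")
    cv <- 100 * apply(boots, 2, stats::sd, na.rm = TRUE) / abs(est)
  }
  names(cv) <- fit$free
  cv
}
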