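#' Log-linear inhibition of TNF-alpha production by baicalein
#'
#' The inhibition fraction \eqn{f(C) = \alpha \ln C}: the proportion by
#' which the zero-order TNF-\eqn{\alpha} production is reduced at drug
#' concentration \eqn{C}.  Natural logarithm, so `alpha` is the increment
#' of the inhibition fraction per e-fold rise in concentration.
#'
#' For `conc` in \[0, 1\] \eqn{\mu}M the fraction is defined as 0: the
#' control arm has no drug, and extrapolating \eqn{\alpha \ln C < 0} below
#' 1 \eqn{\mu}M would predict stimulation, outside the model's supported
#' 10--40 \eqn{\mu}M range.
#'
#' @param alpha Non-negative inhibition coefficient (dimensionless).
#' @param conc Baicalein concentration(s), \eqn{\mu}M; vectorized.
#' @return Inhibition fraction(s) in \[0, 1).
#'   Errors if \eqn{\alpha \ln C \ge 1} for any element (the model would
#'   predict negative production).
#' @export
#' @examples
#' drug_effect(0.0832, exp(1))  # 0.0832: +8.32% inhibition per e-fold
#' drug_effect(0.0832, c(10, 20, 40))
drug_effect <- function(alpha, conc) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, is.numeric(conc))
  if (!is.finite(alpha) || alpha < 0) stop("alpha must be finite and >= 0")
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("conc must be finite and >= 0")
  f <- ifelse(conc > 1, alpha * log(conc), 0)
  if (any(f >= 1))
    stop("alpha * ln(conc) >= 1 at conc = ",
         paste(conc[f >= 1], collapse = ", "),
         ": inhibition fraction reaches total shutdown; ",
         "invalid parameter/concentration combination")
  f
}

#' Exact solution of the TNF-alpha turnover equation
#'
#' The TNF-\eqn{\alpha} state obeys the linear indirect-response equation
#' \eqn{dT/dt = k_{in}(1 - f) - k_{out} T} with constant inhibition
#' fraction \eqn{f}, whose solution is
#' \eqn{T(t) = S/k_{out} + (T_0 - S/k_{out}) e^{-k_{out} t}} with
#' \eqn{S = k_{in}(1 - f)}, degenerating to \eqn{T_0 + S t} when
#' \eqn{k_{out} = 0}.  Used both as the solver oracle and for the exact
#' delayed lookups \eqn{T(t - \tau)}; times \eqn{\le 0} return the
#' pre-stimulus history `tnf0`.
#'
#' @param params A [pd_params()] object.
#' @param conc Baicalein concentration (\eqn{\mu}M), scalar.
#' @param t Time(s) in hours post-LPS; vectorized.  Values \eqn{\le 0}
#'   return `params$tnf0`.
#' @return TNF-\eqn{\alpha} level(s) at `t`.
#' @export
#' @examples
#' p <- baicalein_reference_params()
#' tnf_closed_form(p, conc = 0, t = c(0, 1, 2))
tnf_closed_form <- function(params, conc, t) {
  stopifnot(is_pd_params(params), is.numeric(t))
  f <- drug_effect(params$alpha, conc)
  S <- params$k_in_tnf * (1 - f)
  tpos <- pmax(t, 0)
  if (params$k_out_tnf > 0) {
    A <- S / params$k_out_tnf
    A + (params$tnf0 - A) * exp(-params$k_out_tnf * tpos)
  } else {
    params$tnf0 + S * tpos
  }
}

#' Delayed TNF-alpha lookup on a stored trajectory
#'
#' Returns the TNF-\eqn{\alpha} value at \eqn{t - \tau} by monotone cubic
#' interpolation of a stored trajectory, for use in the lagged production
#' terms of the IL-6 and iNOS equations.  When \eqn{t - \tau \le 0} the
#' pre-stimulus history value is returned.  (The default cascade solver
#' does not need this: TNF-\eqn{\alpha} has an exact solution which is
#' evaluated directly at \eqn{t - \tau}.)
#'
#' @param trajectory A `pd_trajectory` from [simulate_cascade()].
#' @param t Lookup time (h), scalar or vector, within the stored grid.
#' @param tau Non-negative lag (h).
#' @param history_value Value used for \eqn{t - \tau \le 0}; defaults to
#'   the trajectory's TNF-\eqn{\alpha} baseline.
#' @return Interpolated TNF-\eqn{\alpha} value(s); errors if
#'   \eqn{t - \tau} exceeds the stored grid (no extrapolation).
#' @export
delayed_tnf <- function(trajectory, t, tau,
                        history_value = trajectory$states[1, "tnf"]) {
  stopifnot(inherits(trajectory, "pd_trajectory"),
            is.numeric(t), is.numeric(tau), length(tau) == 1, tau >= 0)
  u <- t - tau
  if (any(u > max(trajectory$time) + 1e-12))
    stop("t - tau = ", max(u), " exceeds the stored grid end (",
         max(trajectory$time), " h); extrapolation forbidden")
  fun <- stats::splinefun(trajectory$time, trajectory$states[, "tnf"],
                          method = "monoH.FC")
  out <- ifelse(u > 0, fun(pmin(u, max(trajectory$time))), history_value)
  out
}

#' Solve the four-state cytokine cascade
#'
#' Integrates the turnover cascade
#' \deqn{dT/dt = k_{in,TNF}(1 - \alpha\ln C) - k_{out,TNF} T}
#' \deqn{dI/dt = k_{in,IL6}\, T(t-\tau_1) - k_{out,IL6} I}
#' \deqn{dE/dt = k_{in,iNOS}\, T(t-\tau_2) - k_{out,iNOS} E}
#' \deqn{dN/dt = k_{in,NO}\, E^{\delta} - k_{out,NO} N}
#' for one treatment arm on an output grid starting at 0.  The delayed
#' TNF-\eqn{\alpha} terms use the exact linear-ODE solution (history
#' `tnf0` for arguments \eqn{\le 0}), so no delay-differential machinery
#' is required.  The default solver is a compiled adaptive
#' Dormand--Prince 5(4) stepper split at the lag kink points; `"lsoda"`
#' routes through [deSolve::ode()] as an independent integration path.
#'
#' @param params A [pd_params()] object.
#' @param conc Baicalein concentration (\eqn{\mu}M), scalar.
#' @param times Output grid (h), strictly increasing, starting at 0.
#' @param rtol,atol Local relative/absolute integration tolerances
#'   (defaults 1e-8).
#' @param solver `"rk45"` (compiled, default) or `"lsoda"` ([deSolve]).
#' @return A `pd_trajectory`: list with `time`, a `states` matrix with
#'   columns `tnf`, `il6`, `inos`, `no`, plus `conc`, `inhibition` and
#'   `params`.  States more negative than \eqn{-10^{-9}} abort; smaller
#'   negative overshoot is clipped to 0 with a warning.
#' @export
#' @examples
#' p <- baicalein_reference_params()
#' tr <- simulate_cascade(p, conc = 40, times = c(0, 1, 2, 4, 8, 12))
#' head(as.data.frame(tr))
simulate_cascade <- function(params, conc, times, rtol = 1e-8, atol = 1e-8,
                             solver = c("rk45", "lsoda")) {
  stopifnot(is_pd_params(params), is.numeric(times), length(times) >= 1)
  solver <- match.arg(solver)
  if (times[1] != 0) stop("time grid must start at 0 (LPS addition)")
  if (any(diff(times) <= 0)) stop("time grid must be strictly increasing")
  f <- drug_effect(params$alpha, conc)
  if (solver == "rk45") {
    states <- cascade_solve_cpp(solver_param_vector(params), f, times,
                                rtol, atol)
  } else {
    states <- cascade_solve_lsoda(params, f, times, rtol, atol)
  }
  colnames(states) <- c("tnf", "il6", "inos", "no")
  if (any(states < -1e-9))
    stop("integrator produced a negative state beyond tolerance (min ",
         min(states), ")")
  if (any(states < 0)) {
    warning("clipping ", sum(states < 0),
            " marginally negative state value(s) to 0")
    states[states < 0] <- 0
  }
  structure(list(time = times, states = states, conc = conc,
                 inhibition = f, params = params,
                 interpolation = "exact closed-form TNF lookup"),
            class = "pd_trajectory")
}

# deSolve route: same equations, same exact delayed TNF lookup
cascade_solve_lsoda <- function(params, f, times, rtol, atol) {
  p <- params
  S <- p$k_in_tnf * (1 - f)
  tnf_at <- function(u) {
    if (u <= 0) return(p$tnf0)
    if (p$k_out_tnf > 0) {
      A <- S / p$k_out_tnf
      A + (p$tnf0 - A) * exp(-p$k_out_tnf * u)
    } else p$tnf0 + S * u
  }
  rhs <- function(t, y, parms) {
    list(c(S - p$k_out_tnf * y[1],
           p$k_in_il6 * tnf_at(t - p$tau1) - p$k_out_il6 * y[2],
           p$k_in_inos * tnf_at(t - p$tau2) - p$k_out_inos * y[3],
           p$k_in_no * max(y[3], 0)^p$delta - p$k_out_no * y[4]))
  }
  y0 <- c(p$tnf0, p$il6_0, p$inos0, p$no0)
  out <- deSolve::ode(y0, times, rhs, parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) stop("lsoda integration failed")
  unname(out[, 2:5, drop = FALSE])
}

#' @export
print.pd_trajectory <- function(x, ...) {
  cat("Cascade trajectory: baicalein ", x$conc, " uM (inhibition fraction ",
      signif(x$inhibition, 4), "), ", length(x$time), " grid points over [0, ",
      max(x$time), "] h\n", sep = "")
  utils::str(x$states)
  invisible(x)
}

#' @export
as.data.frame.pd_trajectory <- function(x, ...) {
  data.frame(baicalein_uM = x$conc, time_h = x$time,
             tnf = x$states[, "tnf"], il6 = x$states[, "il6"],
             inos = x$states[, "inos"], no = x$states[, "no"])
}

#' Relative iNOS expression ratio from immunoblot band intensities
#'
#' Western-blot iNOS signals are normalized to the GAPDH loading control
#' and then to the time-0 control lane:
#' \deqn{ratio = \frac{iNOS/GAPDH}{iNOS_0/GAPDH_0}.}
#'
#' @param inos_signal,gapdh_signal Band intensities at the measured time
#'   point (arbitrary units, > 0); vectorized.
#' @param inos0_signal,gapdh0_signal Band intensities of the time-0
#'   control lane (> 0).
#' @return Dimensionless relative expression ratio(s).
#' @export
#' @examples
#' inos_relative_ratio(3.0, 1.5, 0.8, 1.6)  # 4
inos_relative_ratio <- function(inos_signal, gapdh_signal,
                                inos0_signal, gapdh0_signal) {
  sig <- c(inos_signal, gapdh_signal, inos0_signal, gapdh0_signal)
  if (any(!is.finite(sig)) || any(sig <= 0))
    stop("all band intensities must be finite and > 0")
  (inos_signal / gapdh_signal) / (inos0_signal / gapdh0_signal)
}
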