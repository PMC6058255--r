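#' Residual-error model for observed analyte values
#'
#' The three residual weightings screened when fitting the cascade:
#' \describe{
#'   \item{additive}{\eqn{y = \hat y + \sigma_{add}\,\varepsilon}}
#'   \item{proportional}{\eqn{y = \hat y (1 + \sigma_{prop}\,\varepsilon)}
#'     ("multiplicative" weighting)}
#'   \item{power}{\eqn{y = \hat y + \sigma_{add}\, \hat y^{\gamma}
#'     \varepsilon}}
#' }
#' with \eqn{\varepsilon \sim N(0,1)} and truncation of generated values
#' at 0.  Sigmas may be scalars (shared across analytes) or named vectors
#' over `TNF`, `IL6`, `iNOS`, `NO`.
#'
#' @param kind One of `"additive"`, `"proportional"`, `"power"`.
#' @param sigma_add Additive/power scale in analyte units (>= 0).
#' @param sigma_prop Proportional scale as a fraction (>= 0).
#' @param power_exponent Exponent \eqn{\gamma} of the power model
#'   (dimensionless, fixed rather than estimated).
#' @return An object of class `pd_error_model`.
#' @export
#' @examples
#' error_model("proportional", sigma_prop = 0.1)
error_model <- function(kind = c("proportional", "additive", "power"),
                        sigma_add = 0, sigma_prop = 0, power_exponent = 0.5) {
  kind <- match.arg(kind)
  check_sigma <- function(s, nm) {
    if (any(!is.finite(s)) || any(s < 0)) stop(nm, " must be >= 0")
    if (length(s) > 1 && !setequal(names(s), analyte_levels()))
      stop(nm, " must be a scalar or named over TNF, IL6, iNOS, NO")
    s
  }
  check_sigma(sigma_add, "sigma_add")
  check_sigma(sigma_prop, "sigma_prop")
  stopifnot(is.finite(power_exponent))
  structure(list(kind = kind, sigma_add = sigma_add,
                 sigma_prop = sigma_prop, power_exponent = power_exponent),
            class = "pd_error_model")
}

#' @export
print.pd_error_model <- function(x, ...) {
  cat("Residual-error model: ", x$kind, sep = "")
  if (x$kind == "additive") cat(" (sigma_add ",
                                paste(signif(x$sigma_add, 3), collapse = "/"),
                                ")", sep = "")
  if (x$kind == "proportional") cat(" (sigma_prop ",
                                    paste(signif(x$sigma_prop, 3),
                                          collapse = "/"), ")", sep = "")
  if (x$kind == "power") cat(" (sigma_add ",
                             paste(signif(x$sigma_add, 3), collapse = "/"),
                             ", exponent ", x$power_exponent, ")", sep = "")
  cat("\n")
  invisible(x)
}

# per-analyte sigma for the model's active scale parameter
error_sigma_for <- function(em, analyte) {
  s <- if (em$kind == "proportional") em$sigma_prop else em$sigma_add
  if (length(s) > 1) unname(s[analyte]) else s
}

# residual standard deviation at prediction `pred` for one analyte
error_sd_at <- function(em, analyte, pred) {
  s <- error_sigma_for(em, analyte)
  switch(em$kind,
         additive = rep_len(s, length(pred)),
         proportional = s * pred,
         power = s * pred^em$power_exponent)
}

#' Perturb noise-free values with the residual-error model
#'
#' Adds one Gaussian draw per value on the observation scale, using the
#' current RNG state (seed management belongs to the caller, e.g.
#' [generate_dataset()]).  Results are truncated at 0, since
#' concentrations and expression ratios cannot be negative.
#'
#' @param values Non-negative noise-free values.
#' @param em A [error_model()].
#' @param analyte Analyte label (`TNF`, `IL6`, `iNOS`, `NO`) selecting the
#'   per-analyte sigma when sigmas are vectors.
#' @return Noisy values, same length as `values`.
#' @export
#' @examples
#' set.seed(1)
#' apply_error(c(100, 200), error_model("proportional", sigma_prop = 0.1),
#'             "TNF")
apply_error <- function(values, em, analyte = "TNF") {
  stopifnot(inherits(em, "pd_error_model"), is.numeric(values),
            all(values >= 0))
  sd <- error_sd_at(em, analyte, values)
  pmax(values + sd * stats::rnorm(length(values)), 0)
}
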