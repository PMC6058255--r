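#' Read and write time-course datasets as CSV
#'
#' The on-disk format is a UTF-8 CSV with header
#' `arm_id,baicalein_uM,analyte,time_h,replicate,value`, `.` as the
#' decimal mark and analytes in `TNF`, `IL6`, `iNOS`, `NO`.  Numeric
#' columns are serialized at full double precision (`%.17g`), so a
#' write--read round trip is value-exact.
#'
#' @param path File path.
#' @return `read_dataset()` returns the dataset data.frame; malformed
#'   input is rejected with the offending line numbers (distinct errors
#'   for missing columns, non-numeric fields, negative values, unknown
#'   analytes and duplicate keys).  A header-only file yields an empty
#'   dataset with a warning.
#' @export
read_dataset <- function(path) {
  req <- c("arm_id", "baicalein_uM", "analyte", "time_h", "replicate",
           "value")
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(req, names(raw))
  if (length(missing))
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(raw), req)
  if (length(extra))
    stop("unexpected column(s) in ", path, ": ",
         paste(extra, collapse = ", "))
  if (!nrow(raw)) {
    warning("header-only file: ", path)
    return(data.frame(arm_id = character(), baicalein_uM = numeric(),
                      analyte = character(), time_h = numeric(),
                      replicate = integer(), value = numeric()))
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad))
      stop("non-numeric ", col, " at line(s) ",
           paste(bad + 1, collapse = ", "), " of ", path)
    v
  }
  out <- data.frame(arm_id = raw$arm_id, baicalein_uM = num("baicalein_uM"),
                    analyte = raw$analyte, time_h = num("time_h"),
                    replicate = as.integer(num("replicate")),
                    value = num("value"))
  tryCatch(validate_dataset(out), error = function(e)
    stop(conditionMessage(e), " (rows count from the first data line of ",
         path, ")", call. = FALSE))
  out
}

#' @rdname read_dataset
#' @param dataset Dataset data.frame (see [predict_design()]).
#' @export
write_dataset <- function(dataset, path) {
  validate_dataset(dataset)
  fmt <- function(v) sprintf("%.17g", v)
  out <- data.frame(arm_id = dataset$arm_id,
                    baicalein_uM = fmt(dataset$baicalein_uM),
                    analyte = dataset$analyte,
                    time_h = fmt(dataset$time_h),
                    replicate = dataset$replicate,
                    value = fmt(dataset$value))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Pipeline run configuration
#'
#' A validated bundle of everything a simulate/fit/recover run needs:
#' parameter values, the fixed set, the design, the error model, seeds
#' and fit options.  Round-trips losslessly through JSON; unknown keys
#' are rejected on construction and on read.
#'
#' @param params A [pd_params()] object (generating truth or fit inits).
#' @param fixed Names of parameters held fixed during fitting.
#' @param design A [study_design()].
#' @param em A [error_model()].
#' @param seed Base RNG seed.
#' @param n_sim Number of simulation replicates for recovery runs.
#' @param n_starts Multi-start count for fits.
#' @param rtol Integrator tolerance.
#' @return An object of class `pd_run_config`.
#' @export
run_config <- function(params, fixed = c("k_out_inos", "k_out_no",
                                         "tnf0", "il6_0", "inos0", "no0"),
                       design = default_design(),
                       em = error_model("proportional", sigma_prop = 0.1),
                       seed = 100, n_sim = 20, n_starts = 8, rtol = 1e-8) {
  stopifnot(is_pd_params(params), inherits(design, "pd_design"),
            inherits(em, "pd_error_model"))
  structure(list(params = params, fixed = fixed, design = design,
                 error_model = em, seed = seed, n_sim = n_sim,
                 n_starts = n_starts, rtol = rtol),
            class = "pd_run_config")
}

#' @rdname run_config
#' @param config A `pd_run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "pd_run_config"))
  obj <- list(params = as.list(unclass(config$params)),
              fixed = as.list(config$fixed),
              design = list(arms = config$design$arms,
                            times = config$design$times,
                            replicates = as.list(config$design$replicates)),
              error_model = unclass(config$error_model),
              seed = config$seed, n_sim = config$n_sim,
              n_starts = config$n_starts, rtol = config$rtol)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- c("params", "fixed", "design", "error_model", "seed", "n_sim",
             "n_starts", "rtol")
  unknown <- setdiff(names(obj), known)
  if (length(unknown))
    stop("unknown key(s) in ", path, ": ", paste(unknown, collapse = ", "))
  missing <- setdiff(known, names(obj))
  if (length(missing))
    stop("missing key(s) in ", path, ": ", paste(missing, collapse = ", "))
  em <- obj$error_model
  run_config(
    params = do.call(pd_params, obj$params),
    fixed = unlist(obj$fixed),
    design = study_design(arms = obj$design$arms,
                          times = obj$design$times,
                          replicates = unlist(obj$design$replicates)),
    em = error_model(em$kind, sigma_add = unlist(em$sigma_add),
                     sigma_prop = unlist(em$sigma_prop),
                     power_exponent = em$power_exponent),
    seed = obj$seed, n_sim = obj$n_sim, n_starts = obj$n_starts,
    rtol = obj$rtol)
}

#' Serialize a fit or recovery result to JSON
#'
#' Writes the numeric content of a `pd_fit` or `pd_recovery` object
#' (estimates, sigmas, likelihood and information criteria, convergence
#' metadata; or the recovery summary table) to a JSON file.  Function
#' closures and raw estimate matrices are omitted from fit output.
#'
#' @param x A `pd_fit` or `pd_recovery`.
#' @param path JSON file path.
#' @export
write_result <- function(x, path) {
  if (inherits(x, "pd_fit")) {
    obj <- list(kind = "fit",
                estimates = as.list(unclass(x$estimates)),
                free = as.list(x$free), fixed = as.list(x$fixed),
                error_kind = x$error_kind, sigma = as.list(x$sigma),
                cv_percent = if (!is.null(x$cv_percent))
                  as.list(x$cv_percent),
                minus2LL = x$minus2LL, aic = x$aic, bic = x$bic,
                n_obs = x$n_obs, p = x$p,
                convergence = x$convergence[c("status", "best_start",
                                              "n_converged")],
                seed = x$seed)
  } else if (inherits(x, "pd_recovery")) {
    obj <- list(kind = "recovery", summary = x$summary,
                n_sim = x$n_sim, n_failed = x$n_failed, seeds = x$seeds)
  } else stop("unsupported object class: ", paste(class(x), collapse = "/"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}
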