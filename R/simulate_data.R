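#' Noise-free expectation surface of a study design
#'
#' Evaluates the cascade model at every (arm, analyte, time, replicate)
#' cell of a design.  Replicates within a cell are identical: this is the
#' model-expected dataset before residual error.
#'
#' @param params A [pd_params()] object.
#' @param design A [study_design()].
#' @param ... Passed to [simulate_cascade()] (e.g. `rtol`, `solver`).
#' @return A long-format data.frame with columns `arm_id`, `baicalein_uM`,
#'   `analyte`, `time_h`, `replicate`, `value` — the layout every
#'   estimator and diagnostic in the package consumes.
#' @seealso [generate_dataset()], [read_dataset()]
#' @export
#' @examples
#' head(predict_design(baicalein_reference_params(), default_design()))
predict_design <- function(params, design, ...) {
  stopifnot(is_pd_params(params), inherits(design, "pd_design"))
  state_col <- c(TNF = "tnf", IL6 = "il6", iNOS = "inos", NO = "no")
  rows <- lapply(design$arms, function(conc) {
    tr <- simulate_cascade(params, conc, times = c(0, design$times), ...)
    keep <- match(design$times, tr$time)
    do.call(rbind, lapply(analyte_levels(), function(a) {
      nrep <- design$replicates[[a]]
      vals <- tr$states[keep, state_col[[a]]]
      data.frame(arm_id = arm_id_of(conc), baicalein_uM = conc,
                 analyte = a,
                 time_h = rep(design$times, each = nrep),
                 replicate = rep(seq_len(nrep), times = length(design$times)),
                 value = rep(vals, each = nrep))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic time-course dataset
#'
#' [predict_design()] plus one residual-error draw per record; emulates
#' the statistical structure of the four-arm RAW264.7 experiment
#' (TNF-\eqn{\alpha}/IL-6 by ELISA, NO by Griess, iNOS as a blot ratio)
#' so that estimation and diagnostics are testable without laboratory
#' data.  The seed fully determines the output.
#'
#' @param params Generating [pd_params()].
#' @param design A [study_design()].
#' @param em A [error_model()]; zero sigmas reproduce [predict_design()]
#'   exactly.
#' @param seed Integer RNG seed.
#' @param ... Passed to [simulate_cascade()].
#' @return Dataset data.frame as in [predict_design()], with attribute
#'   `meta` recording the generating parameters, error model and seed.
#' @export
#' @examples
#' d <- generate_dataset(baicalein_reference_params(), default_design(),
#'                       error_model("proportional", sigma_prop = 0.1),
#'                       seed = 101)
#' nrow(d)  # 300
generate_dataset <- function(params, design, em, seed, ...) {
  stopifnot(inherits(em, "pd_error_model"))
  base <- predict_design(params, design, ...)
  set.seed(seed)
  for (a in analyte_levels()) {
    idx <- base$analyte == a
    base$value[idx] <- apply_error(base$value[idx], em, a)
  }
  attr(base, "meta") <- list(params = unclass(params),
                             error_model = unclass(em), seed = seed)
  base
}

# structural checks shared by readers and estimators
validate_dataset <- function(dataset) {
  req <- c("arm_id", "baicalein_uM", "analyte", "time_h", "replicate",
           "value")
  missing <- setdiff(req, names(dataset))
  if (length(missing))
    stop("dataset is missing column(s): ", paste(missing, collapse = ", "))
  bad <- which(!dataset$analyte %in% analyte_levels())
  if (length(bad))
    stop("unknown analyte in row(s) ", paste(bad, collapse = ", "),
         ": ", paste(unique(dataset$analyte[bad]), collapse = ", "))
  neg <- which(dataset$value < 0)
  if (length(neg))
    stop("negative value in row(s) ", paste(neg, collapse = ", "))
  key <- with(dataset, paste(arm_id, analyte, time_h, replicate))
  if (anyDuplicated(key))
    stop("duplicate (arm, analyte, time, replicate) key in row(s) ",
         paste(which(duplicated(key)), collapse = ", "))
  invisible(dataset)
}
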