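#' Study design: arms, observation times, replicate counts
#'
#' Describes the in-vitro experiment blueprint: LPS-stimulated treatment
#' arms distinguished by baicalein concentration, post-LPS sampling times,
#' and replicate counts per analyte.
#'
#' @param arms Numeric vector of baicalein concentrations (\eqn{\mu}M),
#'   one per arm; 0 is the LPS-only control.
#' @param times Observation times (h post-LPS), strictly increasing, > 0.
#' @param replicates Named integer vector giving replicate counts for the
#'   analytes `TNF`, `IL6`, `iNOS`, `NO`.
#' @return An object of class `pd_design`.
#' @seealso [default_design()]
#' @export
study_design <- function(arms, times,
                         replicates = c(TNF = 3, IL6 = 3, iNOS = 6, NO = 3)) {
  stopifnot(is.numeric(arms), length(arms) >= 1, all(arms >= 0),
            !anyDuplicated(arms),
            is.numeric(times), all(times > 0), all(diff(times) > 0))
  if (!setequal(names(replicates), analyte_levels()))
    stop("replicates must be named TNF, IL6, iNOS, NO")
  replicates <- replicates[analyte_levels()]
  if (any(replicates < 1)) stop("replicate counts must be >= 1")
  structure(list(arms = sort(arms), times = times,
                 replicates = replicates),
            class = "pd_design")
}

analyte_levels <- function() c("TNF", "IL6", "iNOS", "NO")

#' Default four-arm RAW264.7 time-course design
#'
#' Arms 0/10/20/40 \eqn{\mu}M baicalein (all LPS-stimulated), observation
#' times 1, 2, 4, 8, 12 h post-LPS, triplicates for TNF-\eqn{\alpha},
#' IL-6 and NO and sextuplicates for iNOS.  The 24 h point, at which the
#' treated arms have returned to the LPS-only level and which is excluded
#' from fitting, can be re-added.
#'
#' @param include_24h Logical; append the 24 h observation time.
#' @return A `pd_design`.
#' @export
#' @examples
#' d <- default_design()
#' length(d$arms)   # 4
#' d$times          # 1 2 4 8 12
default_design <- function(include_24h = FALSE) {
  times <- c(1, 2, 4, 8, 12)
  if (include_24h) times <- c(times, 24)
  study_design(arms = c(0, 10, 20, 40), times = times)
}

#' @export
print.pd_design <- function(x, ...) {
  cat("Study design: ", length(x$arms), " arms (baicalein ",
      paste(x$arms, collapse = "/"), " uM), times ",
      paste(x$times, collapse = ", "), " h post-LPS\n", sep = "")
  cat("Replicates:", paste(names(x$replicates), x$replicates,
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# total record count of a complete dataset under the design
design_n_records <- function(design) {
  length(design$arms) * length(design$times) * sum(design$replicates)
}

arm_id_of <- function(conc) {
  ifelse(conc == 0, "LPS", paste0("Bai", conc))
}
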