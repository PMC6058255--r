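#' Goodness-of-fit table for a fitted cascade model
#'
#' Per-record observed vs predicted values, raw residuals and residuals
#' standardized by the fitted error model's standard deviation at the
#' prediction.  The attached summary gives, per analyte, the slope of
#' observed-vs-predicted through the origin
#' (\eqn{\sum o p / \sum p^2}; 1 for a perfect fit) and the mean
#' standardized residual (0 in expectation for a well-specified model).
#'
#' @param fit A `pd_fit` from [fit_cascade()].
#' @param dataset The dataset the fit should be judged against (normally
#'   the fitted one).
#' @return A data.frame with columns `arm_id`, `baicalein_uM`, `analyte`,
#'   `time_h`, `replicate`, `observed`, `predicted`, `residual`,
#'   `std_residual`, with a per-analyte `summary` data.frame attached as
#'   an attribute (`attr(x, "summary")`).
#' @export
gof <- function(fit, dataset) {
  stopifnot(inherits(fit, "pd_fit"))
  validate_dataset(dataset)
  pred <- predict_records(fit$estimates, dataset, rtol = fit$rtol)
  sd <- numeric(nrow(dataset))
  for (a in unique(dataset$analyte)) {
    i <- dataset$analyte == a
    sd[i] <- error_sd_at(fit$error_model, a, pred[i])
  }
  out <- data.frame(arm_id = dataset$arm_id,
                    baicalein_uM = dataset$baicalein_uM,
                    analyte = dataset$analyte, time_h = dataset$time_h,
                    replicate = dataset$replicate,
                    observed = dataset$value, predicted = pred,
                    residual = dataset$value - pred,
                    std_residual = (dataset$value - pred) / sd)
  summ <- do.call(rbind, lapply(split(out, out$analyte), function(g) {
    data.frame(analyte = g$analyte[1],
               slope_origin = sum(g$observed * g$predicted) /
                 sum(g$predicted^2),
               mean_std_residual = mean(g$std_residual),
               n = nrow(g))
  }))
  rownames(summ) <- NULL
  attr(out, "summary") <- summ
  out
}

# model prediction for each record of a dataset
predict_records <- function(params, dataset, rtol = 1e-8) {
  state_col <- c(TNF = "tnf", IL6 = "il6", iNOS = "inos", NO = "no")
  times <- sort(unique(dataset$time_h))
  pred <- numeric(nrow(dataset))
  for (conc in unique(dataset$baicalein_uM)) {
    tr <- simulate_cascade(params, conc, times = c(0, times), rtol = rtol)
    i <- dataset$baicalein_uM == conc
    pred[i] <- tr$states[cbind(match(dataset$time_h[i], tr$time),
                               match(state_col[dataset$analyte[i]],
                                     colnames(tr$states)))]
  }
  pred
}

#' Visual-predictive-check envelope table
#'
#' For each (arm, analyte, time) cell, simulates `n_sim` datasets from
#' the model and error model, takes the median across replicates within
#' the cell for each simulation, and reports quantiles of those simulated
#' medians as the predictive envelope.  When a dataset is supplied its
#' observed replicate medians are attached for overlay: under a
#' well-specified model about 90% of them should fall inside the 5--95%
#' envelope.
#'
#' @param params A [pd_params()] object (typically fitted estimates).
#' @param em A [error_model()].
#' @param design A [study_design()].
#' @param n_sim Number of simulated datasets (default 200).
#' @param quantiles Envelope quantiles (default 5/50/95%).
#' @param seed RNG seed.
#' @param dataset Optional observed dataset for overlay.
#' @return Data.frame per cell with the prediction, envelope columns
#'   `q<level>`, and (if `dataset` given) `obs_median`.
#' @export
vpc <- function(params, em, design, n_sim = 200,
                quantiles = c(0.05, 0.5, 0.95), seed = 1, dataset = NULL) {
  stopifnot(is_pd_params(params), inherits(em, "pd_error_model"),
            inherits(design, "pd_design"), n_sim >= 1)
  state_col <- c(TNF = "tnf", IL6 = "il6", iNOS = "inos", NO = "no")
  set.seed(seed)
  rows <- list()
  for (conc in design$arms) {
    tr <- simulate_cascade(params, conc, times = c(0, design$times))
    for (a in analyte_levels()) {
      nrep <- design$replicates[[a]]
      for (ti in seq_along(design$times)) {
        p <- tr$states[ti + 1, state_col[[a]]]
        sdv <- error_sd_at(em, a, p)
        sims <- matrix(pmax(stats::rnorm(nrep * n_sim, p, sdv), 0), nrep)
        med <- apply(sims, 2, stats::median)
        q <- stats::quantile(med, quantiles, names = FALSE)
        rows[[length(rows) + 1]] <- data.frame(
          arm_id = arm_id_of(conc), baicalein_uM = conc, analyte = a,
          time_h = design$times[ti], predicted = p,
          t(stats::setNames(q, paste0("q", quantiles * 100))))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(dataset)) {
    validate_dataset(dataset)
    obs <- stats::aggregate(value ~ baicalein_uM + analyte + time_h,
                            dataset, stats::median)
    names(obs)[names(obs) == "value"] <- "obs_median"
    out <- merge(out, obs, all.x = TRUE, sort = FALSE)
  }
  out
}

#' Dense per-arm trajectories for plotting
#'
#' Thin wrapper over [simulate_cascade()] returning a tidy long table of
#' the four states on a dense grid, one block per arm.
#'
#' @param params A [pd_params()] object.
#' @param arms Baicalein concentrations (\eqn{\mu}M).
#' @param grid Output grid (h) starting at 0.
#' @param ... Passed to [simulate_cascade()].
#' @return Data.frame with `arm_id`, `baicalein_uM`, `analyte`, `time_h`,
#'   `value`.
#' @export
timecourse_plot_data <- function(params, arms = c(0, 10, 20, 40),
                                 grid = seq(0, 12, by = 0.1), ...) {
  state_col <- c(TNF = "tnf", IL6 = "il6", iNOS = "inos", NO = "no")
  out <- do.call(rbind, lapply(arms, function(conc) {
    tr <- simulate_cascade(params, conc, times = grid, ...)
    do.call(rbind, lapply(analyte_levels(), function(a)
      data.frame(arm_id = arm_id_of(conc), baicalein_uM = conc,
                 analyte = a, time_h = tr$time,
                 value = tr$states[, state_col[[a]]])))
  }))
  rownames(out) <- NULL
  out
}

#' Diagnostic plots
#'
#' `plot_gof()` draws observed vs predicted per analyte with the
#' identity line; `plot_vpc()` overlays the predictive envelope on the
#' observed medians; `plot_timecourse()` shows the fitted trajectories
#' with the data.  All require the `ggplot2` package.
#'
#' @param gof_table Output of [gof()].
#' @return A ggplot object.
#' @export
plot_gof <- function(gof_table) {
  require_ggplot()
  ggplot2::ggplot(gof_table,
                  ggplot2::aes(x = .data$predicted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "rosybrown2") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~analyte, scales = "free") +
    ggplot2::labs(x = "Predicted", y = "Observed")
}

#' @rdname plot_gof
#' @param vpc_table Output of [vpc()].
#' @export
plot_vpc <- function(vpc_table) {
  require_ggplot()
  qcols <- grep("^q", names(vpc_table), value = TRUE)
  g <- ggplot2::ggplot(vpc_table, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[[qcols[1]]],
                                      ymax = .data[[qcols[length(qcols)]]]),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data[[qcols[2]]]),
                       colour = "steelblue") +
    ggplot2::facet_grid(analyte ~ arm_id, scales = "free_y") +
    ggplot2::labs(x = "Time post-LPS (h)", y = "Level")
  if ("obs_median" %in% names(vpc_table))
    g <- g + ggplot2::geom_point(ggplot2::aes(y = .data$obs_median),
                                 size = 1)
  g
}

#' @rdname plot_gof
#' @param curves Output of [timecourse_plot_data()].
#' @param dataset Optional observed dataset to overlay as points.
#' @export
plot_timecourse <- function(curves, dataset = NULL) {
  require_ggplot()
  g <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$time_h,
                                            y = .data$value,
                                            colour = .data$arm_id)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = "Time post-LPS (h)", y = "Level",
                  colour = "Arm")
  if (!is.null(dataset))
    g <- g + ggplot2::geom_point(
      data = dataset,
      ggplot2::aes(x = .data$time_h, y = .data$value,
                   colour = .data$arm_id), size = 1, alpha = 0.7)
  g
}

require_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package")
}
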