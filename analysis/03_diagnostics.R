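#!/usr/bin/env Rscript
# Step 3 — predictive checks of the fitted model.
#
# Visual predictive check (200 simulated datasets from the fitted
# parameters and error model) and dense fitted time courses, written as
# tables; plots are drawn when ggplot2 is available.

library(inflaPD)

cfg <- read_run_config("results/config.json")
dataset <- read_dataset("results/dataset.csv")
fit_obj <- jsonlite::fromJSON("results/fit.json")
est <- do.call(pd_params, fit_obj$estimates)
em <- error_model(fit_obj$error_kind, sigma_prop = unlist(fit_obj$sigma))

v <- vpc(est, em, cfg$design, n_sim = 200, seed = cfg$seed,
         dataset = dataset)
utils::write.csv(v, "results/vpc.csv", row.names = FALSE)
cover <- mean(v$obs_median >= v$q5 & v$obs_median <= v$q95)
cat(sprintf("VPC: %.0f%% of the %d observed cell medians fall inside the",
            100 * cover, nrow(v)), "\n5-95% simulation envelope",
    "(nominal 90%).\n")

curves <- timecourse_plot_data(est, arms = cfg$design$arms,
                               grid = seq(0, 12, by = 0.25))
utils::write.csv(curves, "results/timecourses.csv", row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  dir.create("results/figures", showWarnings = FALSE)
  refit <- structure(list(estimates = est, error_model = em, rtol = 1e-8),
                     class = "pd_fit")
  ggplot2::ggsave("results/figures/gof.png", plot_gof(gof(refit, dataset)),
                  width = 7, height = 5, dpi = 120)
  ggplot2::ggsave("results/figures/vpc.png", plot_vpc(v),
                  width = 9, height = 7, dpi = 120)
  ggplot2::ggsave("results/figures/timecourses.png",
                  plot_timecourse(curves, dataset),
                  width = 8, height = 6, dpi = 120)
  cat("Figures written under results/figures/.\n")
}
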