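#!/usr/bin/env Rscript
# Stage 4: mixed-model comparisons across mowing regimes.
#
# Runs the complete pipeline (stages 1-3 internally) and fits the
# regime-comparison models with a locality random intercept: binomial GLMM
# for individual emigration, gamma GLMMs for dispersal and displacement
# distances, Poisson GLMM for seasonal population size, and Gaussian mixed
# models comparing per-patch survival and capture probability (where the
# intercept-only model competes with the regime model by AIC). Continuous
# covariates are normalised by mean and SD.

suppressMessages(library(meadowmrr))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

report <- run_all(list(sim = sim_config()), seed = seed,
                  out_dir = file.path("results", "report"))
print(report)

for (nm in names(report$model_tables)) {
  cat("\n==", nm, "==\n")
  print(report$model_tables[[nm]], digits = 3, row.names = FALSE)
}

if (!is.null(report$models$emigration)) {
  fit <- report$models$emigration
  nd <- expand.grid(regime = factor(c("unmown", "recovered", "mown"),
                                    levels = c("unmown", "recovered", "mown")),
                    sex = factor("F", levels = c("F", "M")),
                    pop_size = mean(report$patch_table$N_total, na.rm = TRUE),
                    connectivity = mean(report$patch_table$S_j),
                    area = mean(report$patch_table$area_m2))
  pr <- predict_response(fit, nd)
  cat("\nPredicted emigration probability (female, average patch):\n")
  print(data.frame(regime = nd$regime, fit = round(pr$fit, 3),
                   se = round(pr$se, 3)), row.names = FALSE)
}
cat("\nAll report tables written to results/report/\n")
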