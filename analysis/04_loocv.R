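#!/usr/bin/env Rscript

# Stage 4: leave-one-out cross-validation experiment and final report.
#
# Runs the n-fold leave-one-out procedure for the three discharge
# outcomes on the same analysis table as stage 3, reports the pooled
# out-of-fold evaluation panel, compares each final model's MPE_C
# coefficient with the published single-predictor model, and renders the
# combined markdown report.

suppressMessages(library(rmkpredict))

cohort <- read_cohort(file.path("results", "cohort"))
features <- read.csv(file.path("results", "features.csv"))
clinical <- cohort$patients[, setdiff(names(cohort$patients),
                                      c("MPE_A", "MPE_C", "MPE_D", "MS_B",
                                        "MPE_C_std"))]
tab <- merge(clinical, features[, c("id", "MPE_A", "MPE_C", "MPE_D", "MS_B")],
             by = "id")

loocv <- run_loocv(tab)
pm <- published_models()
cat(sprintf("LOOCV over %d records (%d fold fits per outcome):\n",
            loocv$n, loocv$outcomes[[1]]$n_fits))
for (o in names(loocv$outcomes)) {
  oo <- loocv$outcomes[[o]]
  ct <- oo$model$coefficients
  beta <- if ("MPE_C" %in% ct$term) ct$estimate[ct$term == "MPE_C"] else NA
  cat(sprintf("MI_%s: R2 %.3f, RMSE %.2f (RMSE_n %s%%), Spearman r %.3f (%s); final MPE_C beta %.2f (generating %.2f)\n",
              o, oo$report$r_squared, oo$report$rmse,
              format(round_rmse_n(oo$report$rmse_n, mi_scale(o))),
              oo$report$spearman_r, oo$report$strength,
              beta, pm$slope[pm$outcome == o]))
}
write_report_json(loocv, file.path("results", "loocv.json"))

ssv <- run_ssv(tab, seed = 20229L)
write_report_markdown(ssv, loocv, file.path("results", "report.md"))
cat("Wrote results/loocv.json and results/report.md\n")
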