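#!/usr/bin/env Rscript

# Stage 3: split-sample validation experiment.
#
# Joins the extracted kinematic features with the clinical table,
# standardizes the modelling variables, draws the 75/25 partition,
# verifies the sets are balanced, fits the covariate-adjusted model for
# each discharge outcome on the training set with backward elimination,
# and evaluates on the held-out validation set.  Writes results/ssv.json.

suppressMessages(library(rmkpredict))

cohort <- read_cohort(file.path("results", "cohort"))
features <- read.csv(file.path("results", "features.csv"))

# analysis table: clinical columns + the *extracted* metrics
clinical <- cohort$patients[, setdiff(names(cohort$patients),
                                      c("MPE_A", "MPE_C", "MPE_D", "MS_B",
                                        "MPE_C_std"))]
tab <- merge(clinical, features[, c("id", "MPE_A", "MPE_C", "MPE_D", "MS_B")],
             by = "id")

seed <- 20229L
ssv <- run_ssv(tab, seed = seed)
cat(sprintf("Split (seed %d): %d training / %d validation; balance tests %s.\n",
            seed, length(ssv$split$train), length(ssv$split$validation),
            if (ssv$balance$balanced) "passed" else "FLAGGED"))
for (o in names(ssv$outcomes)) {
  oo <- ssv$outcomes[[o]]
  cat(sprintf("MI_%s: kept %s | train R2 %.3f, validation R2 %.3f, validation RMSE %.2f (RMSE_n %s%%)\n",
              o, paste(oo$model$predictors, collapse = "+"),
              oo$training$r_squared, oo$validation$r_squared,
              oo$validation$rmse,
              format(round_rmse_n(oo$validation$rmse_n, mi_scale(o)))))
}
write_report_json(ssv, file.path("results", "ssv.json"))
cat("Wrote results/ssv.json\n")
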