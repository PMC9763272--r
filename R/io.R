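# File interfaces: trajectory and cohort CSVs, a YAML run manifest, and
# JSON / markdown report writers.

#' Write / read a trajectory CSV
#'
#' One file per movement: columns `t`, `x`, `y`, `vx`, `vy` in SI units.
#'
#' @param traj An [trajectory()] object.
#' @param path Output CSV path.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "rmk_trajectory"))
  df <- data.frame(t = traj$t, x = traj$x, y = traj$y)
  if (!is.null(traj$vx)) {
    df$vx <- traj$vx
    df$vy <- traj$vy
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param direction,side Movement labels (not stored in the CSV itself).
#' @param sample_rate Optional nominal rate (Hz).
#' @export
read_trajectory_csv <- function(path, direction, side, sample_rate = NULL) {
  df <- utils::read.csv(path)
  trajectory(t = df$t, x = df$x, y = df$y,
             vx = if ("vx" %in% names(df)) df$vx else NULL,
             vy = if ("vy" %in% names(df)) df$vy else NULL,
             direction = direction, side = side, sample_rate = sample_rate)
}

#' Write a synthetic cohort to disk
#'
#' Emits `cohort.csv` (one row per patient), per-movement trajectory
#' CSVs under `trajectories/` named `<id>_<direction>_<repetition>.csv`,
#' and `manifest.yaml` recording the generator configuration (including
#' the seed), so a run can be reproduced exactly.
#'
#' @param cohort An `rmk_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rmk_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$patients, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$trajectories)) {
    tdir <- file.path(dir, "trajectories")
    dir.create(tdir, showWarnings = FALSE)
    for (id in names(cohort$trajectories)) {
      for (d in names(cohort$trajectories[[id]])) {
        reps <- cohort$trajectories[[id]][[d]]
        for (r in seq_along(reps)) {
          write_trajectory_csv(reps[[r]],
                               file.path(tdir, sprintf("%s_%s_%d.csv", id, d, r)))
        }
      }
    }
  }
  cfg <- cohort$config
  # YAML loses names on atomic vectors; store named vectors as maps
  yamlify <- function(x) {
    if (is.list(x)) lapply(x, yamlify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  manifest <- list(
    package = "rmkpredict",
    config = yamlify(unclass(cfg)),
    n_patients = nrow(cohort$patients),
    has_trajectories = !is.null(cohort$trajectories)
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `cohort.csv`, `manifest.yaml` and
#'   (optionally) `trajectories/`.
#' @return An `rmk_cohort`.
#' @export
read_cohort <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  cfg <- manifest$config
  config <- generator_config(
    n_patients = cfg$n_patients, target_distance = cfg$target_distance,
    sample_rate = cfg$sample_rate,
    outcome_coefficients = lapply(cfg$outcome_coefficients, unlist),
    noise_sd = unlist(cfg$noise_sd),
    demographics = utils::modifyList(cfg$demographics,
                                     list(age_range = unlist(cfg$demographics$age_range))),
    mpe_profile = lapply(cfg$mpe_profile, unlist),
    ms_profile = unlist(cfg$ms_profile), class_noise = cfg$class_noise,
    n_repetitions = cfg$n_repetitions, trajectories = cfg$trajectories,
    seed = cfg$seed
  )
  patients <- utils::read.csv(file.path(dir, "cohort.csv"),
                              stringsAsFactors = FALSE)
  trajectories <- NULL
  tdir <- file.path(dir, "trajectories")
  if (manifest$has_trajectories && dir.exists(tdir)) {
    trajectories <- lapply(patients$id, function(id) {
      side <- patients$side[patients$id == id]
      per_dir <- lapply(DIRECTIONS, function(d) {
        files <- sort(list.files(tdir, sprintf("^%s_%s_\\d+\\.csv$", id, d),
                                 full.names = TRUE))
        lapply(files, read_trajectory_csv, direction = d, side = side,
               sample_rate = config$sample_rate)
      })
      names(per_dir) <- DIRECTIONS
      per_dir
    })
    names(trajectories) <- patients$id
  }
  structure(list(patients = patients, trajectories = trajectories,
                 config = config),
            class = "rmk_cohort")
}

report_list <- function(report) {
  scale <- mi_scale(report$outcome)
  list(n = report$n, n_predictors = report$n_predictors,
       RMSE = report$rmse,
       RMSE_n = round_rmse_n(report$rmse_n, scale),
       RMSE_n_unrounded = report$rmse_n,
       MAE = report$mae, MAE_n = report$mae_n,
       MAE_denominator = report$mae_denominator,
       R2 = report$r_squared, R2_adj = report$adj_r_squared,
       spearman_r = report$spearman_r, spearman_p = report$spearman_p,
       strength = report$strength)
}

model_list <- function(model) {
  list(outcome = model$outcome, predictors = model$predictors,
       n = model$n, r_squared = model$r_squared,
       adj_r_squared = model$adj_r_squared,
       coefficients = model$coefficients)
}

#' Serialize validation results to JSON
#'
#' Mirrors the evaluation-table structure: per outcome, the metric panel
#' for each prediction set (training/validation for the split-sample
#' experiment, the pooled out-of-fold set for LOOCV) plus the fitted
#' model's coefficient table.
#'
#' @param result An `rmk_ssv` or `rmk_loocv` object.
#' @param path Output JSON path.
#' @export
write_report_json <- function(result, path) {
  out <- if (inherits(result, "rmk_ssv")) {
    list(procedure = "split_sample_validation", seed = result$seed,
         n_train = length(result$split$train),
         n_validation = length(result$split$validation),
         balanced = result$balance$balanced,
         balance_tests = result$balance$table,
         outcomes = lapply(result$outcomes, function(o) {
           list(model = model_list(o$model),
                training = report_list(o$training),
                validation = report_list(o$validation))
         }))
  } else if (inherits(result, "rmk_loocv")) {
    list(procedure = "leave_one_out_cross_validation", n = result$n,
         outcomes = lapply(result$outcomes, function(o) {
           list(model = model_list(o$model), n_fits = o$n_fits,
                loocv = report_list(o$report))
         }))
  } else {
    stop("unsupported result type")
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

metric_row <- function(label, rep) {
  scale <- mi_scale(rep$outcome)
  sprintf("| %s | %.3f | %s | %.3f (%.3f) | %.3f (%.0f%%) | %.3f (%s) |",
          label, rep$rmse, format(round_rmse_n(rep$rmse_n, scale)),
          rep$r_squared, rep$adj_r_squared, rep$mae, rep$mae_n,
          rep$spearman_r, rep$strength)
}

#' Render a human-readable markdown report
#'
#' @param ssv An `rmk_ssv` result (or NULL to omit the section).
#' @param loocv An `rmk_loocv` result (or NULL).
#' @param path Output markdown path.
#' @export
write_report_markdown <- function(ssv = NULL, loocv = NULL, path) {
  lines <- c("# Discharge Motricity Index prediction report", "")
  header <- c("| Set | RMSE | RMSE_n (%) | R2 (adj) | MAE (MAE_n) | Spearman r |",
              "|---|---|---|---|---|---|")
  if (!is.null(ssv)) {
    lines <- c(lines, "## Split-sample validation",
               sprintf("Split seed %d: %d training / %d validation records; balance tests %s.",
                       ssv$seed, length(ssv$split$train),
                       length(ssv$split$validation),
                       if (ssv$balance$balanced) "passed (no significant imbalance)"
                       else "FLAGGED an imbalance"), "")
    for (o in names(ssv$outcomes)) {
      oo <- ssv$outcomes[[o]]
      lines <- c(lines, sprintf("### MI_%s (predictors: %s)", o,
                                paste(oo$model$predictors, collapse = ", ")),
                 header,
                 metric_row("training", oo$training),
                 metric_row("validation", oo$validation), "")
    }
  }
  if (!is.null(loocv)) {
    lines <- c(lines, "## Leave-one-out cross-validation",
               sprintf("%d records, %d fold fits per outcome.",
                       loocv$n, loocv$outcomes[[1]]$n_fits), "")
    pm <- published_models()
    for (o in names(loocv$outcomes)) {
      oo <- loocv$outcomes[[o]]
      lines <- c(lines, sprintf("### MI_%s (final model: %s)", o,
                                paste(oo$model$predictors, collapse = ", ")),
                 header, metric_row("loocv", oo$report), "")
      if ("MPE_C" %in% oo$model$coefficients$term) {
        est <- oo$model$coefficients
        lines <- c(lines, sprintf(
          "Final-model MPE_C coefficient %.2f (published single-predictor model: intercept %.2f, slope %.2f).",
          est$estimate[est$term == "MPE_C"],
          pm$intercept[pm$outcome == o], pm$slope[pm$outcome == o]), "")
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
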