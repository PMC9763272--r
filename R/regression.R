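# Outcome-prediction models: standardization, split-sample validation
# with its balance-test battery, leave-one-out cross-validation,
# covariate-adjusted least-squares regression with significance-based
# predictor selection, and the published single-predictor models.

RMK_METRICS <- c("MPE_A", "MPE_C", "MPE_D", "MS_B")
STD_VARS <- c("age", "onset", RMK_METRICS)
OUTCOMES <- c("ELBOW", "SHOULDER", "UL")

#' Standardize a variable to zero mean and unit variance
#'
#' `z = (v - mean) / SD` with the n-1 (sample) SD.  The transform is
#' returned so held-out or new cases can be projected onto the same
#' scale.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return List with `values` (standardized), `center` and `scale`.
#' @export
standardize <- function(values) {
  if (length(unique(values)) < 2L) {
    stop("standardization needs at least two distinct values")
  }
  m <- mean(values)
  s <- stats::sd(values)
  list(values = (values - m) / s, center = m, scale = s)
}

#' Standardize the modelling variables of a cohort table
#'
#' Applies [standardize()] to age, stroke-onset time and the four
#' kinematic metrics (clinical scores are left on their native scale).
#' Optionally the transform is estimated on a subset of rows (e.g. the
#' training set) and projected onto all rows.
#'
#' @param df Cohort data.frame.
#' @param vars Columns to standardize.
#' @param estimate_rows Row indices the means/SDs are computed on
#'   (default: all rows).
#' @return List with `data` (transformed df) and `transform` (data.frame
#'   of variable, center, scale).
#' @export
standardize_cohort <- function(df, vars = STD_VARS,
                               estimate_rows = seq_len(nrow(df))) {
  vars <- intersect(vars, names(df))
  tr <- lapply(vars, function(v) {
    sub <- df[[v]][estimate_rows]
    if (length(unique(sub)) < 2L) {
      stop(sprintf("variable '%s' has zero variance; cannot standardize", v))
    }
    s <- standardize(sub)
    df[[v]] <<- (df[[v]] - s$center) / s$scale
    data.frame(variable = v, center = s$center, scale = s$scale)
  })
  list(data = df, transform = do.call(rbind, tr))
}

#' Random train/validation partition
#'
#' Uniform random partition without replacement; the training size is
#' `train_frac * n` rounded half up (66 patients at 75% give a
#' 50-patient training and 16-patient validation set).
#'
#' @param n Number of records (>= 4).
#' @param train_frac Training fraction in (0, 1); default 0.75.
#' @param seed Integer seed.
#' @return Object of class `rmk_split`: list with sorted `train` and
#'   `validation` index vectors.
#' @export
split_sample <- function(n, train_frac = 0.75, seed = 1L) {
  if (n < 4L) stop("split-sample validation needs n >= 4")
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  n_train <- as.integer(floor(train_frac * n + 0.5))  # round half up
  set.seed(seed)
  train <- sort(sample.int(n, n_train))
  structure(
    list(train = train, validation = setdiff(seq_len(n), train),
         n = n, train_frac = train_frac, seed = as.integer(seed)),
    class = "rmk_split"
  )
}

# Mann-Whitney / ANOVA choice by Shapiro-Wilk normality pre-test at 5%.
continuous_balance_test <- function(values, grp) {
  normal <- all(vapply(split(values, grp), function(v) {
    if (length(v) < 3L || length(unique(v)) < 2L) return(FALSE)
    stats::shapiro.test(v)$p.value > 0.05
  }, logical(1)))
  if (normal) {
    fit <- stats::aov(values ~ grp)
    list(test = "ANOVA", p = summary(fit)[[1]][["Pr(>F)"]][1])
  } else {
    p <- suppressWarnings(stats::wilcox.test(values ~ grp, exact = FALSE)$p.value)
    list(test = "Mann-Whitney", p = p)
  }
}

categorical_balance_test <- function(values, grp) {
  values <- factor(values)  # drops levels absent from both sets
  if (nlevels(values) < 2L) {
    return(list(test = "none (single level)", p = 1))
  }
  tab <- table(grp, values)
  cs <- suppressWarnings(stats::chisq.test(tab))
  if (any(cs$expected == 0)) {
    list(test = "Fisher exact", p = stats::fisher.test(tab)$p.value)
  } else {
    list(test = "Chi-square", p = cs$p.value)
  }
}

#' Balance tests between training and validation sets
#'
#' Checks that the random split produced comparable sets: chi-square for
#' categorical variables (Fisher's exact test when a zero expected count
#' makes the chi-square approximation invalid), and for continuous
#' variables ANOVA when both groups pass a Shapiro-Wilk normality
#' pre-test at 5%, otherwise the Mann-Whitney test.  Additionally the
#' cohort is randomly divided into four 25% groups and every pairwise
#' combination is compared with the Kruskal-Wallis test under Bonferroni
#' correction (raw p times the number of comparisons, capped at 1).
#'
#' @param df Cohort table.
#' @param split An [split_sample()] result.
#' @param continuous,categorical Variable names of each type.
#' @param seed Seed for the four-group subdivision.
#' @param alpha Flagging threshold (default 0.05).
#' @return List with `table` (variable, test, p, flagged), `four_group`
#'   (pairwise Kruskal-Wallis with Bonferroni-corrected p), and
#'   `balanced` (TRUE when nothing is flagged).
#' @export
balance_tests <- function(df, split,
                          continuous = intersect(c("age", "onset", RMK_METRICS,
                                                   "MI_ELBOW_T1", "MI_SHOULDER_T1",
                                                   "MI_UL_T1"), names(df)),
                          categorical = intersect(c("sex", "side", "etiology"),
                                                  names(df)),
                          seed = split$seed + 1L, alpha = 0.05) {
  if (!length(split$train) || !length(split$validation)) {
    stop("both sets must be non-empty")
  }
  grp <- factor(ifelse(seq_len(nrow(df)) %in% split$train,
                       "training", "validation"))
  rows <- lapply(c(categorical, continuous), function(v) {
    res <- if (v %in% categorical) {
      categorical_balance_test(df[[v]], grp)
    } else {
      continuous_balance_test(df[[v]], grp)
    }
    data.frame(variable = v, test = res$test, p = res$p,
               flagged = res$p <= alpha)
  })
  tab <- do.call(rbind, rows)

  set.seed(seed)
  g4 <- sample(rep_len(1:4, nrow(df)))
  pairs <- utils::combn(4, 2)
  m <- ncol(pairs)
  fg <- lapply(continuous, function(v) {
    do.call(rbind, lapply(seq_len(m), function(j) {
      sel <- g4 %in% pairs[, j]
      p <- stats::kruskal.test(df[[v]][sel], factor(g4[sel]))$p.value
      data.frame(variable = v, groups = paste(pairs[, j], collapse = "-"),
                 p_raw = p, p_bonferroni = min(1, m * p))
    }))
  })
  fg <- do.call(rbind, fg)
  list(table = tab, four_group = fg,
       balanced = !any(tab$flagged) && !any(fg$p_bonferroni <= alpha))
}

#' Default predictor set for an outcome model
#'
#' Age, sex, stroke-onset time, the same outcome's admission score, and
#' the four kinematic metrics — the covariate-adjusted design (p = 8).
#'
#' @param outcome `"ELBOW"`, `"SHOULDER"` or `"UL"`.
#' @export
default_predictors <- function(outcome) {
  outcome <- match.arg(outcome, OUTCOMES)
  c("age", "sex", "onset", paste0("MI_", outcome, "_T1"), RMK_METRICS)
}

#' Fit a least-squares multiple linear regression
#'
#' Ordinary least squares of one discharge outcome on a design of
#' standardized predictors and covariates, with standard errors and
#' two-sided p-values from the t distribution on n - p - 1 degrees of
#' freedom.  The design must be full rank; collinear columns are named
#' in the error.
#'
#' @param data Model frame (numeric columns).
#' @param outcome_col Name of the outcome column.
#' @param predictors Character vector of predictor columns (may be empty
#'   for an intercept-only model).
#' @param outcome Outcome label stored in the model (defaults to
#'   `outcome_col`).
#' @return Object of class `rmk_model`: coefficients table (estimate,
#'   SE, t, p), n, R-squared, adjusted R-squared, residual variance, the
#'   underlying `lm` fit and the data (kept for refits during predictor
#'   selection).
#' @export
fit_ols <- function(data, outcome_col, predictors, outcome = outcome_col) {
  stopifnot(outcome_col %in% names(data), all(predictors %in% names(data)))
  n <- nrow(data)
  p <- length(predictors)
  if (n <= p + 1L) stop("need n > number of parameters")
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, predictors, drop = FALSE]))
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop(sprintf("design is rank deficient; collinear column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  rhs <- if (p == 0L) "1" else paste(sprintf("`%s`", predictors), collapse = " + ")
  fml <- stats::as.formula(paste0("`", outcome_col, "` ~ ", rhs))
  fit <- stats::lm(fml, data = data)
  sm <- summary(fit)
  ct <- as.data.frame(sm$coefficients)
  names(ct) <- c("estimate", "std_error", "statistic", "p_value")
  ct <- cbind(term = gsub("`", "", rownames(ct)), ct)
  rownames(ct) <- NULL
  structure(
    list(outcome = outcome, outcome_col = outcome_col,
         predictors = predictors, coefficients = ct, n = n,
         r_squared = sm$r.squared,
         adj_r_squared = if (p > 0) adjusted_r_squared(sm$r.squared, n, p) else sm$r.squared,
         sigma2 = sm$sigma^2, fit = fit, data = data),
    class = "rmk_model"
  )
}

#' @export
predict.rmk_model <- function(object, newdata, ...) {
  unname(stats::predict(object$fit, newdata = newdata))
}

#' @export
print.rmk_model <- function(x, ...) {
  cat(sprintf("<rmk_model> MI_%s ~ %s  (n = %d, R^2 = %.3f)\n",
              x$outcome,
              if (length(x$predictors)) paste(x$predictors, collapse = " + ") else "1",
              x$n, x$r_squared))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Backward elimination of non-significant kinematic predictors
#'
#' Repeatedly drops the least-significant eliminable predictor with
#' p > `alpha` and refits, until every remaining eliminable predictor is
#' significant.  By default only the kinematic metrics are eliminable
#' and the clinical covariates are always kept; pass them in
#' `eliminable` to allow their removal too.  May return an
#' intercept-plus-covariates (or intercept-only) model.
#'
#' @param model An [fit_ols()] result.
#' @param alpha Significance threshold (default 0.05).
#' @param eliminable Predictors allowed to be dropped (default: the
#'   kinematic metrics present in the model).
#' @return The reduced, refitted `rmk_model`.
#' @export
select_significant <- function(model, alpha = 0.05,
                               eliminable = intersect(model$predictors,
                                                      RMK_METRICS)) {
  stopifnot(inherits(model, "rmk_model"))
  repeat {
    ct <- model$coefficients
    cand <- ct[ct$term %in% eliminable & ct$p_value > alpha, ]
    if (!nrow(cand)) return(model)
    drop_term <- cand$term[which.max(cand$p_value)]
    model <- fit_ols(model$data, model$outcome_col,
                     setdiff(model$predictors, drop_term), model$outcome)
  }
}

# Numeric model frame: 0/1 coding for sex (male = 1) and side (left = 1);
# etiology is descriptive only and never enters the design.  Records with
# missing modelling fields are rejected (no imputation).
cohort_frame <- function(cohort) {
  df <- if (inherits(cohort, "rmk_cohort")) cohort$patients else cohort
  df <- as.data.frame(df)
  if (is.character(df$sex) || is.factor(df$sex)) {
    df$sex <- as.integer(as.character(df$sex) == "male")
  }
  if (is.character(df$side) || is.factor(df$side)) {
    df$side <- as.integer(as.character(df$side) == "left")
  }
  used <- intersect(c("age", "sex", "onset", RMK_METRICS,
                      paste0("MI_", rep(OUTCOMES, each = 2), "_T",
                             rep(1:2, times = 3))), names(df))
  bad <- !stats::complete.cases(df[, used, drop = FALSE])
  if (any(bad)) {
    ids <- if ("id" %in% names(df)) df$id[bad] else which(bad)
    stop(sprintf("incomplete record(s) rejected: %s",
                 paste(ids, collapse = ", ")))
  }
  df
}

#' Split-sample validation of the outcome models
#'
#' The full procedure for the 75/25 experiment: standardize the
#' modelling variables, draw the random partition, run the balance-test
#' battery, fit the covariate-adjusted model on the training set with
#' backward elimination of non-significant kinematic predictors, and
#' evaluate on the training and held-out validation sets separately.
#'
#' @param cohort An `rmk_cohort` or its patients data.frame.
#' @param outcomes Outcomes to model (default all three).
#' @param seed Seed for the partition (four-group subdivision uses
#'   seed + 1).
#' @param train_frac Training fraction (default 0.75).
#' @param alpha Selection threshold.
#' @param standardize_scope `"cohort"` (default): means/SDs from the
#'   full cohort before the split, matching the procedure order
#'   (standardization prior to modelling); `"training"`: transform
#'   estimated on the training rows only and projected onto validation
#'   rows, avoiding the (mild) leakage of the default.
#' @param mae_denominator Passed to [validation_report()].
#' @return Object of class `rmk_ssv`: `split`, `balance`, and per
#'   outcome the selected `model`, `training` and `validation` reports
#'   and the per-patient predictions.
#' @export
run_ssv <- function(cohort, outcomes = OUTCOMES, seed = 1L,
                    train_frac = 0.75, alpha = 0.05,
                    standardize_scope = c("cohort", "training"),
                    mae_denominator = "mean_observed") {
  standardize_scope <- match.arg(standardize_scope)
  df <- cohort_frame(cohort)
  split <- split_sample(nrow(df), train_frac, seed)
  std <- standardize_cohort(df, estimate_rows = if (standardize_scope == "cohort")
    seq_len(nrow(df)) else split$train)
  sdf <- std$data
  balance <- balance_tests(df, split)
  res <- lapply(outcomes, function(o) {
    ycol <- paste0("MI_", o, "_T2")
    model <- fit_ols(sdf[split$train, ], ycol, default_predictors(o), o)
    model <- select_significant(model, alpha)
    scale <- mi_scale(o)
    out <- list(model = model)
    for (set in c("training", "validation")) {
      rows <- if (set == "training") split$train else split$validation
      pred <- predict(model, sdf[rows, ])
      out[[set]] <- validation_report(sdf[[ycol]][rows], pred, scale,
                                      length(model$predictors),
                                      mae_denominator)
      out[[paste0(set, "_predictions")]] <-
        data.frame(row = rows, actual = sdf[[ycol]][rows], predicted = pred,
                   predicted_snapped = nearest_valid_score(pred, scale))
    }
    out
  })
  names(res) <- outcomes
  structure(list(seed = as.integer(seed), split = split, balance = balance,
                 standardize_scope = standardize_scope,
                 transform = std$transform, outcomes = res),
            class = "rmk_ssv")
}

#' Leave-one-out cross-validation of the outcome models
#'
#' For each of the n records, the model is fitted on the remaining n - 1
#' and used to predict the record set aside; the validation report is
#' computed on the n pooled out-of-fold predictions.  Also returns the
#' final model fitted on all records — the analogue of the published
#' single-predictor equations when selection is enabled.
#'
#' @inheritParams run_ssv
#' @param select Run backward elimination inside each fold and for the
#'   final model (default TRUE).  With `FALSE` the fixed full design is
#'   used, for which the out-of-fold residuals obey the closed-form
#'   hat-matrix identity.
#' @param standardize_scope `"cohort"` (default, standardization before
#'   modelling) or `"fold"` (transform re-estimated on each fold's n - 1
#'   training records).
#' @return Object of class `rmk_loocv`: per outcome the pooled
#'   `predictions`, the `report`, the final `model` and `n_fits`.
#' @export
run_loocv <- function(cohort, outcomes = OUTCOMES, alpha = 0.05,
                      select = TRUE,
                      standardize_scope = c("cohort", "fold"),
                      mae_denominator = "mean_observed") {
  standardize_scope <- match.arg(standardize_scope)
  df <- cohort_frame(cohort)
  n <- nrow(df)
  if (n < 3L) stop("LOOCV needs n >= 3")
  sdf_all <- standardize_cohort(df)$data
  res <- lapply(outcomes, function(o) {
    ycol <- paste0("MI_", o, "_T2")
    preds <- numeric(n)
    for (i in seq_len(n)) {
      if (standardize_scope == "cohort") {
        train <- sdf_all[-i, ]
        test <- sdf_all[i, , drop = FALSE]
      } else {
        std_i <- standardize_cohort(df, estimate_rows = setdiff(seq_len(n), i))
        train <- std_i$data[-i, ]
        test <- std_i$data[i, , drop = FALSE]
      }
      m <- fit_ols(train, ycol, default_predictors(o), o)
      if (select) m <- select_significant(m, alpha)
      preds[i] <- predict(m, test)
    }
    scale <- mi_scale(o)
    final <- fit_ols(sdf_all, ycol, default_predictors(o), o)
    if (select) final <- select_significant(final, alpha)
    list(predictions = data.frame(row = seq_len(n), actual = df[[ycol]],
                                  predicted = preds,
                                  predicted_snapped =
                                    nearest_valid_score(preds, scale)),
         report = validation_report(df[[ycol]], preds, scale,
                                    length(final$predictors),
                                    mae_denominator),
         model = final, n_fits = n)
  })
  names(res) <- outcomes
  structure(list(outcomes = res, n = n, select = select,
                 standardize_scope = standardize_scope),
            class = "rmk_loocv")
}

#' Published leave-one-out outcome models
#'
#' The final single-predictor models relating discharge Motricity Index
#' scores to the standardized admission movement path error toward the
#' body (MPE_C): score = intercept + slope * MPE_C_std.
#'
#' @return data.frame with `outcome`, `intercept`, `slope`.
#' @export
published_models <- function() {
  data.frame(outcome = OUTCOMES,
             intercept = c(12.99, 13.70, 32.50),
             slope = c(-4.89, -4.26, -11.99))
}

#' Training-set coefficients of the split-sample models
#'
#' Documentation constants: the kinematic-metric coefficients reported
#' for the covariate-adjusted training fits of the split-sample
#' experiment (both MPE_C and MPE_D were significant there).  They
#' belong to the original cohort's training split and are not used in
#' any computation here.
#'
#' @return data.frame with `outcome`, `beta_MPE_C`, `beta_MPE_D`.
#' @export
ssv_training_betas <- function() {
  data.frame(outcome = OUTCOMES,
             beta_MPE_C = c(-5.16, -5.02, -13.52),
             beta_MPE_D = c(3.37, 3.37, 8.26))
}

#' Predict a discharge score with a published model
#'
#' Evaluates the published single-predictor model for an outcome at a
#' standardized admission MPE_C value.  At `mpe_c_std = 0` (a patient at
#' the cohort-average path error) the prediction equals the model's
#' intercept.  The continuous prediction can be snapped downstream with
#' [nearest_valid_score()].
#'
#' @param outcome `"ELBOW"`, `"SHOULDER"` or `"UL"`.
#' @param mpe_c_std Standardized MPE_C value(s) (finite).
#' @return Predicted discharge score(s) in points.
#' @examples
#' predict_published("ELBOW", 0)   # 12.99
#' predict_published("UL", 1.0)    # 20.51
#' @export
predict_published <- function(outcome, mpe_c_std) {
  pm <- published_models()
  if (!outcome %in% pm$outcome) {
    stop(sprintf("unknown outcome '%s'; expected one of %s", outcome,
                 paste(pm$outcome, collapse = ", ")))
  }
  if (any(!is.finite(mpe_c_std))) stop("mpe_c_std must be finite")
  row <- pm[pm$outcome == outcome, ]
  row$intercept + row$slope * mpe_c_std
}
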