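# Evaluation panel: error metrics, normalized variants, R-squared,
# Spearman rank correlation with the strength rubric, and the per-set
# validation report.

check_pair <- function(actual, predicted) {
  if (length(actual) == 0L) stop("empty vectors")
  if (length(actual) != length(predicted)) stop("length mismatch between actual and predicted")
}

#' Root mean squared error
#' @param actual,predicted Equal-length numeric vectors (score points).
#' @return RMSE in score points.
#' @export
rmse <- function(actual, predicted) {
  check_pair(actual, predicted)
  sqrt(mean((actual - predicted)^2))
}

#' Mean absolute error
#' @inheritParams rmse
#' @return MAE in score points. Always <= RMSE on the same residuals.
#' @export
mae <- function(actual, predicted) {
  check_pair(actual, predicted)
  mean(abs(actual - predicted))
}

#' Normalized RMSE (percent of scale range)
#'
#' `RMSE_n = 100 * RMSE / (scale max - scale min)`, the error as a
#' percentage of the attainable score range (33 points for a sub-item,
#' 99 for the 1--100 total).  Returned unrounded; the reporting layer
#' rounds sub-items to integers and the total scale to one decimal
#' ([round_rmse_n()]).
#'
#' @param rmse RMSE in score points.
#' @param scale An [mi_scale()] object.
#' @return Percentage (unrounded).
#' @export
normalize_rmse <- function(rmse, scale) {
  stopifnot(inherits(scale, "mi_scale"))
  rng <- scale$max - scale$min
  if (rng <= 0) stop("scale range must be positive")
  100 * rmse / rng
}

#' Reporting-layer rounding for normalized RMSE
#' @param x Unrounded RMSE_n percentage.
#' @param scale The scale it belongs to (sub-items print as integers, the
#'   UL total with one decimal).
#' @export
round_rmse_n <- function(x, scale) {
  round(x, digits = if (scale$name == "UL") 1L else 0L)
}

#' Normalized MAE
#'
#' `MAE_n = 100 * MAE / denominator`.  The normalizing quantity is
#' selectable: the mean of the observed discharge scores (default; the
#' convention consistent with how normalized MAE percentages relate to
#' the raw MAE values in this setting) or the scale range.
#'
#' @param mae MAE in score points.
#' @param denominator Positive normalizing value in score points (e.g.
#'   `mean(actual)` or `scale$max - scale$min`).
#' @return Percentage.
#' @export
normalize_mae <- function(mae, denominator) {
  if (denominator <= 0) stop("denominator must be positive")
  100 * mae / denominator
}

#' Coefficient of determination and its adjusted form
#'
#' `r_squared` is 1 - SSE/SST with SST around the mean of `actual`;
#' `adjusted_r_squared` applies the small-sample correction
#' `1 - (1 - R^2) * (n - 1) / (n - p - 1)` for `p` predictors.
#'
#' @inheritParams rmse
#' @return Fraction of variance explained.
#' @export
r_squared <- function(actual, predicted) {
  check_pair(actual, predicted)
  sst <- sum((actual - mean(actual))^2)
  if (sst == 0) stop("actual values have zero variance; R^2 undefined")
  1 - sum((actual - predicted)^2) / sst
}

#' @rdname r_squared
#' @param r2 Unadjusted R-squared.
#' @param n Number of observations.
#' @param p Number of predictors (excluding the intercept).
#' @export
adjusted_r_squared <- function(r2, n, p) {
  if (n <= p + 1) stop("adjusted R^2 requires n > p + 1")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks (so ties are handled by averaging),
#' with the two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))`
#' on n - 2 degrees of freedom.  Perfect correlations get p = 0.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, neither constant.
#' @return List with `r` and `p`.
#' @export
spearman_rank <- function(x, y) {
  check_pair(x, y)
  n <- length(x)
  if (n < 3L) stop("Spearman correlation needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  r <- stats::cor(rank(x), rank(y))
  if (abs(r) >= 1) return(list(r = r, p = 0))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Assemble the validation report for one prediction set
#'
#' Computes the full evaluation panel for a set of predictions of one
#' outcome: RMSE and MAE with their normalized variants, R-squared and
#' adjusted R-squared, and the Spearman rank correlation between the
#' therapist-assigned scores and the predictions corrected to the
#' nearest valid discrete score, with the strength label from the
#' rubric.  Error and variance metrics use the raw (uncorrected)
#' predictions; only the rank correlation uses the snapped ones,
#' mirroring how discrete-scale predictions are assessed.
#'
#' @param actual Observed discharge scores.
#' @param predicted Model predictions (continuous).
#' @param scale The outcome's [mi_scale()].
#' @param n_predictors Number of model predictors, for the adjusted
#'   R-squared.
#' @param mae_denominator `"mean_observed"` (default) or `"range"`.
#' @return An object of class `rmk_validation_report`.
#' @export
validation_report <- function(actual, predicted, scale, n_predictors,
                              mae_denominator = c("mean_observed", "range")) {
  mae_denominator <- match.arg(mae_denominator)
  check_pair(actual, predicted)
  n <- length(actual)
  rmse_v <- rmse(actual, predicted)
  mae_v <- mae(actual, predicted)
  denom <- if (mae_denominator == "mean_observed") mean(actual) else scale$max - scale$min
  r2 <- r_squared(actual, predicted)
  snapped <- nearest_valid_score(predicted, scale)
  sp <- spearman_rank(actual, snapped)
  structure(
    list(outcome = scale$name, n = n, n_predictors = n_predictors,
         rmse = rmse_v, rmse_n = normalize_rmse(rmse_v, scale),
         mae = mae_v, mae_n = normalize_mae(mae_v, denom),
         mae_denominator = mae_denominator,
         r_squared = r2,
         adj_r_squared = adjusted_r_squared(r2, n, n_predictors),
         spearman_r = sp$r, spearman_p = sp$p,
         strength = interpret_correlation(sp$r)),
    class = "rmk_validation_report"
  )
}

#' @export
print.rmk_validation_report <- function(x, ...) {
  scale <- mi_scale(x$outcome)
  cat(sprintf("<rmk_validation_report> MI_%s, n = %d\n", x$outcome, x$n))
  cat(sprintf("  RMSE %.3f (RMSE_n %s%%)  MAE %.3f (MAE_n %.0f%%)\n",
              x$rmse, format(round_rmse_n(x$rmse_n, scale)), x$mae, x$mae_n))
  cat(sprintf("  R^2 %.3f (adj %.3f)  Spearman r %.3f (p %.2g, %s)\n",
              x$r_squared, x$adj_r_squared, x$spearman_r, x$spearman_p,
              x$strength))
  invisible(x)
}
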