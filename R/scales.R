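# Motricity Index scale definitions and discrete-score arithmetic.

#' Motricity Index scale definition
#'
#' Builds the scale object used for score validation, normalization and
#' nearest-valid-score snapping.  Each upper-limb sub-item (pinch grasp,
#' elbow flexion, shoulder abduction) is scored on six discrete classes
#' (Wade's values, 0--33); the total upper-limb score is the sum of the
#' three sub-items plus one, so it ranges 1--100 and its attainable values
#' are every sum of three class values plus one.
#'
#' @param name Scale name: `"ELBOW"`, `"SHOULDER"`, `"PINCH"` (sub-items)
#'   or `"UL"` (total upper limb).
#' @param classes Ordered sub-item class values. Default `c(0, 9, 14, 19,
#'   25, 33)`; configurable should a different class calibration be needed.
#' @return An object of class `mi_scale`: a list with `name`, `min`,
#'   `max` and the ordered `valid` score set.
#' @examples
#' mi_scale("ELBOW")$valid
#' mi_scale("UL")$max
#' @export
mi_scale <- function(name = c("ELBOW", "SHOULDER", "PINCH", "UL"),
                     classes = c(0, 9, 14, 19, 25, 33)) {
  name <- match.arg(name)
  if (length(classes) != 6L || is.unsorted(classes, strictly = TRUE)) {
    stop("`classes` must be the six strictly increasing sub-item class values")
  }
  if (name == "UL") {
    sums <- rowSums(expand.grid(classes, classes, classes))
    valid <- sort(unique(sums)) + 1
  } else {
    valid <- classes
  }
  structure(
    list(name = name, min = min(valid), max = max(valid), valid = valid),
    class = "mi_scale"
  )
}

#' Total upper-limb Motricity Index from its sub-items
#'
#' The total score is one plus the sum of the pinch, elbow-flexion and
#' shoulder-abduction sub-items, giving a 1--100 scale (maximum 100).
#'
#' @param elbow,shoulder,pinch Sub-item scores; each must be a member of
#'   the sub-item class set.
#' @param classes Valid sub-item class values (see [mi_scale()]).
#' @return The total score (scalar or vector, points on 1--100).
#' @examples
#' mi_total(33, 33, 33)  # 100
#' mi_total(0, 0, 0)     # 1
#' @export
mi_total <- function(elbow, shoulder, pinch, classes = c(0, 9, 14, 19, 25, 33)) {
  for (nm in c("elbow", "shoulder", "pinch")) {
    v <- get(nm)
    if (!all(v %in% classes)) {
      stop(sprintf("`%s` contains values outside the valid class set {%s}",
                   nm, paste(classes, collapse = ", ")))
    }
  }
  elbow + shoulder + pinch + 1
}

#' Snap a continuous prediction to the nearest valid discrete score
#'
#' Regression predictions are continuous, but therapists can only assign
#' scores from the scale's discrete set.  Each prediction is corrected to
#' the valid score at minimum absolute (Euclidean) distance; exact ties
#' are broken toward the lower score so the correction never inflates
#' predicted recovery.
#'
#' @param x Numeric vector of (finite) predicted scores.
#' @param scale An [mi_scale()] object.
#' @return Vector of members of `scale$valid`, same length as `x`.
#' @examples
#' nearest_valid_score(12.99, mi_scale("ELBOW"))  # 14
#' nearest_valid_score(11.5, mi_scale("ELBOW"))   # 9 (tie -> lower)
#' @export
nearest_valid_score <- function(x, scale) {
  stopifnot(inherits(scale, "mi_scale"), all(is.finite(x)))
  v <- scale$valid  # ascending, so which.min takes the lower score on ties
  vapply(x, function(xi) v[which.min(abs(v - xi))], numeric(1))
}

#' Label the strength of a correlation coefficient
#'
#' Applies the interpretation rubric used for the Spearman correlations:
#' |r| in \[0, 0.3\] very weak, (0.3, 0.5\] weak, (0.5, 0.7\] moderate,
#' (0.7, 1\] strong.  The rubric is applied to |r|, so negative
#' correlations are labelled by magnitude.
#'
#' @param r Correlation coefficient(s), |r| <= 1.
#' @return Character vector of labels.
#' @examples
#' interpret_correlation(c(0.839, 0.627, -0.2))
#' @export
interpret_correlation <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) > 1)) {
    stop("correlation coefficients must be finite with |r| <= 1")
  }
  a <- abs(r)
  out <- character(length(a))
  out[a <= 0.3] <- "very weak"
  out[a > 0.3 & a <= 0.5] <- "weak"
  out[a > 0.5 & a <= 0.7] <- "moderate"
  out[a > 0.7] <- "strong"
  out
}
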