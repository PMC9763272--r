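# Point-to-point 2D reaching trajectories and robot-measured kinematic
# (RMK) metric extraction.
#
# Direction convention in the lesion-side frame (origin at the central
# target, units meters): A = +y (away from the body), C = -y (toward the
# body), D = +x, B = -x.  The movement path error (MPE) of an
# axis-aligned movement is the mean absolute coordinate orthogonal to the
# movement axis, so MPE uses |x| for A and C and |y| for D.

DIRECTIONS <- c("A", "B", "C", "D")

#' Construct a point-to-point 2D trajectory
#'
#' @param t Sample times (seconds), strictly increasing, length >= 2.
#' @param x,y Positions in the task plane (meters), origin at the central
#'   target.
#' @param vx,vy Optional velocity samples (m/s); when absent they can be
#'   derived with [differentiate()].
#' @param direction Movement direction label, one of `"A"`, `"B"`, `"C"`,
#'   `"D"`.
#' @param side Affected side, `"left"` or `"right"`; determines the
#'   lesion-side reference frame (see [to_lesion_frame()]).
#' @param sample_rate Nominal sampling rate in Hz; defaults to the
#'   reciprocal median sample interval.
#' @return An object of class `rmk_trajectory`.
#' @export
trajectory <- function(t, x, y, vx = NULL, vy = NULL,
                       direction, side, sample_rate = NULL) {
  n <- length(t)
  if (n < 2L) stop("a trajectory needs at least 2 samples")
  if (length(x) != n || length(y) != n) stop("t, x, y lengths differ")
  if (any(diff(t) <= 0)) stop("sample times must be strictly increasing")
  if (!is.null(vx) && (length(vx) != n || length(vy) != n)) {
    stop("velocity vectors must match the sample count")
  }
  direction <- match.arg(direction, DIRECTIONS)
  side <- match.arg(side, c("left", "right"))
  if (is.null(sample_rate)) sample_rate <- 1 / stats::median(diff(t))
  structure(
    list(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
         vx = if (is.null(vx)) NULL else as.numeric(vx),
         vy = if (is.null(vy)) NULL else as.numeric(vy),
         direction = direction, side = side, sample_rate = sample_rate),
    class = "rmk_trajectory"
  )
}

#' @export
print.rmk_trajectory <- function(x, ...) {
  cat(sprintf(
    "<rmk_trajectory> direction %s, %s-affected, %d samples @ %.0f Hz, %.2f s\n",
    x$direction, x$side, length(x$t), x$sample_rate, max(x$t) - min(x$t)))
  invisible(x)
}

#' Mirror a trajectory into the lesion-side reference frame
#'
#' The metric reference frame coincides with the lesion side: recordings
#' from right-affected patients are used as-is, while for left-affected
#' patients the x axis (and x velocity) is sign-flipped so that movements
#' of equivalent impairment have identical coordinates regardless of
#' side.  The transform is an involution: applying it twice to a
#' left-affected trajectory restores the original.
#'
#' @param traj An [trajectory()] object with `side` set.
#' @return The trajectory expressed in the lesion-side frame.
#' @export
to_lesion_frame <- function(traj) {
  stopifnot(inherits(traj, "rmk_trajectory"))
  if (is.null(traj$side)) stop("trajectory has no affected `side` set")
  if (traj$side == "left") {
    traj$x <- -traj$x
    if (!is.null(traj$vx)) traj$vx <- -traj$vx
  }
  traj
}

#' Differentiate positions into velocities
#'
#' Central differences on interior samples and one-sided differences at
#' the endpoints, using the actual timestamps (no uniform-rate
#' assumption).  Exact for linear position signals.
#'
#' @param traj A trajectory; any existing velocities are replaced.
#' @return The trajectory with `vx`, `vy` filled in.
#' @export
differentiate <- function(traj) {
  stopifnot(inherits(traj, "rmk_trajectory"))
  t <- traj$t
  if (any(diff(t) == 0)) stop("duplicate timestamps cannot be differentiated")
  traj$vx <- finite_diff(traj$x, t)
  traj$vy <- finite_diff(traj$y, t)
  traj
}

finite_diff <- function(p, t) {
  n <- length(t)
  v <- numeric(n)
  v[1] <- (p[2] - p[1]) / (t[2] - t[1])
  v[n] <- (p[n] - p[n - 1]) / (t[n] - t[n - 1])
  if (n > 2L) {
    k <- 2:(n - 1)
    v[k] <- (p[k + 1] - p[k - 1]) / (t[k + 1] - t[k - 1])
  }
  v
}

#' Movement Path Error (MPE)
#'
#' Mean distance of the travelled path from the ideal straight line
#' joining the central and peripheral targets.  With the peripheral
#' targets on the coordinate axes the ideal line is an axis, so
#' MPE = mean(|y|) for direction D and mean(|x|) for directions A and C.
#' Zero iff every sample lies exactly on the straight line.  The
#' trajectory must already be in the lesion-side frame (the shortcut is
#' exact only there).
#'
#' @param traj A trajectory with direction A, C or D.
#' @return MPE in meters (>= 0).
#' @export
compute_mpe <- function(traj) {
  stopifnot(inherits(traj, "rmk_trajectory"))
  if (!traj$direction %in% c("A", "C", "D")) {
    stop(sprintf("MPE is defined for directions A, C, D only (got %s)",
                 traj$direction))
  }
  if (traj$direction == "D") mean(abs(traj$y)) else mean(abs(traj$x))
}

#' Mean Movement Speed (MS)
#'
#' Mean of the resultant planar velocity magnitude,
#' `mean(sqrt(vx^2 + vy^2))`, over the movement.  Uses recorded
#' velocities when present, otherwise differentiates the positions.
#' Defined for every direction.
#'
#' @param traj A trajectory.
#' @return MS in m/s (>= 0).
#' @export
compute_ms <- function(traj) {
  stopifnot(inherits(traj, "rmk_trajectory"))
  if (is.null(traj$vx) || is.null(traj$vy)) traj <- differentiate(traj)
  mean(sqrt(traj$vx^2 + traj$vy^2))
}

#' Count speed peaks of a movement
#'
#' Number of strict local maxima of the resultant speed profile whose
#' topographic prominence is at least `min_prominence_frac` times the
#' maximum speed.  A single smooth (e.g. minimum-jerk) movement has one
#' peak; fragmented movements made of submovements have several.
#'
#' @param traj A trajectory (velocities derived if absent).
#' @param min_prominence_frac Prominence threshold as a fraction of peak
#'   speed, in \[0, 1); default 0.05.
#' @return Integer peak count (>= 0).
#' @export
count_speed_peaks <- function(traj, min_prominence_frac = 0.05) {
  stopifnot(inherits(traj, "rmk_trajectory"),
            min_prominence_frac >= 0, min_prominence_frac < 1)
  if (is.null(traj$vx) || is.null(traj$vy)) traj <- differentiate(traj)
  s <- sqrt(traj$vx^2 + traj$vy^2)
  smax <- max(s)
  if (smax == 0) return(0L)
  if (length(s) < 3L) return(0L)
  idx <- find_peaks(s)
  if (!length(idx)) return(0L)
  prom <- vapply(idx, function(i) peak_prominence(s, i), numeric(1))
  sum(prom >= min_prominence_frac * smax)
}

# Interior local maxima, plateau-aware: a maximal run of equal samples
# bounded by a rise on the left and a fall on the right counts as one
# peak (at the plateau midpoint).  A symmetric bell sampled with an even
# count has two equal center samples, which a strict s[i-1] < s[i] >
# s[i+1] test would miss.
find_peaks <- function(s) {
  d <- diff(s)
  nz <- which(d != 0)
  if (length(nz) < 2L) return(integer(0))
  sg <- sign(d[nz])
  peaks <- integer(0)
  for (j in seq_len(length(nz) - 1L)) {
    if (sg[j] > 0 && sg[j + 1L] < 0) {
      peaks <- c(peaks, as.integer((nz[j] + 1L + nz[j + 1L]) %/% 2L))
    }
  }
  peaks
}

# Topographic prominence of peak i: height above the higher of the two
# key saddles (lowest point between the peak and the nearest higher
# terrain on each side; the side minimum if nothing higher exists).
peak_prominence <- function(s, i) {
  h <- s[i]
  left <- s[seq_len(i - 1)]
  right <- s[seq(i + 1, length(s))]
  key <- function(seg) {
    higher <- which(seg > h)
    if (length(higher)) min(seg[seq(min(higher), length(seg))]) else min(seg)
  }
  # walk outward: reverse the left segment so index 1 is adjacent to the peak
  h - max(key(rev(left)), key(right))
}

#' Extract the per-patient robot-measured kinematic feature panel
#'
#' Computes the predictive feature set from one patient's movements: the
#' movement path errors for directions A, C and D and the mean movement
#' speed for direction B, plus the full per-direction panel (MPE where
#' defined, MS and speed-peak count for every direction).  Trajectories
#' are first mirrored into the lesion-side frame; multiple repetitions of
#' a direction are averaged (arithmetic mean).
#'
#' @param trajectories Named list with elements `A`, `B`, `C`, `D`; each
#'   element is a single trajectory or a list of repetitions.
#' @param min_prominence_frac Passed to [count_speed_peaks()].
#' @return An object of class `rmk_features`: list with `MPE_A`, `MPE_C`,
#'   `MPE_D`, `MS_B` (the model inputs) and `panel`, a data.frame with
#'   one row per direction (`mpe` is `NA` for direction B, where the
#'   error metric is undefined).
#' @export
extract_features <- function(trajectories, min_prominence_frac = 0.05) {
  missing_dir <- setdiff(DIRECTIONS, names(trajectories))
  if (length(missing_dir)) {
    stop(sprintf("missing required direction(s): %s",
                 paste(missing_dir, collapse = ", ")))
  }
  per_dir <- lapply(DIRECTIONS, function(d) {
    reps <- trajectories[[d]]
    if (inherits(reps, "rmk_trajectory")) reps <- list(reps)
    reps <- lapply(reps, to_lesion_frame)
    mpe <- if (d == "B") NA_real_ else mean(vapply(reps, compute_mpe, numeric(1)))
    ms <- mean(vapply(reps, compute_ms, numeric(1)))
    peaks <- mean(vapply(reps, count_speed_peaks, numeric(1),
                         min_prominence_frac = min_prominence_frac))
    data.frame(direction = d, n_repetitions = length(reps),
               mpe = mpe, ms = ms, speed_peaks = peaks)
  })
  panel <- do.call(rbind, per_dir)
  structure(
    list(MPE_A = panel$mpe[panel$direction == "A"],
         MPE_C = panel$mpe[panel$direction == "C"],
         MPE_D = panel$mpe[panel$direction == "D"],
         MS_B = panel$ms[panel$direction == "B"],
         panel = panel),
    class = "rmk_features"
  )
}

#' @export
print.rmk_features <- function(x, ...) {
  cat(sprintf(
    "<rmk_features> MPE_A %.4f m, MPE_C %.4f m, MPE_D %.4f m, MS_B %.4f m/s\n",
    x$MPE_A, x$MPE_C, x$MPE_D, x$MS_B))
  invisible(x)
}
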