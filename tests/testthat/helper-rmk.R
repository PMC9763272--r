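# Shared fixture builders (all fixtures are generated in code).

# Straight center-out movement at constant speed along the direction axis.
straight_trajectory <- function(direction = "C", side = "right",
                                distance = 0.14, speed = 0.1, n = 101) {
  duration <- distance / speed
  t <- seq(0, duration, length.out = n)
  frac <- t / duration
  ax <- switch(direction, A = c(0, 1), B = c(-1, 0), C = c(0, -1), D = c(1, 0))
  trajectory(t = t,
             x = distance * frac * ax[1], y = distance * frac * ax[2],
             vx = rep(speed * ax[1], n), vy = rep(speed * ax[2], n),
             direction = direction, side = side)
}

# One straight trajectory per direction, shared speed.
straight_set <- function(speed = 0.1, side = "right") {
  out <- lapply(c("A", "B", "C", "D"), straight_trajectory,
                side = side, speed = speed)
  names(out) <- c("A", "B", "C", "D")
  out
}

# Small cohort configuration for fast pipeline tests.
quick_config <- function(...) {
  generator_config(trajectories = FALSE, ...)
}

# Independent normal-equations OLS oracle (solve(X'X) X'y).
normal_equations_fit <- function(X, y) {
  Xi <- cbind(1, X)
  drop(solve(t(Xi) %*% Xi, t(Xi) %*% y))
}
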