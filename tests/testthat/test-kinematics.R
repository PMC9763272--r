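test_that("trajectory constructor validates its invariants", {
  expect_error(trajectory(t = 1, x = 0, y = 0, direction = "A", side = "right"),
               "at least 2")
  expect_error(trajectory(t = c(0, 0.1, 0.05), x = 1:3, y = 1:3,
                          direction = "A", side = "right"),
               "strictly increasing")
})

test_that("lesion-frame transform mirrors x for left-affected and is an involution", {
  t <- seq(0, 1, length.out = 11)
  tr_r <- trajectory(t, x = rep(0.10, 11), y = rep(0.05, 11),
                     vx = rep(0.1, 11), vy = rep(0, 11),
                     direction = "D", side = "right")
  expect_identical(to_lesion_frame(tr_r), tr_r)  # right-affected: identity

  tr_l <- trajectory(t, x = rep(0.10, 11), y = rep(0.05, 11),
                     vx = rep(0.1, 11), vy = rep(0, 11),
                     direction = "D", side = "left")
  fl <- to_lesion_frame(tr_l)
  expect_equal(fl$x, rep(-0.10, 11))
  expect_equal(fl$vx, rep(-0.1, 11))
  expect_equal(fl$y, tr_l$y)
  expect_identical(to_lesion_frame(fl), tr_l)    # mirror involution
})

test_that("MPE measures mean deviation from the ideal axis line", {
  # exactly on the straight line -> 0
  expect_identical(compute_mpe(straight_trajectory("C")), 0)
  expect_identical(compute_mpe(straight_trajectory("A")), 0)
  expect_identical(compute_mpe(straight_trajectory("D")), 0)

  # constant lateral offset of 0.01 m -> 0.01 (direction C uses |x|)
  tr <- straight_trajectory("C")
  tr$x <- tr$x + 0.01
  expect_equal(compute_mpe(tr), 0.01)

  # half-sine deviation of amplitude 0.02, dense sampling -> 2a/pi
  n <- 1000
  t <- seq(0, 1, length.out = n)
  dev <- 0.02 * sin(pi * seq(0, 1, length.out = n))
  trd <- trajectory(t, x = 0.14 * seq(0, 1, length.out = n), y = dev,
                    direction = "D", side = "right")
  brute <- mean(abs(dev))  # frozen oracle: numeric mean of |a sin(pi k/N)|
  expect_equal(compute_mpe(trd), brute)
  expect_equal(compute_mpe(trd), 2 * 0.02 / pi, tolerance = 0.01)
  expect_equal(compute_mpe(trd), 0.01273, tolerance = 0.01)

  expect_error(compute_mpe(straight_trajectory("B")), "directions A, C, D")
})

test_that("MS is the mean resultant speed, from recorded or derived velocities", {
  tr <- straight_trajectory("D", speed = 0.1)
  expect_equal(compute_ms(tr), 0.1)

  # stationary -> 0
  t <- seq(0, 1, length.out = 51)
  still <- trajectory(t, x = rep(0, 51), y = rep(0, 51),
                      direction = "A", side = "right")
  expect_equal(compute_ms(still), 0)

  # minimum-jerk 0.14 m in 1.0 s, dense sampling -> ~0.14 m/s
  n <- 1000
  tau <- seq(0, 1, length.out = n)
  mj <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  mjd <- 30 * tau^2 * (1 - tau)^2
  trmj <- trajectory(tau, x = 0.14 * mj, y = rep(0, n),
                     vx = 0.14 * mjd, vy = rep(0, n),
                     direction = "D", side = "right")
  oracle <- mean(0.14 * mjd)  # numeric mean of the analytic speed profile
  expect_equal(compute_ms(trmj), oracle)
  expect_equal(compute_ms(trmj), 0.14, tolerance = 0.01)

  # velocities derived when absent agree closely with analytic ones
  trmj$vx <- NULL
  trmj$vy <- NULL
  expect_equal(compute_ms(trmj), oracle, tolerance = 1e-3)
})

test_that("differentiation is exact for linear signals and O(dt^2) for quadratics", {
  t <- seq(0, 2, length.out = 401)  # 200 Hz
  lin <- trajectory(t, x = 0.1 * t, y = rep(0.3, length(t)),
                    direction = "D", side = "right")
  d <- differentiate(lin)
  expect_equal(d$vx, rep(0.1, length(t)))
  expect_equal(d$vy, rep(0, length(t)))

  quad <- trajectory(t, x = t^2, y = rep(0, length(t)),
                     direction = "D", side = "right")
  dq <- differentiate(quad)
  interior <- 2:(length(t) - 1)
  expect_lt(max(abs(dq$vx[interior] - 2 * t[interior])), (diff(t)[1])^2 * 10)

  dup <- trajectory(c(0, 1, 2), x = 1:3, y = 1:3, direction = "D", side = "right")
  dup$t <- c(0, 1, 1)
  expect_error(differentiate(dup), "duplicate")
})

test_that("speed-peak counting finds prominent local maxima", {
  # single minimum-jerk bell -> 1
  tr <- generate_trajectory("B", target_mpe = 0, mean_speed = 0.1)
  expect_equal(count_speed_peaks(tr), 1L)

  # two submovement bells separated by a near-zero valley -> 2
  t <- seq(0, 2, length.out = 401)
  bell <- function(tt, c) 0.2 * exp(-((tt - c) / 0.15)^2)
  v <- bell(t, 0.5) + bell(t, 1.5)
  two <- trajectory(t, x = cumsum(v) * diff(t)[1], y = rep(0, length(t)),
                    vx = v, vy = rep(0, length(t)),
                    direction = "D", side = "right")
  # brute-force strict local-maxima scan as the oracle
  s <- sqrt(two$vx^2 + two$vy^2)
  brute <- sum(vapply(2:(length(s) - 1), function(i)
    s[i] > s[i - 1] && s[i] > s[i + 1], logical(1)))
  expect_equal(brute, 2L)
  expect_equal(count_speed_peaks(two), 2L)

  # a flat-topped (plateau) maximum counts once, not zero or twice
  sp <- c(0, 1, 2, 2, 2, 1, 0)
  plat <- trajectory(seq_along(sp) / 10, x = cumsum(sp) / 10,
                     y = rep(0, 7), vx = sp, vy = rep(0, 7),
                     direction = "D", side = "right")
  expect_equal(count_speed_peaks(plat), 1L)
  # an even sample count splits a symmetric bell into two equal center
  # samples; still one peak
  even_bell <- generate_trajectory("B", target_mpe = 0, mean_speed = 0.15)
  expect_equal(length(even_bell$t) %% 2, 0)
  expect_equal(count_speed_peaks(even_bell), 1L)

  # zero speed -> 0 peaks
  still <- trajectory(t, x = rep(0, length(t)), y = rep(0, length(t)),
                      vx = rep(0, length(t)), vy = rep(0, length(t)),
                      direction = "D", side = "right")
  expect_equal(count_speed_peaks(still), 0L)

  # low-prominence ripples are not counted
  ripple <- v + 0.001 * sin(40 * pi * t)
  noisy <- trajectory(t, x = cumsum(ripple) * diff(t)[1],
                      y = rep(0, length(t)), vx = ripple,
                      vy = rep(0, length(t)), direction = "D", side = "right")
  expect_equal(count_speed_peaks(noisy, min_prominence_frac = 0.05), 2L)
})

test_that("feature extraction averages repetitions and names missing directions", {
  set <- straight_set(speed = 0.12)
  f <- extract_features(set)
  expect_equal(f$MPE_A, 0)
  expect_equal(f$MPE_C, 0)
  expect_equal(f$MPE_D, 0)
  expect_equal(f$MS_B, 0.12)
  expect_true(is.na(f$panel$mpe[f$panel$direction == "B"]))

  # two repetitions of C with MPE 0.01 and 0.03 -> mean 0.02
  c1 <- straight_trajectory("C")
  c1$x <- c1$x + 0.01
  c2 <- straight_trajectory("C")
  c2$x <- c2$x + 0.03
  set$C <- list(c1, c2)
  expect_equal(extract_features(set)$MPE_C, 0.02)

  expect_error(extract_features(set[c("A", "C", "D")]), "B")
})

test_that("MPE is stable under resampling of the same deviation profile", {
  # the same lateral deviation profile (half-sine in time) sampled at
  # different densities gives the same MPE up to discretization error
  mpe_at <- function(n) {
    u <- seq(0, 1, length.out = n)
    tr <- trajectory(u, x = 0.02 * sin(pi * u), y = 0.14 * u,
                     direction = "A", side = "right")
    compute_mpe(tr)
  }
  dense <- mpe_at(4001)
  expect_equal(mpe_at(201), dense, tolerance = 5e-3)
  expect_equal(mpe_at(1001), dense, tolerance = 1e-3)
  expect_equal(dense, 2 * 0.02 / pi, tolerance = 1e-3)
})

test_that("MS scales inversely with duration for a fixed path", {
  tr1 <- generate_trajectory("D", target_mpe = 0.01, mean_speed = 0.1)
  # same path traversed in half the time: speeds double exactly
  tr2 <- tr1
  tr2$t <- tr1$t / 2
  tr2$vx <- 2 * tr1$vx
  tr2$vy <- 2 * tr1$vy
  expect_equal(compute_ms(tr2) / compute_ms(tr1), 2)
  # and the generator honors the calibration at matched sampling density
  g2 <- generate_trajectory("D", target_mpe = 0.01, mean_speed = 0.2,
                            config = generator_config(sample_rate = 400))
  expect_equal(compute_ms(g2) / compute_ms(tr1), 2, tolerance = 5e-3)
})

test_that("mirror consistency: left-affected features equal the right-affected ones", {
  for (mpe in c(0.005, 0.03)) {
    right <- lapply(c(A = "A", B = "B", C = "C", D = "D"), function(d)
      generate_trajectory(d, target_mpe = mpe, mean_speed = 0.12, side = "right"))
    left <- lapply(c(A = "A", B = "B", C = "C", D = "D"), function(d)
      generate_trajectory(d, target_mpe = mpe, mean_speed = 0.12, side = "left"))
    fr <- extract_features(right)
    fl <- extract_features(left)
    expect_equal(fl$MPE_A, fr$MPE_A)
    expect_equal(fl$MPE_C, fr$MPE_C)
    expect_equal(fl$MPE_D, fr$MPE_D)
    expect_equal(fl$MS_B, fr$MS_B)
  }
})

test_that("the |x|/|y| shortcut equals the brute-force point-to-line distance", {
  # ideal line for direction A is the y axis; distance of (x, y) to it is |x|
  set.seed(42)
  for (rep in 1:5) {
    n <- 200
    t <- seq(0, 1.5, length.out = n)
    x <- cumsum(rnorm(n, 0, 1e-3))
    y <- 0.14 * t / max(t) + cumsum(rnorm(n, 0, 1e-3))
    tr <- trajectory(t, x, y, direction = "A", side = "right")
    brute <- mean(vapply(seq_len(n), function(k) {
      # distance from (x,y) to the line through (0,0) with direction (0,1)
      p <- c(x[k], y[k]); u <- c(0, 1)
      sqrt(sum((p - sum(p * u) * u)^2))
    }, numeric(1)))
    expect_equal(compute_mpe(tr), brute, tolerance = 1e-12)
  }
})
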