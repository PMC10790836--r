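test_that("silent slider gives zero indicators everywhere", {
  d <- toy_design(c(20, 45, 70))
  slider <- new_trace(rep(0, 20 * 80 + 1), 20)
  sa <- compute_sa_indicators(slider, d)
  expect_equal(sa$mSA, rep(0, 3))
  expect_equal(sa$iSA, rep(0, 3))
  expect_error(compute_w_start(slider, d), "undefined")
})

test_that("triangular bumps give exact peak and area", {
  d <- toy_design(c(20, 45))
  slider <- triangle_slider(c(20, 45), height = c(0.8, 0.5))
  sa <- compute_sa_indicators(slider, d)
  expect_equal(sa$mSA, c(0.8, 0.5))
  # base 5 s triangles: area = h * 5 / 2
  expect_equal(sa$iSA, c(2.0, 1.25), tolerance = 1e-9)
})

test_that("area integral matches dense quadrature for a smooth bump", {
  d <- toy_design(30)
  rate <- 20
  t <- seq(0, 60, by = 1 / rate)
  bump <- function(t) ifelse(abs(t - 30) < 3, 0.7 * cos(pi * (t - 30) / 6)^1,
                             0)
  slider <- new_trace(pmax(bump(t), 0), rate)
  sa <- compute_sa_indicators(slider, d)
  oracle <- stats::integrate(function(x) pmax(bump(x), 0), 27, 33,
                             rel.tol = 1e-10)$value
  expect_equal(sa$iSA, oracle, tolerance = 1e-3)
})

test_that("w_start is the mean anticipation over responsive trials", {
  # both responses start exactly 4 s before t_level
  d <- toy_design(c(20, 45))
  t <- seq(0, 60, by = 1 / 20)
  y <- numeric(length(t))
  y[(t >= 16 & t <= 21) | (t >= 41 & t <= 46)] <- 0.5
  expect_equal(compute_w_start(new_trace(y, 20), d), 4.0)

  # anticipations of 2 s and 4 s average to 3 s
  y2 <- numeric(length(t))
  y2[t >= 18 & t <= 21] <- 0.5
  y2[t >= 41 & t <= 46] <- 0.5
  expect_equal(compute_w_start(new_trace(y2, 20), d), 3.0)

  # a silent trial is excluded from the mean, not averaged as zero
  d3 <- toy_design(c(20, 45, 70))
  y3 <- numeric(20 * 80 + 1)
  t3 <- seq(0, 80, by = 1 / 20)
  y3[t3 >= 18 & t3 <= 21] <- 0.5
  y3[t3 >= 43 & t3 <= 46] <- 0.5
  expect_equal(compute_w_start(new_trace(y3, 20), d3), 2.0)
})

test_that("SCR attribution window is closed-left open-right", {
  d <- toy_design(100)
  w <- window_params(4, 3)
  ev <- function(t, a = 0.2) data.frame(t_onset = t, amplitude = a)
  expect_equal(assign_scr_indicators(ev(102.9), d, w)$nSCR, 1)
  expect_equal(assign_scr_indicators(ev(103.1), d, w)$nSCR, 0)
  expect_equal(assign_scr_indicators(ev(103.0), d, w)$nSCR, 0)
  expect_equal(assign_scr_indicators(ev(96.0), d, w)$nSCR, 1)
  expect_equal(assign_scr_indicators(ev(95.9), d, w)$nSCR, 0)
  none <- assign_scr_indicators(ev(50), d, w)
  expect_equal(none$nSCR, 0)
  expect_equal(none$mSCR, 0)
  multi <- assign_scr_indicators(
    data.frame(t_onset = c(98, 99, 101), amplitude = c(0.1, 0.4, 0.2)),
    d, w)
  expect_equal(multi$nSCR, 3)
  expect_equal(multi$mSCR, 0.4)
  expect_error(assign_scr_indicators(ev(100), d, window_params(20, 10)),
               "overlap")
})

test_that("indicators are invariant to shifting the session clock", {
  d <- toy_design(c(20, 45))
  slider <- triangle_slider(c(20, 45), height = c(0.6, 0.3))
  base <- compute_sa_indicators(slider, d)
  shift <- 500
  d2 <- toy_design(c(20, 45) + shift)
  slider2 <- new_trace(slider$y, slider$rate, t0 = shift)
  shifted <- compute_sa_indicators(slider2, d2)
  expect_equal(base$mSA, shifted$mSA)
  expect_equal(base$iSA, shifted$iSA)
  ev <- data.frame(t_onset = c(19, 46), amplitude = c(0.2, 0.3))
  ev2 <- data.frame(t_onset = c(19, 46) + shift, amplitude = c(0.2, 0.3))
  w <- window_params(3, 3)
  expect_equal(assign_scr_indicators(ev, d, w)[, -1],
               assign_scr_indicators(ev2, d2, w)[, -1])
})

test_that("zero-noise traces yield the ground-truth indicators end to end", {
  d <- build_design(seed = 5)
  d$trials <- d$trials[1:8, ]
  tv <- simulate_traces(d, seed = 11, noise_sd = 0, tonic_drift = 0)
  ind <- extract_indicators(tv$slider, tv$eda, d)
  expect_equal(ind$mSA, tv$truth$mSA)
  expect_equal(ind$iSA, tv$truth$iSA, tolerance = 1e-3)
  expect_equal(ind$nSCR, tv$truth$nSCR)
  expect_equal(ind$mSCR, tv$truth$mSCR, tolerance = 0.01)
})
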