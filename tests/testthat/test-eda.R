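test_that("preprocessing preserves constants and removes impulsive spikes", {
  tr <- new_trace(rep(2.5, 625 * 30), 625)
  out <- preprocess_eda(tr)
  expect_equal(out$rate, 78)
  expect_true(all(abs(out$y - 2.5) < 1e-9))
  expect_equal(length(out$y), floor(29.9984 * 78) + 1, tolerance = 2)

  # a single-sample 10 uS spike must vanish under the 1 s median
  y <- rep(2, 625 * 30)
  y[625 * 15] <- 12
  sp <- preprocess_eda(new_trace(y, 625))
  expect_lt(max(abs(sp$y - 2)), 1e-6)

  expect_error(preprocess_eda(new_trace(rep(1, 30), 625)), "shorter")
  expect_error(preprocess_eda(new_trace(rep(1, 100), 20)), "at least")
})

test_that("a 5 Hz sinusoid is attenuated by the designed stop-band factor", {
  # input already on the 78 Hz grid and a single-sample (identity)
  # median isolate the Butterworth stage from the nonlinear steps
  rate <- 78; f <- 5
  t <- seq(0, 60, by = 1 / rate)
  tr <- new_trace(2 + 0.5 * sin(2 * pi * f * t), rate)
  out <- preprocess_eda(tr, median_s = 0.001)
  mid <- out$y[seq(10 * 78, 50 * 78)]
  gain_emp <- (max(mid) - min(mid)) / 2 / 0.5
  # zero-phase filtering applies the designed magnitude twice; evaluate
  # the transfer function H(z) = B(z)/A(z) at z = exp(i w) directly
  bf <- signal::butter(4, 1 / 39, type = "low")
  z <- exp(-1i * 2 * pi * f / 78 * (seq_along(bf$b) - 1))
  gain_design <- Mod(sum(bf$b * z) / sum(bf$a * z))^2
  expect_lt(abs(gain_emp - gain_design), 0.2 * gain_design + 1e-4)
  expect_lt(gain_emp, 1e-2)
})

test_that("decomposition is a faithful round trip with a sparse driver", {
  # tonic-only input: driver stays at numerical-residue level
  t <- seq(0, 120, by = 1 / 625)
  tonic_only <- new_trace(2 + 0.0008 * t, 625)
  dec0 <- decompose_eda(preprocess_eda(tonic_only))
  expect_lt(max(dec0$driver$mass), 0.02)

  # one injected response of amplitude a: local driver mass ~ a, tonic flat
  a <- 0.4
  tr <- synthetic_eda(60, a, dur = 120)
  dec <- decompose_eda(preprocess_eda(tr))
  near <- abs(dec$driver$t - 60) < 1
  expect_equal(sum(dec$driver$mass[near]), a, tolerance = 0.05)
  expect_lt(sum(dec$driver$mass[!near]), 0.05)
  expect_lt(diff(range(dec$tonic$y)), 0.1)

  # round trip: reconstruction error under 1% of the signal range
  expect_lt(dec$recon_rms, 0.01 * dec$signal_range)
  set.seed(8)
  tr2 <- synthetic_eda(c(20, 45, 80, 81.5), c(0.3, 0.15, 0.2, 0.4),
                       dur = 120, drift_per_s = 5e-4, noise_sd = 0.008)
  dec2 <- decompose_eda(preprocess_eda(tr2))
  expect_lt(dec2$recon_rms, 0.01 * dec2$signal_range)
})

test_that("detection applies the amplitude threshold and recovers events", {
  # amplitudes 0.3 and 0.04: only the first survives the 0.05 uS rule
  tr <- synthetic_eda(c(30, 70), c(0.3, 0.04), dur = 110)
  ev <- detect_scrs(decompose_eda(preprocess_eda(tr)))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$t_onset, 30, tolerance = 0.2)
  expect_equal(ev$amplitude, 0.3, tolerance = 0.05)

  # noise-free, well-separated events >= 0.1 uS: one-to-one recovery
  onsets <- c(15, 42, 65, 90, 118)
  amps <- c(0.1, 0.35, 0.2, 0.5, 0.12)
  ev2 <- detect_scrs(decompose_eda(preprocess_eda(
    synthetic_eda(onsets, amps, dur = 140))))
  expect_equal(nrow(ev2), length(onsets))
  expect_true(all(abs(ev2$t_onset - onsets) < 0.2))
  expect_false(is.unsorted(ev2$t_onset))

  # flat trace: empty list
  flat <- decompose_eda(preprocess_eda(new_trace(rep(2, 625 * 40), 625)))
  expect_equal(nrow(detect_scrs(flat)), 0L)
})

test_that("superimposed responses one second apart are separated", {
  tr <- synthetic_eda(c(50, 51), c(0.3, 0.25), dur = 90)
  ev <- detect_scrs(decompose_eda(preprocess_eda(tr)))
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$t_onset, c(50, 51), tolerance = 0.25)
  expect_equal(ev$amplitude, c(0.3, 0.25), tolerance = 0.06)
})

test_that("detector meets the recall and false-positive benchmark", {
  set.seed(17)
  dur <- 420
  onsets <- seq(8, dur - 12, by = 13)
  onsets <- onsets + runif(length(onsets), -3, 3)
  amps <- runif(length(onsets), 0.1, 0.6)
  tr <- synthetic_eda(onsets, amps, dur = dur, drift_per_s = 2e-4,
                      noise_sd = 0.01)
  ev <- detect_scrs(decompose_eda(preprocess_eda(tr)))
  matched <- vapply(onsets, function(x) any(abs(ev$t_onset - x) < 1),
                    logical(1))
  false_pos <- vapply(ev$t_onset, function(x) all(abs(onsets - x) > 1),
                      logical(1))
  expect_gte(mean(matched), 0.95)
  expect_lte(sum(false_pos) / nrow(ev), 0.05)
})

test_that("the Bateman response has unit peak at its mode", {
  t <- seq(0, 20, by = 1e-3)
  y <- bateman_irf(t)
  expect_equal(max(y), 1, tolerance = 1e-6)
  t_peak <- log(2 / 0.75) * 0.75 * 2 / (2 - 0.75)
  expect_equal(t[which.max(y)], t_peak, tolerance = 1e-2)
  expect_true(all(bateman_irf(c(-1, -0.01)) == 0))
})
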