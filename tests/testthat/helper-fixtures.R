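# Shared fixtures, all built in code.

# minimal hand-built session design for toy-scale window tests
toy_design <- function(t_level, ttc = rep(3, length(t_level)),
                       offset = rep(1.5, length(t_level)), spacing = 25,
                       participant_id = 1L) {
  trials <- data.frame(trial_id = seq_along(t_level), ttc = ttc,
                       offset = offset,
                       walk_dir = rep("same", length(t_level)),
                       avoid_side = rep("left", length(t_level)),
                       t_level = t_level, t_start = t_level - ttc)
  structure(list(participant_id = participant_id, trials = trials,
                 vehicle_speed = 30, pedestrian_speed = 4.5,
                 spacing = spacing, seed = 0L, levels = factor_levels()),
            class = "session_design")
}

# slider trace with triangular bumps (peak exactly at t_level)
triangle_slider <- function(t_level, height, rise = 2.5, fall = 2.5,
                            rate = 20, t_end = max(t_level) + 10) {
  t <- seq(0, t_end, by = 1 / rate)
  y <- numeric(length(t))
  for (i in seq_along(t_level)) {
    tl <- t_level[i]
    up <- t >= tl - rise & t < tl
    dn <- t >= tl & t <= tl + fall
    y[up] <- pmax(y[up], height[i] * (t[up] - (tl - rise)) / rise)
    y[dn] <- pmax(y[dn], height[i] * (1 - (t[dn] - tl) / fall))
  }
  new_trace(y, rate)
}

# synthetic EDA: flat-ish tonic + Bateman responses at known onsets
synthetic_eda <- function(onsets, amps, dur, rate = 625, tonic = 2,
                          drift_per_s = 0, noise_sd = 0) {
  t <- seq(0, dur, by = 1 / rate)
  y <- tonic + drift_per_s * t
  for (i in seq_along(onsets)) {
    idx <- which(t >= onsets[i] & t <= onsets[i] + 16)
    y[idx] <- y[idx] + amps[i] * bateman_irf(t[idx] - onsets[i])
  }
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  new_trace(y, rate)
}

# indicator-level dataset drawn from a known conditional structure on the
# modelling (standardized) scale: SA gaussian per condition cell, SCR
# Tweedie with log-link mean in SA; used for structure-recovery studies
simulate_bn_dataset <- function(n_participants = 20, seed = 1,
                                b = c(-2.45, 1.5), phi = 1.2, xi = 1.6,
                                sa_sd = 0.76, scr_on = "SA") {
  designs <- lapply(seq_len(n_participants), function(i)
    build_design(participant_id = i, seed = seed * 1000 + i))
  trials <- do.call(rbind, lapply(designs, `[[`, "trials"))
  cellz <- c(low = -0.57, mid = 0.37, high = 1.18)
  withr_seed <- seed * 13 + 7
  riskbn:::with_seed(withr_seed, {
    band <- riskbn:::sa_band(trials$ttc, trials$offset)
    sa <- rnorm(nrow(trials), cellz[band], sa_sd)
    lin <- switch(scr_on,
                  SA = b[1] + b[2] * sa,
                  TTC = b[1] + b[2] * (3.5 - trials$ttc),
                  none = rep(b[1], nrow(trials)))
    scr <- sample_tweedie(nrow(trials), exp(lin), phi, xi)
    data.frame(TTC = factor(trials$ttc), Offset = factor(trials$offset),
               SA = sa, SCR = scr)
  })
}
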