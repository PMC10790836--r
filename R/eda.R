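#' Canonical skin conductance response shape (Bateman function)
#'
#' Bi-exponential impulse response `exp(-t/tau2) - exp(-t/tau1)` for
#' `t >= 0`, normalised to unit peak so that an event of amplitude `a`
#' contributes a phasic deflection whose maximum is `a` microsiemens.
#'
#' @param t Time since response onset, seconds (vectorised; negative times
#'   give 0).
#' @param tau1 Rise time constant, seconds (default 0.75).
#' @param tau2 Decay time constant, seconds (default 2).
#' @return Response values, unit peak.
#' @export
bateman_irf <- function(t, tau1 = 0.75, tau2 = 2) {
  stopifnot(tau2 > tau1, tau1 > 0)
  t_peak <- log(tau2 / tau1) * tau1 * tau2 / (tau2 - tau1)
  peak <- exp(-t_peak / tau2) - exp(-t_peak / tau1)
  out <- ifelse(t >= 0, (exp(-t / tau2) - exp(-t / tau1)) / peak, 0)
  out
}

reflect_pad <- function(y, n) {
  n <- min(n, length(y) - 1L)
  c(rev(y[2:(n + 1L)]), y, rev(y[(length(y) - n):(length(y) - 1L)]))
}

#' Preprocess a raw electrodermal trace
#'
#' Standard conditioning chain: resampling to 78 Hz (linear interpolation),
#' a 1 s moving-median to remove impulsive artefacts, and a zero-phase
#' 4th-order Butterworth low-pass at 1 Hz. Edges are handled by reflection
#' padding.
#'
#' @param raw An `rb_trace` with `rate >= 78` Hz.
#' @param target_rate Output rate, Hz.
#' @param median_s Moving-median window, seconds.
#' @param lowpass_hz Low-pass cut-off, Hz.
#' @return An `rb_trace` at `target_rate`.
#' @export
preprocess_eda <- function(raw, target_rate = 78, median_s = 1,
                           lowpass_hz = 1) {
  stopifnot(inherits(raw, "rb_trace"))
  if (raw$rate < target_rate)
    stop("raw sampling rate must be at least the target rate")
  dur <- (length(raw$y) - 1) / raw$rate
  if (dur <= median_s)
    stop("trace shorter than the moving-median window")

  t_raw <- trace_times(raw)
  t_new <- seq(t_raw[1], t_raw[length(t_raw)], by = 1 / target_rate)
  y <- stats::approx(t_raw, raw$y, xout = t_new)$y

  k <- round(median_s * target_rate)
  if (k %% 2 == 0) k <- k + 1L
  pad <- (k - 1L) %/% 2L
  ym <- stats::runmed(reflect_pad(y, pad), k)
  ym <- ym[(pad + 1L):(pad + length(y))]

  bf <- signal::butter(4, lowpass_hz / (target_rate / 2), type = "low")
  npad <- min(length(ym) - 1L, 6L * target_rate)
  # centring removes the start-up transient of the zero-state filter
  offset <- mean(ym)
  yf <- signal::filtfilt(bf, reflect_pad(ym - offset, npad)) + offset
  yf <- yf[(npad + 1L):(npad + length(ym))]

  new_trace(yf, target_rate, t0 = t_new[1])
}

# slowly varying tonic level: rolling low quantile on a decimated grid,
# smoothed and interpolated back
estimate_tonic <- function(trace, window_s = 8, grid_hz = 2) {
  t <- trace_times(trace)
  tg <- seq(t[1], t[length(t)], by = 1 / grid_hz)
  yg <- stats::approx(t, trace$y, xout = tg)$y
  half <- round(window_s * grid_hz / 2)
  n <- length(yg)
  base <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    min(yg[lo:hi])
  }, numeric(1))
  # smooth the rolling minimum (moving average, two passes)
  k <- max(3L, 2L * half + 1L)
  sm <- base
  for (p in 1:2) {
    pad <- (k - 1L) %/% 2L
    sp <- reflect_pad(sm, pad)
    sm <- stats::filter(sp, rep(1 / k, k), sides = 2)
    sm <- as.numeric(sm[(pad + 1L):(pad + n)])
  }
  stats::approx(tg, sm, xout = t, rule = 2)$y
}

#' Decompose a preprocessed trace into tonic and phasic-driver parts
#'
#' Simplified deconvolution of the phasic component against a fixed
#' Bateman impulse response: the tonic level is estimated as a smoothed
#' rolling minimum, and the residual is inverted by non-negative least
#' squares on the discretised convolution, giving a sparse non-negative
#' driver whose point masses are response amplitudes (unit-peak IRF). The
#' driver is solved on a coarser grid (`driver_rate`) in overlapping
#' chunks, earlier chunks' contributions being subtracted before each
#' solve, which keeps the problem size linear in the trace length while
#' still separating superimposed responses.
#'
#' @param trace A preprocessed `rb_trace` (78 Hz).
#' @param tau1,tau2 Bateman time constants, seconds.
#' @param driver_rate Driver grid rate, Hz (default 10; onset resolution
#'   0.1 s).
#' @param chunk_s Chunk length for the NNLS solves, seconds.
#' @param match_preprocessing Convolve the deconvolution kernel with the
#'   same zero-phase low-pass used in preprocessing (default `TRUE`).
#'   Zero-phase filtering spreads a response's rising edge backwards in
#'   time; deconvolving against the filtered kernel removes the resulting
#'   onset bias.
#' @param lowpass_hz Cut-off of the preprocessing low-pass, Hz (used only
#'   when `match_preprocessing` is `TRUE`).
#' @return List of class `eda_decomposition`: `tonic` (`rb_trace`),
#'   `driver` (data frame `t`, `mass` on the driver grid), `phasic`
#'   (`rb_trace`, reconvolved driver), `recon_rms` (RMS reconstruction
#'   error of tonic + phasic against the input) and `signal_range`.
#' @export
decompose_eda <- function(trace, tau1 = 0.75, tau2 = 2, driver_rate = 10,
                          chunk_s = 30, match_preprocessing = TRUE,
                          lowpass_hz = 1) {
  stopifnot(inherits(trace, "rb_trace"))
  t <- trace_times(trace)
  rate <- trace$rate
  tonic <- estimate_tonic(trace)
  resid <- trace$y - tonic

  span <- 6 * tau2                       # kernel support used in the solves
  lead <- if (match_preprocessing) 1.5 else 0
  kfun <- if (match_preprocessing) {
    kt <- seq(-lead - 1, span + 1, by = 1 / rate)
    ky <- bateman_irf(kt, tau1, tau2)
    bf <- signal::butter(4, lowpass_hz / (rate / 2), type = "low")
    kyf <- signal::filtfilt(bf, c(numeric(4 * rate), ky, numeric(4 * rate)))
    kyf <- kyf[(4 * rate + 1):(4 * rate + length(ky))]
    function(dt) {
      out <- numeric(length(dt))
      ok <- dt >= kt[1] & dt <= kt[length(kt)]
      out[ok] <- stats::approx(kt, kyf, xout = dt[ok])$y
      out
    }
  } else {
    function(dt) bateman_irf(dt, tau1, tau2)
  }

  dt_d <- 1 / driver_rate
  tg <- seq(t[1], t[length(t)], by = dt_d)
  mass <- numeric(length(tg))

  ## chunked NNLS with a trailing column overlap: masses in the overlap
  ## are re-estimated by the next chunk, so boundary columns never absorb
  ## the leading edge of a response that onsets just past the chunk
  overlap <- as.integer(10 * driver_rate)
  k_start <- 1L
  while (k_start <= length(tg)) {
    k_end <- min(length(tg), k_start + as.integer(chunk_s * driver_rate) - 1L)
    c_hi <- min(length(tg), k_end + overlap)
    cols <- k_start:c_hi
    r_lo <- max(1L, floor((tg[k_start] - lead - t[1]) * rate) + 1L)
    r_hi <- min(length(t), ceiling((tg[c_hi] + span - t[1]) * rate) + 1L)
    rows <- r_lo:r_hi
    A <- outer(t[rows], tg[cols], function(ti, tj) kfun(ti - tj))
    # subtract what earlier chunks already explain in this row window
    prev <- which(mass > 0 & tg < tg[k_start])
    b <- resid[rows]
    if (length(prev)) {
      for (j in prev) {
        if (tg[j] + span < t[rows[1]]) next
        b <- b - mass[j] * kfun(t[rows] - tg[j])
      }
    }
    sol <- pracma::lsqnonneg(A, b)
    keep <- cols <= k_end
    mass[cols[keep]] <- sol$x[keep]
    k_start <- k_end + 1L
  }

  ## reconvolve the driver for the reconstruction check
  phasic <- numeric(length(t))
  nz <- which(mass > 0)
  for (j in nz) {
    idx <- which(t >= tg[j] - lead & t <= tg[j] + 10 * tau2)
    phasic[idx] <- phasic[idx] + mass[j] * kfun(t[idx] - tg[j])
  }
  recon <- tonic + phasic
  rng <- diff(range(trace$y))
  structure(list(
    tonic = new_trace(tonic, rate, t0 = trace$t0),
    driver = data.frame(t = tg, mass = mass),
    phasic = new_trace(phasic, rate, t0 = trace$t0),
    recon_rms = sqrt(mean((recon - trace$y)^2)),
    signal_range = rng,
    tau1 = tau1, tau2 = tau2
  ), class = "eda_decomposition")
}

#' Detect skin conductance responses in a phasic driver
#'
#' Driver masses below `floor` are discarded as reconstruction residue;
#' the remaining point masses are clustered (gaps below `gap_s` merge into
#' one response, so responses whose onsets differ by 1 s or more stay
#' separate), and each cluster becomes one candidate SCR with onset at its
#' first mass. The amplitude is either the cluster's total driver mass
#' (default; equals the peak deflection of an isolated response under the
#' unit-peak IRF) or the peak of the reconvolved cluster. Only responses
#' with amplitude strictly above `threshold` (0.05 microsiemens) are
#' retained.
#'
#' @param decomposition An [decompose_eda()] result, or a data frame with
#'   columns `t`, `mass`.
#' @param threshold Retention threshold, microsiemens.
#' @param floor Driver mass below which a grid point is treated as zero.
#' @param gap_s Merge gap, seconds.
#' @param amplitude Amplitude definition: `"mass"` or `"peak"`.
#' @return Data frame of class `scr_events` with `t_onset`, `amplitude`,
#'   sorted by onset.
#' @export
detect_scrs <- function(decomposition, threshold = 0.05, floor = 0.005,
                        gap_s = 0.4, amplitude = c("mass", "peak")) {
  amplitude <- match.arg(amplitude)
  drv <- if (inherits(decomposition, "eda_decomposition"))
    decomposition$driver else decomposition
  stopifnot(is.data.frame(drv), all(c("t", "mass") %in% names(drv)))
  tau1 <- if (inherits(decomposition, "eda_decomposition"))
    decomposition$tau1 else 0.75
  tau2 <- if (inherits(decomposition, "eda_decomposition"))
    decomposition$tau2 else 2

  keep <- which(drv$mass > floor)
  empty <- data.frame(t_onset = numeric(), amplitude = numeric())
  class(empty) <- c("scr_events", "data.frame")
  if (!length(keep)) return(empty)

  tt <- drv$t[keep]; mm <- drv$mass[keep]
  cluster <- cumsum(c(1, diff(tt) > gap_s))
  # onset: mass-weighted time of the cluster's leading masses (the NNLS
  # solution brackets a continuous onset with neighbouring grid points)
  onsets <- vapply(split(seq_along(tt), cluster), function(ix) {
    lead <- ix[tt[ix] <= tt[ix[1]] + 0.6]
    sum(tt[lead] * mm[lead]) / sum(mm[lead])
  }, numeric(1))
  amps <- if (amplitude == "mass") {
    tapply(mm, cluster, sum)
  } else {
    vapply(split(seq_along(tt), cluster), function(ix) {
      tfine <- seq(min(tt[ix]), max(tt[ix]) + 6 * tau2, by = 0.02)
      max(colSums(mm[ix] * t(outer(tfine, tt[ix], function(a, b)
        bateman_irf(a - b, tau1, tau2)))))
    }, numeric(1))
  }
  sel <- amps > threshold
  out <- data.frame(t_onset = as.numeric(onsets[sel]),
                    amplitude = as.numeric(amps[sel]))
  out <- out[order(out$t_onset), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("scr_events", "data.frame")
  out
}
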