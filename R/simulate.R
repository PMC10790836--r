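#' Generative ground truth for the synthetic study
#'
#' Encodes the generative counterpart of the dependency structure the
#' analysis is designed to recover: subjective assessment (SA) is Gaussian
#' around condition-cell means following a low/mid/high pattern (risk low
#' when TTC >= 3 s and offset >= 1 m, moderate when TTC = 2.5 s or offset
#' = 0.5 m, high when TTC = 2 s); the number of skin conductance responses
#' follows a Tweedie compound-Poisson law whose mean is exponential in the
#' trial's SA (log link); and the maximum SCR amplitude is the largest of
#' the manoeuvre's per-event amplitudes, whose mean decreases with TTC.
#'
#' The default link coefficients were set, via the closed-form Tweedie
#' zero mass, so that the probability of a manoeuvre eliciting no response
#' spans roughly 0.6 (calm trials) to 0.1 (critical trials) and the overall
#' share of exact zeros is close to 46 percent.
#'
#' @param levels A [factor_levels()] object.
#' @param sa_scr_link If `FALSE`, the SA -> SCR-count link slope is zeroed
#'   and the intercept re-set so the marginal zero share is preserved
#'   (independence null for structure-recovery studies).
#' @param sa_sigma Within-cell SD of SA (slider units).
#' @param scr_dispersion,scr_index Tweedie dispersion and index parameter
#'   shared by the SCR indicators.
#' @return An object of class `ground_truth`.
#' @export
make_ground_truth <- function(levels = factor_levels(), sa_scr_link = TRUE,
                              sa_sigma = 0.15, scr_dispersion = 1.2,
                              scr_index = 1.6) {
  freqs <- condition_frequencies(levels)
  band <- sa_band(freqs$ttc, freqs$offset)
  means <- c(low = 0.25, mid = 0.45, high = 0.70)[band]
  names(means) <- paste(freqs$ttc, freqs$offset, sep = "_")

  if (sa_scr_link) {
    link <- c(b0 = -5.66, b1 = 8.3)
  } else {
    # constant mean chosen to keep the marginal zero share near 46%
    link <- c(b0 = -2.47, b1 = 0)
  }
  mscr <- stats::setNames(seq(0.5, 0.2, length.out = length(levels$ttc)),
                          as.character(levels$ttc))

  structure(list(
    sa_cell_means = means, sa_sigma = sa_sigma,
    isa_scale = 2.5,               # area of the slider bump per unit peak
    isa_width_cv = 0.2,            # trial-to-trial bump-width variability
    scr_link_coeffs = link,
    scr_dispersion = scr_dispersion, scr_index = scr_index,
    mscr_ttc_means = mscr,
    levels = levels
  ), class = "ground_truth")
}

# low/mid/high band of a condition (vectorised)
sa_band <- function(ttc, offset) {
  ifelse(ttc <= 2.0, "high",
         ifelse(ttc >= 3.0 & offset >= 1.0, "low", "mid"))
}

gt_sa_mean <- function(gt, ttc, offset) {
  unname(gt$sa_cell_means[paste(ttc, offset, sep = "_")])
}

#' Simulate indicator-level data for one or more sessions
#'
#' Fast path that skips the signal level: per manoeuvre it draws the raw
#' subjective indicators (mSA Gaussian in its condition cell, iSA a scaled
#' copy with proportional noise) and the SCR indicators from one shared
#' latent event count per manoeuvre — `N ~ Poisson` with the rate implied
#' by the trial's mSA through the log link, `nSCR` the matching gamma
#' compound sum (so it is marginally Tweedie), and `mSCR` the maximum of
#' `N` per-event amplitudes whose mean decreases with TTC. Sharing `N`
#' enforces the extraction identity that a manoeuvre with no responses
#' has both indicators exactly zero (`nSCR = 0` iff `mSCR = 0`).
#'
#' @param designs A `session_design` or list of them.
#' @param gt A [make_ground_truth()] object.
#' @param seed Integer seed; the table is reproducible given the seed.
#' @return Data frame with one row per participant x trial: `participant_id`,
#'   `trial_id`, `ttc`, `offset`, `mSA`, `iSA`, `nSCR`, `mSCR`.
#' @export
simulate_indicators <- function(designs, gt = make_ground_truth(),
                                seed = 1L) {
  stopifnot(inherits(gt, "ground_truth"))
  if (inherits(designs, "session_design")) designs <- list(designs)
  with_seed(seed, {
    out <- lapply(designs, function(d) {
      tr <- d$trials
      m <- gt_sa_mean(gt, tr$ttc, tr$offset)
      mSA <- pmax(stats::rnorm(nrow(tr), m, gt$sa_sigma), 0)
      # iSA shares the trial's slider curve with mSA: area = peak times
      # bump width, whose trial-to-trial variability is isa_width_cv
      width <- pmax(stats::rnorm(nrow(tr), 1, gt$isa_width_cv), 0.2)
      iSA <- gt$isa_scale * mSA * width
      mu_n <- exp(gt$scr_link_coeffs[["b0"]] +
                    gt$scr_link_coeffs[["b1"]] * mSA)
      xi <- gt$scr_index; phi <- gt$scr_dispersion
      alpha <- (2 - xi) / (xi - 1)
      lam <- tweedie_lambda(mu_n, phi, xi)
      N <- stats::rpois(nrow(tr), lam)
      # nSCR: gamma compound sum given N (marginally Tweedie)
      tau_n <- phi * (xi - 1) * mu_n^(xi - 1)
      nSCR <- numeric(nrow(tr))
      pos <- N > 0
      nSCR[pos] <- stats::rgamma(sum(pos), shape = N[pos] * alpha,
                                 scale = tau_n[pos])
      # mSCR: maximum of N per-event amplitudes, mean set by TTC
      mu_amp <- unname(gt$mscr_ttc_means[as.character(tr$ttc)])
      mSCR <- numeric(nrow(tr))
      for (i in which(pos))
        mSCR[i] <- max(stats::rgamma(N[i], shape = alpha,
                                     scale = mu_amp[i] / alpha))
      data.frame(participant_id = d$participant_id,
                 trial_id = tr$trial_id, ttc = tr$ttc, offset = tr$offset,
                 mSA = mSA, iSA = iSA, nSCR = nSCR, mSCR = mSCR)
    })
    do.call(rbind, out)
  })
}

#' Simulate slider and electrodermal traces for one session
#'
#' Signal-level twin of [simulate_indicators()]. The 20 Hz slider trace is
#' zero between manoeuvres and carries one piecewise-linear bump per
#' manoeuvre whose peak equals the trial's ground-truth mSA, rising from
#' `rise` seconds before `t_level` and returning to zero `fall` seconds
#' after it (so the true iSA is `peak * (rise + fall) / 2`). The
#' electrodermal trace at `eda_rate` Hz is a slowly varying tonic level
#' plus one canonical Bateman response per SCR event plus white noise;
#' event counts per manoeuvre are Poisson with the ground-truth rate
#' implied by the trial's mSA, and event amplitudes are the matching gamma
#' summands of the compound-Poisson law.
#'
#' @param design A `session_design`.
#' @param gt A [make_ground_truth()] object.
#' @param seed Integer seed.
#' @param slider_rate,eda_rate Sampling rates in Hz (20 and 625).
#' @param rise,fall Slider bump rise/fall durations, seconds.
#' @param tau1,tau2 Bateman IRF time constants, seconds.
#' @param tonic_base Baseline skin conductance level, microsiemens.
#' @param tonic_drift Tonic random-walk amplitude, microsiemens per minute.
#' @param noise_sd SD of additive white measurement noise, microsiemens.
#' @param amp_threshold Amplitude above which an injected event counts
#'   towards the ground-truth nSCR/mSCR (matches the detector threshold).
#' @return List with `slider` and `eda` (`rb_trace`), `events` (data frame
#'   `trial_id`, `t_onset`, `amplitude`), and `truth` (per-trial
#'   ground-truth indicators `mSA`, `iSA`, `nSCR`, `mSCR`).
#' @export
simulate_traces <- function(design, gt = make_ground_truth(), seed = 1L,
                            slider_rate = 20, eda_rate = 625,
                            rise = 3, fall = 2, tau1 = 0.75, tau2 = 2,
                            tonic_base = 2, tonic_drift = 0.05,
                            noise_sd = 0.005, amp_threshold = 0.05) {
  stopifnot(inherits(design, "session_design"))
  tr <- design$trials
  if (any(diff(tr$t_level) < rise + fall + 1))
    stop("trials overlap: slider bumps would merge")
  t_end <- max(tr$t_level) + 15

  with_seed(seed, {
    m <- gt_sa_mean(gt, tr$ttc, tr$offset)
    mSA <- pmax(stats::rnorm(nrow(tr), m, gt$sa_sigma), 0)
    iSA <- mSA * (rise + fall) / 2

    ## slider: piecewise-linear bump per manoeuvre
    ts <- seq(0, t_end, by = 1 / slider_rate)
    ys <- numeric(length(ts))
    for (i in seq_len(nrow(tr))) {
      tl <- tr$t_level[i]
      up <- ts >= tl - rise & ts < tl
      dn <- ts >= tl & ts <= tl + fall
      ys[up] <- pmax(ys[up], mSA[i] * (ts[up] - (tl - rise)) / rise)
      ys[dn] <- pmax(ys[dn], mSA[i] * (1 - (ts[dn] - tl) / fall))
    }
    slider <- new_trace(ys, slider_rate)

    ## SCR events: compound-Poisson occurrences inside each trial window
    lam <- tweedie_lambda(exp(gt$scr_link_coeffs[["b0"]] +
                                gt$scr_link_coeffs[["b1"]] * mSA),
                          gt$scr_dispersion, gt$scr_index)
    alpha <- (2 - gt$scr_index) / (gt$scr_index - 1)
    ev <- list()
    for (i in seq_len(nrow(tr))) {
      k <- stats::rpois(1, lam[i])
      if (k == 0) next
      k <- min(k, 4L)  # bounded so 1.2 s spacing fits the event window
      mu_i <- exp(gt$scr_link_coeffs[["b0"]] +
                    gt$scr_link_coeffs[["b1"]] * mSA[i])
      tau_g <- gt$scr_dispersion * (gt$scr_index - 1) *
        mu_i^(gt$scr_index - 1)
      amp <- stats::rgamma(k, shape = alpha, scale = tau_g)
      # onsets inside [-2.5, 2.3] s around t_level with >= 1.2 s separation
      gaps <- if (k > 1) stats::runif(k - 1, 1.2, 1.6) else numeric()
      start <- stats::runif(1, -2.5, 2.3 - sum(gaps))
      base <- start + c(0, cumsum(gaps))
      ev[[i]] <- data.frame(trial_id = tr$trial_id[i],
                            t_onset = tr$t_level[i] + base,
                            amplitude = amp)
    }
    events <- if (length(ev)) do.call(rbind, ev) else
      data.frame(trial_id = integer(), t_onset = numeric(),
                 amplitude = numeric())
    rownames(events) <- NULL

    ## EDA = tonic + phasic + noise at eda_rate
    te <- seq(0, t_end, by = 1 / eda_rate)
    step_sd <- tonic_drift / sqrt(60 * eda_rate)
    tonic <- tonic_base + cumsum(stats::rnorm(length(te), 0, step_sd))
    phasic <- numeric(length(te))
    if (nrow(events)) {
      for (i in seq_len(nrow(events))) {
        idx <- which(te >= events$t_onset[i] &
                       te <= events$t_onset[i] + 8 * tau2)
        phasic[idx] <- phasic[idx] +
          events$amplitude[i] * bateman_irf(te[idx] - events$t_onset[i],
                                            tau1, tau2)
      }
    }
    noise <- if (noise_sd > 0) stats::rnorm(length(te), 0, noise_sd) else 0
    eda <- new_trace(tonic + phasic + noise, eda_rate)

    ## ground-truth indicators (events below the detector threshold do not
    ## count, mirroring the retained-SCR rule)
    nSCR <- mSCR <- numeric(nrow(tr))
    for (i in seq_len(nrow(tr))) {
      e <- events[events$trial_id == tr$trial_id[i] &
                    events$amplitude > amp_threshold, , drop = FALSE]
      nSCR[i] <- nrow(e)
      mSCR[i] <- if (nrow(e)) max(e$amplitude) else 0
    }
    truth <- data.frame(participant_id = design$participant_id,
                        trial_id = tr$trial_id, ttc = tr$ttc,
                        offset = tr$offset, mSA = mSA, iSA = iSA,
                        nSCR = nSCR, mSCR = mSCR)

    list(slider = slider, eda = eda, events = events, truth = truth)
  })
}
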