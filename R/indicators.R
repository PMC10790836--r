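#' Window parameters for SCR attribution
#'
#' An SCR is attributed to a manoeuvre when its onset falls no more than
#' `w_start` seconds before the moment the vehicle is level with the
#' pedestrian and no more than `w_end` seconds after it. `w_start` is a
#' per-participant quantity (mean anticipation of the slider response);
#' `w_end` defaults to the literature value of 3 s.
#'
#' @param w_start Seconds before `t_level` (>= 0).
#' @param w_end Seconds after `t_level` (> 0), default 3.
#' @return A list of class `window_params`.
#' @export
window_params <- function(w_start, w_end = 3) {
  stopifnot(is.numeric(w_start), w_start >= 0, w_end > 0)
  structure(list(w_start = w_start, w_end = w_end),
            class = "window_params")
}

# per-trial slider windows: the interval between the returns-to-zero
# bracketing t_level, bounded by the midpoints towards neighbour trials
slider_windows <- function(slider, design, eps = 1e-6) {
  t <- trace_times(slider)
  y <- slider$y
  tl <- design$trials$t_level
  half <- design$spacing / 2
  lapply(seq_along(tl), function(i) {
    lo_t <- max(t[1], tl[i] - half)
    hi_t <- min(t[length(t)], tl[i] + half)
    idx <- which(t >= lo_t & t <= hi_t)
    pos <- y[idx] > eps
    if (!any(pos)) return(integer())
    # contract to the positive run bracketing t_level (nearest zeros)
    i_lvl <- idx[which.min(abs(t[idx] - tl[i]))]
    rel <- i_lvl - idx[1] + 1L
    if (!pos[rel]) {
      # t_level itself at zero: take the positive run closest to it
      runs <- rle(pos)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      cand <- which(runs$values)
      pickd <- vapply(cand, function(r)
        min(abs(c(starts[r], ends[r]) - rel)), numeric(1))
      r <- cand[which.min(pickd)]
      return(idx[starts[r]:ends[r]])
    }
    lo <- rel; while (lo > 1L && pos[lo - 1L]) lo <- lo - 1L
    hi <- rel; while (hi < length(pos) && pos[hi + 1L]) hi <- hi + 1L
    if (lo == 1L || hi == length(pos))
      warning("slider window not bounded by zeros; midpoint split used")
    # include the bracketing zero samples so the area integral closes
    lo <- max(1L, lo - 1L); hi <- min(length(pos), hi + 1L)
    idx[lo:hi]
  })
}

#' Subjective-assessment indicators per manoeuvre
#'
#' For each manoeuvre, `mSA` is the maximum slider value inside the
#' manoeuvre's window (the positive excursion bracketing `t_level`) and
#' `iSA` is the trapezoidal integral of the slider over that window — the
#' area under the curve. Both are 0 for silent manoeuvres.
#'
#' @param slider A 20 Hz `rb_trace` of the hand-slider signal.
#' @param design The matching `session_design`.
#' @param eps Strict-positivity guard (fraction of full scale).
#' @return Data frame `trial_id`, `mSA`, `iSA`.
#' @export
compute_sa_indicators <- function(slider, design, eps = 1e-6) {
  stopifnot(inherits(slider, "rb_trace"), inherits(design, "session_design"))
  t <- trace_times(slider)
  wins <- slider_windows(slider, design, eps)
  res <- t(vapply(wins, function(idx) {
    if (!length(idx)) return(c(0, 0))
    yy <- slider$y[idx]; tt <- t[idx]
    isa <- if (length(idx) > 1L)
      sum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2) else 0
    c(max(yy), isa)
  }, numeric(2)))
  data.frame(trial_id = design$trials$trial_id,
             mSA = res[, 1], iSA = res[, 2])
}

#' Per-participant anticipation window `w_start`
#'
#' For every manoeuvre with a non-zero slider response, the delay between
#' the first strictly positive slider sample and the moment the vehicle is
#' level with the pedestrian is recorded; `w_start` is the mean of those
#' delays. Silent manoeuvres carry no defined delay and are excluded from
#' the mean.
#'
#' @inheritParams compute_sa_indicators
#' @return `w_start` in seconds.
#' @export
compute_w_start <- function(slider, design, eps = 1e-6) {
  stopifnot(inherits(slider, "rb_trace"), inherits(design, "session_design"))
  t <- trace_times(slider)
  wins <- slider_windows(slider, design, eps)
  tl <- design$trials$t_level
  deltas <- vapply(seq_along(wins), function(i) {
    idx <- wins[[i]]
    if (!length(idx)) return(NA_real_)
    first_pos <- idx[slider$y[idx] > eps][1]
    tl[i] - t[first_pos]
  }, numeric(1))
  deltas <- deltas[!is.na(deltas)]
  if (!length(deltas))
    stop("w_start undefined: no manoeuvre has a positive slider response")
  mean(deltas)
}

#' Windowed SCR indicators per manoeuvre
#'
#' Counts and summarises the detected SCRs attributable to each manoeuvre:
#' an event belongs to a manoeuvre when its onset lies in
#' `[t_level - w_start, t_level + w_end)` (closed left, open right).
#' `nSCR` is the event count, `mSCR` the maximum amplitude among them (0
#' when none).
#'
#' @param events A data frame of detected events (`t_onset`, `amplitude`).
#' @param design The `session_design`.
#' @param w A [window_params()] object.
#' @return Data frame `trial_id`, `nSCR`, `mSCR`.
#' @export
assign_scr_indicators <- function(events, design, w) {
  stopifnot(inherits(design, "session_design"), inherits(w, "window_params"))
  tl <- design$trials$t_level
  if (w$w_start + w$w_end > design$spacing)
    stop("attribution windows of adjacent trials overlap")
  res <- t(vapply(tl, function(x) {
    sel <- events$t_onset >= x - w$w_start & events$t_onset < x + w$w_end
    if (!any(sel)) c(0, 0) else c(sum(sel), max(events$amplitude[sel]))
  }, numeric(2)))
  data.frame(trial_id = design$trials$trial_id,
             nSCR = res[, 1], mSCR = res[, 2])
}

#' End-to-end indicator extraction for one session
#'
#' Runs the full signal path: SA indicators and `w_start` from the slider,
#' EDA preprocessing, tonic/phasic decomposition, SCR detection, and
#' windowed SCR attribution.
#'
#' @param slider,eda `rb_trace` signals of one session (20 Hz slider, raw
#'   EDA at 625 Hz or already preprocessed at 78 Hz).
#' @param design The `session_design`.
#' @param w_end Attribution window after `t_level`, seconds.
#' @param threshold SCR retention threshold, microsiemens.
#' @param ... Passed to [decompose_eda()].
#' @return Data frame with one row per trial: `participant_id`,
#'   `trial_id`, `ttc`, `offset`, `mSA`, `iSA`, `nSCR`, `mSCR`; the
#'   participant's `w_start` is attached as an attribute.
#' @export
extract_indicators <- function(slider, eda, design, w_end = 3,
                               threshold = 0.05, ...) {
  sa <- compute_sa_indicators(slider, design)
  ws <- compute_w_start(slider, design)
  pre <- if (eda$rate > 100) preprocess_eda(eda) else eda
  dec <- decompose_eda(pre, ...)
  ev <- detect_scrs(dec, threshold = threshold)
  scr <- assign_scr_indicators(ev, design, window_params(ws, w_end))
  out <- data.frame(participant_id = design$participant_id,
                    trial_id = design$trials$trial_id,
                    ttc = design$trials$ttc,
                    offset = design$trials$offset,
                    mSA = sa$mSA, iSA = sa$iSA,
                    nSCR = scr$nSCR, mSCR = scr$mSCR)
  attr(out, "w_start") <- ws
  out
}
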