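#' Factor levels of the avoidance-manoeuvre design
#'
#' The within-subject design manipulates the time-to-collision (TTC) at
#' manoeuvre onset and the lateral offset left between the vehicle and the
#' pedestrian at the closest passing point.
#'
#' @param ttc TTC levels in seconds, strictly increasing.
#' @param offset Lateral offset levels in metres, strictly increasing.
#' @return A list of class `factor_levels`.
#' @export
factor_levels <- function(ttc = c(2.0, 2.5, 3.0, 3.5),
                          offset = c(0.5, 1.0, 1.5)) {
  stopifnot(length(ttc) >= 1, length(offset) >= 1,
            !is.unsorted(ttc, strictly = TRUE),
            !is.unsorted(offset, strictly = TRUE))
  structure(list(ttc = ttc, offset = offset), class = "factor_levels")
}

#' Condition frequencies of the experimental plan
#'
#' Only 8 of the 12 (TTC, offset) combinations are run: the full offset
#' 1.5 m row at frequency 1/8 each, and offsets 1.0 m and 0.5 m only at
#' TTC 3.0 and 3.5 s (1/8 each). The offset 1.5 m row therefore carries
#' half of all trials.
#'
#' @param levels A [factor_levels()] object.
#' @return A data frame with columns `ttc`, `offset`, `freq` (8 rows,
#'   frequencies summing to 1).
#' @export
condition_frequencies <- function(levels = factor_levels()) {
  stopifnot(inherits(levels, "factor_levels"))
  grid <- expand.grid(ttc = levels$ttc, offset = levels$offset,
                      KEEP.OUT.ATTRS = FALSE)
  # offset rows below the maximum are restricted to the two largest TTCs
  top2 <- sort(levels$ttc, decreasing = TRUE)[1:2]
  keep <- grid$offset == max(levels$offset) | grid$ttc %in% top2
  grid <- grid[keep, , drop = FALSE]
  grid$freq <- 1 / nrow(grid)
  rownames(grid) <- NULL
  grid
}

#' Marginal frequencies of one factor
#' @param freqs A condition-frequency table from [condition_frequencies()].
#' @param factor One of `"ttc"`, `"offset"`.
#' @return Named numeric vector of marginal frequencies.
#' @export
marginal_frequencies <- function(freqs, factor = c("ttc", "offset")) {
  factor <- match.arg(factor)
  tapply(freqs$freq, freqs[[factor]], sum)
}

#' Build one participant's session design
#'
#' Lays out the 32 pedestrian-avoidance manoeuvres of a session: condition
#' counts follow the plan frequencies exactly (frequency times 32), the
#' pedestrian walking direction is balanced 16/16, the avoidance side is
#' balanced, and the trial order is randomised by `seed`. Pedestrians are
#' spaced 25 s apart on the session clock; the vehicle is level with the
#' pedestrian (`t_level`) TTC seconds after manoeuvre onset (`t_start`).
#'
#' @param levels A [factor_levels()] object.
#' @param participant_id Integer participant identifier.
#' @param seed Integer seed; the layout is deterministic given the seed.
#' @param n_trials Number of manoeuvres per session (32).
#' @param spacing Seconds between consecutive pedestrians (25).
#' @param t_first Session time of the first `t_level`, seconds.
#' @param vehicle_speed,pedestrian_speed Speeds in kph (30 and 4.5);
#'   recorded as metadata.
#' @return An object of class `session_design`: a list with
#'   `participant_id`, a `trials` data frame (`trial_id`, `ttc`, `offset`,
#'   `walk_dir`, `avoid_side`, `t_start`, `t_level`), the speeds, `spacing`
#'   and `seed`.
#' @export
build_design <- function(levels = factor_levels(), participant_id = 1L,
                         seed = 1L, n_trials = 32L, spacing = 25,
                         t_first = 20, vehicle_speed = 30,
                         pedestrian_speed = 4.5) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  freqs <- condition_frequencies(levels)
  if (abs(sum(freqs$freq) - 1) > 1e-12)
    stop("condition frequencies must sum to 1")
  counts <- freqs$freq * n_trials
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("n_trials is not compatible with the condition frequencies")
  counts <- as.integer(round(counts))

  conditions <- freqs[rep(seq_len(nrow(freqs)), counts), c("ttc", "offset")]
  walk <- rep(c("same", "opposite"), length.out = n_trials)
  avoid <- rep(c("left", "right"), length.out = n_trials)

  trials <- with_seed(seed, {
    ord <- sample.int(n_trials)
    data.frame(
      trial_id = seq_len(n_trials),
      ttc = conditions$ttc[ord],
      offset = conditions$offset[ord],
      walk_dir = sample(walk),
      avoid_side = sample(avoid),
      stringsAsFactors = FALSE
    )
  })
  trials$t_level <- t_first + (trials$trial_id - 1L) * spacing
  trials$t_start <- trials$t_level - trials$ttc

  structure(list(participant_id = participant_id, trials = trials,
                 vehicle_speed = vehicle_speed,
                 pedestrian_speed = pedestrian_speed,
                 spacing = spacing, seed = seed, levels = levels),
            class = "session_design")
}

#' @export
print.session_design <- function(x, ...) {
  cat(sprintf("<session_design> participant %s: %d trials, spacing %g s\n",
              x$participant_id, nrow(x$trials), x$spacing))
  print(table(ttc = x$trials$ttc, offset = x$trials$offset))
  invisible(x)
}

#' Write a session design to CSV
#' @param design A `session_design`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path) {
  stopifnot(inherits(design, "session_design"))
  d <- design$trials
  out <- data.frame(participant_id = design$participant_id,
                    trial_id = d$trial_id, ttc_s = d$ttc,
                    offset_m = d$offset, walk_dir = d$walk_dir,
                    avoid_side = d$avoid_side, t_start_s = d$t_start,
                    t_level_s = d$t_level)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
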