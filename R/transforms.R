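#' Power transform of a non-negative indicator
#'
#' Elementwise `x^exponent` with `exponent` in (0, 1]; monotone, fixes 0
#' and 1, and compresses the right tail (a square root for `mSA`, a cube
#' root for `iSA` in the standard pipeline).
#'
#' @param x Non-negative values.
#' @param exponent Exponent in (0, 1].
#' @return Transformed values.
#' @export
power_transform <- function(x, exponent) {
  if (any(x < 0, na.rm = TRUE)) stop("power_transform requires x >= 0")
  stopifnot(exponent > 0, exponent <= 1)
  x^exponent
}

#' Standardize values within participant
#'
#' With `center = TRUE` each participant's values are centred and scaled
#' to unit unbiased SD (used for the subjective indicators). With
#' `center = FALSE` values are only divided by the participant's unbiased
#' SD, so exact zeros stay exactly zero — required for the SCR indicators,
#' whose zero mass the Tweedie node models.
#'
#' @param x Numeric values.
#' @param participant Participant identifier, same length as `x`.
#' @param center Centre as well as scale?
#' @return Standardized values in the original order.
#' @note With 20 participants of 32 values each, the centred pipeline
#'   forces the pooled unbiased SD of all 640 values to
#'   `sqrt(620/639) = 0.98506` regardless of the input data.
#' @export
standardize_by_participant <- function(x, participant, center = TRUE) {
  stopifnot(length(x) == length(participant))
  out <- numeric(length(x))
  for (p in unique(participant)) {
    idx <- participant == p
    v <- x[idx]
    if (length(v) < 2L)
      stop(sprintf("participant %s has fewer than 2 values", p))
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      stop(sprintf("participant %s has zero within-participant variance", p))
    out[idx] <- if (center) (v - mean(v)) / s else v / s
  }
  out
}

#' Adjusted Fisher-Pearson sample skewness
#'
#' `g1 * sqrt(n * (n - 1)) / (n - 2)` where `g1 = m3 / m2^(3/2)` with
#' central sample moments `m2`, `m3`.
#'
#' @param x Numeric sample, `n >= 3`.
#' @return Skewness coefficient.
#' @export
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3L) stop("skewness requires at least 3 values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  g1 <- m3 / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Shapiro-Wilk normality check
#'
#' @param x Numeric sample, `3 <= n <= 5000`.
#' @return List with the `W` statistic and `p` value.
#' @export
normality_check <- function(x) {
  if (length(x) < 3L || length(x) > 5000L)
    stop("Shapiro-Wilk test requires 3 <= n <= 5000")
  s <- stats::shapiro.test(x)
  list(W = unname(s$statistic), p = s$p.value)
}

#' Default normalization settings
#'
#' @return List of class `transform_params`: power exponents per
#'   subjective indicator (1/2 for `mSA`, 1/3 for `iSA`), centring flags
#'   (subjective indicators are centred and scaled; SCR indicators are
#'   scaled only, preserving their zero mass).
#' @export
transform_params <- function(sa_exponents = c(mSA = 1 / 2, iSA = 1 / 3),
                             center_sa = TRUE, center_scr = FALSE) {
  stopifnot(all(sa_exponents > 0), all(sa_exponents <= 1))
  structure(list(sa_exponents = sa_exponents, center_sa = center_sa,
                 center_scr = center_scr), class = "transform_params")
}

#' Normalize an indicator table for modelling
#'
#' Applies the full pipeline: power transforms to the subjective
#' indicators, then per-participant centring and scaling; SCR indicators
#' are scaled per participant without centring. Transformed columns are
#' appended with a `_t` suffix.
#'
#' @param indicators Data frame with `participant_id`, `mSA`, `iSA`,
#'   `nSCR`, `mSCR`.
#' @param params A [transform_params()] object.
#' @return The input with `mSA_t`, `iSA_t`, `nSCR_t`, `mSCR_t` appended.
#' @export
transform_indicators <- function(indicators, params = transform_params()) {
  stopifnot(inherits(params, "transform_params"),
            all(c("participant_id", "mSA", "iSA", "nSCR", "mSCR") %in%
                  names(indicators)))
  pid <- indicators$participant_id
  for (v in c("mSA", "iSA")) {
    tv <- power_transform(indicators[[v]], params$sa_exponents[[v]])
    indicators[[paste0(v, "_t")]] <-
      standardize_by_participant(tv, pid, center = params$center_sa)
  }
  for (v in c("nSCR", "mSCR")) {
    indicators[[paste0(v, "_t")]] <-
      standardize_by_participant(indicators[[v]], pid,
                                 center = params$center_scr)
  }
  indicators
}
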