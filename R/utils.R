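#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded at `seed`,
#' then restores the previous RNG state so that callers never perturb the
#' session stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# numerically stable log(sum(exp(x))) along matrix rows
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Uniformly sampled signal trace
#'
#' Light container for a uniformly sampled physiological or slider signal.
#'
#' @param y Numeric vector of samples.
#' @param rate Sampling rate in Hz.
#' @param t0 Time of the first sample, seconds (session clock).
#' @return An object of class `rb_trace` with elements `y`, `rate`, `t0`.
#' @export
new_trace <- function(y, rate, t0 = 0) {
  stopifnot(is.numeric(y), all(is.finite(y)), rate > 0)
  structure(list(y = as.numeric(y), rate = rate, t0 = t0), class = "rb_trace")
}

#' @export
print.rb_trace <- function(x, ...) {
  cat(sprintf("<rb_trace> %d samples @ %.5g Hz, t = [%.2f, %.2f] s\n",
              length(x$y), x$rate, x$t0, x$t0 + (length(x$y) - 1) / x$rate))
  invisible(x)
}

#' Time stamps of a trace
#' @param x An `rb_trace`.
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "rb_trace"))
  x$t0 + seq_along(x$y) / x$rate - 1 / x$rate
}

#' @export
as.data.frame.rb_trace <- function(x, ...) {
  data.frame(time_s = trace_times(x), value = x$y)
}
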