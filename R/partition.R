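#' Enumerate all set partitions of k elements
#'
#' Generates every partition via restricted growth strings; the count is
#' the k-th Bell number (1, 1, 2, 5, 15, 52, 203, 877, 4140 for k = 0..8).
#'
#' @param k Number of elements (1 to 12).
#' @return List of integer block-assignment vectors (blocks numbered by
#'   first appearance).
#' @export
enumerate_partitions <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > 12L)
    stop("k must be an integer between 1 and 12")
  k <- as.integer(k)
  out <- vector("list", 0L)
  recurse <- function(prefix, mx) {
    pos <- length(prefix) + 1L
    if (pos > k) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (b in seq_len(mx + 1L)) recurse(c(prefix, b), max(mx, b))
  }
  recurse(integer(), 0L)
  out
}

#' Score one condition partition
#'
#' Gaussian block model: one mean per block and, by default, one SD per
#' block (`n_params = 2 * blocks`), so that a grouping claims the
#' conditions in a block share a full distribution, not just a location.
#' A pooled single SD across blocks (`n_params = blocks + 1`) is
#' available via `pooled_sd = TRUE`. All scale estimates are maximum
#' likelihood and the BIC is `-2 loglik + n_params * log(n)`.
#'
#' @param assignment Integer block assignment over the conditions (one
#'   entry per condition, matching `sort(unique(condition))`), as produced
#'   by [enumerate_partitions()].
#' @param values Numeric observations.
#' @param condition Condition label per observation.
#' @param pooled_sd Share one SD across blocks instead of one per block.
#' @return List of class `condition_partition`: `assignment`, `blocks`
#'   (condition labels per block), `block_means`, `sd`, `loglik`,
#'   `n_params`, `bic`, `n`.
#' @export
score_partition <- function(assignment, values, condition,
                            pooled_sd = FALSE) {
  lev <- sort(unique(condition))
  if (length(assignment) != length(lev))
    stop("assignment length must equal the number of conditions")
  if (any(tabulate(match(condition, lev)) < 2L))
    stop("every condition needs at least 2 observations")
  block <- assignment[match(condition, lev)]
  nb <- max(assignment)
  if (!setequal(unique(assignment), seq_len(nb)))
    stop("empty block in partition assignment")

  means <- tapply(values, block, mean)
  mu <- as.numeric(means[as.character(block)])
  n <- length(values)
  if (pooled_sd) {
    sig <- sqrt(mean((values - mu)^2))
    ll <- sum(stats::dnorm(values, mu, sig, log = TRUE))
    npar <- nb + 1L
  } else {
    sig <- tapply(values - mu, block, function(r) sqrt(mean(r^2)))
    ll <- sum(stats::dnorm(values, mu,
                           as.numeric(sig[as.character(block)]), log = TRUE))
    npar <- 2L * nb
  }
  structure(list(
    assignment = assignment,
    blocks = split(lev, assignment),
    block_means = as.numeric(means), sd = sig, loglik = ll,
    n_params = npar, bic = -2 * ll + npar * log(n), n = n
  ), class = "condition_partition")
}

# BICs of every partition from per-condition sufficient statistics
partition_bics <- function(parts, values, condition, pooled_sd) {
  lev <- sort(unique(condition))
  ci <- match(condition, lev)
  n_c <- tabulate(ci, length(lev))
  s_c <- vapply(seq_along(lev), function(i) sum(values[ci == i]),
                numeric(1))
  q_c <- vapply(seq_along(lev), function(i) sum(values[ci == i]^2),
                numeric(1))
  n <- length(values)
  vapply(parts, function(a) {
    nb <- max(a)
    n_b <- vapply(seq_len(nb), function(b) sum(n_c[a == b]), numeric(1))
    s_b <- vapply(seq_len(nb), function(b) sum(s_c[a == b]), numeric(1))
    q_b <- vapply(seq_len(nb), function(b) sum(q_c[a == b]), numeric(1))
    rss_b <- q_b - s_b^2 / n_b
    if (pooled_sd) {
      sig2 <- sum(rss_b) / n
      ll <- -n / 2 * (log(2 * pi * sig2) + 1)
      -2 * ll + (nb + 1) * log(n)
    } else {
      ll <- sum(-n_b / 2 * (log(2 * pi * rss_b / n_b) + 1))
      -2 * ll + 2 * nb * log(n)
    }
  }, numeric(1))
}

#' Exhaustive condition clustering by BIC
#'
#' Scores every set partition of the condition levels (4140 for the 8
#' observed factor combinations) under the Gaussian block model and
#' selects, among the partitions whose BIC lies within the
#' positive-evidence threshold of the minimum, the most parsimonious one
#' (fewest blocks; ties broken by BIC). Blocks of the selected grouping
#' are labelled in ascending order of their mean (`low`, `mid`, `high`
#' for three blocks); other partitions within the threshold are reported
#' as alternatives.
#'
#' @param values Numeric observations (typically a transformed subjective
#'   indicator).
#' @param condition Condition label per observation.
#' @param grades An [raftery_grades()] object; its first threshold is the
#'   indistinguishability band.
#' @param pooled_sd Passed to [score_partition()].
#' @return List of class `condition_clustering`: `best` (the selected
#'   `condition_partition` with `labels` added), `alternatives` (other
#'   partitions within the threshold, by ascending BIC), `n_partitions`
#'   and a `table` of all partition BICs in enumeration order.
#' @export
cluster_conditions <- function(values, condition,
                               grades = raftery_grades(),
                               pooled_sd = FALSE) {
  lev <- sort(unique(condition))
  parts <- enumerate_partitions(length(lev))
  bics <- partition_bics(parts, values, condition, pooled_sd)
  near <- which(bics - min(bics) < grades$thresholds[1])
  nblocks <- vapply(parts[near], max, integer(1))
  near <- near[order(nblocks, bics[near])]
  best <- score_partition(parts[[near[1L]]], values, condition,
                          pooled_sd = pooled_sd)
  best$labels <- block_labels(best$block_means)
  alt_ix <- setdiff(near[order(bics[near])], near[1L])
  structure(list(
    best = best,
    alternatives = lapply(parts[alt_ix], score_partition, values = values,
                          condition = condition, pooled_sd = pooled_sd),
    n_partitions = length(parts),
    table = data.frame(
      partition = vapply(parts, paste, character(1), collapse = ""),
      n_blocks = vapply(parts, max, integer(1)),
      bic = bics)
  ), class = "condition_clustering")
}

block_labels <- function(means) {
  nb <- length(means)
  base <- switch(as.character(nb),
                 "1" = "all", "2" = c("low", "high"),
                 "3" = c("low", "mid", "high"),
                 paste0("level ", seq_len(nb)))
  # label blocks by ascending mean, keep block order
  base[rank(means, ties.method = "first")]
}

#' @export
print.condition_clustering <- function(x, ...) {
  b <- x$best
  cat(sprintf("<condition_clustering> %d partitions scored; best: %d block(s), BIC %.3f\n",
              x$n_partitions, length(b$block_means), b$bic))
  for (i in seq_along(b$blocks))
    cat(sprintf("  %s (mean %.3f): %s\n", b$labels[i], b$block_means[i],
                paste(b$blocks[[i]], collapse = ", ")))
  if (length(x$alternatives))
    cat(sprintf("  %d alternative partition(s) within the evidence threshold\n",
                length(x$alternatives)))
  invisible(x)
}
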