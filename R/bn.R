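#' Raftery grades of evidence for BIC differences
#'
#' BIC gaps above 2, 6 and 10 count as positive, strong and very strong
#' evidence; gaps below 2 leave the models indistinguishable.
#'
#' @param thresholds Strictly increasing gap thresholds.
#' @param labels Labels matching `thresholds`.
#' @return List of class `evidence_grades`.
#' @export
raftery_grades <- function(thresholds = c(2, 6, 10),
                           labels = c("positive", "strong", "very strong")) {
  stopifnot(length(thresholds) == length(labels),
            !is.unsorted(thresholds, strictly = TRUE))
  structure(list(thresholds = thresholds, labels = labels),
            class = "evidence_grades")
}

grade_gap <- function(gap, grades) {
  ix <- findInterval(gap, grades$thresholds)
  ifelse(ix == 0, "indistinguishable", grades$labels[pmax(ix, 1)])
}

#' Enumerate the candidate network structures
#'
#' The two factors TTC and offset are root nodes (no parents, no edge
#' between them). Candidate structures vary the factor parents of the SA
#' node (any subset of {TTC, Offset}), the factor parents of the SCR node
#' (likewise), and the inter-indicator edge (none, SA -> SCR, or
#' SCR -> SA): 4 x 4 x 3 = 48 acyclic structures.
#'
#' @param link Restrict to given inter-node edges (default all three).
#' @return List of `bn_structure` objects (fields `sa_parents`,
#'   `scr_parents`, `link`, `id`).
#' @export
enumerate_structures <- function(link = c("none", "sa_to_scr", "scr_to_sa")) {
  subsets <- list(character(), "TTC", "Offset", c("TTC", "Offset"))
  out <- list()
  for (sp in subsets) for (cp in subsets) for (lk in link) {
    s <- structure(list(sa_parents = sp, scr_parents = cp, link = lk),
                   class = "bn_structure")
    s$id <- structure_id(s)
    out[[length(out) + 1L]] <- s
  }
  out
}

node_parents <- function(s, node) {
  if (node == "SA") c(s$sa_parents, if (s$link == "scr_to_sa") "SCR")
  else c(s$scr_parents, if (s$link == "sa_to_scr") "SA")
}

structure_id <- function(s) {
  fmt <- function(node) {
    p <- node_parents(s, node)
    if (!length(p)) sprintf("L(%s)", node)
    else sprintf("L(%s|%s)", node, paste(p, collapse = ","))
  }
  paste(fmt("SA"), fmt("SCR"), sep = " x ")
}

#' @export
print.bn_structure <- function(x, ...) {
  cat("<bn_structure>", x$id, "\n")
  invisible(x)
}

gaussian_cell_fit <- function(y, cells) {
  groups <- split(y, cells, drop = TRUE)
  ll <- 0
  par <- lapply(groups, function(v) {
    if (length(v) < 2L) stop("a parent configuration has fewer than 2 rows")
    mu <- mean(v)
    sig <- sqrt(mean((v - mu)^2))   # MLE scale, likelihood-coherent
    ll <<- ll + sum(stats::dnorm(v, mu, sig, log = TRUE))
    c(mean = mu, sd = sig)
  })
  list(parameters = par, loglik = ll, n_params = 2L * length(groups))
}

# gaussian node with discrete + continuous parents: per-cell intercepts
# and variances plus one common slope, so the continuous parent is a
# strict one-parameter extension of the per-cell factor model
gaussian_mixed_fit <- function(y, data, disc, cont, maxit = 30L) {
  cells <- if (length(disc)) interaction(data[disc], drop = TRUE)
           else factor(rep("all", length(y)))
  x <- data[[cont]]
  Xd <- if (nlevels(cells) > 1L) stats::model.matrix(~ 0 + cells)
        else matrix(1, length(y), 1L)
  X <- cbind(Xd, x)
  sig <- stats::setNames(rep(stats::sd(y), nlevels(cells)),
                         levels(cells))
  ll_old <- -Inf
  for (it in seq_len(maxit)) {
    w <- 1 / sig[as.character(cells)]^2
    fit <- stats::lm.wfit(X, y, w)
    mu <- drop(X %*% fit$coefficients)
    sig <- vapply(split(y - mu, cells), function(r) sqrt(mean(r^2)),
                  numeric(1))
    ll <- sum(stats::dnorm(y, mu, sig[as.character(cells)], log = TRUE))
    if (abs(ll - ll_old) < 1e-10) break
    ll_old <- ll
  }
  cf <- fit$coefficients
  names(cf) <- c(levels(cells), cont)
  list(parameters = list(coef = cf, sd = sig), loglik = ll,
       n_params = 2L * nlevels(cells) + 1L)
}

#' Fit one node's conditional distribution
#'
#' Factor roots keep their design frequencies (no free parameters);
#' Gaussian nodes with factor parents get a mean and SD per observed
#' parent cell; a continuous parent adds a single common slope on top of
#' the per-cell intercepts and variances, so it always costs exactly one
#' extra parameter. Tweedie nodes get log-link cell means (shared
#' dispersion and index parameter), again plus one common slope when a
#' continuous parent is present. Factor combinations absent from the
#' design are skipped, never imputed.
#'
#' @param node One of `"TTC"`, `"Offset"`, `"SA"`, `"SCR"`.
#' @param parents Character vector of parent node names.
#' @param data Data frame with columns `TTC`, `Offset` (factors), `SA`,
#'   `SCR` (numeric).
#' @param freqs Condition-frequency table (for root nodes).
#' @param xi_grid,refine Passed to [fit_tweedie_glm()] for the SCR node.
#' @return List of class `node_fit`: `node`, `family`, `parameters`,
#'   `loglik`, `n_params`.
#' @export
fit_node <- function(node, parents, data, freqs = condition_frequencies(),
                     xi_grid = seq(1.05, 1.95, by = 0.1), refine = TRUE) {
  stopifnot(node %in% c("TTC", "Offset", "SA", "SCR"))
  if (node %in% c("TTC", "Offset")) {
    if (length(parents)) stop("factor nodes are roots")
    marg <- marginal_frequencies(freqs, tolower(if (node == "TTC") "ttc"
                                                else "offset"))
    p <- marg[as.character(data[[node]])]
    if (any(is.na(p) | p == 0)) stop("observed level with zero design frequency")
    return(structure(list(node = node, family = "discrete-fixed",
                          parameters = marg, loglik = sum(log(p)),
                          n_params = 0L), class = "node_fit"))
  }

  disc <- intersect(parents, c("TTC", "Offset"))
  cont <- setdiff(parents, disc)
  y <- data[[node]]

  if (node == "SA") {
    fit <- if (length(cont)) {
      gaussian_mixed_fit(y, data, disc, cont)
    } else if (length(disc)) {
      gaussian_cell_fit(y, interaction(data[disc], drop = TRUE))
    } else {
      gaussian_cell_fit(y, rep(1L, length(y)))
    }
    return(structure(c(list(node = node, family = "gaussian"), fit),
                     class = "node_fit"))
  }

  ## Tweedie node: log-link cell means (shared dispersion and index);
  ## a continuous parent adds one common slope on top of the cell means
  X <- if (length(disc)) {
    cells <- interaction(data[disc], drop = TRUE)
    Xd <- stats::model.matrix(~ 0 + cells)
    if (length(cont)) cbind(Xd, data[[cont]]) else Xd
  } else if (length(cont)) {
    cbind("(Intercept)" = 1, data[[cont]])
  } else {
    matrix(1, nrow(data), 1L, dimnames = list(NULL, "(Intercept)"))
  }
  if (length(cont)) colnames(X)[ncol(X)] <- cont
  tw <- fit_tweedie_glm(y, X, xi_grid = xi_grid, refine = refine)
  structure(list(node = node, family = "tweedie",
                 parameters = list(beta = tw$beta, phi = tw$phi, xi = tw$xi),
                 loglik = tw$loglik, n_params = tw$n_params,
                 fit = tw), class = "node_fit")
}

node_bic <- function(fit, n) -2 * fit$loglik + fit$n_params * log(n)

#' Score one network structure
#'
#' Node-wise BIC (`-2 loglik + n_params * log(n)`) summed over the four
#' nodes; by the factorisation of the joint likelihood of a Bayesian
#' network this equals the monolithic BIC of the joint model. Lower is
#' better.
#'
#' @param structure A `bn_structure`.
#' @param data Data frame with `TTC`, `Offset` factors and `SA`, `SCR`.
#' @param freqs Condition-frequency table.
#' @param cache Optional environment for node-fit reuse across structures.
#' @param ... Passed to [fit_node()].
#' @return List of class `network_score`: `structure`, `node_fits`,
#'   `node_bics`, `total_bic`.
#' @export
score_network <- function(structure, data, freqs = condition_frequencies(),
                          cache = NULL, ...) {
  n <- nrow(data)
  get_fit <- function(node, parents) {
    key <- paste(node, paste(sort(parents), collapse = ","), sep = "|")
    if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
    f <- tryCatch(fit_node(node, parents, data, freqs, ...),
                  error = function(e)
                    stop(sprintf("node %s: %s", node, conditionMessage(e)),
                         call. = FALSE))
    if (!is.null(cache)) cache[[key]] <- f
    f
  }
  fits <- list(
    TTC = get_fit("TTC", character()),
    Offset = get_fit("Offset", character()),
    SA = get_fit("SA", node_parents(structure, "SA")),
    SCR = get_fit("SCR", node_parents(structure, "SCR"))
  )
  bics <- vapply(fits, node_bic, numeric(1), n = n)
  structure(list(structure = structure, node_fits = fits,
                 node_bics = bics, total_bic = sum(bics)),
            class = "network_score")
}

#' Score all 48 candidate structures
#'
#' Exhaustive scoring with node-fit caching (only 8 distinct SA fits and
#' 8 distinct SCR fits exist across the 48 structures).
#'
#' @inheritParams score_network
#' @param structures Candidate list, default [enumerate_structures()].
#' @return Data frame with one row per structure: `id`, `link`, node BICs
#'   and `total_bic`; the structures and scores are attached as
#'   attributes `structures` and `scores`.
#' @export
score_all_structures <- function(data, freqs = condition_frequencies(),
                                 structures = enumerate_structures(), ...) {
  cache <- new.env(parent = emptyenv())
  scores <- lapply(structures, score_network, data = data, freqs = freqs,
                   cache = cache, ...)
  tab <- data.frame(
    id = vapply(structures, `[[`, character(1), "id"),
    link = vapply(structures, `[[`, character(1), "link"),
    bic_TTC = vapply(scores, function(s) s$node_bics[["TTC"]], numeric(1)),
    bic_Offset = vapply(scores, function(s) s$node_bics[["Offset"]], numeric(1)),
    bic_SA = vapply(scores, function(s) s$node_bics[["SA"]], numeric(1)),
    bic_SCR = vapply(scores, function(s) s$node_bics[["SCR"]], numeric(1)),
    total_bic = vapply(scores, `[[`, numeric(1), "total_bic")
  )
  attr(tab, "structures") <- structures
  attr(tab, "scores") <- scores
  tab
}

#' Rank scored structures and grade the gaps
#'
#' Sorts ascending by total BIC (ties broken by the structure id for
#' determinism), grades each consecutive gap with the Raftery thresholds,
#' and flags every structure within 2 BIC of the best as indistinguishable
#' from it.
#'
#' @param scores A table from [score_all_structures()] (or any data frame
#'   with `id` and `total_bic`).
#' @param grades An [raftery_grades()] object.
#' @return The table sorted, with `gap_to_next`, `grade_to_next`,
#'   `delta_to_best` and `indistinguishable` columns.
#' @export
rank_and_select <- function(scores, grades = raftery_grades()) {
  stopifnot(nrow(scores) >= 1L)
  ord <- order(scores$total_bic, scores$id)
  out <- scores[ord, , drop = FALSE]
  rownames(out) <- NULL
  gap <- c(diff(out$total_bic), NA_real_)
  out$gap_to_next <- gap
  out$grade_to_next <- c(grade_gap(gap[-length(gap)], grades), NA)
  out$delta_to_best <- out$total_bic - out$total_bic[1]
  out$indistinguishable <- out$delta_to_best < grades$thresholds[1]
  out
}

# does a structure id contain an SA-SCR edge?
has_sa_scr_edge <- function(link) link != "none"
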