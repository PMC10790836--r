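test_that("structure enumeration has the right counts and no duplicates", {
  all48 <- enumerate_structures()
  expect_length(all48, 48L)
  ids <- vapply(all48, `[[`, character(1), "id")
  expect_equal(anyDuplicated(ids), 0L)
  expect_length(enumerate_structures(link = "none"), 16L)
  no_edge_no_scr_parents <- Filter(function(s)
    length(s$scr_parents) == 0, enumerate_structures(link = "none"))
  expect_length(no_edge_no_scr_parents, 4L)
  # acyclicity by construction: never both inter-node edges
  for (s in all48)
    expect_false("SCR" %in% riskbn:::node_parents(s, "SA") &&
                   "SA" %in% riskbn:::node_parents(s, "SCR"))
})

test_that("node fits have closed-form parameters and likelihoods", {
  dat <- data.frame(TTC = factor(rep(c(2, 3.5), each = 3)),
                    Offset = factor(rep(1.5, 6)),
                    SA = c(-1, 0, 1, 2, 3, 4), SCR = c(0, 1, 0, 2, 0, 1))
  f <- fit_node("SA", character(), dat)
  expect_equal(unname(f$parameters[[1]]["mean"]), 1.5)
  sig <- sqrt(mean((dat$SA - 1.5)^2))
  expect_equal(f$loglik, sum(dnorm(dat$SA, 1.5, sig, log = TRUE)))
  expect_equal(f$n_params, 2L)

  ft <- fit_node("SA", "TTC", dat)
  expect_equal(ft$n_params, 4L)
  expect_equal(unname(vapply(ft$parameters, `[`, numeric(1), "mean")),
               c(0, 3))

  # gaussian cell fit recovers exact cell means at zero noise
  gt <- make_ground_truth(sa_sigma = 0)
  ind <- simulate_indicators(build_design(seed = 2), gt, seed = 3)
  dat2 <- data.frame(TTC = factor(ind$ttc), Offset = factor(ind$offset),
                     SA = ind$mSA, SCR = ind$nSCR)
  f2 <- fit_node("SA", c("TTC", "Offset"), dat2)
  cells <- vapply(f2$parameters, `[`, numeric(1), "mean")
  freqs <- condition_frequencies()
  for (i in seq_len(nrow(freqs))) {
    key <- paste(freqs$ttc[i], freqs$offset[i], sep = ".")
    expect_equal(unname(cells[key]),
                 unname(riskbn:::gt_sa_mean(gt, freqs$ttc[i],
                                            freqs$offset[i])))
  }

  # root nodes carry design frequencies and no free parameters
  fr <- fit_node("TTC", character(), dat2)
  expect_equal(fr$n_params, 0L)
  marg <- marginal_frequencies(condition_frequencies(), "ttc")
  expect_equal(fr$loglik,
               sum(log(marg[as.character(ind$ttc)])), ignore_attr = TRUE)
})

test_that("a Tweedie node recovers the generative link slope", {
  dat <- simulate_bn_dataset(seed = 5)
  f <- fit_node("SCR", "SA", dat, xi_grid = seq(1.1, 1.9, 0.2),
                refine = TRUE)
  tw <- f$fit
  expect_lt(abs(tw$beta[["SA"]] - 1.5), 3 * tw$se[["SA"]])
  expect_equal(f$n_params, 4L)
})

test_that("node BIC follows the definition and totals decompose exactly", {
  # arithmetic of the criterion itself
  fake <- structure(list(loglik = -100, n_params = 4L), class = "node_fit")
  expect_equal(riskbn:::node_bic(fake, 640), 200 + 4 * log(640))
  expect_equal(riskbn:::node_bic(fake, 640), 225.8459, tolerance = 1e-4)

  # 30-row fixture: decomposed total equals a monolithic joint computation
  dat <- simulate_bn_dataset(seed = 9)[1:30, ]
  dat <- droplevels(dat[dat$SCR >= 0, ])
  s <- enumerate_structures()[[which(vapply(enumerate_structures(),
    `[[`, character(1), "id") == "L(SA|TTC) x L(SCR|SA)")]]
  sc <- score_network(s, dat, xi_grid = 1.6, refine = FALSE)
  expect_equal(sc$total_bic, sum(sc$node_bics))

  # joint log-likelihood recomputed from the fitted parameters, row by row
  marg_t <- marginal_frequencies(condition_frequencies(), "ttc")
  marg_o <- marginal_frequencies(condition_frequencies(), "offset")
  sa_par <- sc$node_fits$SA$parameters
  mu_sa <- vapply(as.character(dat$TTC), function(l)
    sa_par[[l]][["mean"]], numeric(1))
  sd_sa <- vapply(as.character(dat$TTC), function(l)
    sa_par[[l]][["sd"]], numeric(1))
  tw <- sc$node_fits$SCR$fit
  mu_scr <- exp(tw$beta[["(Intercept)"]] + tw$beta[["SA"]] * dat$SA)
  joint_ll <- sum(log(marg_t[as.character(dat$TTC)])) +
    sum(log(marg_o[as.character(dat$Offset)])) +
    sum(dnorm(dat$SA, mu_sa, sd_sa, log = TRUE)) +
    sum(tweedie_logpdf(dat$SCR, mu_scr, tw$phi, tw$xi))
  p_total <- sum(vapply(sc$node_fits, `[[`, integer(1), "n_params"))
  expect_equal(sc$total_bic, -2 * joint_ll + p_total * log(nrow(dat)),
               tolerance = 1e-8)
})

test_that("a pure-noise parent mostly increases the BIC", {
  worse <- vapply(1:10, function(r) {
    dat <- simulate_bn_dataset(seed = 200 + r, scr_on = "none")
    s2 <- enumerate_structures(link = "none")
    ids <- vapply(s2, `[[`, character(1), "id")
    # SCR is generated independent of everything: any parent is noise
    base <- score_network(s2[[which(ids == "L(SA|TTC,Offset) x L(SCR)")]],
                          dat, xi_grid = 1.6, refine = FALSE)
    sc2 <- score_network(
      s2[[which(ids == "L(SA|TTC,Offset) x L(SCR|Offset)")]],
      dat, xi_grid = 1.6, refine = FALSE)
    sc2$total_bic > base$total_bic
  }, logical(1))
  expect_gte(mean(worse), 0.7)
})

test_that("ranking grades gaps with the Raftery thresholds", {
  g <- raftery_grades()
  tab <- data.frame(id = c("a", "b", "c", "d"),
                    total_bic = c(100, 101.5, 108.5, 120))
  rk <- rank_and_select(tab, g)
  expect_equal(rk$id, c("a", "b", "c", "d"))
  expect_equal(rk$grade_to_next[1:3],
               c("indistinguishable", "strong", "very strong"))
  expect_equal(rk$indistinguishable, c(TRUE, TRUE, FALSE, FALSE))
  # exact ties: stable order by id
  tie <- data.frame(id = c("z", "a"), total_bic = c(5, 5))
  expect_equal(rank_and_select(tie, g)$id, c("a", "z"))
})
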