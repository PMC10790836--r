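test_that("set-partition enumeration counts the Bell numbers", {
  bell <- c(1, 2, 5, 15, 52, 203, 877, 4140)
  for (k in c(1, 3, 8)) {
    parts <- enumerate_partitions(k)
    expect_length(parts, bell[k])
    expect_equal(anyDuplicated(vapply(parts, paste, character(1),
                                      collapse = "")), 0L)
  }
  expect_error(enumerate_partitions(0), "between 1 and 12")
  expect_error(enumerate_partitions(13), "between 1 and 12")
})

test_that("partition scoring has closed-form single-block likelihood", {
  set.seed(5)
  x <- rnorm(80)
  cond <- rep(letters[1:8], 10)
  single <- score_partition(rep(1L, 8), x, cond)
  mu <- mean(x); sig <- sqrt(mean((x - mu)^2))
  expect_equal(single$loglik, sum(dnorm(x, mu, sig, log = TRUE)))
  expect_equal(single$n_params, 2L)
  expect_equal(single$bic, -2 * single$loglik + 2 * log(80))
  expect_error(score_partition(c(1L, 3L, rep(1L, 6)), x, cond),
               "empty block")
})

test_that("scoring is invariant to permuting condition labels", {
  set.seed(6)
  x <- rnorm(160, rep(c(0, 0, 2, 2, 2, 5, 5, 5), 20))
  cond <- rep(letters[1:8], 20)
  a <- score_partition(c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L), x, cond)
  perm <- c(b = "a", a = "b", c = "c", d = "d", e = "e", f = "f",
            g = "g", h = "h")
  b <- score_partition(c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L), x,
                       unname(perm[cond]))
  expect_equal(a$bic, b$bic)
})

test_that("well-separated groups are recovered exactly and labelled by mean", {
  set.seed(7)
  truth <- c(a = 0, b = 0, c = 4, d = 4, e = 4, f = 9, g = 9, h = 9)
  cond <- rep(names(truth), 20)
  x <- rnorm(length(cond), truth[cond], 0.5)
  cl <- cluster_conditions(x, cond)
  expect_equal(cl$n_partitions, 4140L)
  got <- lapply(cl$best$blocks, sort)
  expect_equal(length(got), 3L)
  expect_setequal(got[[which(cl$best$labels == "low")]], c("a", "b"))
  expect_setequal(got[[which(cl$best$labels == "mid")]], c("c", "d", "e"))
  expect_setequal(got[[which(cl$best$labels == "high")]],
                  c("f", "g", "h"))
  means <- cl$best$block_means
  expect_true(means[cl$best$labels == "low"] <
                means[cl$best$labels == "mid"])
  expect_true(means[cl$best$labels == "mid"] <
                means[cl$best$labels == "high"])
  # the correct grouping beats all-singletons (penalty check)
  all_single <- score_partition(1:8, x, cond)
  expect_lt(cl$best$bic, all_single$bic)
})

test_that("identically distributed conditions collapse to one block", {
  wins <- vapply(1:20, function(r) {
    riskbn:::with_seed(700 + r, {
      x <- rnorm(160)
      cond <- rep(letters[1:8], 20)
      length(cluster_conditions(x, cond)$best$block_means) == 1L
    })
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("the fast scoring path agrees with the reference scorer", {
  set.seed(9)
  x <- rnorm(160, rep(c(0, 1), each = 80))
  cond <- rep(letters[1:8], 20)
  cl <- cluster_conditions(x, cond)
  ref <- vapply(enumerate_partitions(8)[c(1, 500, 2000, 4140)],
                function(a) score_partition(a, x, cond)$bic, numeric(1))
  fast <- cl$table$bic[c(1, 500, 2000, 4140)]
  expect_equal(fast, ref, tolerance = 1e-10)
})

test_that("study-pattern condition means produce the low/mid/high grouping", {
  designs <- lapply(1:20, function(i) build_design(participant_id = i,
                                                   seed = 40 + i))
  ind <- transform_indicators(simulate_indicators(designs, seed = 13))
  cond <- paste(ind$ttc, ind$offset, sep = "_")
  cl <- cluster_conditions(ind$iSA_t, cond)
  expect_equal(length(cl$best$block_means), 3L)
  blocks <- cl$best$blocks
  labels <- cl$best$labels
  expect_setequal(blocks[[which(labels == "high")]], "2_1.5")
  expect_setequal(blocks[[which(labels == "mid")]],
                  c("2.5_1.5", "3_0.5", "3.5_0.5"))
  expect_setequal(blocks[[which(labels == "low")]],
                  c("3_1", "3_1.5", "3.5_1", "3.5_1.5"))
})
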