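test_that("uniform blocks respect degenerate probabilities", {
  expect_length(build_block_uniform(50, 50, 0)$pre, 0)
  full <- build_block_uniform(10, 10, 1, same_pop = TRUE, seed = 1)
  expect_length(full$pre, 90)  # complete digraph minus the diagonal
  expect_true(all(full$pre != full$post))
})

test_that("uniform block density matches the binomial expectation", {
  n <- 500; p <- 0.168
  blk <- build_block_uniform(n, n, p, same_pop = TRUE, seed = 2)
  expected <- p * n * (n - 1)
  expect_lt(abs(length(blk$pre) - expected), 3 * sqrt(expected * (1 - p)))
})

test_that("skewed blocks draw exactly the expected edge count, without duplicates", {
  blk <- build_block_skewed(200, 300, 0.1, k_out = 5, k_in = 5, seed = 3)
  expect_length(blk$pre, floor(0.1 * 200 * 300))
  key <- (blk$pre - 1) * 300 + blk$post
  expect_false(any(duplicated(key)))
})

test_that("zero skewness reduces to uniform index statistics", {
  n <- 500; p <- 0.1
  sk <- build_block_skewed(n, n, p, 0, 0, same_pop = TRUE, seed = 4)
  un <- build_block_uniform(n, n, p, same_pop = TRUE, seed = 5)
  deg_sk <- tabulate(sk$post, n)
  deg_un <- tabulate(un$post, n)
  ks <- suppressWarnings(stats::ks.test(deg_sk, deg_un))
  expect_gt(ks$p.value, 0.01)
})

test_that("positive skewness inflates the in-degree variance", {
  wins <- vapply(1:10, function(s) {
    v0 <- var(tabulate(build_block_skewed(400, 400, 0.1, 0, 0, seed = s)$post, 400))
    v5 <- var(tabulate(build_block_skewed(400, 400, 0.1, 0, 5, seed = s + 100)$post, 400))
    v5 > v0
  }, logical(1))
  expect_true(all(wins))
})

test_that("presynaptic index marginal follows the truncated exponential", {
  n_pre <- 1000; n_post <- 40000; p <- 0.0025; k <- 2
  blk <- build_block_skewed(n_pre, n_post, p, k_out = k, k_in = 0, seed = 6)
  expect_gte(length(blk$pre), 1e5)
  pmf <- truncexp_pmf(n_pre, k)
  # 10 equal-width index bins
  bins <- cut(blk$pre, breaks = seq(0.5, n_pre + 0.5, length.out = 11))
  obs <- as.numeric(table(bins))
  expp <- vapply(split(pmf, rep(1:10, each = n_pre / 10)), sum, numeric(1))
  chi <- suppressWarnings(stats::chisq.test(obs, p = expp))
  expect_gt(chi$p.value, 0.01)
})

test_that("weight correlations preserve the mean and induce within-target correlation", {
  blk <- build_block_uniform(200, 200, 0.2, seed = 7)
  blk$weights <- rep(1, length(blk$pre))
  blk$delays <- rep(1, length(blk$pre))
  same <- apply_weight_correlations(blk, 0, 0, seed = 8)
  expect_identical(same$weights, blk$weights)

  zeta <- rlnorm(1e6, -1 / 2, 1)  # shape mu = -c^2/2 with c = 1
  expect_lt(abs(mean(zeta) - 1), 0.005)

  mean_w <- numeric(10); mean_cc <- numeric(10)
  for (s in 1:10) {
    b2 <- apply_weight_correlations(blk, c_in = 1, c_out = 0, seed = s)
    mean_w[s] <- mean(b2$weights)
    # weights sharing a postsynaptic target vary together across targets
    grp <- split(b2$weights, b2$post)
    within_sd <- mean(vapply(grp, sd, numeric(1)), na.rm = TRUE)
    across_sd <- sd(vapply(grp, mean, numeric(1)))
    mean_cc[s] <- across_sd - within_sd
  }
  expect_lt(abs(mean(mean_w) - 1), 0.15)   # E[zeta] = 1, Monte-Carlo error
  expect_true(all(mean_cc > 0))            # common per-target factor dominates
})

test_that("structural heterogeneity only alters the designated blocks", {
  hom <- build_microcircuit(120, "Hom", seed = 17)
  str_ <- build_microcircuit(120, "Str", seed = 17)
  ctab <- connection_params()
  for (b in seq_along(hom$blocks)) {
    if (ctab$k_in[b] == 0 && ctab$k_out[b] == 0) {
      expect_identical(hom$blocks[[b]]$pre, str_$blocks[[b]]$pre)
      expect_identical(hom$blocks[[b]]$post, str_$blocks[[b]]$post)
    } else {
      expect_false(identical(hom$blocks[[b]]$pre, str_$blocks[[b]]$pre) &&
                     identical(hom$blocks[[b]]$post, str_$blocks[[b]]$post))
    }
    expect_identical(hom$blocks[[b]]$weights[1], str_$blocks[[b]]$weights[1])
  }
})
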