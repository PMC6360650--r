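test_that("KS statistic equals the brute-force ECDF supremum on small random instances", {
  set.seed(41)
  for (i in 1:300) {
    m <- sample(1:12, 1); n <- sample(1:12, 1)
    # mix of continuous and tied-value samples
    x <- if (i %% 3 == 0) sample(1:6, m, TRUE) else rnorm(m)
    y <- if (i %% 3 == 0) sample(1:6, n, TRUE) else rnorm(n, 0.5)
    expect_identical(ks_statistic(x, y)$statistic, brute_ks_D(x, y))
  }
})

test_that("KS statistic handles the canonical hand-worked cases", {
  expect_equal(ks_statistic(c(1, 2, 3), c(1.5, 2.5))$statistic, 1 / 3)
  ident <- ks_statistic(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p.value, 1)
  expect_equal(ks_statistic(c(1, 2), c(5, 6, 7))$statistic, 1)
  expect_error(ks_statistic(numeric(0), 1:3), "non-empty")
})

test_that("uncorrected KS p-value matches the asymptotic value of stats::ks.test", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(80); y <- rnorm(60, 0.2)
    ours <- ks_statistic(x, y, correction = FALSE)
    ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-4)
  }
})

test_that("log-scale KS p-values stay ordered far past double underflow", {
  lp1 <- ks_statistic(rep(0:1, 500), rep(10:11, 500))$log.p.value
  expect_lt(lp1, log(1e-300))
  # larger samples with the same D = 1 are more significant
  lp2 <- ks_statistic(rep(0:1, 800), rep(10:11, 800))$log.p.value
  expect_lt(lp2, lp1)
})

test_that("u test matches wilcox.test and t test matches t.test", {
  set.seed(43)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1)); y <- rnorm(sample(5:40, 1), 0.3)
    if (i %% 4 == 0) { x <- round(x); y <- round(y) } # force ties
    u <- u_test(x, y)
    w <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(u$statistic, unname(w$statistic))
    expect_equal(u$p.value, w$p.value, tolerance = 1e-10)
    tt <- t_test(x, y)
    tr <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(tt$statistic, unname(tr$statistic), tolerance = 1e-12)
    expect_equal(tt$p.value, tr$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate two-group inputs give p = 1 with a warning", {
  expect_warning(tt <- t_test(c(2, 2, 2), c(2, 2)), "pooled variance")
  expect_equal(tt$p.value, 1)
  expect_warning(u <- u_test(c(2, 2), c(2, 2, 2)), "tied")
  expect_equal(u$p.value, 1)
})

test_that("mean and variance alternatives have the expected power profile", {
  set.seed(44)
  # same mean, different variance: KS detects, U and T do not
  x <- rnorm(400, 0, 1); y <- rnorm(400, 0, 2)
  expect_lt(ks_statistic(x, y)$p.value, 1e-4)
  expect_gt(u_test(x, y)$p.value, 0.05)
  expect_gt(t_test(x, y)$p.value, 0.05)
  # location shift: all three detect
  y2 <- rnorm(400, 0.5, 1)
  expect_lt(ks_statistic(x, y2)$p.value, 0.01)
  expect_lt(u_test(x, y2)$p.value, 0.01)
  expect_lt(t_test(x, y2)$p.value, 0.01)
})

test_that("weighted Stouffer combination matches its closed form", {
  res <- combine_stouffer(c(0.5, 0.5, 0.01, 0.5, 0.5),
                          weights = c(0.25, 0.5, 1, 0.5, 0.25))
  expect_equal(res$Z, qnorm(0.99) / sqrt(1.625), tolerance = 1e-12)
  expect_equal(round(res$Z, 3), 1.825)
  expect_equal(round(res$p.value, 3), 0.034)

  # all p = 0.5 gives Z = 0, p = 0.5 under any weights
  res0 <- combine_stouffer(rep(0.5, 5), weights = runif(5, 0.1, 2))
  expect_equal(res0$Z, 0, tolerance = 1e-12)
  expect_equal(res0$p.value, 0.5, tolerance = 1e-12)

  # single-term identity
  expect_equal(combine_stouffer(0.037)$p.value, 0.037, tolerance = 1e-12)
})

test_that("Stouffer Z is invariant to positive rescaling of the weights", {
  set.seed(45)
  for (i in 1:20) {
    p <- runif(5, 0.001, 0.999)
    w <- runif(5, 0.1, 3)
    a <- combine_stouffer(p, w)
    b <- combine_stouffer(p, w * runif(1, 0.01, 50))
    expect_equal(a$Z, b$Z, tolerance = 1e-10)
  }
})

test_that("Fisher combination matches the chi-squared closed form", {
  res <- combine_fisher(c(0.1, 0.1, 0.1))
  expect_equal(res$statistic, -2 * 3 * log(0.1), tolerance = 1e-12)
  expect_equal(res$p.value, pchisq(-6 * log(0.1), df = 6, lower.tail = FALSE),
               tolerance = 1e-12)
  # single p is returned unchanged (chi-squared with 2 df identity)
  expect_equal(combine_fisher(0.2)$p.value, 0.2, tolerance = 1e-12)
  # boundary p = 1 values are clamped (warning checked elsewhere)
  expect_equal(suppressWarnings(combine_fisher(c(1, 1, 1))$p.value), 1,
               tolerance = 1e-10)
})

test_that("boundary p-values are clamped with a warning", {
  expect_warning(res <- combine_stouffer(c(0, 0.5, 1)), "clamped")
  expect_true(is.finite(res$Z))
})

test_that("decreasing any single p never increases the combined p", {
  set.seed(46)
  for (i in 1:30) {
    p <- runif(5, 0.01, 0.99)
    w <- runif(5, 0.2, 2)
    j <- sample(5, 1)
    p2 <- p; p2[j] <- p[j] * runif(1)
    expect_lte(combine_stouffer(p2, w)$p.value, combine_stouffer(p, w)$p.value)
    expect_lte(combine_fisher(p2)$p.value, combine_fisher(p)$p.value)
  }
})

test_that("neighbor combination uses the weighted window and truncates at ends", {
  scored <- tibble::tibble(
    ref_position = 0:6, ref_base = "A",
    log_p_single = log(c(0.5, 0.5, 0.5, 0.01, 0.5, 0.5, 0.5)),
    p_single = c(0.5, 0.5, 0.5, 0.01, 0.5, 0.5, 0.5)
  )
  out <- combine_neighbor_pvalues(scored, method = "stouffer", k = 2)
  center <- combine_stouffer(c(0.5, 0.5, 0.01, 0.5, 0.5),
                             weights = c(0.25, 0.5, 1, 0.5, 0.25))
  expect_equal(out$Z[out$ref_position == 3], center$Z, tolerance = 1e-12)
  # position 0 has no left neighbors: truncated window of 3 terms
  edge <- combine_stouffer(c(0.5, 0.5, 0.5), weights = c(1, 0.5, 0.25))
  expect_equal(out$Z[out$ref_position == 0], edge$Z, tolerance = 1e-12)
  # k = 0 reduces to the single-base p-value
  out0 <- combine_neighbor_pvalues(scored, method = "stouffer", k = 0)
  expect_equal(out0$p_combined, scored$p_single, tolerance = 1e-12)
  # fisher route
  outf <- combine_neighbor_pvalues(scored, method = "fisher", k = 1)
  expect_equal(outf$p_combined[4],
               combine_fisher(c(0.5, 0.01, 0.5))$p.value, tolerance = 1e-12)
})

test_that("neighborhood ranking suppresses lower-ranked neighbors greedily", {
  sites <- tibble::tibble(
    ref_position = c(100L, 101L, 200L),
    log_p_combined = log(c(1e-9, 1e-8, 1e-6)),
    p_combined = c(1e-9, 1e-8, 1e-6)
  )
  out <- neighborhood_rank(sites, window = 2)
  expect_equal(out$rank, c(1L, NA, 2L))

  # all sites far apart: identity ranking by p
  sites2 <- tibble::tibble(ref_position = c(10L, 50L, 90L),
                           log_p_combined = log(c(0.3, 0.1, 0.2)),
                           p_combined = c(0.3, 0.1, 0.2))
  expect_equal(neighborhood_rank(sites2, window = 2)$rank, c(3L, 1L, 2L))

  # adjacent equal p-values: leftmost accepted
  sites3 <- tibble::tibble(ref_position = c(20L, 21L),
                           log_p_combined = log(c(0.05, 0.05)),
                           p_combined = c(0.05, 0.05))
  expect_equal(neighborhood_rank(sites3, window = 2)$rank, c(1L, NA))
})

test_that("the suppressed-site set does not depend on input row order", {
  set.seed(47)
  sites <- tibble::tibble(
    ref_position = sample(1:200, 60),
    log_p_combined = log(runif(60))
  )
  sites$p_combined <- exp(sites$log_p_combined)
  a <- neighborhood_rank(sites, window = 2)
  perm <- sample(nrow(sites))
  b <- neighborhood_rank(sites[perm, ], window = 2)
  accepted_a <- sort(a$ref_position[!is.na(a$rank)])
  accepted_b <- sort(b$ref_position[!is.na(b$rank)])
  expect_identical(accepted_a, accepted_b)
})
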