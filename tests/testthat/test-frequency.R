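test_that("mutation frequency is the dilution-scaled colony ratio", {
  expect_equal(mutation_frequency(30, 1e2, 150, 1e5), 2e-4)
  expect_equal(mutation_frequency(0, 1e3, 100, 1e5), 0)
  expect_equal(mutation_frequency(10, 1, 10, 1), 1.0)
  expect_error(mutation_frequency(5, 10, 0, 10, culture_id = "c7"), "c7")
  # scale invariance: multiplying both dilution factors by a constant
  set.seed(5)
  for (i in 1:20) {
    ns <- sample(0:100, 1); nn <- sample(1:500, 1)
    ds <- sample(1:1000, 1); dn <- sample(1:1e6, 1); k <- sample(2:50, 1)
    expect_equal(mutation_frequency(ns, ds * k, nn, dn * k),
                 mutation_frequency(ns, ds, nn, dn))
  }
})

test_that("group medians and fold changes behave as ratios of medians", {
  f <- c(1e-5, 2e-5, 3e-5, 2e-7, 1e-7, 4e-7)
  g <- rep(c("guide", "control"), each = 3)
  s <- frequency_summary(f, g)
  expect_equal(s$median[s$group == "guide"], 2e-5)
  expect_equal(s$median[s$group == "control"], 2e-7)
  expect_equal(fold_change(s, "guide", "control"), 100)
  expect_equal(fold_change(s, "guide", "guide"), 1.0)
  # even group size: median is the mean of the central pair
  s2 <- frequency_summary(c(1, 3, 5, 7), rep("a", 4))
  expect_equal(s2$median, 4)
  s3 <- frequency_summary(c(0, 0, 1), c("a", "a", "b"))
  expect_warning(fc <- fold_change(s3, "b", "a"), "infinite")
  expect_equal(fc, Inf)
})

test_that("exact Mann-Whitney agrees with brute-force enumeration for all small sizes", {
  brute <- function(x, y) {
    pooled <- c(x, y)
    N <- length(pooled); m <- length(x)
    r <- rank(pooled)
    u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
    combs <- combn(N, m)
    us <- apply(combs, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
    eps <- 1e-9
    min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
  }
  set.seed(9)
  for (m in 1:5) {
    for (n in m:(10 - m)) {
      x <- rnorm(m); y <- rnorm(n)
      res <- mann_whitney_exact(x, y)
      expect_equal(res$p, brute(x, y), label = sprintf("m=%d n=%d", m, n))
      expect_equal(res$method, "exact")
    }
  }
})

test_that("the no-tie exact route matches wilcox.test", {
  set.seed(21)
  for (i in 1:20) {
    m <- sample(3:8, 1); n <- sample(3:8, 1)
    x <- rnorm(m); y <- rnorm(n)
    ours <- mann_whitney_exact(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("complete separation of six versus six gives the recurring p-value", {
  res <- mann_whitney_exact(c(7, 8, 9, 10, 11, 12), 1:6)
  expect_equal(res$p, 2 / 924)
  expect_equal(sprintf("%.4f", res$p), "0.0022")
  expect_equal(res$U, 36)
  # 3 vs 3 separation: 2 / C(6,3)
  expect_equal(mann_whitney_exact(4:6, 1:3)$p, 0.1)
  # identical constant samples: no separation, ties route
  res_tie <- mann_whitney_exact(rep(1, 4), rep(1, 4))
  expect_equal(res_tie$p, 1.0)
  expect_equal(res_tie$method, "exact_permutation")
})

test_that("tied samples use exact permutation of mid-ranks when feasible", {
  x <- c(1, 2, 2, 3); y <- c(2, 3, 3, 4)
  res <- mann_whitney_exact(x, y)
  expect_equal(res$method, "exact_permutation")
  # independent enumeration over assignments of the pooled values
  pooled <- c(x, y); r <- rank(pooled); m <- length(x)
  us <- apply(combn(8, 4), 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  u_obs <- sum(r[1:4]) - m * (m + 1) / 2
  p_manual <- min(1, 2 * min(mean(us <= u_obs + 1e-9),
                             mean(us >= u_obs - 1e-9)))
  expect_equal(res$p, p_manual)
  expect_equal(res$U, unname(suppressWarnings(
    stats::wilcox.test(x, y))$statistic))
})

test_that("large tied samples fall back to the corrected normal approximation", {
  set.seed(2)
  x <- sample(1:5, 30, replace = TRUE)
  y <- sample(2:6, 30, replace = TRUE)
  res <- mann_whitney_exact(x, y)
  expect_equal(res$method, "normal_approx")
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
})

test_that("p-values are proper and symmetric in the sample order", {
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(sample(2:7, 1)); y <- rnorm(sample(2:7, 1))
    p <- mann_whitney_exact(x, y)$p
    expect_gt(p, 0)
    expect_lte(p, 1)
    expect_equal(p, mann_whitney_exact(y, x)$p)
  }
})

test_that("rank correlation is monotone-consistent and centers at zero", {
  expect_equal(rank_correlation(1:8, (1:8)^3), 1.0)
  expect_equal(rank_correlation(1:8, -(1:8)), -1.0)
  expect_warning(rho <- rank_correlation(rep(1, 5), 1:5), "constant")
  expect_true(is.na(rho))
  # random permutations: mean rho near 0 (permutation oracle)
  set.seed(13)
  rhos <- replicate(300, rank_correlation(1:20, sample(20)))
  expect_lt(abs(mean(rhos)), 3 / sqrt(300 * 19))
})
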