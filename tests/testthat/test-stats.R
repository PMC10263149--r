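# Exact engines are checked against independent oracles: full sign-vector
# enumeration, combinatorial rank enumeration, the binomial pmf rule, and
# base R's reference implementations.

test_that("signed-rank: 12 days all above 0.5 give V = 78, p = 1/4096", {
  vals <- seq(0.55, 0.77, by = 0.02)
  r <- wilcoxon_signed_rank(vals, mu = 0.5, alternative = "greater")
  expect_identical(unname(r$statistic["V"]), 78)
  expect_equal(r$p.value, 1 / 4096)
  expect_true(r$exact)
})

test_that("signed-rank: an n = 12 configuration with V = 58 gives p = 0.076", {
  # negative deviations carry absolute ranks {3, 8, 9}: V = 78 - 20 = 58
  dev <- c(1, 2, -3, 4, 5, 6, 7, -8, -9, 10, 11, 12) / 100
  r <- wilcoxon_signed_rank(0.5 + dev, mu = 0.5, alternative = "greater")
  expect_identical(unname(r$statistic["V"]), 58)
  expect_equal(r$p.value, 310 / 4096)
  expect_equal(round(r$p.value, 3), 0.076)
})

test_that("signed-rank null for n = 12 matches 2^12 sign-vector enumeration", {
  ranks <- 1:12
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 12)))
  V_all <- as.vector(signs %*% ranks)
  expect_equal(mean(V_all >= 78), 1 / 4096)
  expect_equal(mean(V_all >= 58), 310 / 4096)
  # package tail probabilities agree with enumeration at every V
  pmf <- beeflight:::signed_rank_null_pmf(2L * ranks)
  for (v in c(0, 10, 39, 58, 70, 78)) {
    expect_equal(sum(pmf[(2 * v + 1):length(pmf)]), mean(V_all >= v))
  }
})

test_that("signed-rank: tiny-n and tie handling match brute enumeration", {
  r <- wilcoxon_signed_rank(c(0.7, 0.9), mu = 0.5, alternative = "greater")
  expect_identical(unname(r$statistic["V"]), 3)
  expect_equal(r$p.value, 0.25)
  # tied absolute deviations: oracle enumerates all sign vectors with
  # midranks
  vals <- c(0.6, 0.6, 0.45, 0.8, 0.8, 0.3)
  d <- vals - 0.5
  rk <- rank(abs(d))
  V_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
  V_all <- as.vector(signs %*% rk)
  for (alt in c("greater", "less")) {
    r2 <- wilcoxon_signed_rank(vals, 0.5, alt)
    want <- if (alt == "greater") mean(V_all >= V_obs) else
      mean(V_all <= V_obs)
    expect_equal(r2$p.value, want)
  }
})

test_that("signed-rank agrees with the reference implementation (no ties)", {
  set.seed(7)
  for (i in 1:5) {
    x <- round(rnorm(10, 0.55, 0.2), 6)
    for (alt in c("greater", "less", "two.sided")) {
      ours <- wilcoxon_signed_rank(x, 0.5, alt)
      ref <- suppressWarnings(wilcox.test(x, mu = 0.5, alternative = alt,
                                          exact = TRUE))
      expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
      expect_equal(unname(ours$statistic["V"]), unname(ref$statistic))
    }
  }
})

test_that("binomial test: symmetric tails and brute-force oracle", {
  r <- binomial_test(10, 10)
  expect_equal(r$p.value, 2 / 1024)
  expect_equal(binomial_test(6, 12)$p.value, 1)
  # small-P rule vs direct enumeration, including asymmetric p0
  for (n in c(7, 12, 20)) {
    for (p0 in c(0.5, 0.3)) {
      for (k in c(0, 2, n %/% 2, n)) {
        pmf <- dbinom(0:n, n, p0)
        want <- sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
        expect_equal(binomial_test(k, n, p0)$p.value, want)
        expect_equal(binomial_test(k, n, p0)$p.value,
                     binom.test(k, n, p0)$p.value, tolerance = 1e-9)
      }
    }
  }
  expect_error(binomial_test(3, 0), ">= 1")
})

test_that("rank-sum: separation, ties, and reference agreement", {
  # fully separated m = n = 4: one-sided p = 1 / choose(8, 4)
  r <- wilcoxon_rank_sum(c(5, 6, 7, 8), c(1, 2, 3, 4), "greater")
  expect_equal(r$p.value, 1 / 70)
  expect_true(r$exact)
  # identical samples: two-sided p capped at 1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  # exact branch equals the reference exact distribution
  set.seed(11)
  for (i in 1:5) {
    a <- rnorm(5); b <- rnorm(6)
    for (alt in c("greater", "less", "two.sided")) {
      ours <- wilcoxon_rank_sum(a, b, alt)
      ref <- wilcox.test(a, b, alternative = alt, exact = TRUE)
      expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
    }
  }
  # approximation is close to the exact answer at m = n = 12
  set.seed(12)
  a <- rnorm(12); b <- rnorm(12, 0.5)
  approx <- wilcoxon_rank_sum(a, b, "two.sided")
  exact <- wilcox.test(a, b, exact = TRUE)$p.value
  expect_false(approx$exact)
  expect_lt(abs(approx$p.value - exact), 0.01)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("ANOVA: degenerate, algebraic and sum-of-squares oracles", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  r <- one_way_anova(g)
  expect_equal(unname(r$statistic["F"]), 0)
  expect_equal(r$p.value, 1)
  expect_true(all(tukey_hsd(g)$p_adj == 1))
  # two groups: F is the square of the pooled-variance t statistic
  set.seed(21)
  a <- rnorm(8); b <- rnorm(9, 0.7)
  f <- unname(one_way_anova(list(a, b))$statistic["F"])
  t2 <- unname(t.test(a, b, var.equal = TRUE)$statistic)^2
  expect_equal(f, t2, tolerance = 1e-10)
  # 3 x 10 seeded data against a hand sum-of-squares computation
  set.seed(22)
  gs <- list(x = rnorm(10), y = rnorm(10, 0.4), z = rnorm(10, 0.9))
  all_v <- unlist(gs)
  grand <- mean(all_v)
  ssb <- sum(vapply(gs, function(v) length(v) * (mean(v) - grand)^2, 1))
  ssw <- sum(vapply(gs, function(v) sum((v - mean(v))^2), 1))
  f_hand <- (ssb / 2) / (ssw / 27)
  r3 <- one_way_anova(gs)
  expect_equal(unname(r3$statistic["F"]), f_hand, tolerance = 1e-8)
  # cross-check against the built-in fitter
  df <- data.frame(v = all_v, g = rep(names(gs), each = 10))
  ref <- anova(aov(v ~ g, df))
  expect_equal(unname(r3$statistic["F"]), ref$`F value`[1], tolerance = 1e-10)
  expect_equal(r3$p.value, ref$`Pr(>F)`[1], tolerance = 1e-10)
  expect_error(one_way_anova(list(c(1, 1), c(1, 1))), "0/0")
})

test_that("Tukey HSD matches the reference on balanced designs", {
  set.seed(23)
  gs <- list(a = rnorm(8), b = rnorm(8, 0.5), c = rnorm(8, 1))
  ours <- tukey_hsd(gs)
  df <- data.frame(v = unlist(gs), g = rep(names(gs), each = 8))
  ref <- TukeyHSD(aov(v ~ g, df))$g
  ref <- ref[order(rownames(ref)), , drop = FALSE]
  ours <- ours[order(ours$pair), ]
  expect_equal(ours$diff, unname(ref[, "diff"]), tolerance = 1e-10)
  expect_equal(ours$p_adj, unname(ref[, "p adj"]), tolerance = 1e-8)
})

test_that("Kruskal-Wallis: degenerate case, reference and permutation null", {
  expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1)))$p.value, 1)
  set.seed(31)
  gs <- list(rnorm(7), rnorm(8, 0.5), c(1, 1, 2, 2, 3))  # includes ties
  ours <- kruskal_wallis(gs)
  ref <- kruskal.test(unlist(gs), rep(1:3, times = lengths(gs)))
  expect_equal(unname(ours$statistic["H"]), unname(ref$statistic),
               tolerance = 1e-12)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
  # tiny instance: chi-squared p close to the enumerated permutation null
  set.seed(3)
  a <- round(rnorm(4, 0, 1), 2); b <- round(rnorm(4, 1.2, 1), 2)
  obs <- unname(kruskal_wallis(list(a, b))$statistic["H"])
  pool <- c(a, b)
  combos <- utils::combn(8, 4)
  perm_h <- apply(combos, 2, function(ix) {
    unname(kruskal_wallis(list(pool[ix], pool[-ix]))$statistic["H"])
  })
  p_perm <- mean(perm_h >= obs - 1e-12)
  p_chi <- kruskal_wallis(list(a, b))$p.value
  expect_lt(abs(p_chi - p_perm), 0.08)
})

test_that("two-group Kruskal-Wallis is consistent with the rank-sum test", {
  set.seed(41)
  for (i in 1:5) {
    a <- rnorm(9); b <- rnorm(9, 1)
    p_kw <- kruskal_wallis(list(a, b))$p.value
    p_rs <- wilcoxon_rank_sum(a, b, "two.sided")$p.value
    expect_identical(p_kw < 0.05, p_rs < 0.05)
  }
})
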