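test_that("square-root transform stabilizes Poisson-like variance", {
  expect_equal(stabilize(c(0, 4, 9)), c(0, 2, 3))
  expect_error(stabilize(c(1, -2)), "nonnegative")
  set.seed(2026)
  for (lambda in c(25, 100)) {
    v <- var(sqrt(rpois(2e4, lambda)))
    expect_equal(v, 0.25, tolerance = 0.1)
  }
})

test_that("Bartlett matches a direct computation and flags degeneracy", {
  g <- list(a = c(4.1, 5.2, 6.3, 5.8, 4.9), b = c(1.0, 9.0, 3.5, 7.2, 5.5))
  res <- bartlett_groups(g)
  # independent hand computation of the classical statistic (k = 2, n = 5)
  n <- c(5, 5)
  s2 <- c(var(g$a), var(g$b))
  N <- 10
  sp2 <- sum((n - 1) * s2) / (N - 2)
  num <- (N - 2) * log(sp2) - sum((n - 1) * log(s2))
  C <- 1 + (sum(1 / (n - 1)) - 1 / (N - 2)) / (3 * (2 - 1))
  expect_equal(res$statistic, num / C, tolerance = 1e-10)
  expect_equal(res$df, 1)
  expect_equal(res$p.value, pchisq(num / C, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  # identical groups: equal variances, p = 1
  same <- list(c(1, 2, 3), c(1, 2, 3))
  expect_equal(bartlett_groups(same)$p.value, 1, tolerance = 1e-9)
  expect_error(bartlett_groups(list(c(1, 1, 1), c(1, 2, 3))), "degenerate")
})

test_that("Bartlett detects a tenfold variance ratio", {
  set.seed(11)
  hits <- mean(replicate(60, {
    g <- list(rnorm(50, sd = 1), rnorm(50, sd = sqrt(10)))
    bartlett_groups(g)$p.value < 0.01
  }))
  expect_gte(hits, 0.95)
})

test_that("one-way ANOVA reproduces hand-computed and reference values", {
  res <- anova_oneway(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$F, 13.5)
  expect_identical(res$df_between, 1L)
  expect_identical(res$df_within, 4L)
  # translation invariance
  res2 <- anova_oneway(list(c(1, 2, 3) + 100, c(4, 5, 6) + 100))
  expect_equal(res2$F, res$F)
  # identical constant groups: F defined as 0
  expect_equal(anova_oneway(list(c(5, 5, 5), c(5, 5, 5)))$F, 0)
  # cross-check against the lm route on random data
  set.seed(3)
  g <- list(rnorm(8), rnorm(6, 1), rnorm(7, 0.5))
  ref <- anova(lm(unlist(g) ~ factor(rep(1:3, times = c(8, 6, 7)))))
  mine <- anova_oneway(g)
  expect_equal(mine$F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(mine$p.value, ref$`Pr(>F)`[1], tolerance = 1e-10)
  expect_error(anova_oneway(list(1, 2)), "n > k")
})

test_that("Dunnett reduces to the two-sided t test for a single comparison", {
  set.seed(21)
  a <- rnorm(8)
  b <- rnorm(8, 1)
  res <- dunnett_test(list(ctrl = a, trt = b), "ctrl", n_mc = 2e5)
  tt <- t.test(b, a, var.equal = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-9)
  expect_lt(abs(res$p_adj - tt$p.value), 0.005)
  expect_gte(res$p_adj, res$p_raw - 0.005)
})

test_that("Dunnett agrees with an independent raw-data simulation oracle", {
  groups <- list(ctrl = c(4.9, 5.4, 5.1, 5.3, 4.8),
                 t1 = c(5.8, 6.1, 5.6, 6.0, 5.9),
                 t2 = c(5.0, 5.3, 5.2, 4.7, 5.1))
  res <- dunnett_test(groups, "ctrl", n_mc = 2e5)
  # oracle: simulate raw null samples, recompute the max-|t| distribution
  set.seed(909)
  n <- 5
  maxabs <- replicate(4e4, {
    x <- matrix(rnorm(3 * n), n)
    s2 <- sum((x - rep(colMeans(x), each = n))^2) / (3 * n - 3)
    tt <- (colMeans(x)[-1] - colMeans(x)[1]) / sqrt(s2 * (2 / n))
    max(abs(tt))
  })
  for (i in 1:2) {
    oracle_p <- mean(maxabs >= abs(res$t[i]))
    expect_lt(abs(res$p_adj[i] - oracle_p), 0.01)
  }
  # identical groups: adjusted p near 1
  same <- list(ctrl = c(1, 2, 3), a = c(1, 2, 3), b = c(1, 2, 3))
  expect_true(all(dunnett_test(same, "ctrl", n_mc = 2e4)$p_adj > 0.99))
  expect_error(dunnett_test(groups, "nope"), "control")
})

test_that("Benjamini-Hochberg step-up adjustment", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.04, 5)), rep(0.04, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27, 0.6)
  adj <- bh_fdr(p)
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_true(all(adj >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the full endpoint recipe aggregates to batch means", {
  dat <- data.frame(
    treatment = rep(c("vehicle", "drug"), each = 6),
    batch = rep(c("b1", "b2", "b1", "b2"), each = 3),
    value = c(1, 4, 9, 4, 9, 16, 16, 25, 36, 25, 36, 49)
  )
  st <- puncta_group_stats(dat, control = "vehicle", n_mc = 1e4)
  agg <- st$batch_means
  expect_equal(sort(agg$z), sort(c(mean(c(1, 2, 3)), mean(c(2, 3, 4)),
                                   mean(c(4, 5, 6)), mean(c(5, 6, 7)))))
  expect_identical(nrow(st$dunnett), 1L)
  expect_match(st$dunnett$comparison, "drug - vehicle")
})
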