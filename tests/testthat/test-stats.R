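test_that("pooled two-sample t-test matches hand computation", {
  r <- ttest_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  expect_equal(r$p_two_tailed, 0.0213, tolerance = 1e-3)
  same <- ttest_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_two_tailed, 1)
  expect_error(ttest_two_sample(c(1, 1), c(1, 1)), "zero pooled variance")
  expect_error(ttest_two_sample(1, c(1, 2)), "n >= 2")
  # Welch option exists and differs under variance heterogeneity
  w <- ttest_two_sample(c(1, 2, 3), c(2, 9, 16), var_equal = FALSE)
  expect_lt(w$df, 4)
})

test_that("summary path reproduces the raw path exactly", {
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(7 + i %% 5, 10, 3)
    b <- rnorm(9, 12, 2)
    raw <- ttest_two_sample(a, b)
    smry <- ttest_from_summary(group_summary(a), group_summary(b))
    expect_equal(smry$statistic, raw$statistic, tolerance = 1e-12)
    expect_equal(smry$df, raw$df)
    expect_equal(smry$p_two_tailed, raw$p_two_tailed, tolerance = 1e-12)
  }
  eq <- ttest_from_summary(group_summary(mean = 5, sem = 1, n = 10),
                           group_summary(mean = 5, sem = 2, n = 12))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_two_tailed, 1)
})

test_that("printed-table rows are reproduced from their summaries", {
  # apical total length, infralimbic L2/3 reconstruction table
  r1 <- ttest_from_summary(
    group_summary(mean = 592.80, sem = 63.95, n = 10),
    group_summary(mean = 802.39, sem = 72.07, n = 10))
  expect_lt(abs(r1$p_two_tailed - 0.0432), 2e-4)
  # input resistance, prelimbic L2/3 recording table
  r2 <- ttest_from_summary(
    group_summary(mean = 140.96, sem = 10.51, n = 28),
    group_summary(mean = 182.44, sem = 16.34, n = 31))
  expect_lt(abs(r2$p_two_tailed - 0.0415), 2e-4)
})

test_that("Sidak adjustment: closed forms, monotonicity, Bonferroni bound", {
  expect_equal(sidak_adjust(0.07, m = 1), 0.07)
  expect_equal(sidak_adjust(0.01, m = 10), 1 - 0.99^10)
  expect_equal(sidak_adjust(0.01, m = 10), 0.0956, tolerance = 1e-3)
  expect_equal(sidak_adjust(0.5, m = 10), 0.999, tolerance = 1e-3)
  p <- sort(runif(50))
  adj <- sidak_adjust(p, m = 8)
  expect_true(all(diff(adj) >= 0))
  expect_true(all(adj >= p - 1e-15))
  expect_true(all(adj <= pmin(1, 8 * p) + 1e-12))
})

test_that("quadratic fit: interpolation, linear data, degenerate design", {
  x <- c(-2, 0, 1, 3, 7)
  y <- 0.5 * x^2 - 1.2 * x + 3
  f <- poly2_fit(x, y)
  expect_equal(unname(f$coefficients), c(0.5, -1.2, 3), tolerance = 1e-10)
  flin <- poly2_fit(x, 2 * x + 1)
  expect_equal(unname(flin$coefficients["a"]), 0, tolerance = 1e-12)
  expect_error(poly2_fit(c(1, 1, 1), c(1, 2, 3)), "rank-deficient")
  expect_error(poly2_fit(c(1, 2), c(1, 2)), ">= 3")
})

test_that("quadratic fit linear coefficient is unbiased under noise", {
  set.seed(3)
  x <- seq(0, 10, length.out = 12)
  b_hat <- replicate(500, {
    y <- 0.3 * x^2 + 2 * x + 1 + rnorm(12, 0, 1)
    poly2_fit(x, y)$coefficients["b"]
  })
  mc_se <- sd(b_hat) / sqrt(length(b_hat))
  expect_lt(abs(mean(b_hat) - 2), 2 * mc_se + 1e-12)
})

test_that("two-way ANOVA matches a hand-partitioned 2x3 design", {
  # balanced 2x3, 4 replicates, hand-computable sums of squares
  set.seed(10)
  d <- expand.grid(rep = 1:4, A = c("g1", "g2"), B = c("b1", "b2", "b3"))
  d$y <- round(rnorm(nrow(d), 10, 3), 2)
  out <- anova_two_way(d, "y", "A", "B")

  # independent oracle: classical balanced-design partition
  g <- mean(d$y)
  ssA <- sum(tapply(d$y, d$A, function(v) length(v) * (mean(v) - g)^2))
  ssB <- sum(tapply(d$y, d$B, function(v) length(v) * (mean(v) - g)^2))
  cellm <- tapply(d$y, list(d$A, d$B), mean)
  ssCells <- 4 * sum((cellm - g)^2)
  ssAB <- ssCells - ssA - ssB
  ssE <- sum((d$y - cellm[cbind(d$A, d$B)])^2)
  expect_equal(out$ss, c(ssA, ssB, ssAB), tolerance = 1e-9)
  msE <- ssE / (nrow(d) - 6)
  expect_equal(out$F, c(ssA / 1, ssB / 2, ssAB / 2) / msE, tolerance = 1e-9)
  expect_equal(attr(out, "ss_total"),
               sum((d$y - g)^2), tolerance = 1e-9)
})

test_that("ANOVA sums of squares are conserved on random layouts", {
  set.seed(20)
  for (i in 1:30) {
    nA <- sample(2:3, 1); nB <- sample(2:4, 1)
    d <- expand.grid(rep = seq_len(sample(2:5, 1)), A = seq_len(nA),
                     B = seq_len(nB))
    d$y <- rnorm(nrow(d))
    out <- anova_two_way(d, "y", "A", "B")
    expect_equal(attr(out, "ss_total"),
                 sum((d$y - mean(d$y))^2), tolerance = 1e-9)
    expect_equal(sum(out$ss) + attr(out, "ss_residual"),
                 attr(out, "ss_total"), tolerance = 1e-9)
  }
})

test_that("ANOVA degenerate and invariance properties", {
  d <- expand.grid(rep = 1:3, A = 1:2, B = 1:3)
  d$y <- 5
  out <- anova_two_way(d, "y", "A", "B")
  expect_equal(out$F, c(0, 0, 0))
  expect_equal(out$p, c(1, 1, 1))
  # affine response rescaling with positive slope leaves F and p unchanged
  set.seed(30)
  d$y <- rnorm(nrow(d))
  o1 <- anova_two_way(d, "y", "A", "B")
  d2 <- d; d2$y <- 3.7 * d$y - 11
  o2 <- anova_two_way(d2, "y", "A", "B")
  expect_equal(o2$F, o1$F, tolerance = 1e-9)
  expect_equal(o2$p, o1$p, tolerance = 1e-9)
})

test_that("repeated-measures ANOVA uses the mixed partition", {
  set.seed(40)
  n_s <- 6; levels_b <- 4
  d <- expand.grid(subject = 1:(2 * n_s), B = seq_len(levels_b))
  d$A <- ifelse(d$subject <= n_s, "sham", "SNI")
  d$y <- rnorm(nrow(d)) + 0.5 * (d$A == "SNI") + 0.2 * d$B +
    rep(rnorm(2 * n_s), levels_b)  # subject random effect
  out <- anova_two_way(d, "y", "A", "B", subject = "subject",
                       repeated = TRUE)
  expect_equal(out$df1, c(1, 3, 3))
  expect_equal(out$df2, c(2 * n_s - 2, 3 * (2 * n_s - 2), 3 * (2 * n_s - 2)))
  # between-factor F tested against the subject stratum: replicate by
  # aggregating to subject means (classical equivalence)
  subj_means <- aggregate(y ~ subject + A, d, mean)
  f_between <- anova(aov(y ~ A, subj_means))
  expect_equal(out$F[1], f_between$`F value`[1] , tolerance = 1e-9)
  expect_equal(out$p[1], f_between$`Pr(>F)`[1], tolerance = 1e-9)

  # missing cell diagnostics
  d_miss <- d[!(d$subject == 3 & d$B == 2), ]
  expect_error(anova_two_way(d_miss, "y", "A", "B", subject = "subject",
                             repeated = TRUE),
               "subject 3 has no observation")
})

test_that("post-hoc Sidak comparisons per level", {
  set.seed(50)
  d <- expand.grid(rep = 1:8, A = c("sham", "SNI"), B = c("10", "20", "30"))
  d$y <- rnorm(nrow(d)) + ifelse(d$A == "SNI" & d$B == "20", 2, 0)
  ph <- posthoc_sidak(d, "y", "A", "B")
  expect_equal(nrow(ph), 3)
  expect_equal(ph$p_adj, sidak_adjust(ph$p, 3))
  expect_lt(ph$p_adj[ph$level == "20"], 0.05)
})

test_that("group table assembly: summaries, p per row, star flags", {
  set.seed(60)
  feats <- data.frame(
    group = rep(c("sham", "SNI"), each = 12),
    rmp_mV = c(rnorm(12, -77, 2), rnorm(12, -73, 2)),  # built-in effect
    tau_m_ms = rnorm(24, 25, 4))
  tab <- build_group_table(feats)
  expect_equal(sort(tab$feature), sort(c("rmp_mV", "tau_m_ms")))
  r <- tab[tab$feature == "rmp_mV", ]
  expect_true(r$star)
  raw <- ttest_two_sample(feats$rmp_mV[feats$group == "sham"],
                          feats$rmp_mV[feats$group == "SNI"])
  expect_equal(r$p, raw$p_two_tailed, tolerance = 1e-12)
  # single-group input: summaries only
  one <- build_group_table(feats[feats$group == "sham", ])
  expect_false("p" %in% names(one))
  # n < 2 in a group -> not testable
  small <- data.frame(group = c("sham", "sham", "SNI"), v = c(1, 2, 3))
  expect_false(build_group_table(small)$testable)
})
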