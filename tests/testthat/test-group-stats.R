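test_that("assumption checks report Shapiro-Wilk and Levene p-values", {
  # under a normal null both p-values are usually unremarkable
  clear <- sapply(1:20, function(seed) {
    set.seed(seed)
    g <- replicate(3, rnorm(50), simplify = FALSE)
    ck <- check_assumptions(g)
    min(ck$normality_p) > 0.05 && ck$homogeneity_p > 0.05
  })
  expect_gt(mean(clear), 0.6)

  # a strongly skewed group is detected with high probability
  caught <- sapply(1:20, function(seed) {
    set.seed(100 + seed)
    ck <- check_assumptions(list(rexp(200), rnorm(200), rnorm(200)))
    ck$normality_p[1] < 0.05
  })
  expect_gt(mean(caught), 0.9)

  # identical groups: homogeneity boundary handled without error
  ck <- check_assumptions(list(c(1, 1, 1), c(1, 1, 1)))
  expect_identical(ck$homogeneity_p, 1)
  expect_error(check_assumptions(list(1:2, 1:5)),
               class = "esportkin_config_error")
})

test_that("log bootstrap gives deterministic percentile CIs of the log mean", {
  b <- log_bootstrap(c(2, 2, 2), B = 200, seed = 1)
  expect_equal(b$ci, c(log(2), log(2)))
  expect_equal(b$mean, log(2))

  v <- rlnorm(30, 0, 0.5)
  b1 <- log_bootstrap(v, B = 500, seed = 99)
  b2 <- log_bootstrap(v, B = 500, seed = 99)
  expect_identical(b1$ci, b2$ci)
  b3 <- log_bootstrap(v, B = 500, seed = 100)
  expect_false(identical(b1$ci, b3$ci))

  expect_error(log_bootstrap(c(1, -2, 3), seed = 1), "index 2",
               class = "esportkin_transform_error")
})

test_that("bootstrap CI coverage of the log mean is near nominal", {
  hits <- sapply(1:1000, function(rep) {
    set.seed(3000 + rep)
    v <- rlnorm(30, meanlog = 0, sdlog = 0.5)
    ci <- log_bootstrap(v, B = 1000, level = 0.95, seed = 7000 + rep)$ci
    ci[1] <= 0 && 0 <= ci[2]
  })
  expect_lt(abs(mean(hits) - 0.95), 0.03)
})

test_that("one-way ANOVA reproduces the hand-worked decomposition", {
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  an <- one_way_anova(g)
  expect_equal(an$F, 3)
  expect_identical(c(an$df1, an$df2), c(2L, 6L))
  expect_equal(an$eta2, 0.5)

  ident <- one_way_anova(list(rep(2, 5), rep(2, 4)))
  expect_identical(c(ident$F, ident$eta2, ident$p), c(0, 0, 1))
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  for (seed in 1:5) {
    set.seed(seed)
    g1 <- rnorm(12, 0, 1); g2 <- rnorm(9, 0.8, 1)
    an <- one_way_anova(list(g1, g2))
    tt <- t.test(g1, g2, var.equal = TRUE)
    expect_lt(abs(an$F - unname(tt$statistic)^2), 1e-9)
    expect_lt(abs(an$p - tt$p.value), 1e-9)
  }
})

test_that("eta-squared from an F summary matches the SS decomposition identity", {
  expect_equal(round(eta_squared_from_summary(17.787, 2, 60), 3), 0.372)
  expect_equal(round(eta_squared_from_summary(21.468, 2, 60), 3), 0.417)
  expect_identical(eta_squared_from_summary(0, 2, 60), 0)
  for (seed in 1:5) {
    set.seed(10 + seed)
    g <- replicate(3, rnorm(8, sd = 2), simplify = FALSE)
    g[[2]] <- g[[2]] + 1
    an <- one_way_anova(g)
    expect_lt(abs(eta_squared_from_summary(an$F, an$df1, an$df2) - an$eta2),
              1e-9)
  }
})

test_that("Fisher LSD uses the pooled MSE with omnibus residual df", {
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  an <- one_way_anova(g)
  ph <- lsd_posthoc(g, an)
  ac <- ph[ph$pair == "a vs c", ]
  expect_equal(ac$t, -2.449, tolerance = 1e-3)
  expect_identical(ac$df, 6L)
  expect_equal(ac$p, 0.0499, tolerance = 5e-3)

  # identical pair within a varying family
  g2 <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(5, 6, 9))
  ph2 <- lsd_posthoc(g2, one_way_anova(g2))
  expect_identical(ph2[ph2$pair == "a vs b", "p"], 1)

  # p decreases monotonically with |mean difference| at fixed variance
  base <- c(-1, 0, 1)
  ps <- sapply(seq(0.5, 3, by = 0.5), function(d) {
    g3 <- list(a = base, b = base + d, c = base + 10)
    ph3 <- lsd_posthoc(g3, one_way_anova(g3))
    ph3[ph3$pair == "a vs b", "p"]
  })
  expect_true(all(diff(ps) < 0))
})

test_that("one-sample t test against a reference ratio", {
  r <- one_sample_t(c(1.1, 1.2, 1.3), mu0 = 1)
  expect_equal(r$t, 3.464, tolerance = 1e-3)
  expect_identical(r$df, 2)
  r0 <- one_sample_t(c(0.9, 1.1), mu0 = 1)
  expect_identical(c(r0$t, r0$p), c(0, 1))
  expect_error(one_sample_t(c(1, 1, 1)), class = "esportkin_degenerate_error")
})

test_that("chi-square contingency matches the O-E definition", {
  r <- chi_square_contingency(rbind(c(10, 0), c(0, 10)))
  expect_equal(r$chi2, 20)
  expect_identical(r$df, 1L)

  same <- chi_square_contingency(rbind(c(5, 10, 5), c(10, 20, 10)))
  expect_equal(same$chi2, 0)

  set.seed(9)
  tab <- matrix(rpois(9, 12) + 1L, 3, 3)
  r <- chi_square_contingency(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  brute <- 0
  for (i in 1:3) for (j in 1:3) brute <- brute + (tab[i, j] - E[i, j])^2 / E[i, j]
  expect_lt(abs(r$chi2 - brute), 1e-9)
  expect_identical(r$df, 4L)

  expect_error(chi_square_contingency(rbind(c(0, 0), c(3, 4))),
               class = "esportkin_degenerate_error")
})

test_that("Sidak thresholds follow the closed form and its limits", {
  expect_equal(round(sidak_threshold(9, 0.05), 3), 0.006)
  expect_equal(sidak_threshold(1, 0.05), 0.05)
  expect_equal(sidak_threshold(2, 0.05), 0.0253, tolerance = 1e-3)
  m <- 1:20
  th <- sapply(m, sidak_threshold, alpha = 0.05)
  expect_true(all(diff(th) < 0))
  # converges to the Bonferroni alpha/m as alpha -> 0
  expect_lt(abs(sidak_threshold(7, 1e-6) / (1e-6 / 7) - 1), 1e-4)
})

test_that("genre-by-DPI contingency applies the Sidak-corrected follow-ups", {
  genre <- rep(c("FPS", "MOBA", "Adventure"), times = c(32, 16, 15))
  set.seed(4)
  dpi <- c(sample(c(400, 1000, 1600), 32, TRUE, c(0.6, 0.3, 0.1)),
           sample(c(400, 1000, 1600), 16, TRUE, c(0.1, 0.2, 0.7)),
           sample(c(400, 1000, 1600), 15, TRUE, c(1, 1, 1) / 3))
  res <- dpi_contingency(genre, dpi)
  expect_identical(res$df, 4L)
  expect_identical(nrow(res$pairwise), 9L)
  expect_equal(res$sidak_alpha, sidak_threshold(9, 0.05))
  expect_true(all(res$pairwise$phi2 >= 0, na.rm = TRUE))
  res2 <- dpi_contingency(genre, dpi)
  expect_identical(res, res2)
})
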