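test_that("global magnitude implements both norm modes", {
  expect_identical(global_magnitude(3, 4, 0, "as_printed"), 7)
  expect_identical(global_magnitude(3, 4, 0, "euclidean"), 5)
  expect_identical(global_magnitude(0, 0, 0, "as_printed"), 0)
  expect_identical(global_magnitude(0, 0, 0, "euclidean"), 0)
  expect_identical(global_magnitude(-1, -1, -1, "as_printed"), 3)
  expect_error(global_magnitude(1:3, 1:2, 1:3), class = "esportkin_format_error")

  # L1-of-absolutes dominates the euclidean norm frame by frame
  set.seed(1)
  x <- rnorm(500); y <- rnorm(500); z <- rnorm(500)
  expect_true(all(global_magnitude(x, y, z, "as_printed") >=
                    global_magnitude(x, y, z, "euclidean")))
})

test_that("rms matches closed forms", {
  expect_identical(rms(rep(-3, 10)), 3)
  t <- seq(0, 10, by = 1 / 500)
  expect_lt(abs(rms(sin(2 * pi * 3 * t)) - 1 / sqrt(2)), 1e-3)
  expect_error(rms(numeric(0)), class = "esportkin_format_error")
})

test_that("segment ratios divide distal by proximal RMS", {
  r <- segment_ratios(2, 1, 0.5)
  expect_identical(c(r$hand_forearm_ratio, r$forearm_arm_ratio), c(2, 2))
  r <- segment_ratios(1.3, 1.3, 1.3)
  expect_identical(c(r$hand_forearm_ratio, r$forearm_arm_ratio), c(1, 1))
  r <- segment_ratios(1, 2, 4)
  expect_identical(c(r$hand_forearm_ratio, r$forearm_arm_ratio), c(0.5, 0.5))
  expect_error(segment_ratios(1, 0, 1), class = "esportkin_degenerate_error")
})

test_that("zero-crossing counting sums per-axis sign flips with zeros carried forward", {
  ones <- rep(1, 4)
  expect_identical(count_zero_crossings(c(1, -1, 1, -1), ones, ones), 3L)
  expect_identical(count_zero_crossings(ones, ones, ones), 0L)
  # an exact zero carries the previous sign: no double count on touch-and-go
  expect_identical(count_zero_crossings(c(1, 0, 1, -1), ones, ones), 1L)
  expect_identical(count_zero_crossings(c(1, 0, -1, 1), ones, ones), 2L)
  # deadband flattens small oscillations
  v <- c(1, -0.01, 0.01, -1)
  expect_identical(count_zero_crossings(v, ones, ones, deadband = 0), 3L)
  expect_identical(count_zero_crossings(v, ones, ones, deadband = 0.05), 1L)

  # brute-force oracle on a phase-shifted sine
  t <- seq(0, 10, by = 1 / 500)
  v <- sin(2 * pi * 1 * t + 0.1)
  brute <- 0L
  prev <- sign(v[1])
  for (i in 2:length(v)) {
    s <- sign(v[i])
    if (s == 0) s <- prev
    if (s * prev < 0) brute <- brute + 1L
    prev <- s
  }
  expect_identical(count_zero_crossings(v, rep(1, length(v)),
                                        rep(1, length(v))), brute)
})

test_that("cumulative distance sums absolute displacement changes", {
  expect_equal(cumulative_distance(c(0, 0.1, 0.3, 0.2)), 0.4)
  ramp <- seq(0, 2.5, length.out = 100)
  expect_equal(cumulative_distance(ramp), 2.5)
  set.seed(2)
  d <- cumsum(rnorm(200))
  expect_equal(cumulative_distance(d), cumulative_distance(rev(d)))
  # additive under concatenation at a shared endpoint
  expect_equal(cumulative_distance(d[1:100]) + cumulative_distance(d[100:200]),
               cumulative_distance(d))
  expect_error(cumulative_distance(1), class = "esportkin_format_error")
})

test_that("confidence ellipse recovers Gaussian geometry", {
  set.seed(7)
  q95 <- qchisq(0.95, 2)
  iso <- cbind(rnorm(1e5), rnorm(1e5))
  fit <- fit_confidence_ellipse(iso, 0.95)
  expect_lt(abs(fit$area_cm2 / (pi * q95) - 1), 0.02)
  expect_lt(abs(fit$long_short_ratio - 1), 0.02)

  ani <- cbind(rnorm(1e5, sd = 2), rnorm(1e5, sd = 1))
  fit <- fit_confidence_ellipse(ani, 0.95)
  expect_lt(abs(fit$long_short_ratio / 2 - 1), 0.02)

  expect_error(fit_confidence_ellipse(cbind(1:3, 2 * (1:3))),
               class = "esportkin_degenerate_error")
  expect_error(fit_confidence_ellipse(cbind(1:2, c(1, 2))),
               class = "esportkin_degenerate_error")
})

test_that("ellipse fits are scale-equivariant and rotation-invariant", {
  set.seed(8)
  pts <- cbind(rnorm(400, sd = 3), rnorm(400, sd = 1.2))
  fit <- fit_confidence_ellipse(pts)
  s <- 2.5
  fs <- fit_confidence_ellipse(pts * s)
  expect_lt(abs(fs$a / (s * fit$a) - 1), 1e-9)
  expect_lt(abs(fs$b / (s * fit$b) - 1), 1e-9)
  expect_lt(abs(fs$area_cm2 / (s^2 * fit$area_cm2) - 1), 1e-9)
  expect_lt(abs(fs$long_short_ratio / fit$long_short_ratio - 1), 1e-9)

  th <- 0.73
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  fr <- fit_confidence_ellipse(pts %*% R)
  expect_lt(abs(fr$area_cm2 / fit$area_cm2 - 1), 1e-9)
  expect_lt(abs(fr$long_short_ratio / fit$long_short_ratio - 1), 1e-9)
})

test_that("every metric agrees with an independent single-loop reference", {
  set.seed(42)
  for (rep in 1:5) {
    x <- rnorm(100); y <- rnorm(100); z <- rnorm(100)

    l1 <- l2 <- numeric(100)
    for (i in 1:100) {
      l1[i] <- abs(x[i]) + abs(y[i]) + abs(z[i])
      l2[i] <- sqrt(x[i]^2 + y[i]^2 + z[i]^2)
    }
    expect_lt(max(abs(global_magnitude(x, y, z, "as_printed") - l1)), 1e-9)
    expect_lt(max(abs(global_magnitude(x, y, z, "euclidean") - l2)), 1e-9)

    acc <- 0
    for (i in 1:100) acc <- acc + l1[i]^2
    expect_lt(abs(rms(l1) - sqrt(acc / 100)), 1e-9)

    cd <- 0
    for (i in 2:100) cd <- cd + abs(l2[i] - l2[i - 1])
    expect_lt(abs(cumulative_distance(l2) - cd), 1e-9)

    zc <- 0L
    for (ax in list(x, y, z)) {
      prev <- sign(ax[1])
      for (i in 2:100) {
        s <- sign(ax[i]); if (s == 0) s <- prev
        if (s * prev < 0) zc <- zc + 1L
        prev <- s
      }
    }
    expect_identical(count_zero_crossings(x, y, z), zc)

    # ellipse via explicit sums and the 2x2 closed-form eigenvalues
    mx <- sum(x) / 100; my <- sum(y) / 100
    sxx <- sxy <- syy <- 0
    for (i in 1:100) {
      sxx <- sxx + (x[i] - mx)^2
      syy <- syy + (y[i] - my)^2
      sxy <- sxy + (x[i] - mx) * (y[i] - my)
    }
    sxx <- sxx / 99; syy <- syy / 99; sxy <- sxy / 99
    disc <- sqrt(((sxx - syy) / 2)^2 + sxy^2)
    lam1 <- (sxx + syy) / 2 + disc
    lam2 <- (sxx + syy) / 2 - disc
    q <- qchisq(0.95, 2)
    fit <- fit_confidence_ellipse(cbind(x, y))
    expect_lt(abs(fit$a - sqrt(q * lam1)), 1e-9)
    expect_lt(abs(fit$b - sqrt(q * lam2)), 1e-9)
    expect_lt(abs(fit$area_cm2 - pi * sqrt(q * lam1) * sqrt(q * lam2)), 1e-9)
  }
})

test_that("session summaries are deterministic and flag degenerate geometry", {
  sim <- preset_session("MOBA", seed = 31, duration_s = 20)
  cfg <- preprocess_config()
  pr <- lapply(c("hand", "forearm", "arm"),
               function(p) preprocess_sensor(sim$session[[p]], cfg))
  s1 <- summarize_session(pr[[1]], pr[[2]], pr[[3]], cfg)
  s2 <- summarize_session(pr[[1]], pr[[2]], pr[[3]], cfg)
  expect_identical(s1, s2)
  expect_false(s1$ellipse_degenerate)
  expect_gt(s1$hand_rms, 0)

  # motionless session: near-zero metrics, ellipse flagged not thrown
  m <- matrix(rep(c(120, -80, 975), each = 5000, times = 3), 5000, 9)
  still <- session_from_matrix(m)
  prs <- lapply(c("hand", "forearm", "arm"),
                function(p) preprocess_sensor(still[[p]], cfg))
  summ <- summarize_session(prs[[1]], prs[[2]], prs[[3]], cfg)
  expect_lt(summ$hand_rms, 0.01)
  expect_lt(summ$cumulative_distance_m, 0.01)
  expect_true(summ$ellipse_degenerate)
  expect_true(is.na(summ$hand_forearm_ratio))
})

test_that("an isotropic movement field yields a near-circular ellipse", {
  ratios <- sapply(c(11, 23, 31), function(seed) {
    spec <- synthetic_spec("MOBA", event_rate_hz = 5, amp_mean_cm = 2,
                           amp_sd_cm = 0.5, spatial_cov_cm2 = diag(c(4, 4)),
                           move_dur_s = c(0.08, 0.12), duration_s = 600,
                           seed = seed)
    sim <- simulate_session(spec)
    h <- preprocess_sensor(sim$session$hand)
    fit_confidence_ellipse(cbind(h$disp_x$samples, h$disp_y$samples) * 100)$
      long_short_ratio
  })
  expect_lt(median(abs(ratios - 1)), 0.05)
})
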