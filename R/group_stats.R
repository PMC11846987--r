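as_group_list <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    ek_stop("need a list of at least 2 groups", "esportkin_config_error")
  }
  lapply(groups, as.numeric)
}

#' Check distributional assumptions per group
#'
#' Shapiro-Wilk normality test within each group and Levene's test (absolute
#' deviations from the group mean, the SPSS default) for homogeneity of
#' variance across groups. Reporting only: no accept/reject decision is
#' taken here.
#'
#' @param groups Named list of numeric vectors, each of length >= 3.
#' @return List with `normality_p` (named per group) and `homogeneity_p`.
#' @export
check_assumptions <- function(groups) {
  groups <- as_group_list(groups)
  if (any(lengths(groups) < 3L)) {
    ek_stop("each group needs n >= 3", "esportkin_config_error")
  }
  normality_p <- vapply(groups, function(g) {
    if (stats::sd(g) == 0) return(NA_real_)  # shapiro.test rejects constants
    stats::shapiro.test(g)$p.value
  }, double(1))
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), lengths(groups)))
  # boundary: zero spread deviations everywhere => no evidence against
  # homogeneity; report p = 1 instead of propagating 0/0
  dev <- abs(values - stats::ave(values, fac))
  homogeneity_p <- if (all(dev == 0)) 1 else {
    lt <- car::leveneTest(values, fac, center = mean)
    lt[["Pr(>F)"]][1L]
  }
  list(normality_p = normality_p, homogeneity_p = homogeneity_p)
}

# Save/restore the global RNG state so seeded helpers are deterministic
# without disturbing the caller's random stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Log transform with a bootstrap CI of the transformed mean
#'
#' Natural-log transforms a positive sample and computes a percentile
#' bootstrap confidence interval of the transformed mean from `B` simple
#' resamples with replacement. Deterministic given `seed`.
#'
#' @param values Positive numeric vector.
#' @param B Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed (optional; required for reproducibility).
#' @return List with `transformed`, `mean`, and `ci` (length-2 vector).
#' @export
log_bootstrap <- function(values, B = 1000, level = 0.95, seed = NULL) {
  values <- as.numeric(values)
  if (any(values <= 0)) {
    ek_stop(sprintf("nonpositive value at index %d cannot be log-transformed",
                    which(values <= 0)[1L]),
            "esportkin_transform_error")
  }
  if (B < 1) ek_stop("B must be >= 1", "esportkin_config_error")
  lv <- log(values)
  n <- length(lv)
  boot_means <- with_local_seed(seed, {
    vapply(seq_len(B), function(i) mean(lv[sample.int(n, n, replace = TRUE)]),
           double(1))
  })
  alpha <- 1 - level
  ci <- unname(stats::quantile(boot_means, c(alpha / 2, 1 - alpha / 2),
                               type = 7))
  list(transformed = lv, mean = mean(lv), ci = ci)
}

#' One-way between-groups ANOVA with eta-squared
#'
#' Standard between/within sum-of-squares decomposition over k groups, with
#' effect size `eta2 = SS_between / SS_total`. If every value is identical
#' the decomposition is degenerate and F = 0 (not an error).
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return An object of class `group_comparison`: `F`, `df1`, `df2`, `p`,
#'   `eta2`, group `means`, pooled `mse`, and (after [lsd_posthoc()]) the
#'   pairwise `posthoc` table.
#' @export
one_way_anova <- function(groups) {
  groups <- as_group_list(groups)
  if (any(lengths(groups) < 2L)) {
    ek_stop("each group needs n >= 2", "esportkin_config_error")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  df1 <- nlevels(fac) - 1L
  df2 <- length(values) - nlevels(fac)
  if (stats::sd(values) == 0) {
    out <- list(F = 0, df1 = df1, df2 = df2, p = 1, eta2 = 0,
                means = vapply(groups, mean, double(1)), mse = 0,
                n = lengths(groups), posthoc = NULL)
    return(structure(out, class = "group_comparison"))
  }
  fit <- stats::anova(stats::lm(values ~ fac))
  ss_between <- fit[["Sum Sq"]][1L]
  ss_within <- fit[["Sum Sq"]][2L]
  structure(list(F = fit[["F value"]][1L], df1 = df1, df2 = df2,
                 p = fit[["Pr(>F)"]][1L],
                 eta2 = ss_between / (ss_between + ss_within),
                 means = vapply(groups, mean, double(1)),
                 mse = ss_within / df2, n = lengths(groups), posthoc = NULL),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison: F(%d,%d) = %.3f, p = %.4g, eta2 = %.3f>\n",
              x$df1, x$df2, x$F, x$p, x$eta2))
  invisible(x)
}

#' Fisher LSD post hoc pairwise comparisons
#'
#' Unadjusted pairwise t tests using the pooled within-group mean square of
#' the omnibus ANOVA with its residual degrees of freedom. By definition no
#' multiplicity correction is applied; the omnibus F gates interpretation,
#' not computation.
#'
#' @param groups The same list of groups passed to [one_way_anova()].
#' @param anova The corresponding `group_comparison`.
#' @return Data frame with columns `pair`, `diff`, `t`, `df`, `p`.
#' @export
lsd_posthoc <- function(groups, anova) {
  groups <- as_group_list(groups)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  if (!identical(unname(lengths(groups)), unname(anova$n))) {
    ek_stop("groups do not match the ANOVA they were tested with",
            "esportkin_config_error")
  }
  combs <- utils::combn(names(groups), 2L)
  rows <- apply(combs, 2L, function(pair) {
    g1 <- groups[[pair[1L]]]; g2 <- groups[[pair[2L]]]
    d <- mean(g1) - mean(g2)
    if (anova$mse == 0) {
      tval <- if (d == 0) 0 else Inf
    } else {
      tval <- d / sqrt(anova$mse * (1 / length(g1) + 1 / length(g2)))
    }
    p <- if (is.infinite(tval)) 0 else 2 * stats::pt(-abs(tval), anova$df2)
    data.frame(pair = paste(pair, collapse = " vs "), diff = d, t = tval,
               df = anova$df2, p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Eta-squared from a reported one-way ANOVA summary
#'
#' For a one-way design `eta2 = SS_between / SS_total` is recoverable from
#' the F statistic and its degrees of freedom alone:
#' `df1*F / (df1*F + df2)`.
#'
#' @param F F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return Eta-squared in `[0, 1]`.
#' @export
eta_squared_from_summary <- function(F, df1, df2) {
  if (F < 0 || df1 < 1 || df2 < 1) {
    ek_stop("need F >= 0 and dfs >= 1", "esportkin_config_error")
  }
  df1 * F / (df1 * F + df2)
}

#' One-sample t test against a reference value
#'
#' Used for the ellipse long:short axis ratio against 1 (a circular
#' displacement footprint), on the raw ratio scale.
#'
#' @param values Numeric sample (n >= 2, nonzero variance).
#' @param mu0 Reference value (default 1).
#' @return List with `t`, `df`, `p`, `mu0`, `mean`.
#' @export
one_sample_t <- function(values, mu0 = 1) {
  values <- as.numeric(values)
  if (length(values) < 2L) ek_stop("need n >= 2", "esportkin_config_error")
  if (stats::sd(values) == 0) {
    ek_stop("zero variance sample (degenerate)", "esportkin_degenerate_error")
  }
  tt <- stats::t.test(values, mu = mu0)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mu0 = mu0, mean = mean(values))
}

#' Pearson chi-square test of a contingency table
#'
#' Omnibus test without continuity correction, df = (r-1)(c-1).
#'
#' @param table Matrix of nonnegative integer counts (>= 2 rows and columns).
#' @return List with `chi2`, `df`, `p`, `n`, `expected`.
#' @export
chi_square_contingency <- function(table) {
  tab <- as.matrix(table)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    ek_stop("table needs at least 2 rows and 2 columns",
            "esportkin_format_error")
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    ek_stop("counts must be nonnegative integers", "esportkin_format_error")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    ek_stop("zero row or column marginal (degenerate table)",
            "esportkin_degenerate_error")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, n = sum(tab), expected = ct$expected)
}

#' Sidak-corrected per-comparison significance threshold
#'
#' `1 - (1 - alpha)^(1/m)` controls the family-wise error over m independent
#' comparisons; e.g. m = 9 at alpha = 0.05 gives 0.00568 (printed as 0.006).
#'
#' @param m Number of comparisons (>= 1).
#' @param alpha Family-wise significance level in (0, 1).
#' @return Corrected per-comparison alpha.
#' @export
sidak_threshold <- function(m, alpha = 0.05) {
  if (m < 1) ek_stop("m must be >= 1", "esportkin_config_error")
  if (!(alpha > 0 && alpha < 1)) {
    ek_stop("alpha must be in (0, 1)", "esportkin_config_error")
  }
  1 - (1 - alpha)^(1 / m)
}

#' Genre-by-DPI contingency analysis with Sidak correction
#'
#' Omnibus Pearson chi-square on the genre x DPI count table, followed by
#' pairwise 2x2 follow-ups: for each DPI level and each genre pair, a
#' chose-this-DPI vs not table, 9 comparisons in total, each assessed
#' against the Sidak-corrected threshold. Pairwise effect sizes are phi
#' squared (`chi2 / n`).
#'
#' @param genre Factor/character vector of session genres.
#' @param dpi Integer vector of DPI settings (NA rows are dropped).
#' @param alpha Family-wise level (default 0.05).
#' @return An object of class `contingency_result`: omnibus `chi2`, `df`,
#'   `p`, the count `table`, `pairwise` data frame (comparison, chi2, p,
#'   phi2, significant flag) and `sidak_alpha`.
#' @export
dpi_contingency <- function(genre, dpi, alpha = 0.05) {
  keep <- !is.na(dpi)
  genre <- factor(genre[keep], levels = GENRES)
  dpi <- factor(dpi[keep], levels = DPI_LEVELS)
  tab <- table(genre, dpi)
  omni <- chi_square_contingency(tab)
  pairs <- utils::combn(rownames(tab), 2L)
  m <- ncol(pairs) * ncol(tab)
  sidak_alpha <- sidak_threshold(m, alpha)
  rows <- list()
  for (lev in colnames(tab)) {
    for (j in seq_len(ncol(pairs))) {
      g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
      sub <- rbind(c(tab[g1, lev], sum(tab[g1, ]) - tab[g1, lev]),
                   c(tab[g2, lev], sum(tab[g2, ]) - tab[g2, lev]))
      res <- tryCatch(chi_square_contingency(sub),
                      esportkin_degenerate_error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        dpi = lev, comparison = paste(g1, "vs", g2),
        chi2 = if (is.null(res)) NA_real_ else res$chi2,
        p = if (is.null(res)) NA_real_ else res$p,
        phi2 = if (is.null(res)) NA_real_ else res$chi2 / res$n,
        significant = if (is.null(res)) FALSE else res$p <= sidak_alpha,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(chi2 = omni$chi2, df = omni$df, p = omni$p,
                 table = unclass(tab), pairwise = do.call(rbind, rows),
                 sidak_alpha = sidak_alpha, alpha = alpha),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("<contingency_result: chi2(%d) = %.3f, p = %.4g, sidak alpha = %.4g>\n",
              x$df, x$chi2, x$p, x$sidak_alpha))
  invisible(x)
}
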