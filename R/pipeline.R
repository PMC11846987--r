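COHORT_METRICS <- c("hand_rms", "hand_forearm_ratio", "forearm_arm_ratio",
                    "zero_crossings", "cumulative_distance_m",
                    "ellipse_area_cm2")

resolve_session <- function(x, metadata = NULL) {
  if (inherits(x, "session")) return(x)
  read_session(x, metadata = metadata)
}

#' Process one session into a metrics-table row
#'
#' Reads (or accepts) a session, pre-processes all three sensors, and
#' summarizes it into one row of the per-session metrics table.
#'
#' @param session_or_path A [session()] or a recording CSV path.
#' @param config A [preprocess_config()].
#' @param deadband Velocity deadband for zero-crossing counting (m/s).
#' @param coverage Ellipse coverage level.
#' @param verbose Log stage progress to stderr.
#' @return One-row data frame in the metrics-table column order.
#' @export
run_session <- function(session_or_path, config = preprocess_config(),
                        deadband = 0, coverage = 0.95, verbose = FALSE) {
  s <- resolve_session(session_or_path)
  log_msg <- function(fmt, ...) {
    if (verbose) message(sprintf(paste0("[%s] ", fmt), s$participant_id, ...))
  }
  t0 <- proc.time()[["elapsed"]]
  processed <- lapply(PLACEMENTS, function(p) preprocess_sensor(s[[p]], config))
  names(processed) <- PLACEMENTS
  log_msg("preprocess: %.2fs, fraction unchanged %.4f",
          proc.time()[["elapsed"]] - t0,
          mean(vapply(processed, `[[`, 0, "fraction_unchanged")))
  summ <- summarize_session(processed$hand, processed$forearm, processed$arm,
                            config, deadband = deadband, coverage = coverage)
  log_msg("metrics: rms %.3g m/s^2, distance %.3g m", summ$hand_rms,
          summ$cumulative_distance_m)
  summary_row(s, summ)
}

#' Run the cohort-level analysis
#'
#' Builds the per-session metrics table, then for each kinematic metric runs
#' the assumption checks, log transform with bootstrap CIs per group, the
#' one-way genre ANOVA with eta-squared and Fisher LSD post hocs; a
#' genre-by-DPI contingency analysis with Sidak-corrected pairwise
#' follow-ups; and a one-sample t test of the ellipse long:short ratio
#' against 1 per genre.
#'
#' @param sessions List of [session()] objects or recording CSV paths
#'   (>= 2 genres, each with >= 3 sessions).
#' @param config A [preprocess_config()].
#' @param seed Integer seed driving the bootstrap streams.
#' @param alpha Family-wise significance level (default 0.05).
#' @param bootstrap_n Bootstrap resamples per CI (default 1000).
#' @param coverage Ellipse coverage level (default 0.95).
#' @param deadband Velocity deadband for zero-crossing counts (m/s).
#' @param out_dir Optional directory: writes `metrics.csv` and
#'   `cohort_report.json` there.
#' @param verbose Log progress to stderr.
#' @return An object of class `cohort_report`: `metrics_table`,
#'   `comparisons` (one per metric: assumptions, bootstrap CIs, ANOVA,
#'   posthoc), `dpi_analysis`, `shape_tests`, `config_echo`, `seed`.
#' @export
run_cohort <- function(sessions, config = preprocess_config(), seed = 1L,
                       alpha = 0.05, bootstrap_n = 1000, coverage = 0.95,
                       deadband = 0, out_dir = NULL, verbose = FALSE) {
  sessions <- lapply(sessions, resolve_session)
  genres <- vapply(sessions, `[[`, "", "genre")
  counts <- table(genres)
  if (length(counts) < 2L || any(counts < 3L)) {
    ek_stop("need >= 2 genres with >= 3 sessions each",
            "esportkin_config_error")
  }
  rows <- lapply(sessions, run_session, config = config, deadband = deadband,
                 coverage = coverage, verbose = verbose)
  metrics <- do.call(rbind, rows)

  comparisons <- list()
  for (m in COHORT_METRICS) {
    vals <- metrics[[m]]
    ok <- is.finite(vals)
    groups <- split(vals[ok], factor(genres[ok], levels = unique(genres)))
    groups <- groups[lengths(groups) > 0L]
    boot <- lapply(seq_along(groups), function(i) {
      log_bootstrap(groups[[i]], B = bootstrap_n, level = coverage,
                    seed = (seed + 31L * i + match(m, COHORT_METRICS)) %%
                      2147483647L)
    })
    names(boot) <- names(groups)
    log_groups <- lapply(boot, `[[`, "transformed")
    an <- one_way_anova(log_groups)
    an$posthoc <- lsd_posthoc(log_groups, an)
    comparisons[[m]] <- list(
      variable = m,
      assumptions = check_assumptions(groups),
      assumptions_log = check_assumptions(log_groups),
      bootstrap_ci = lapply(boot, function(b) {
        list(mean_log = b$mean, ci_log = b$ci)
      }),
      anova = an)
  }

  shape_tests <- lapply(split(metrics$ellipse_long_short, genres), function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2L || stats::sd(v) == 0) return(NULL)
    one_sample_t(v, mu0 = 1)
  })

  dpi_analysis <- if (sum(!is.na(metrics$dpi)) >= 4L &&
                      length(unique(genres[!is.na(metrics$dpi)])) >= 2L) {
    tryCatch(dpi_contingency(metrics$genre, metrics$dpi, alpha),
             esportkin_error = function(e) NULL)
  } else NULL

  report <- structure(list(metrics_table = metrics,
                           comparisons = comparisons,
                           dpi_analysis = dpi_analysis,
                           shape_tests = shape_tests,
                           config_echo = c(unclass(config),
                                           list(alpha = alpha,
                                                bootstrap_n = bootstrap_n,
                                                coverage = coverage,
                                                deadband = deadband)),
                           seed = seed),
                      class = "cohort_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_metrics_table(metrics, file.path(out_dir, "metrics.csv"))
    write_cohort_report(report, file.path(out_dir, "cohort_report.json"))
  }
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report: %d sessions, %d metric comparisons, seed %d>\n",
              nrow(x$metrics_table), length(x$comparisons), x$seed))
  for (m in names(x$comparisons)) {
    an <- x$comparisons[[m]]$anova
    cat(sprintf("  %-22s F(%d,%d) = %7.3f, p = %.4g, eta2 = %.3f\n",
                m, an$df1, an$df2, an$F, an$p, an$eta2))
  }
  invisible(x)
}
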