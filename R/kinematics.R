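#' Per-frame global magnitude of a tri-axial signal
#'
#' Combines the x, y, z component traces into one nonnegative magnitude
#' trace. `"as_printed"` returns the per-frame sum of absolute components
#' `|x| + |y| + |z|`; `"euclidean"` returns `sqrt(x^2 + y^2 + z^2)`. The
#' sum-of-absolutes form is the session default; the Euclidean option is the
#' conventional vector norm and is never smaller than 1/sqrt(3) of it.
#'
#' @param x,y,z Numeric component vectors of equal length.
#' @param norm_mode `"as_printed"` or `"euclidean"`.
#' @return Numeric magnitude vector.
#' @export
global_magnitude <- function(x, y, z,
                             norm_mode = c("as_printed", "euclidean")) {
  norm_mode <- match.arg(norm_mode)
  if (length(x) != length(y) || length(y) != length(z)) {
    ek_stop("component traces have unequal length", "esportkin_format_error")
  }
  if (norm_mode == "as_printed") abs(x) + abs(y) + abs(z)
  else sqrt(x^2 + y^2 + z^2)
}

#' Root mean square of a trace
#'
#' @param x Numeric vector (length >= 1).
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x) {
  if (length(x) < 1L) ek_stop("empty trace", "esportkin_format_error")
  sqrt(mean(x^2))
}

#' Limb-segment RMS acceleration ratios
#'
#' Distal-over-proximal ratios of the per-segment global RMS accelerations:
#' hand:forearm and forearm:arm. Ratios above 1 indicate a segment moving
#' with larger acceleration magnitude than its proximal neighbour.
#'
#' @param hand_rms,forearm_rms,arm_rms Per-segment RMS accelerations (m/s^2).
#' @return Named list with `hand_forearm_ratio` and `forearm_arm_ratio`.
#' @export
segment_ratios <- function(hand_rms, forearm_rms, arm_rms) {
  if (forearm_rms <= 0 || arm_rms <= 0) {
    ek_stop("zero RMS denominator (degenerate signal)",
            "esportkin_degenerate_error")
  }
  list(hand_forearm_ratio = hand_rms / forearm_rms,
       forearm_arm_ratio = forearm_rms / arm_rms)
}

# Signed zero-crossing count of one velocity axis. Samples with
# |v| <= deadband are treated as zero; exact zeros carry the previous sign
# forward, so a touch-and-return does not count as two crossings.
count_axis_crossings <- function(v, deadband) {
  s <- sign(v)
  s[abs(v) <= deadband] <- 0
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-1L] * s[-length(s)] < 0)
}

#' Count velocity zero-crossings over the three axes
#'
#' The repetitive-motion index: per axis, counts sign flips between
#' consecutive effective samples (product < 0), with exact zeros carrying the
#' previous sign forward, and sums the three axis counts. A deadband above 0
#' treats small |v| as zero, suppressing noise-inflated counts during idle
#' periods (the zero-crossing rate of band-limited sensor noise does not
#' shrink with its amplitude, so raw counts are dominated by noise whenever
#' the hand rests).
#'
#' @param vx,vy,vz Velocity component vectors of equal length (m/s).
#' @param deadband Velocity magnitude below which samples count as zero
#'   (m/s, default 0).
#' @return Integer total count.
#' @export
count_zero_crossings <- function(vx, vy, vz, deadband = 0) {
  if (length(vx) != length(vy) || length(vy) != length(vz)) {
    ek_stop("velocity traces have unequal length", "esportkin_format_error")
  }
  if (deadband < 0) ek_stop("deadband must be >= 0", "esportkin_config_error")
  count_axis_crossings(vx, deadband) +
    count_axis_crossings(vy, deadband) +
    count_axis_crossings(vz, deadband)
}

#' Cumulative distance travelled
#'
#' Sum of absolute frame-to-frame changes of the global displacement trace.
#'
#' @param disp_global Global displacement magnitude trace (m), length >= 2.
#' @return Total distance in metres.
#' @export
cumulative_distance <- function(disp_global) {
  if (length(disp_global) < 2L) {
    ek_stop("need at least 2 displacement frames", "esportkin_format_error")
  }
  sum(abs(diff(disp_global)))
}

#' Fit a coverage (confidence) ellipse to 2D displacement points
#'
#' Fits the ellipse containing the requested fraction of a Gaussian point
#' cloud: the sample covariance of the points is eigen-decomposed and the
#' semi-axes are `sqrt(q * lambda)` with `q` the chi-square quantile at the
#' coverage level with 2 degrees of freedom (q = 5.9915 at 0.95). This is a
#' population-coverage ellipse of the displacement cloud, not a standard
#' error ellipse of its mean.
#'
#' @param points Two-column matrix (or data frame) of x, y displacement
#'   coordinates in cm; at least 3 non-collinear rows.
#' @param coverage Coverage level (default 0.95).
#' @return An object of class `ellipse_fit` with semi-axes `a >= b` (cm),
#'   `area_cm2 = pi*a*b`, `long_short_ratio = a/b`, `center`,
#'   `orientation_rad` and `coverage`.
#' @export
fit_confidence_ellipse <- function(points, coverage = 0.95) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) ek_stop("points must have 2 columns",
                               "esportkin_format_error")
  if (nrow(pts) < 3L) ek_stop("need at least 3 points",
                              "esportkin_degenerate_error")
  if (!(coverage > 0 && coverage < 1)) {
    ek_stop("coverage must be in (0, 1)", "esportkin_config_error")
  }
  S <- stats::cov(pts)
  eig <- eigen(S, symmetric = TRUE)
  lambda <- eig$values
  if (lambda[2L] <= 1e-12 * max(lambda[1L], 1)) {
    ek_stop("points are (near-)collinear: degenerate ellipse geometry",
            "esportkin_degenerate_error")
  }
  q <- stats::qchisq(coverage, df = 2)
  a <- sqrt(q * lambda[1L])
  b <- sqrt(q * lambda[2L])
  structure(list(a = a, b = b, area_cm2 = pi * a * b,
                 long_short_ratio = a / b,
                 center = colMeans(pts),
                 orientation_rad = atan2(eig$vectors[2L, 1L],
                                         eig$vectors[1L, 1L]),
                 coverage = coverage),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("<ellipse_fit %g%%: a=%.3g cm, b=%.3g cm, area=%.3g cm^2, a/b=%.3g>\n",
              100 * x$coverage, x$a, x$b, x$area_cm2, x$long_short_ratio))
  invisible(x)
}

#' Summarize one session into its kinematic metrics
#'
#' Assembles the per-session metric suite from the three pre-processed limb
#' segments: per-segment RMS global acceleration, the two segment ratios,
#' the summed hand-velocity zero-crossing count, the cumulative hand travel
#' distance, and the coverage ellipse of the hand's x-y displacement (in cm).
#' A motionless session yields a degenerate displacement cloud; the summary
#' is then flagged (`ellipse_degenerate = TRUE`) with `NA` ellipse fields
#' rather than failing.
#'
#' @param hand,forearm,arm `processed_signals` from [preprocess_sensor()].
#' @param config The [preprocess_config()] used (echoed into the summary).
#' @param deadband Velocity deadband for the zero-crossing count (m/s).
#' @param coverage Ellipse coverage level (default 0.95).
#' @return An object of class `kinematic_summary`.
#' @export
summarize_session <- function(hand, forearm, arm,
                              config = preprocess_config(),
                              deadband = 0, coverage = 0.95) {
  segs <- list(hand = hand, forearm = forearm, arm = arm)
  lens <- vapply(segs, function(s) length(s$acc_global), integer(1))
  rates <- vapply(segs, `[[`, 0, "rate")
  if (length(unique(lens)) != 1L || length(unique(rates)) != 1L) {
    ek_stop("segments differ in length or rate", "esportkin_format_error")
  }
  hand_rms <- rms(hand$acc_global)
  forearm_rms <- rms(forearm$acc_global)
  arm_rms <- rms(arm$acc_global)
  # a motionless segment has zero RMS: flag rather than fail the session
  ratios <- tryCatch(segment_ratios(hand_rms, forearm_rms, arm_rms),
                     esportkin_degenerate_error = function(e) {
                       list(hand_forearm_ratio = NA_real_,
                            forearm_arm_ratio = NA_real_)
                     })
  zc <- count_zero_crossings(hand$vel_x$samples, hand$vel_y$samples,
                             hand$vel_z$samples, deadband)
  cd <- cumulative_distance(hand$disp_global)
  pts_cm <- cbind(hand$disp_x$samples, hand$disp_y$samples) * 100
  ellipse <- tryCatch(fit_confidence_ellipse(pts_cm, coverage),
                      esportkin_degenerate_error = function(e) NULL)
  structure(list(hand_rms = hand_rms, forearm_rms = forearm_rms,
                 arm_rms = arm_rms,
                 hand_forearm_ratio = ratios$hand_forearm_ratio,
                 forearm_arm_ratio = ratios$forearm_arm_ratio,
                 zero_crossings = zc, cumulative_distance_m = cd,
                 ellipse = ellipse,
                 ellipse_degenerate = is.null(ellipse),
                 fraction_unchanged = mean(c(hand$fraction_unchanged,
                                             forearm$fraction_unchanged,
                                             arm$fraction_unchanged)),
                 norm_mode = config$norm_mode, deadband = deadband),
            class = "kinematic_summary")
}

#' @export
print.kinematic_summary <- function(x, ...) {
  cat("<kinematic_summary>\n")
  cat(sprintf("  RMS acc (m/s^2): hand %.3g, forearm %.3g, arm %.3g\n",
              x$hand_rms, x$forearm_rms, x$arm_rms))
  cat(sprintf("  ratios: hand:forearm %.3g, forearm:arm %.3g\n",
              x$hand_forearm_ratio, x$forearm_arm_ratio))
  cat(sprintf("  zero-crossings %d, distance %.3g m\n",
              x$zero_crossings, x$cumulative_distance_m))
  if (x$ellipse_degenerate) cat("  ellipse: degenerate (flagged)\n")
  else cat(sprintf("  ellipse: area %.3g cm^2, long:short %.3g\n",
                   x$ellipse$area_cm2, x$ellipse$long_short_ratio))
  invisible(x)
}

# Flatten a kinematic_summary (plus identifiers) into one metrics-table row.
summary_row <- function(s, summary) {
  data.frame(participant_id = s$participant_id, genre = s$genre,
             dpi = ifelse(is.na(s$dpi), NA_integer_, s$dpi),
             hand_rms = summary$hand_rms, forearm_rms = summary$forearm_rms,
             arm_rms = summary$arm_rms,
             hand_forearm_ratio = summary$hand_forearm_ratio,
             forearm_arm_ratio = summary$forearm_arm_ratio,
             zero_crossings = summary$zero_crossings,
             cumulative_distance_m = summary$cumulative_distance_m,
             ellipse_a_cm = ifelse(summary$ellipse_degenerate, NA_real_,
                                   summary$ellipse$a),
             ellipse_b_cm = ifelse(summary$ellipse_degenerate, NA_real_,
                                   summary$ellipse$b),
             ellipse_area_cm2 = ifelse(summary$ellipse_degenerate, NA_real_,
                                       summary$ellipse$area_cm2),
             ellipse_long_short = ifelse(summary$ellipse_degenerate, NA_real_,
                                         summary$ellipse$long_short_ratio),
             ellipse_degenerate = summary$ellipse_degenerate,
             fraction_unchanged = summary$fraction_unchanged,
             stringsAsFactors = FALSE)
}
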