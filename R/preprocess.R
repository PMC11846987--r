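#' Pre-processing configuration
#'
#' Parameters of the per-axis pre-processing chain. Defaults follow the
#' analysis conditions the pipeline was built for: outliers beyond 3 SD
#' replaced by linear interpolation, a 2nd-order Butterworth band-pass with a
#' 0.5--11 Hz passband, zero-phase (forward-backward) filtering, and drift
#' control re-applied after each integration.
#'
#' @param outlier_k SD multiplier of the outlier threshold (default 3).
#' @param band_low_hz High-pass corner frequency in Hz (default 0.5).
#' @param band_high_hz Low-pass corner frequency in Hz (default 11).
#' @param filter_order Butterworth design order (default 2).
#' @param zero_phase Apply the filter forward-backward (default `TRUE`).
#' @param drift_correction Re-apply mean removal and the `band_low_hz`
#'   high-pass after each integration stage (default `TRUE`). Set `FALSE`
#'   for a strict single-integration chain with no drift control.
#' @param norm_mode Global magnitude mode: `"as_printed"` (per-frame
#'   `|x|+|y|+|z|`) or `"euclidean"` (`sqrt(x^2+y^2+z^2)`).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(outlier_k = 3, band_low_hz = 0.5,
                              band_high_hz = 11, filter_order = 2,
                              zero_phase = TRUE, drift_correction = TRUE,
                              norm_mode = c("as_printed", "euclidean")) {
  norm_mode <- match.arg(norm_mode)
  if (!(outlier_k > 0)) ek_stop("outlier_k must be > 0",
                                "esportkin_config_error")
  if (!(band_low_hz > 0 && band_low_hz < band_high_hz)) {
    ek_stop("need 0 < band_low_hz < band_high_hz", "esportkin_config_error")
  }
  if (filter_order < 1) ek_stop("filter_order must be >= 1",
                                "esportkin_config_error")
  structure(list(outlier_k = outlier_k, band_low_hz = band_low_hz,
                 band_high_hz = band_high_hz,
                 filter_order = as.integer(filter_order),
                 zero_phase = isTRUE(zero_phase),
                 drift_correction = isTRUE(drift_correction),
                 norm_mode = norm_mode),
            class = "preprocess_config")
}

#' Replace outlying samples by linear interpolation
#'
#' Samples further than `k` standard deviations from the trace mean (mean and
#' SD computed once over the full trace, population SD) are replaced by
#' linear interpolation between the nearest non-outlier neighbours; outliers
#' at the edges take the nearest valid value. A constant trace has SD 0 and
#' the strict `>` comparison then flags nothing.
#'
#' @param trace An [axis_trace()].
#' @param k SD multiplier (default 3).
#' @return List with `trace` (cleaned) and `fraction_replaced`.
#' @export
replace_outliers <- function(trace, k = 3) {
  x <- trace$samples
  n <- length(x)
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))  # single pass, population SD
  bad <- abs(x - mu) > k * sdev
  if (all(bad)) {
    ek_stop("all samples flagged as outliers (degenerate input)",
            "esportkin_degenerate_error")
  }
  if (any(bad)) {
    good_idx <- which(!bad)
    # linear interpolation between nearest valid neighbours; rule = 2 extends
    # the nearest valid value over leading/trailing outliers
    x[bad] <- stats::approx(good_idx, x[good_idx], xout = which(bad),
                            method = "linear", rule = 2)$y
  }
  list(trace = trace_with(trace, x), fraction_replaced = mean(bad))
}

#' Remove the whole-trace mean (gravity zeroing)
#'
#' Subtracts the global session-mean acceleration from every frame, removing
#' the static gravity component under the assumption that sensor orientation
#' is constant over the session.
#'
#' @param trace An [axis_trace()].
#' @return The zero-mean trace.
#' @export
remove_mean <- function(trace) {
  trace_with(trace, trace$samples - mean(trace$samples))
}

#' Convert a trace from milli-g to m/s^2
#'
#' Multiplies by standard gravity 9.80665 m/s^2 per 1000 mG and retags the
#' units.
#'
#' @param trace An [axis_trace()] with units `"mG"`.
#' @return The converted trace with units `"m_s2"`.
#' @export
convert_mg_to_ms2 <- function(trace) {
  if (trace$units != "mG") {
    ek_stop(sprintf("expected units mG, got %s", trace$units),
            "esportkin_unit_error")
  }
  trace_with(trace, trace$samples * (9.80665 / 1000), units = "m_s2")
}

# Zero-phase filtering via forward-backward application with odd-reflection
# padding at both ends (the signal is extended by its point reflection about
# each endpoint). Plain signal::filtfilt starts both passes from zero state,
# which leaks large edge transients; reflection padding lets the transient
# decay inside the padding instead of the data. Pad length is 3 periods of
# the lowest corner frequency, enough for the 2nd-order 0.5 Hz transient to
# decay below 1e-5.
zero_phase_filter <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  left <- 2 * x[1L] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  xp <- c(left, x, right)
  y <- as.numeric(signal::filter(filt, xp))
  y <- rev(as.numeric(signal::filter(filt, rev(y))))
  y[(pad + 1L):(pad + n)]
}

single_pass_filter <- function(filt, x) {
  as.numeric(signal::filter(filt, x))
}

filter_pad_samples <- function(config, rate) {
  as.integer(ceiling(3 * rate / config$band_low_hz))
}

#' Band-pass filter a trace (Butterworth)
#'
#' Applies a Butterworth band-pass of the configured design order between
#' `band_low_hz` and `band_high_hz`. With `zero_phase = TRUE` the filter runs
#' forward-backward (zero lag, squared magnitude response); otherwise a
#' single causal pass is used.
#'
#' @param trace An [axis_trace()].
#' @param config A [preprocess_config()].
#' @return The filtered trace.
#' @export
bandpass_filter <- function(trace, config = preprocess_config()) {
  rate <- trace$rate
  if (config$band_high_hz >= rate / 2) {
    ek_stop("band_high_hz must be below the Nyquist frequency",
            "esportkin_config_error")
  }
  x <- trace$samples
  min_len <- 3L * (2L * config$filter_order + 1L)
  if (length(x) < min_len) {
    ek_stop(sprintf("trace shorter than filter warm-up length (%d samples)",
                    min_len),
            "esportkin_length_error")
  }
  bf <- signal::butter(config$filter_order,
                       c(config$band_low_hz, config$band_high_hz) / (rate / 2),
                       type = "pass")
  y <- if (config$zero_phase) {
    zero_phase_filter(bf, x, filter_pad_samples(config, rate))
  } else {
    single_pass_filter(bf, x)
  }
  trace_with(trace, y)
}

# High-pass used by the drift-correction step after each integration.
highpass_filter <- function(trace, config) {
  rate <- trace$rate
  hf <- signal::butter(config$filter_order,
                       config$band_low_hz / (rate / 2), type = "high")
  y <- if (config$zero_phase) {
    zero_phase_filter(hf, trace$samples, filter_pad_samples(config, rate))
  } else {
    single_pass_filter(hf, trace$samples)
  }
  trace_with(trace, y)
}

#' Cumulative trapezoid integration of a trace
#'
#' Integrates acceleration to velocity (or velocity to displacement) with a
#' cumulative trapezoid rule starting at 0. With `drift_correction = TRUE`
#' the integrated trace is high-pass filtered at the band's lower corner and
#' mean-removed before return, which suppresses the random-walk drift that
#' double integration of noise otherwise accumulates.
#'
#' @param trace An [axis_trace()] with units `"m_s2"` or `"m_s"`.
#' @param drift_correction Apply drift control to the integral.
#' @param config A [preprocess_config()] (supplies the high-pass corner).
#' @return The integrated trace with units demoted one derivative.
#' @export
integrate_trapezoid <- function(trace, drift_correction = TRUE,
                                config = preprocess_config()) {
  if (!trace$units %in% c("m_s2", "m_s")) {
    ek_stop(sprintf("cannot integrate units %s", trace$units),
            "esportkin_unit_error")
  }
  new_units <- if (trace$units == "m_s2") "m_s" else "m"
  dt <- 1 / trace$rate
  x <- trace$samples
  y <- c(0, cumsum((x[-1L] + x[-length(x)]) / 2) * dt)
  out <- trace_with(trace, y, units = new_units)
  if (drift_correction) {
    out <- highpass_filter(out, config)
    out <- remove_mean(out)
  }
  out
}

#' Run the full pre-processing chain on one sensor recording
#'
#' Per axis, applies in order: outlier replacement, gravity zeroing, mG to
#' m/s^2 conversion, Butterworth band-pass, integration to velocity, and
#' integration to displacement. Then assembles the per-frame global
#' acceleration and displacement magnitudes under the configured norm mode.
#'
#' @param recording A [sensor_recording()] in mG.
#' @param config A [preprocess_config()].
#' @return An object of class `processed_signals` with per-axis acceleration
#'   (`acc_x` ...), velocity (`vel_x` ...) and displacement (`disp_x` ...)
#'   traces, global magnitude traces `acc_global` and `disp_global`, and
#'   `fraction_unchanged`, the mean proportion of samples not replaced as
#'   outliers.
#' @export
preprocess_sensor <- function(recording, config = preprocess_config()) {
  if (recording_units(recording) != "mG") {
    ek_stop("preprocess_sensor expects raw traces in mG",
            "esportkin_unit_error")
  }
  acc <- vel <- disp <- list()
  fraction_replaced <- numeric(3)
  for (i in seq_along(AXIS_LABELS)) {
    ax <- AXIS_LABELS[i]
    cleaned <- replace_outliers(recording[[ax]], config$outlier_k)
    fraction_replaced[i] <- cleaned$fraction_replaced
    tr <- remove_mean(cleaned$trace)
    tr <- convert_mg_to_ms2(tr)
    tr <- bandpass_filter(tr, config)
    acc[[ax]] <- tr
    vel[[ax]] <- integrate_trapezoid(tr, config$drift_correction, config)
    disp[[ax]] <- integrate_trapezoid(vel[[ax]], config$drift_correction,
                                      config)
  }
  acc_global <- global_magnitude(acc$x$samples, acc$y$samples, acc$z$samples,
                                 config$norm_mode)
  disp_global <- global_magnitude(disp$x$samples, disp$y$samples,
                                  disp$z$samples, config$norm_mode)
  structure(list(placement = recording$placement,
                 rate = recording_rate(recording),
                 acc_x = acc$x, acc_y = acc$y, acc_z = acc$z,
                 vel_x = vel$x, vel_y = vel$y, vel_z = vel$z,
                 disp_x = disp$x, disp_y = disp$y, disp_z = disp$z,
                 acc_global = acc_global, disp_global = disp_global,
                 fraction_unchanged = mean(1 - fraction_replaced)),
            class = "processed_signals")
}

#' @export
print.processed_signals <- function(x, ...) {
  cat(sprintf("<processed_signals %s: %d frames @ %g Hz, %.2f%% unchanged>\n",
              x$placement, length(x$acc_global), x$rate,
              100 * x$fraction_unchanged))
  invisible(x)
}
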