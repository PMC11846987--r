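#' Construct a single-axis accelerometer trace
#'
#' An `axis_trace` is a uniformly sampled real-valued signal from one axis of
#' one tri-axial accelerometer, together with its axis label, physical units
#' and sampling rate. Sample spacing is implied by the rate (`1/rate` s); no
#' explicit time stamps are stored.
#'
#' @param samples Numeric vector of samples (length >= 2, all finite).
#' @param axis Axis label, one of `"x"`, `"y"`, `"z"`.
#' @param units Unit tag: `"mG"` (milli-g), `"m_s2"` (m/s^2), `"m_s"` (m/s)
#'   or `"m"` (metres).
#' @param rate Sampling frequency in Hz (default 500).
#' @return An object of class `axis_trace`.
#' @export
axis_trace <- function(samples, axis = "x", units = "mG", rate = 500) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    ek_stop("axis_trace needs at least 2 samples", "esportkin_format_error")
  }
  if (!all(is.finite(samples))) {
    ek_stop(sprintf("non-finite sample at index %d",
                    which(!is.finite(samples))[1L]),
            "esportkin_parse_error")
  }
  if (!axis %in% AXIS_LABELS) ek_stop("axis must be x, y or z",
                                      "esportkin_format_error")
  if (!units %in% UNIT_TAGS) ek_stop("unknown units tag",
                                     "esportkin_unit_error")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    ek_stop("rate must be a positive number", "esportkin_rate_error")
  }
  structure(list(samples = samples, axis = axis, units = units, rate = rate),
            class = "axis_trace")
}

# Clone a trace with new samples (and optionally new units).
trace_with <- function(trace, samples, units = trace$units) {
  axis_trace(samples, axis = trace$axis, units = units, rate = trace$rate)
}

#' @export
print.axis_trace <- function(x, ...) {
  cat(sprintf("<axis_trace %s: %d samples @ %g Hz [%s]>\n",
              x$axis, length(x$samples), x$rate, x$units))
  invisible(x)
}

#' Construct a tri-axial sensor recording for one limb segment
#'
#' @param placement One of `"hand"`, `"forearm"`, `"arm"`.
#' @param x,y,z `axis_trace` objects with identical length, units and rate.
#' @return An object of class `sensor_recording`.
#' @export
sensor_recording <- function(placement, x, y, z) {
  if (!placement %in% PLACEMENTS) {
    ek_stop("placement must be hand, forearm or arm", "esportkin_format_error")
  }
  tr <- list(x = x, y = y, z = z)
  for (ax in AXIS_LABELS) {
    if (!inherits(tr[[ax]], "axis_trace")) {
      ek_stop("x, y, z must be axis_trace objects", "esportkin_format_error")
    }
  }
  lens <- vapply(tr, function(t) length(t$samples), integer(1))
  if (length(unique(lens)) != 1L) {
    ek_stop(sprintf("%s: axis traces have unequal length", placement),
            "esportkin_format_error")
  }
  if (length(unique(vapply(tr, `[[`, "", "units"))) != 1L) {
    ek_stop(sprintf("%s: axis traces have mixed units", placement),
            "esportkin_unit_error")
  }
  if (length(unique(vapply(tr, `[[`, 0, "rate"))) != 1L) {
    ek_stop(sprintf("%s: axis traces have mixed sampling rates", placement),
            "esportkin_rate_error")
  }
  structure(list(placement = placement, x = x, y = y, z = z),
            class = "sensor_recording")
}

recording_length <- function(rec) length(rec$x$samples)
recording_rate <- function(rec) rec$x$rate
recording_units <- function(rec) rec$x$units

#' Construct a gameplay session
#'
#' Bundles the three limb-segment recordings of one participant with the
#' session metadata (game genre, mouse DPI setting, nominal duration).
#' Sessions longer than `duration_s` are truncated; shorter ones are accepted
#' with a warning (recordings stop at "up to 10 minutes" of play).
#'
#' @param participant_id Opaque participant identifier.
#' @param genre One of `"FPS"`, `"MOBA"`, `"Adventure"`.
#' @param dpi Mouse resolution setting: 400, 1000 or 1600 (or `NA`).
#' @param duration_s Nominal session duration in seconds (<= 600).
#' @param hand,forearm,arm `sensor_recording` objects sharing length and rate.
#' @return An object of class `session`.
#' @export
session <- function(participant_id, genre, dpi, duration_s, hand, forearm, arm) {
  if (!genre %in% GENRES) ek_stop("unknown genre label",
                                  "esportkin_format_error")
  if (!is.na(dpi)) {
    dpi <- as.integer(dpi)
    if (!dpi %in% DPI_LEVELS) ek_stop("dpi must be 400, 1000 or 1600",
                                      "esportkin_format_error")
  }
  recs <- list(hand = hand, forearm = forearm, arm = arm)
  for (p in PLACEMENTS) {
    if (!inherits(recs[[p]], "sensor_recording")) {
      ek_stop("hand, forearm, arm must be sensor_recording objects",
              "esportkin_format_error")
    }
  }
  lens <- vapply(recs, recording_length, integer(1))
  rates <- vapply(recs, recording_rate, double(1))
  if (length(unique(lens)) != 1L) {
    ek_stop("recordings have unequal length", "esportkin_format_error")
  }
  if (length(unique(rates)) != 1L) {
    ek_stop("recordings have mixed sampling rates", "esportkin_rate_error")
  }
  if (duration_s > 600) ek_stop("duration_s exceeds 600 s",
                                "esportkin_format_error")
  n <- lens[[1L]]; rate <- rates[[1L]]
  n_nominal <- round(duration_s * rate)
  if (n > n_nominal + 1L) {
    # truncate over-long recordings to the nominal duration
    recs <- lapply(recs, function(rec) {
      for (ax in AXIS_LABELS) {
        rec[[ax]] <- trace_with(rec[[ax]], rec[[ax]]$samples[seq_len(n_nominal)])
      }
      rec
    })
    n <- n_nominal
  } else if (n < n_nominal - 1L) {
    warning(sprintf("session %s: recording (%d samples) shorter than nominal %g s; duration adjusted",
                    participant_id, n, duration_s))
    duration_s <- n / rate
  }
  structure(list(participant_id = as.character(participant_id), genre = genre,
                 dpi = dpi, duration_s = duration_s,
                 hand = recs$hand, forearm = recs$forearm, arm = recs$arm),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session %s: %s, %s DPI, %.1f s, %d samples @ %g Hz [%s]>\n",
              x$participant_id, x$genre,
              ifelse(is.na(x$dpi), "?", x$dpi), x$duration_s,
              recording_length(x$hand), recording_rate(x$hand),
              recording_units(x$hand)))
  invisible(x)
}

#' Validate a session against its structural invariants
#'
#' Reporting-only check: never throws. Each violated invariant yields one
#' entry naming the invariant and where it was violated.
#'
#' @param s A `session` (possibly hand-built or corrupted).
#' @return Character vector of violations; empty when the session is valid.
#' @export
validate_session <- function(s) {
  report <- character(0)
  note <- function(txt) report <<- c(report, txt)
  if (!is.list(s)) return("session: not a list")
  if (is.null(s$genre) || !s$genre %in% GENRES) note("genre: unknown label")
  if (!is.null(s$dpi) && !is.na(s$dpi) && !s$dpi %in% DPI_LEVELS) {
    note("dpi: not in {400, 1000, 1600}")
  }
  lens <- c(); rates <- c()
  for (p in PLACEMENTS) {
    rec <- s[[p]]
    if (is.null(rec)) { note(sprintf("%s: recording missing", p)); next }
    for (ax in AXIS_LABELS) {
      tr <- rec[[ax]]
      if (is.null(tr)) { note(sprintf("%s_%s: trace missing", p, ax)); next }
      if (length(tr$samples) < 2L) note(sprintf("%s_%s: length >= 2", p, ax))
      if (!all(is.finite(tr$samples))) {
        note(sprintf("%s_%s: all samples finite", p, ax))
      }
      if (is.null(tr$rate) || !is.finite(tr$rate) || tr$rate <= 0) {
        note(sprintf("%s_%s: rate > 0", p, ax))
      } else {
        rates <- c(rates, tr$rate)
      }
      if (is.null(tr$units) || !tr$units %in% UNIT_TAGS) {
        note(sprintf("%s_%s: unknown units tag", p, ax))
      }
      lens <- c(lens, length(tr$samples))
    }
  }
  if (length(unique(lens)) > 1L) note("traces: equal length")
  if (length(unique(rates)) > 1L) note("traces: equal rate")
  if (!is.null(s$duration_s) && length(rates) && length(lens)) {
    if (is.finite(s$duration_s) && s$duration_s > 600) note("duration_s <= 600")
    n_nom <- s$duration_s * rates[1L]
    if (is.finite(n_nom) && abs(lens[1L] - n_nom) > 1) {
      note("duration_s x rate = trace length (within one sample)")
    }
  }
  report
}
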