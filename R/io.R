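# Recording CSV dialect
# ---------------------
# One header block of "#key=value" lines (rate_hz, units, participant_id,
# genre, dpi), then a column header
#   t,hand_x,hand_y,hand_z,forearm_x,forearm_y,forearm_z,arm_x,arm_y,arm_z
# comma separated, "." decimal, UTF-8. The time column is derived (index/rate)
# and only checked on read; non-uniform time stamps beyond 1e-6 s jitter are
# rejected because the uniform-rate assumption underlies integration.

SESSION_COLUMNS <- c("t",
                     paste("hand", AXIS_LABELS, sep = "_"),
                     paste("forearm", AXIS_LABELS, sep = "_"),
                     paste("arm", AXIS_LABELS, sep = "_"))

#' Read a recording CSV into a session
#'
#' @param path Path to a recording CSV in the package's exchange dialect.
#' @param metadata Optional named list overriding header metadata
#'   (`participant_id`, `genre`, `dpi`, `duration_s`).
#' @return A validated [session()].
#' @export
read_session <- function(path, metadata = NULL) {
  if (!file.exists(path)) {
    ek_stop(sprintf("no such file: %s", path), "esportkin_io_error")
  }
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  hdr_idx <- grep("^#", head_lines)
  hdr <- list()
  for (ln in head_lines[hdr_idx]) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) hdr[[trimws(kv[1L])]] <- trimws(kv[2L])
  }
  rate <- as.numeric(hdr$rate_hz %||% 500)
  units <- hdr$units %||% "mG"
  dt <- data.table::fread(path, skip = length(hdr_idx), header = TRUE,
                          sep = ",", na.strings = NULL)
  missing_cols <- setdiff(SESSION_COLUMNS, names(dt))
  if (length(missing_cols)) {
    ek_stop(sprintf("missing column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "esportkin_format_error")
  }
  for (col in SESSION_COLUMNS) {
    v <- dt[[col]]
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(v))
      data.table::set(dt, j = col, value = v)
    }
    if (anyNA(v) || !all(is.finite(v))) {
      ek_stop(sprintf("non-finite value in column %s at row %d",
                      col, which(!is.finite(v))[1L]),
              "esportkin_parse_error")
    }
  }
  n <- nrow(dt)
  if (n < 2L) ek_stop("fewer than 2 data rows", "esportkin_format_error")
  t_expect <- (seq_len(n) - 1L) / rate
  if (max(abs(dt$t - t_expect)) > 1e-6) {
    ek_stop("time stamps deviate from a uniform 1/rate grid by more than 1e-6 s",
            "esportkin_rate_error")
  }
  meta <- list(participant_id = hdr$participant_id %||% "unknown",
               genre = hdr$genre %||% NA_character_,
               dpi = suppressWarnings(as.integer(hdr$dpi %||% NA)),
               duration_s = n / rate)
  for (k in names(metadata)) meta[[k]] <- metadata[[k]]
  recs <- lapply(PLACEMENTS, function(p) {
    axes <- lapply(AXIS_LABELS, function(ax) {
      axis_trace(dt[[paste(p, ax, sep = "_")]], axis = ax,
                 units = units, rate = rate)
    })
    sensor_recording(p, axes[[1L]], axes[[2L]], axes[[3L]])
  })
  session(meta$participant_id, meta$genre, meta$dpi, meta$duration_s,
          hand = recs[[1L]], forearm = recs[[2L]], arm = recs[[3L]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a session to a recording CSV
#'
#' Inverse of [read_session()]: `read_session(write_session(s))` reproduces
#' `s` within float round-off (samples are written with 15 significant
#' digits) and metadata exactly.
#'
#' @param s A [session()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(s, path) {
  rate <- recording_rate(s$hand)
  n <- recording_length(s$hand)
  hdr <- c(sprintf("#rate_hz=%.10g", rate),
           sprintf("#units=%s", recording_units(s$hand)),
           sprintf("#participant_id=%s", s$participant_id),
           sprintf("#genre=%s", s$genre),
           sprintf("#dpi=%s", ifelse(is.na(s$dpi), "NA", s$dpi)))
  dt <- data.table::data.table(t = (seq_len(n) - 1L) / rate)
  for (p in PLACEMENTS) {
    for (ax in AXIS_LABELS) {
      data.table::set(dt, j = paste(p, ax, sep = "_"),
                      value = s[[p]][[ax]]$samples)
    }
  }
  ok <- tryCatch({
    writeLines(hdr, path)
    data.table::fwrite(dt, path, append = TRUE, col.names = TRUE, sep = ",")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path)) {
    ek_stop(sprintf("cannot write %s", path), "esportkin_io_error")
  }
  invisible(path)
}

# Fixed column order of the per-session metrics table (External Interfaces).
METRICS_COLUMNS <- c("participant_id", "genre", "dpi",
                     "hand_rms", "forearm_rms", "arm_rms",
                     "hand_forearm_ratio", "forearm_arm_ratio",
                     "zero_crossings", "cumulative_distance_m",
                     "ellipse_a_cm", "ellipse_b_cm", "ellipse_area_cm2",
                     "ellipse_long_short", "ellipse_degenerate",
                     "fraction_unchanged")

#' Write / read the per-session metrics table
#'
#' One row per session: identifiers, then the kinematic summary fields in a
#' fixed column order.
#'
#' @param metrics Data frame of per-session metrics (see [run_cohort()]).
#' @param path CSV path.
#' @return `path` (write) or a data frame (read).
#' @export
write_metrics_table <- function(metrics, path) {
  missing_cols <- setdiff(METRICS_COLUMNS, names(metrics))
  if (length(missing_cols)) {
    ek_stop(sprintf("metrics table missing column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "esportkin_format_error")
  }
  data.table::fwrite(metrics[, METRICS_COLUMNS], path, sep = ",")
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  as.data.frame(data.table::fread(path, sep = ","))
}

#' Write a cohort report as JSON
#'
#' @param report A `cohort_report` from [run_cohort()].
#' @param path Output JSON path.
#' @export
write_cohort_report <- function(report, path) {
  out <- report
  out$metrics_table <- as.data.frame(out$metrics_table)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}
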