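# Minimum-jerk unit profiles on normalized time tau in [0, 1]:
# displacement 10t^3 - 15t^4 + 6t^5 reaches 1 with zero boundary velocity
# and acceleration; scale by D, D/T, D/T^2 for a stroke of length D over T.
mj_pos <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
mj_vel <- function(tau) 30 * tau^2 - 60 * tau^3 + 30 * tau^4
mj_acc <- function(tau) 60 * tau - 180 * tau^2 + 120 * tau^3

#' Minimum-jerk point-to-point movement profile
#'
#' Fifth-order minimum-jerk profile for a straight ballistic reach of a
#' given distance and duration: endpoint velocity and acceleration are zero,
#' displacement ends exactly at the distance, and peak velocity is
#' 15/8 x distance/duration.
#'
#' @param distance_cm Movement amplitude (cm, > 0).
#' @param duration_s Movement duration (s, > 0).
#' @param rate_hz Sampling rate (Hz, > 0).
#' @return List of numeric vectors `displacement` (cm), `velocity` (cm/s)
#'   and `acceleration` (cm/s^2) sampled on `seq(0, duration_s, 1/rate_hz)`.
#' @export
min_jerk_profile <- function(distance_cm, duration_s, rate_hz = 500) {
  if (distance_cm <= 0 || duration_s <= 0 || rate_hz <= 0) {
    ek_stop("distance, duration and rate must be > 0",
            "esportkin_config_error")
  }
  tau <- seq(0, duration_s, by = 1 / rate_hz) / duration_s
  list(displacement = distance_cm * mj_pos(tau),
       velocity = (distance_cm / duration_s) * mj_vel(tau),
       acceleration = (distance_cm / duration_s^2) * mj_acc(tau))
}

#' Specification of a synthetic gameplay recording
#'
#' Parameters of the generative model: ballistic hand movements occur as a
#' Poisson stream of out-and-back minimum-jerk flicks from a home position
#' on the mousepad plane, with flick targets drawn from a genre-specific
#' spatial covariance, superimposed on a static gravity offset, white
#' measurement noise and rare spike artefacts. Forearm and arm signals are
#' attenuated copies of the hand motion with independent noise.
#'
#' @param genre Genre label (`"FPS"`, `"MOBA"`, `"Adventure"`).
#' @param rate_hz Sampling rate (default 500 Hz).
#' @param duration_s Session length in seconds (default 600, i.e. 10 min).
#' @param event_rate_hz Mean ballistic events per second (Poisson rate).
#' @param amp_mean_cm Mean flick amplitude in cm (sets the overall spatial
#'   scale together with `spatial_cov_cm2`).
#' @param amp_sd_cm SD of the flick amplitude (log-normal heterogeneity).
#' @param spatial_cov_cm2 Symmetric positive-definite 2x2 target covariance
#'   on the mousepad plane (cm^2); its eigenvalue ratio controls how oblong
#'   the displacement footprint is.
#' @param move_dur_s Length-2 range of single-stroke durations (s).
#' @param noise_sd_mg White measurement noise SD per axis (mG).
#' @param gravity_mg Static 3-vector acceleration offset (mG).
#' @param outlier_rate Per-sample probability of an artefact spike
#'   (0 <= rate < 0.05).
#' @param segment_attenuation Length-2 factors in (0, 1]: forearm and arm
#'   acceleration scale relative to the hand.
#' @param seed Integer seed; every random draw in [simulate_session()] flows
#'   from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(genre = "FPS", rate_hz = 500, duration_s = 600,
                           event_rate_hz = 1.2, amp_mean_cm = 3.9,
                           amp_sd_cm = 1.2,
                           spatial_cov_cm2 = diag(c(16, 4)),
                           move_dur_s = c(0.15, 0.30), noise_sd_mg = 2,
                           gravity_mg = c(120, -80, 975),
                           outlier_rate = 0.002,
                           segment_attenuation = c(0.5, 0.3), seed = 1L) {
  if (!genre %in% GENRES) ek_stop("unknown genre label",
                                  "esportkin_format_error")
  S <- as.matrix(spatial_cov_cm2)
  if (!isTRUE(all.equal(S, t(S))) || any(eigen(S, TRUE)$values <= 0)) {
    ek_stop("spatial_cov_cm2 must be symmetric positive definite",
            "esportkin_config_error")
  }
  if (outlier_rate < 0 || outlier_rate >= 0.05) {
    ek_stop("outlier_rate must be in [0, 0.05)", "esportkin_config_error")
  }
  if (any(segment_attenuation <= 0) || any(segment_attenuation > 1)) {
    ek_stop("attenuation factors must be in (0, 1]", "esportkin_config_error")
  }
  if (duration_s > 600 || duration_s <= 0) {
    ek_stop("duration_s must be in (0, 600]", "esportkin_config_error")
  }
  if (length(move_dur_s) != 2L || any(move_dur_s <= 0) ||
      move_dur_s[1L] > move_dur_s[2L]) {
    ek_stop("move_dur_s must be an increasing positive range",
            "esportkin_config_error")
  }
  structure(list(genre = genre, rate_hz = rate_hz, duration_s = duration_s,
                 event_rate_hz = event_rate_hz, amp_mean_cm = amp_mean_cm,
                 amp_sd_cm = amp_sd_cm, spatial_cov_cm2 = S,
                 move_dur_s = move_dur_s, noise_sd_mg = noise_sd_mg,
                 gravity_mg = gravity_mg, outlier_rate = outlier_rate,
                 segment_attenuation = segment_attenuation,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Genre presets for the synthetic generator
#'
#' Documented default operating points per genre, chosen once to reproduce
#' the qualitative regimes of the three genres: FPS flicks are the largest
#' and most anisotropic (fast aim movements over a wide, oblong pad area);
#' MOBA has the highest event rate within a compact, near-circular area
#' (frequent click-to-move commands); Adventure is the sparsest and slowest,
#' over an oblong area. Noise, gravity and outlier settings are shared so
#' that genre contrasts come from the movement field alone.
#'
#' @param genre `"FPS"`, `"MOBA"` or `"Adventure"`.
#' @param seed Integer seed stored in the spec.
#' @return A [synthetic_spec()].
#' @export
genre_preset <- function(genre = c("FPS", "MOBA", "Adventure"), seed = 1L) {
  genre <- match.arg(genre)
  switch(genre,
    FPS = synthetic_spec("FPS", event_rate_hz = 1.2, amp_mean_cm = 3.9,
                         amp_sd_cm = 1.2, spatial_cov_cm2 = diag(c(16, 4)),
                         move_dur_s = c(0.15, 0.30),
                         segment_attenuation = c(0.5, 0.3), seed = seed),
    MOBA = synthetic_spec("MOBA", event_rate_hz = 2.2, amp_mean_cm = 1.9,
                          amp_sd_cm = 0.6,
                          spatial_cov_cm2 = diag(c(2.6, 2.2)),
                          move_dur_s = c(0.12, 0.25),
                          segment_attenuation = c(0.8, 0.55), seed = seed),
    Adventure = synthetic_spec("Adventure", event_rate_hz = 0.8,
                               amp_mean_cm = 3.1, amp_sd_cm = 1.0,
                               spatial_cov_cm2 = diag(c(12, 3)),
                               move_dur_s = c(0.30, 0.50),
                               segment_attenuation = c(0.7, 0.5),
                               seed = seed))
}

# Approximate mean radius of a centred 2D Gaussian with covariance S
# (exact for the isotropic case); used to normalize the target scale so
# that amp_mean_cm is the mean flick amplitude.
gaussian_mean_radius <- function(S) sqrt(pi / 4 * sum(diag(S)))

#' Simulate one gameplay session with analytic ground truth
#'
#' Plans a Poisson number of ballistic events over the session, draws flick
#' targets from the spec's spatial covariance (times a unit-mean-square
#' log-normal amplitude multiplier), concatenates out-and-back minimum-jerk
#' strokes into a 2D hand path with a small (5% of amplitude) z residual,
#' maps the analytic hand acceleration to the three sensors via the segment
#' attenuation factors, adds the gravity offset, white noise and spike
#' artefacts, and converts to mG. Overlapping planned events are thinned so
#' strokes never superpose. Deterministic under the spec seed: events, noise
#' and outliers use separate derived sub-streams, so toggling outliers does
#' not perturb the path.
#'
#' @param spec A [synthetic_spec()].
#' @param participant_id Identifier stored in the session.
#' @param dpi Optional DPI metadata (default `NA`).
#' @return List with `session` (a [session()]) and `truth`, a ground-truth
#'   list: `true_path_length_m` (sum of planned stroke lengths),
#'   `true_spatial_cov_cm2` (generative target covariance), `n_events`
#'   (kept events), `event_times_s`, `attenuation`, `outliers_injected`
#'   (count over all nine traces).
#' @export
simulate_session <- function(spec, participant_id = "synthetic", dpi = NA) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- round(spec$duration_s * spec$rate_hz)
  rate <- spec$rate_hz
  seed_events <- spec$seed %% 2147483647L
  seed_noise <- (spec$seed + 1000003L) %% 2147483647L
  seed_outl <- (spec$seed + 2000003L) %% 2147483647L

  scale_target <- spec$amp_mean_cm / gaussian_mean_radius(spec$spatial_cov_cm2)
  true_cov <- scale_target^2 * spec$spatial_cov_cm2
  sigma_log <- spec$amp_sd_cm / spec$amp_mean_cm

  plan <- with_local_seed(seed_events, {
    n_raw <- stats::rpois(1L, spec$event_rate_hz * spec$duration_s)
    if (n_raw == 0L) {
      list(targets = matrix(0, 0, 3), starts = numeric(0),
           out_dur = numeric(0), back_dur = numeric(0), dwell = numeric(0))
    } else {
      starts <- sort(stats::runif(n_raw, 0, spec$duration_s))
      out_dur <- stats::runif(n_raw, spec$move_dur_s[1L], spec$move_dur_s[2L])
      back_dur <- stats::runif(n_raw, spec$move_dur_s[1L], spec$move_dur_s[2L])
      dwell <- stats::runif(n_raw, 0.05, 0.15)
      L <- chol(true_cov)
      g <- matrix(stats::rnorm(2L * n_raw), n_raw, 2L) %*% L
      m <- exp(stats::rnorm(n_raw, -sigma_log^2, sigma_log))
      xy <- g * m
      zsign <- sample(c(-1, 1), n_raw, replace = TRUE)
      amp2d <- sqrt(rowSums(xy^2))
      targets <- cbind(xy, 0.05 * amp2d * zsign)
      # thin overlapping events: strokes never superpose
      keep <- logical(n_raw)
      t_free <- 0
      for (i in seq_len(n_raw)) {
        span <- out_dur[i] + dwell[i] + back_dur[i]
        if (starts[i] >= t_free && starts[i] + span <= spec$duration_s) {
          keep[i] <- TRUE
          t_free <- starts[i] + span
        }
      }
      list(targets = targets[keep, , drop = FALSE], starts = starts[keep],
           out_dur = out_dur[keep], back_dur = back_dur[keep],
           dwell = dwell[keep])
    }
  })

  # analytic hand acceleration in m/s^2, one vector per axis
  acc <- matrix(0, n, 3L)
  n_ev <- length(plan$starts)
  for (i in seq_len(n_ev)) {
    p_m <- plan$targets[i, ] / 100  # cm -> m
    for (stroke in 1:2) {
      t0 <- if (stroke == 1L) plan$starts[i] else {
        plan$starts[i] + plan$out_dur[i] + plan$dwell[i]
      }
      Tdur <- if (stroke == 1L) plan$out_dur[i] else plan$back_dur[i]
      sgn <- if (stroke == 1L) 1 else -1
      i0 <- floor(t0 * rate) + 1L
      i1 <- min(n, ceiling((t0 + Tdur) * rate) + 1L)
      idx <- i0:i1
      tau <- ((idx - 1L) / rate - t0) / Tdur
      tau <- pmin(pmax(tau, 0), 1)
      prof <- mj_acc(tau) / Tdur^2
      acc[idx, ] <- acc[idx, ] + sgn * outer(prof, p_m)
    }
  }

  atten <- c(1, spec$segment_attenuation)
  noise <- with_local_seed(seed_noise,
                           array(stats::rnorm(n * 9L, 0, spec$noise_sd_mg),
                                 dim = c(n, 3L, 3L)))
  outl <- with_local_seed(seed_outl, {
    flags <- array(stats::runif(n * 9L) < spec$outlier_rate,
                   dim = c(n, 3L, 3L))
    signs <- array(sample(c(-1, 1), n * 9L, replace = TRUE),
                   dim = c(n, 3L, 3L))
    list(flags = flags, signs = signs)
  })

  recs <- list()
  outliers_injected <- 0L
  for (si in 1:3) {
    axes <- list()
    for (ai in 1:3) {
      x_mg <- acc[, ai] * atten[si] * (1000 / 9.80665) +
        spec$gravity_mg[ai] + noise[, ai, si]
      flags <- outl$flags[, ai, si]
      if (any(flags)) {
        # artefact spikes at 12x the clean-trace SD: unambiguous outliers
        spike <- 12 * stats::sd(x_mg)
        x_mg[flags] <- x_mg[flags] + outl$signs[flags, ai, si] * spike
        outliers_injected <- outliers_injected + sum(flags)
      }
      axes[[ai]] <- axis_trace(x_mg, axis = AXIS_LABELS[ai], units = "mG",
                               rate = rate)
    }
    recs[[si]] <- sensor_recording(PLACEMENTS[si], axes[[1L]], axes[[2L]],
                                   axes[[3L]])
  }

  stroke_len_m <- if (n_ev) sqrt(rowSums(plan$targets^2)) / 100 else numeric(0)
  truth <- list(true_path_length_m = 2 * sum(stroke_len_m),
                true_spatial_cov_cm2 = true_cov,
                n_events = n_ev, event_times_s = plan$starts,
                attenuation = spec$segment_attenuation,
                outliers_injected = outliers_injected)
  sess <- session(participant_id, spec$genre, dpi, n / rate,
                  hand = recs[[1L]], forearm = recs[[2L]], arm = recs[[3L]])
  list(session = sess, truth = truth)
}

# Genre-conditional DPI choice probabilities over 400/1000/1600 (FPS players
# favour low sensitivities, MOBA players high ones).
DPI_CHOICE_PROBS <- list(FPS = c(0.45, 0.30, 0.25),
                         MOBA = c(0.10, 0.15, 0.75),
                         Adventure = c(0.35, 0.35, 0.30))

#' Simulate a cohort of sessions across genres
#'
#' Generates `n_sessions[genre]` sessions per genre from the genre presets,
#' with per-session seeds derived from `seed` and DPI metadata sampled from
#' genre-conditional choice probabilities. Individual players differ: each
#' participant's movement amplitude, event rate and segment attenuation are
#' drawn around the genre preset (log-normal factors with coefficient of
#' variation `participant_cv`), so group comparisons face realistic
#' between-participant variance rather than only within-session noise.
#'
#' @param n_sessions Named integer vector of sessions per genre
#'   (default `c(FPS = 32, MOBA = 16, Adventure = 15)`).
#' @param seed Integer master seed.
#' @param duration_s Session length in seconds (default 600).
#' @param participant_cv Between-participant coefficient of variation of the
#'   amplitude and event-rate scales (default 0.25; 0 disables
#'   heterogeneity).
#' @return List with one element per session, each a
#'   `list(session =, truth =)` as from [simulate_session()].
#' @export
simulate_cohort <- function(n_sessions = c(FPS = 32, MOBA = 16, Adventure = 15),
                            seed = 1L, duration_s = 600,
                            participant_cv = 0.25) {
  out <- list()
  k <- 0L
  for (g in names(n_sessions)) {
    for (i in seq_len(n_sessions[[g]])) {
      k <- k + 1L
      s_seed <- (seed + 7919L * k) %% 2147483647L
      spec <- genre_preset(g, seed = s_seed)
      spec$duration_s <- duration_s
      draws <- with_local_seed((s_seed + 13L) %% 2147483647L, {
        list(dpi = sample(DPI_LEVELS, 1L, prob = DPI_CHOICE_PROBS[[g]]),
             amp = exp(stats::rnorm(1L, -participant_cv^2 / 2,
                                    participant_cv)),
             rate = exp(stats::rnorm(1L, -participant_cv^2 / 2,
                                     participant_cv)),
             att = stats::runif(2L, 1 - participant_cv / 2,
                                1 + participant_cv / 2))
      })
      spec$amp_mean_cm <- spec$amp_mean_cm * draws$amp
      spec$event_rate_hz <- spec$event_rate_hz * draws$rate
      spec$segment_attenuation <- pmin(spec$segment_attenuation * draws$att,
                                       1)
      out[[k]] <- simulate_session(spec, participant_id = sprintf("%s_%02d", g, i),
                                   dpi = draws$dpi)
    }
  }
  out
}
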