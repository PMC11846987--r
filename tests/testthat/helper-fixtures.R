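# Build a session from a 9-column sample matrix (hand/forearm/arm x x/y/z).
session_from_matrix <- function(m, rate = 500, units = "mG", genre = "FPS",
                                dpi = 400, id = "fixture") {
  stopifnot(ncol(m) == 9L)
  recs <- lapply(0:2, function(si) {
    axes <- lapply(1:3, function(ai) {
      axis_trace(m[, si * 3L + ai], axis = c("x", "y", "z")[ai],
                 units = units, rate = rate)
    })
    sensor_recording(c("hand", "forearm", "arm")[si + 1L],
                     axes[[1]], axes[[2]], axes[[3]])
  })
  session(id, genre, dpi, nrow(m) / rate,
          hand = recs[[1]], forearm = recs[[2]], arm = recs[[3]])
}

random_session <- function(n = 5000, rate = 500, seed = 1, genre = "FPS",
                           dpi = 400) {
  set.seed(seed)
  session_from_matrix(matrix(rnorm(n * 9, 0, 50), n, 9), rate = rate,
                      genre = genre, dpi = dpi, id = sprintf("rnd%d", seed))
}

# Short synthetic session from a genre preset.
preset_session <- function(genre = "FPS", seed = 1, duration_s = 30,
                           dpi = 400, ...) {
  spec <- genre_preset(genre, seed = seed)
  spec$duration_s <- duration_s
  extra <- list(...)
  for (k in names(extra)) spec[[k]] <- extra[[k]]
  simulate_session(spec, participant_id = sprintf("%s_s%d", genre, seed),
                   dpi = dpi)
}
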