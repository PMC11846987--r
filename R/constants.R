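# Condition helper: all package errors carry class "esportkin_error" plus a
# specific subclass so callers (and tests) can dispatch on the failure kind.
ek_stop <- function(msg, subclass) {
  stop(errorCondition(msg, class = c(subclass, "esportkin_error", "error")))
}

AXIS_LABELS <- c("x", "y", "z")
UNIT_TAGS <- c("mG", "m_s2", "m_s", "m")
PLACEMENTS <- c("hand", "forearm", "arm")
GENRES <- c("FPS", "MOBA", "Adventure")
DPI_LEVELS <- c(400L, 1000L, 1600L)
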