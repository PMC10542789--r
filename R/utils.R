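# Internal helpers: seeded substreams, frame clock arithmetic, validation.

# Named substreams derived from one master seed, so a change in the number of
# draws consumed by one component never perturbs another.
.substreamOffsets <- c(
  locomotion = 11L, whisking = 23L, outcomes = 37L, spikes = 53L,
  tracks = 71L, decode = 89L, amplitudes = 101L
)

substreamSeed <- function(seed, component) {
  stopifnot(component %in% names(.substreamOffsets))
  off <- .substreamOffsets[[component]]
  as.integer((as.numeric(seed) * 1009 + off * 104729) %% .Machine$integer.max)
}

# Evaluate `expr` under a local RNG state seeded for one substream.
withSubstream <- function(seed, component, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substreamSeed(seed, component))
  expr
}

frameTimes <- function(n, frameRate) (seq_len(n) - 1) / frameRate

# Half-open interval membership [t0, t1)
inWindow <- function(t, t0, t1) t >= t0 & t < t1

.assert <- function(cond, msg, class = "whiskerVR_error") {
  if (!isTRUE(cond)) {
    stop(errorCondition(msg, class = c(class, "error", "condition")))
  }
  invisible(TRUE)
}

configError <- function(msg) {
  stop(errorCondition(msg,
    class = c("whiskerVR_config_error", "whiskerVR_error", "error", "condition")))
}

inputError <- function(msg) {
  stop(errorCondition(msg,
    class = c("whiskerVR_input_error", "whiskerVR_error", "error", "condition")))
}

# Alternating bout structure: exponential bout/rest durations (floored at
# `minLen`) tiled until `duration` is covered.  Returns a logical per-frame
# mask that is TRUE inside active bouts.
boutMask <- function(duration, frameRate, activeMean, restMean,
                     minLen = 0.5, startActive = TRUE) {
  n <- round(duration * frameRate)
  active <- logical(n)
  t <- 0
  state <- startActive
  while (t < duration) {
    len <- max(minLen, rexp(1, 1 / if (state) activeMean else restMean))
    i0 <- floor(t * frameRate) + 1
    i1 <- min(n, ceiling((t + len) * frameRate))
    if (i0 <= n) active[i0:i1] <- state
    t <- t + len
    state <- !state
  }
  active
}
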