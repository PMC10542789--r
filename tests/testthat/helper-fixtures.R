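# Shared fixtures, built in code at test time.

# Cache so expensive sessions are simulated once per test run.
.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, expr, envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# A short full session with tracks, used across kinematics/alignment tests.
shortSession <- function() {
  cached("shortSession", {
    cfg <- sessionConfig(duration = 60, frameRate = 500, nNeurons = 8L,
                         trialDistance = 120, seed = 7L)
    simulateSession(cfg, seed = 7)
  })
}

# One-row neuron spec with explicit parameters.
neuronSpec1 <- function(baseline = 8, tGain = 0, sGain = 0, selfAtt = 1,
                        habSlope = 0, gowSign = 1, lowSign = 1,
                        whiskers = "1") {
  data.frame(neuron_id = 1, class_label = "custom",
             baseline_rate = baseline, transient_gain = tGain,
             onset_latency_s = 0.02, tau_rise_s = 0.01, tau_decay_s = 0.06,
             self_attenuation = selfAtt, sustained_gain = sGain,
             habituation_slope = habSlope, gow_sign = gowSign,
             low_sign = lowSign, preferred_whiskers = whiskers,
             stringsAsFactors = FALSE)
}

# Mean of the transient kernel over a post-onset window [0, w] — the
# kernel-arithmetic oracle used to predict window-averaged responses.
kernelWindowMean <- function(w, latency = 0.02, tauRise = 0.01,
                             tauDecay = 0.06, frameRate = 1000) {
  t <- seq(0, w, by = 1 / frameRate)
  u <- pmax(0, t - latency)
  k <- (1 - exp(-u / tauRise)) * exp(-u / tauDecay)
  k <- k / max((1 - exp(-pmax(0, seq(0, 1, 1e-3) - latency) / tauRise)) *
                 exp(-pmax(0, seq(0, 1, 1e-3) - latency) / tauDecay))
  mean(k)
}

# Independent circumradius oracle: circumcentre of three points from the
# perpendicular-bisector linear system, |curvature| = 1 / circumradius.
circumradiusOracle <- function(p1, p2, p3) {
  A <- rbind(2 * (p2 - p1), 2 * (p3 - p1))
  b <- c(sum(p2^2) - sum(p1^2), sum(p3^2) - sum(p1^2))
  ctr <- solve(A, b)
  sqrt(sum((p1 - ctr)^2))
}

# Small deterministic helper population: class-dependent transient gains
# around movement onset, optional sustained class signal.
decodeFixture <- function(nNeurons = 12, nPerClass = 20, seed = 1,
                          kind = c("transient", "sustained")) {
  kind <- match.arg(kind)
  set.seed(seed)
  labels <- rep(c("rostral", "caudal", "center"), each = nPerClass)
  labels <- sample(labels)
  onsets <- seq(10, by = 6, length.out = length(labels))
  dur <- max(onsets) + 5
  spikes <- lapply(seq_len(nNeurons), function(i) {
    gains <- setNames(runif(3, 0, 25), c("rostral", "caudal", "center"))
    st <- sort(runif(rpois(1, 5 * dur), 0, dur))
    for (k in seq_along(onsets)) {
      g <- gains[labels[k]]
      if (g > 0) {
        span <- if (kind == "transient") c(0, 0.3) else c(0, 5)
        nsp <- rpois(1, g * diff(span) * if (kind == "transient") 1 else 0.4)
        st <- c(st, onsets[k] + runif(nsp, span[1], span[2]))
      }
    }
    sort(st)
  })
  names(spikes) <- seq_len(nNeurons)
  list(spikes = spikes, labels = labels, onsets = onsets)
}

# Exact-series oracle for habituation slopes: OLS slope of the noiseless
# per-repetition window response, including the floor at zero gain.
habExpectedSlope <- function(h, gain, kbar, nReps) {
  k <- seq_len(nReps)
  y <- gain * kbar * pmax(0, 1 + h * (k - 1))
  unname(coef(lm(y ~ k))[2])
}
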