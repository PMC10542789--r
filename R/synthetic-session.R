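# Closed-loop whisker-VR session generator.
#
# The generator emulates the statistics the analysis stages assume:
# volitional running (~23.7 cm/s) in alternating run/rest bouts, rhythmic
# whisking (~19 Hz) with quiescent bouts and surface-tracking setpoints,
# distance-triggered 1 cm surface translations with equal-probability
# outcomes, GoW/LoW contact events of external and self origin, and
# inhomogeneous-Poisson spike trains with transient/sustained response
# structure, self-generated attenuation, and linear habituation.

#' Generate a volitional locomotion speed trace
#'
#' Alternating run/rest bouts; within a run bout the speed fluctuates slowly
#' around \code{meanRunSpeed}.  Bout edges are smoothed with a short
#' (0.2 s) Gaussian ramp so acceleration is finite.
#'
#' @param cfg a \linkS4class{SessionConfig}
#' @param seed integer seed (a dedicated locomotion substream is derived)
#' @return numeric speed trace (cm/s, one value per frame) with a logical
#'   attribute \code{running} marking ground-truth run-bout frames
#' @examples
#' sp <- generateLocomotion(sessionConfig(duration = 30), seed = 1)
#' mean(sp[attr(sp, "running")])
#' @export
generateLocomotion <- function(cfg, seed = cfg@seed) {
  validObject(cfg)
  withSubstream(seed, "locomotion", {
    fr <- cfg@frameRate
    n <- round(cfg@duration * fr)
    running <- if (cfg@restBoutMean <= 0) rep(TRUE, n) else
      boutMask(cfg@duration, fr, cfg@runBoutMean, cfg@restBoutMean,
               minLen = 1)
    target <- ifelse(running, cfg@meanRunSpeed, 0)
    if (cfg@restBoutMean > 0) {
      # 0.2 s Gaussian ramp at bout edges
      half <- max(1L, round(0.1 * fr))
      kern <- exp(-0.5 * (seq(-3, 3, length.out = 2 * half + 1))^2)
      kern <- kern / sum(kern)
      target <- as.numeric(stats::filter(c(rep(target[1], half), target,
                                           rep(target[n], half)),
                                         kern, sides = 2))[half + seq_len(n)]
    }
    speed <- if (cfg@speedSd > 0) {
      # AR(1) fluctuation with ~1 s correlation time, scaled by the ramp
      a <- exp(-1 / fr)
      innov <- rnorm(n, 0, cfg@speedSd * sqrt(1 - a^2))
      noise <- as.numeric(stats::filter(innov, a, "recursive"))
      pmax(0, target + noise * target / cfg@meanRunSpeed)
    } else {
      pmax(0, target)
    }
    attr(speed, "running") <- running
    speed
  })
}

#' Simulate the closed-loop surface protocol
#'
#' A trial is triggered each time the cumulative locomotor distance since the
#' previous trigger crosses \code{trialDistance}.  From the centre the
#' outcome is drawn from \code{outcomeProbs}; from a displaced position the
#' surface returns to the centre.  Each movement is a linear ramp of
#' \code{translationDistance} over \code{translationDuration}.
#'
#' @param speed numeric speed trace (cm/s per frame)
#' @param cfg a \linkS4class{SessionConfig}
#' @param seed integer seed (outcome substream)
#' @return list with \code{surface} (axial position, cm per frame) and
#'   \code{trials} (data.frame: trial, frame, time_s, outcome, is_return,
#'   direction, distance_cm)
#' @examples
#' cfg <- sessionConfig(duration = 40, frameRate = 100)
#' res <- simulateSurface(rep(20, 4000), cfg, seed = 1)
#' res$trials
#' @export
simulateSurface <- function(speed, cfg, seed = cfg@seed) {
  validObject(cfg)
  if (any(!is.finite(speed)) || any(speed < 0))
    inputError("speed trace must be finite and nonnegative")
  withSubstream(seed, "outcomes", {
    fr <- cfg@frameRate
    n <- length(speed)
    cum <- cumsum(speed) / fr
    rampN <- max(1L, round(cfg@translationDuration * fr))
    outNames <- names(cfg@outcomeProbs)
    # axial position per outcome; "out" is far outside the whisker field
    posOf <- c(rostral = cfg@translationDistance,
               caudal = -cfg@translationDistance,
               center = 0, out = 8 * cfg@translationDistance)
    surface <- numeric(n)
    pos <- 0
    d0 <- 0
    rows <- list()
    k <- 0L
    repeat {
      idx <- findInterval(d0 + cfg@trialDistance - 1e-12, cum) + 1L
      if (idx > n) break
      k <- k + 1L
      isReturn <- pos != 0
      if (isReturn) {
        newPos <- 0
        outcome <- "return"
      } else {
        outcome <- sample(outNames, 1L, prob = cfg@outcomeProbs)
        newPos <- posOf[[outcome]]
      }
      direction <- if (newPos > pos) "rostral" else
        if (newPos < pos) "caudal" else "none"
      if (newPos != pos) {
        j1 <- min(n, idx + rampN - 1L)
        ramp <- pos + (newPos - pos) * seq_len(j1 - idx + 1L) / rampN
        if (idx <= n) surface[idx:j1] <- ramp
        if (j1 < n) surface[(j1 + 1L):n] <- newPos
      }
      rows[[k]] <- data.frame(
        trial = k, frame = idx, time_s = (idx - 1) / fr,
        outcome = outcome, is_return = isReturn, direction = direction,
        distance_cm = cum[idx] - d0, stringsAsFactors = FALSE)
      pos <- newPos
      d0 <- cum[idx]
    }
    trials <- if (k) do.call(rbind, rows) else
      data.frame(trial = integer(), frame = integer(), time_s = numeric(),
                 outcome = character(), is_return = logical(),
                 direction = character(), distance_cm = numeric(),
                 stringsAsFactors = FALSE)
    list(surface = surface, trials = trials)
  })
}

#' Generate rhythmic whisking
#'
#' A shared whisk cycle drives all whiskers: a sinusoid at \code{whiskFreq}
#' with multiplicative per-cycle frequency and amplitude jitter, active
#' during whisking bouts and flat at the setpoint during quiescence.  The
#' setpoint of each whisker tracks the surface position at
#' \code{whiskSetpointTracking} degrees/cm (clamped to +/- 1.5 translation
#' distances: out-of-field surfaces are not tracked).
#'
#' @param cfg a \linkS4class{SessionConfig}
#' @param surface surface position trace (cm per frame); scalar 0 allowed
#' @param seed integer seed (whisking substream)
#' @return list with \code{angles} (frames x whiskers matrix, degrees),
#'   \code{whisking} (logical mask), \code{phase} (radians) and
#'   \code{setpoints} (frames x whiskers matrix)
#' @export
generateWhisking <- function(cfg, surface = 0, seed = cfg@seed) {
  validObject(cfg)
  if (cfg@whiskFreq >= cfg@frameRate / 2)
    configError("whiskFreq must be below the Nyquist frequency of frameRate")
  withSubstream(seed, "whisking", {
    fr <- cfg@frameRate
    n <- round(cfg@duration * fr)
    if (length(surface) == 1) surface <- rep(surface, n)
    stopifnot(length(surface) == n)
    whisking <- if (cfg@whiskRestMean <= 0) rep(TRUE, n) else
      boutMask(cfg@duration, fr, cfg@whiskBoutMean, cfg@whiskRestMean,
               minLen = 0.4)
    # phase accumulates at a rate re-drawn each cycle (multiplicative jitter)
    phase <- numeric(n)
    amp <- numeric(n)
    curF <- cfg@whiskFreq * exp(rnorm(1, 0, cfg@whiskFreqJitterSd))
    curA <- cfg@whiskAmplitude * exp(rnorm(1, 0, cfg@whiskAmpJitterSd))
    ph <- runif(1, -pi, pi)
    for (i in seq_len(n)) {
      phase[i] <- ph
      amp[i] <- curA
      ph <- ph + 2 * pi * curF / fr
      if (ph > pi) {
        ph <- ph - 2 * pi
        curF <- cfg@whiskFreq * exp(rnorm(1, 0, cfg@whiskFreqJitterSd))
        curA <- cfg@whiskAmplitude * exp(rnorm(1, 0, cfg@whiskAmpJitterSd))
      }
    }
    tracked <- pmin(pmax(surface, -1.5 * cfg@translationDistance),
                    1.5 * cfg@translationDistance)
    setpoints <- outer(tracked * cfg@whiskSetpointTracking,
                       rep(1, cfg@nWhiskers)) +
      matrix(cfg@whiskerSetpoints, n, cfg@nWhiskers, byrow = TRUE)
    osc <- ifelse(whisking, amp * sin(phase), 0)
    angles <- setpoints + osc + matrix(rnorm(n * cfg@nWhiskers, 0, 0.1),
                                       n, cfg@nWhiskers)
    list(angles = angles, whisking = whisking, phase = phase,
         setpoints = setpoints)
  })
}

# Per-frame contact state: whisker w contacts the surface when it is
# whisking and its sweep interval overlaps the surface band.
contactMatrix <- function(cfg, surface, whisking) {
  n <- length(surface)
  tracked <- pmin(pmax(surface, -1.5 * cfg@translationDistance),
                  1.5 * cfg@translationDistance)
  azLo <- cfg@surfaceAzimuth0 + cfg@azimuthPerCm * surface -
    cfg@surfaceHalfWidth
  azHi <- azLo + 2 * cfg@surfaceHalfWidth
  C <- matrix(FALSE, n, cfg@nWhiskers)
  for (w in seq_len(cfg@nWhiskers)) {
    sp <- cfg@whiskerSetpoints[w] + cfg@whiskSetpointTracking * tracked
    lo <- sp - cfg@whiskAmplitude
    hi <- sp + cfg@whiskAmplitude
    C[, w] <- whisking & (hi >= azLo) & (lo <= azHi)
  }
  C
}

#' Derive ground-truth contact events from session geometry
#'
#' Emits a GoW event whenever a whisker's contact state switches on and a
#' LoW event when it switches off.  A transition is of external origin when
#' the surface is translating at that frame (or within one ramp of it) and
#' of self origin otherwise (whisking resumption or arrest against a
#' stationary surface).  Repetition indices count events within each
#' (kind, origin, direction) stream in temporal order.
#'
#' @param cfg a \linkS4class{SessionConfig}
#' @param surface surface position trace (cm per frame)
#' @param whisking logical whisking-bout mask
#' @return list with \code{events} (data.frame: time_s, frame, whisker_id,
#'   kind, origin, direction, repetition), \code{contact}
#'   (frames x whiskers logical matrix) and \code{touching} (any-whisker
#'   contact mask)
#' @export
deriveContactTruth <- function(cfg, surface, whisking) {
  validObject(cfg)
  fr <- cfg@frameRate
  C <- contactMatrix(cfg, surface, whisking)
  moving <- c(FALSE, abs(diff(surface)) > 0)
  # extend the moving mask by 2 frames so edge effects stay "external"
  movingExt <- moving
  for (s in 1:2) movingExt <- movingExt | c(rep(FALSE, s), head(moving, -s))
  vel <- c(0, diff(surface))
  rows <- list()
  k <- 0L
  for (w in seq_len(ncol(C))) {
    d <- diff(C[, w])
    on <- which(d == 1) + 1L
    off <- which(d == -1) + 1L
    for (f in on) {
      k <- k + 1L
      ext <- movingExt[f]
      dirn <- if (ext) {
        v <- vel[max(which(vel[seq_len(f)] != 0), 1)]
        if (v > 0) "rostral" else "caudal"
      } else "none"
      rows[[k]] <- data.frame(time_s = (f - 1) / fr, frame = f,
                              whisker_id = w, kind = "GoW",
                              origin = if (ext) "external" else "self",
                              direction = dirn, stringsAsFactors = FALSE)
    }
    for (f in off) {
      k <- k + 1L
      ext <- movingExt[f]
      dirn <- if (ext) {
        v <- vel[max(which(vel[seq_len(f)] != 0), 1)]
        if (v > 0) "rostral" else "caudal"
      } else "none"
      rows[[k]] <- data.frame(time_s = (f - 1) / fr, frame = f,
                              whisker_id = w, kind = "LoW",
                              origin = if (ext) "external" else "self",
                              direction = dirn, stringsAsFactors = FALSE)
    }
  }
  events <- if (k) do.call(rbind, rows) else
    data.frame(time_s = numeric(), frame = integer(), whisker_id = integer(),
               kind = character(), origin = character(),
               direction = character(), stringsAsFactors = FALSE)
  events <- events[order(events$time_s, events$whisker_id), , drop = FALSE]
  if (nrow(events)) {
    stream <- interaction(events$kind, events$origin, events$direction,
                          drop = TRUE)
    events$repetition <- stats::ave(seq_len(nrow(events)), stream,
                                    FUN = seq_along)
  } else {
    events$repetition <- integer()
  }
  rownames(events) <- NULL
  list(events = events, contact = C, touching = rowSums(C) > 0)
}

#' Generative parameters for a simulated neuron population
#'
#' Assigns response classes and effect sizes emulating the recorded
#' population: about two thirds of neurons tactile responsive (split between
#' transient and sustained, with a minority responsive in both windows), a
#' small majority preferring gains over losses of whisker contact, strong
#' attenuation of self-generated transients, and a shallow linear
#' habituation of the transient gain across external repetitions.
#'
#' @param n number of neurons
#' @param responsiveFraction fraction of neurons with any tactile response
#' @param transientShare,sustainedShare,bothShare split of the responsive
#'   pool (normalised internally)
#' @param gowPreferringFraction fraction of responsive neurons excited by
#'   GoW and suppressed by LoW (the rest get the opposite polarity)
#' @param baselineRate mean baseline rate (spikes/s; gamma-distributed,
#'   shape 4)
#' @param transientGain peak added rate on external GoW (spikes/s)
#' @param sustainedGain added rate during surface touch (spikes/s)
#' @param selfAttenuation factor in [0, 1] scaling self-generated transients
#' @param habituationSlope fractional change of the transient gain per
#'   external-GoW repetition (<= 0)
#' @param nWhiskers whiskers available as preferred inputs (all preferred by
#'   default)
#' @param seed integer seed
#' @return data.frame of neuron specifications (one row per neuron)
#' @export
makeNeuronSpecs <- function(n, responsiveFraction = 0.67,
                            transientShare = 0.4, sustainedShare = 0.4,
                            bothShare = 0.2,
                            gowPreferringFraction = 0.55,
                            baselineRate = 8, transientGain = 40,
                            sustainedGain = 12, selfAttenuation = 0.4,
                            habituationSlope = -0.02,
                            nWhiskers = 3L, seed = 1L) {
  if (selfAttenuation < 0 || selfAttenuation > 1)
    configError("selfAttenuation must lie in [0, 1]")
  if (baselineRate < 0 || transientGain < 0 || sustainedGain < 0)
    configError("rates and gains must be nonnegative")
  withSubstream(seed, "spikes", {
    nResp <- round(n * responsiveFraction)
    shares <- c(transientShare, sustainedShare, bothShare)
    shares <- shares / sum(shares)
    nT <- round(nResp * shares[1])
    nS <- round(nResp * shares[2])
    nB <- nResp - nT - nS
    labels <- c(rep("transient", nT), rep("sustained", nS),
                rep("both", nB), rep("nonresponsive", n - nResp))
    labels <- sample(labels)
    base <- rgamma(n, shape = 4, rate = 4 / baselineRate)
    tGain <- ifelse(labels %in% c("transient", "both"),
                    transientGain * exp(rnorm(n, 0, 0.15)), 0)
    sGain <- ifelse(labels %in% c("sustained", "both"),
                    sustainedGain * exp(rnorm(n, 0, 0.15)), 0)
    resp <- labels != "nonresponsive"
    pref <- rep(FALSE, n)
    pref[resp] <- sample(rep(c(TRUE, FALSE),
                             times = c(round(sum(resp) *
                                               gowPreferringFraction),
                                       sum(resp) - round(sum(resp) *
                                               gowPreferringFraction))))
    data.frame(
      neuron_id = seq_len(n),
      class_label = labels,
      baseline_rate = base,
      transient_gain = tGain,
      onset_latency_s = 0.02,
      tau_rise_s = 0.01,
      tau_decay_s = 0.06,
      self_attenuation = selfAttenuation,
      sustained_gain = sGain,
      habituation_slope = habituationSlope,
      gow_sign = ifelse(!resp, 1, ifelse(pref, 1, -1)),
      low_sign = ifelse(!resp, 1, ifelse(pref, -1, 1)),
      preferred_whiskers = paste(seq_len(nWhiskers), collapse = ","),
      stringsAsFactors = FALSE)
  })
}

# Peak-normalised difference-of-exponentials transient kernel on the frame
# grid; support truncated at latency + 8 decay constants.
transientKernel <- function(latency, tauRise, tauDecay, frameRate) {
  tmax <- latency + 8 * tauDecay
  t <- seq(0, tmax, by = 1 / frameRate)
  u <- pmax(0, t - latency)
  k <- (1 - exp(-u / tauRise)) * exp(-u / tauDecay)
  if (max(k) > 0) k <- k / max(k)
  k
}

#' Simulate spike trains from ground-truth events
#'
#' Each neuron fires as an inhomogeneous Poisson process (thinning sampler,
#' 2 ms absolute refractory period) with rate
#' \deqn{\lambda(t) = \mathrm{base} + \sum_e s_e \, g \, K(t - t_e)\,
#'   a_e \max(0, 1 + h\,(r_e - 1)) + g_s \cdot \mathrm{touching}(t)}
#' where \eqn{K} is a peak-normalised difference-of-exponentials kernel,
#' \eqn{s_e} the GoW/LoW polarity, \eqn{a_e} the origin factor (1 for
#' external events, \code{self_attenuation} for self events), \eqn{h} the
#' fractional habituation slope applied to external-GoW repetitions
#' \eqn{r_e}, and \eqn{g_s} the sustained gain during surface touch.
#' Negative rates are floored at zero.
#'
#' @param events ground-truth contact events (see
#'   \code{\link{deriveContactTruth}})
#' @param touching per-frame any-contact mask (or frames x whiskers matrix)
#' @param neurons neuron specification data.frame
#'   (see \code{\link{makeNeuronSpecs}})
#' @param duration session duration (s)
#' @param frameRate frame clock rate (frames/s)
#' @param seed integer seed (spike substream)
#' @param refractory absolute refractory period (s)
#' @param sustainedTau rise time constant of the sustained drive (s): the
#'   self-generated touch response builds up over repeated whisks against
#'   the surface rather than stepping on instantaneously
#' @return named list of spike-time vectors, one per neuron
#' @export
simulateSpikes <- function(events, touching, neurons, duration, frameRate,
                           seed = 1L, refractory = 0.002,
                           sustainedTau = 0.5) {
  if (any(neurons$baseline_rate < 0) || any(neurons$transient_gain < 0) ||
      any(neurons$sustained_gain < 0))
    configError("negative rates in neuron specification")
  withSubstream(seed, "spikes", {
    n <- round(duration * frameRate)
    if (is.matrix(touching)) touching <- rowSums(touching) > 0
    if (length(touching) == 1) touching <- rep(touching, n)
    sustDrive <- if (sustainedTau > 0) {
      a <- exp(-1 / (sustainedTau * frameRate))
      as.numeric(stats::filter(touching * (1 - a), a, "recursive"))
    } else {
      as.numeric(touching)
    }
    trains <- vector("list", nrow(neurons))
    for (i in seq_len(nrow(neurons))) {
      nr <- neurons[i, ]
      rate <- rep(nr$baseline_rate, n)
      if (nr$sustained_gain > 0) rate <- rate + nr$sustained_gain * sustDrive
      if (nr$transient_gain > 0 && nrow(events)) {
        kern <- transientKernel(nr$onset_latency_s, nr$tau_rise_s,
                                nr$tau_decay_s, frameRate)
        pref <- as.integer(strsplit(nr$preferred_whiskers, ",")[[1]])
        ev <- events[events$whisker_id %in% pref, , drop = FALSE]
        if (nrow(ev)) {
          sgn <- ifelse(ev$kind == "GoW", nr$gow_sign, nr$low_sign)
          origin <- ifelse(ev$origin == "external", 1, nr$self_attenuation)
          hab <- ifelse(ev$origin == "external" & ev$kind == "GoW",
                        pmax(0, 1 + nr$habituation_slope *
                               (ev$repetition - 1)), 1)
          for (j in seq_len(nrow(ev))) {
            f0 <- ev$frame[j]
            idx <- f0:min(n, f0 + length(kern) - 1L)
            rate[idx] <- rate[idx] + sgn[j] * nr$transient_gain *
              origin[j] * hab[j] * kern[seq_along(idx)]
          }
        }
      }
      rate <- pmax(0, rate)
      trains[[i]] <- poissonThin(rate, frameRate, refractory)
    }
    names(trains) <- as.character(neurons$neuron_id)
    trains
  })
}

# Thinning sampler for an inhomogeneous Poisson process given a frame-grid
# rate, with an absolute refractory period applied in order of time.
poissonThin <- function(rate, frameRate, refractory = 0.002) {
  lamMax <- max(rate)
  dur <- length(rate) / frameRate
  if (lamMax <= 0 || dur <= 0) return(numeric(0))
  m <- rpois(1, lamMax * dur)
  if (m == 0) return(numeric(0))
  cand <- sort(runif(m, 0, dur))
  lam <- rate[pmin(length(rate), floor(cand * frameRate) + 1L)]
  keep <- runif(m) < lam / lamMax
  tt <- cand[keep]
  if (!length(tt)) return(tt)
  out <- numeric(length(tt))
  k <- 1L
  out[1] <- tt[1]
  for (i in seq_along(tt)[-1]) {
    if (tt[i] - out[k] >= refractory) {
      k <- k + 1L
      out[k] <- tt[i]
    }
  }
  out[seq_len(k)]
}

# Render whisker angles as 4 collinear-with-jitter labelled points per
# whisker about a fixed face reference point (image coordinates, y down).
# During contact the whisker bends: a curvature trace rises toward
# `contactKappa` (1/px) with a ~10 ms time constant while in contact and
# relaxes after release; labels are displaced perpendicular to the whisker
# ray by kappa/2 * r^2 (quadratic bend), so Menger curvature of the distal
# labels recovers ~contactKappa during touch.
renderWhiskerTracks <- function(angles, facePoint = c(256, 256), pxPerMm = 20,
                         jitterPx = 0.3, contact = NULL,
                         contactKappa = 2e-3, bendTau = 0.01,
                         frameRate = 500, seed = 1L) {
  withSubstream(seed, "tracks", {
    n <- nrow(angles)
    nw <- ncol(angles)
    radii <- pxPerMm * c(3, 6, 9, 12)   # labels 0..3, base to tip
    bend <- matrix(0, n, nw)
    if (!is.null(contact)) {
      a <- exp(-1 / (bendTau * frameRate))
      for (w in seq_len(nw)) {
        # first-order relaxation toward the contact indicator
        bend[, w] <- contactKappa * as.numeric(
          stats::filter(contact[, w] * (1 - a), a, "recursive"))
      }
    }
    frames <- rep(seq_len(n), times = nw * 4L)
    wid <- rep(rep(seq_len(nw), each = n), times = 4L)
    lab <- rep(0:3, each = n * nw)
    th <- angles[cbind(frames, wid)] * pi / 180
    r <- radii[lab + 1L]
    d <- bend[cbind(frames, wid)] / 2 * r^2   # perpendicular displacement
    data.frame(
      frame = frames, whisker_id = wid, label_index = lab,
      x_px = facePoint[1] + r * sin(th) - d * cos(th) +
        rnorm(length(th), 0, jitterPx),
      y_px = facePoint[2] - r * cos(th) - d * sin(th) +
        rnorm(length(th), 0, jitterPx))
  })
}

#' Build a regular event schedule
#'
#' Convenience generator for parameter-recovery experiments: a single
#' stimulus stream of evenly spaced contact events with repetition indices
#' 1..n, usable directly with \code{\link{simulateSpikes}} without running
#' a full closed-loop session.
#'
#' @param n number of events
#' @param spacing inter-event interval (s)
#' @param start time of the first event (s)
#' @param kind,origin,direction,whisker event stream labels
#' @param frameRate frame clock used for the frame column
#' @return ground-truth-shaped event data.frame
#' @export
makeEventSchedule <- function(n, spacing = 10, start = 5, kind = "GoW",
                              origin = "external", direction = "rostral",
                              whisker = 1L, frameRate = 500) {
  tt <- start + spacing * (seq_len(n) - 1)
  data.frame(time_s = tt, frame = round(tt * frameRate) + 1L,
             whisker_id = whisker, kind = kind, origin = origin,
             direction = direction, repetition = seq_len(n),
             stringsAsFactors = FALSE)
}

#' Contact mask implied by an event schedule
#'
#' Marks frames as touching from each GoW event until \code{hold} seconds
#' later (or the next LoW of the same whisker, whichever is first), for
#' driving sustained responses in \code{\link{simulateSpikes}}.
#'
#' @param events event data.frame (\code{\link{makeEventSchedule}})
#' @param duration session duration (s)
#' @param frameRate frames/s
#' @param hold contact hold time after each GoW (s)
#' @return logical per-frame mask
#' @export
touchingFromEvents <- function(events, duration, frameRate, hold = 5) {
  n <- round(duration * frameRate)
  mask <- logical(n)
  gow <- events[events$kind == "GoW", , drop = FALSE]
  low <- events[events$kind == "LoW", , drop = FALSE]
  for (i in seq_len(nrow(gow))) {
    t0 <- gow$time_s[i]
    tEnd <- t0 + hold
    nextLow <- low$time_s[low$whisker_id == gow$whisker_id[i] &
                            low$time_s > t0]
    if (length(nextLow)) tEnd <- min(tEnd, min(nextLow))
    i0 <- floor(t0 * frameRate) + 1L
    i1 <- min(n, ceiling(tEnd * frameRate))
    if (i0 <= n) mask[i0:i1] <- TRUE
  }
  mask
}

#' Simulate a complete closed-loop session
#'
#' Orchestrates the generator stages under named seed substreams:
#' locomotion, surface protocol, whisking, ground-truth contact events,
#' neuron specification, spike trains and (optionally) rendered whisker
#' point tracks.
#'
#' @param cfg a \linkS4class{SessionConfig}
#' @param seed master integer seed (defaults to \code{cfg@seed})
#' @param neurons optional neuron specification data.frame; generated with
#'   \code{\link{makeNeuronSpecs}} defaults when omitted
#' @param renderTracks logical; render pixel point tracks (memory-heavy for
#'   long sessions).  Default: only for sessions up to 120 s.
#' @return a \linkS4class{Session}
#' @examples
#' s <- simulateSession(sessionConfig(duration = 30, nNeurons = 5L), seed = 2)
#' s
#' @export
simulateSession <- function(cfg, seed = cfg@seed, neurons = NULL,
                            renderTracks = NA) {
  validObject(cfg)
  speed <- generateLocomotion(cfg, seed)
  surf <- simulateSurface(as.numeric(speed), cfg, seed)
  wh <- generateWhisking(cfg, surf$surface, seed)
  truth <- deriveContactTruth(cfg, surf$surface, wh$whisking)
  if (is.null(neurons))
    neurons <- makeNeuronSpecs(cfg@nNeurons, nWhiskers = cfg@nWhiskers,
                               seed = substreamSeed(seed, "spikes"))
  spikes <- simulateSpikes(truth$events, truth$touching, neurons,
                           cfg@duration, cfg@frameRate, seed)
  if (is.na(renderTracks)) renderTracks <- cfg@duration <= 120
  facePoint <- c(256, 256)
  tracks <- if (renderTracks) {
    renderWhiskerTracks(wh$angles, facePoint, cfg@pxPerMm,
                        contact = truth$contact,
                        frameRate = cfg@frameRate, seed = seed)
  } else {
    data.frame(frame = integer(), whisker_id = integer(),
               label_index = integer(), x_px = numeric(), y_px = numeric())
  }
  new("Session",
      speed = as.numeric(speed), surface = surf$surface,
      whiskerTracks = tracks, facePoint = facePoint,
      spikes = spikes, trials = surf$trials, config = cfg,
      groundTruth = list(events = truth$events, neurons = neurons,
                         whisking = wh$whisking, touching = truth$touching,
                         contact = truth$contact, angles = wh$angles,
                         running = attr(speed, "running"),
                         phase = wh$phase))
}
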