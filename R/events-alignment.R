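# Trial segmentation, GoW/LoW labelling, event-aligned PSTHs, z-scoring,
# response-window determination and windowed rates.

#' Segment trials from the surface trace
#'
#' One trial per surface-movement onset, annotated with the movement
#' direction and the cumulative locomotor distance since the previous
#' onset.  A constant surface trace yields an empty table.
#'
#' @param speed speed trace (cm/s per frame)
#' @param surface surface position trace (cm per frame)
#' @param frameRate frames/s
#' @return data.frame: trial, frame, time_s, direction, is_return,
#'   position_from, position_to, distance_cm
#' @export
segmentTrials <- function(speed, surface, frameRate) {
  stopifnot(length(speed) == length(surface))
  dx <- c(0, diff(surface))
  moving <- dx != 0
  r <- rle(moving)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  on <- starts[r$values]
  off <- ends[r$values]
  if (!length(on)) {
    return(data.frame(trial = integer(), frame = integer(),
                      time_s = numeric(), direction = character(),
                      is_return = logical(), position_from = numeric(),
                      position_to = numeric(), distance_cm = numeric(),
                      stringsAsFactors = FALSE))
  }
  cum <- cumsum(speed) / frameRate
  from <- surface[pmax(1, on - 1)]
  to <- surface[off]
  prev <- c(1, head(on, -1))
  data.frame(
    trial = seq_along(on), frame = on, time_s = (on - 1) / frameRate,
    direction = ifelse(to > from, "rostral", "caudal"),
    is_return = abs(to) < abs(from),
    position_from = from, position_to = to,
    distance_cm = cum[on] - cum[prev], stringsAsFactors = FALSE)
}

#' Label surface movements as GoW/LoW stimuli
#'
#' A movement is a GoW stimulus when at least one whisker gained contact
#' within the movement epoch, a LoW stimulus when at least one lost
#' contact; both can hold at once, and a movement within the
#' already-contacted span is neither.
#'
#' @param trials trial table (\code{\link{segmentTrials}})
#' @param events contact events with columns \code{time_s}, \code{kind},
#'   \code{origin}
#' @param epoch seconds after movement onset searched for contact changes
#'   (defaults to one translation ramp plus 100 ms)
#' @return \code{trials} with logical columns \code{gow} and \code{low}
#' @export
labelGowLow <- function(trials, events, epoch = 0.35) {
  ext <- events[events$origin == "external", , drop = FALSE]
  trials$gow <- vapply(trials$time_s, function(t0)
    any(ext$kind == "GoW" & ext$time_s >= t0 & ext$time_s < t0 + epoch),
    logical(1))
  trials$low <- vapply(trials$time_s, function(t0)
    any(ext$kind == "LoW" & ext$time_s >= t0 & ext$time_s < t0 + epoch),
    logical(1))
  trials
}

#' Align spikes to events and bin into a PSTH
#'
#' Bins are half-open \code{[t, t + width)} relative to event onset; a
#' spike exactly at the event time falls in the first post-onset bin.
#' The baseline statistics stored for z-scoring are computed from the
#' per-event rates in \code{baselineWindow}.
#'
#' @param spikes numeric spike times (s)
#' @param eventTimes numeric event onset times (s); at least one
#' @param window peri-event window (s, length 2)
#' @param binWidth bin width (s)
#' @param baselineWindow window used for baseline statistics (s, relative
#'   to onset)
#' @return a \linkS4class{PSTH}
#' @export
alignAndBin <- function(spikes, eventTimes, window = c(-1, 2),
                        binWidth = 0.05, baselineWindow = c(-0.3, 0)) {
  if (!length(eventTimes)) inputError("at least one event is required")
  if (binWidth <= 0) inputError("bin width must be positive")
  edges <- seq(window[1], window[2], by = binWidth)
  if (max(edges) < window[2]) edges <- c(edges, max(edges) + binWidth)
  nb <- length(edges) - 1
  counts <- matrix(0L, length(eventTimes), nb)
  for (i in seq_along(eventTimes)) {
    rel <- spikes - eventTimes[i]
    rel <- rel[rel >= edges[1] & rel < edges[nb + 1]]
    if (length(rel)) {
      b <- findInterval(rel, edges, left.open = FALSE)
      tb <- tabulate(b, nbins = nb)
      counts[i, ] <- tb
    }
  }
  rates <- counts / binWidth
  rate <- colMeans(rates)
  sem <- apply(rates, 2, sd) / sqrt(nrow(rates))
  if (nrow(rates) < 2) sem <- rep(0, ncol(rates))
  baseRates <- vapply(seq_along(eventTimes), function(i) {
    rel <- spikes - eventTimes[i]
    sum(rel >= baselineWindow[1] & rel < baselineWindow[2]) /
      diff(baselineWindow)
  }, numeric(1))
  new("PSTH", binEdges = edges, counts = counts, rate = rate, sem = sem,
      baselineMean = mean(baseRates), baselineSd = sd(baseRates),
      baselineWindow = baselineWindow)
}

#' z-score a PSTH against its baseline statistics
#'
#' @param psth a \linkS4class{PSTH}
#' @return numeric z-scored rate per bin
#' @export
zscorePsth <- function(psth) {
  if (is.na(psth@baselineSd) || psth@baselineSd <= 0)
    inputError(paste("baseline standard deviation is zero;",
                     "neuron must be flagged and excluded"))
  (psth@rate - psth@baselineMean) / psth@baselineSd
}

#' Determine the transient response window from a population PSTH
#'
#' Automates trough-to-trough bracketing of the transient peak: the peak is
#' the maximum bin in (0, 0.6] s post onset; the window runs from the
#' nearest preceding local minimum to the nearest following local minimum,
#' clamped to [0, 0.8] s.  When no interior peak exceeds the baseline mean
#' plus two baseline s.d., the fallback window [0, 0.3] s is returned.
#'
#' @param psth population-mean \linkS4class{PSTH} (50 ms bins over
#'   [-0.5, 1.5] s recommended)
#' @return numeric window \code{c(t0, t1)} in seconds with attribute
#'   \code{fallback}
#' @export
findTransientWindow <- function(psth) {
  ctr <- binCenters(psth)
  rate <- psth@rate
  sel <- which(ctr > 0 & ctr <= 0.6)
  fallback <- c(0, 0.3)
  if (!length(sel)) {
    attr(fallback, "fallback") <- TRUE
    return(fallback)
  }
  peakBin <- sel[which.max(rate[sel])]
  thr <- psth@baselineMean + 2 * ifelse(is.na(psth@baselineSd), 0,
                                        psth@baselineSd)
  if (rate[peakBin] <= thr) {
    attr(fallback, "fallback") <- TRUE
    return(fallback)
  }
  # a trough is a weak local minimum strictly below the peak rate
  # (plateaus at peak level are part of the response, not troughs)
  isTrough <- function(i) {
    lo <- if (i > 1) rate[i - 1] else Inf
    hi <- if (i < length(rate)) rate[i + 1] else Inf
    rate[i] <= lo && rate[i] <= hi && rate[i] < rate[peakBin]
  }
  t0 <- 0
  for (i in rev(seq_len(peakBin - 1))) {
    if (isTrough(i)) { t0 <- psth@binEdges[i]; break }
  }
  t1 <- 0.8
  after <- if (peakBin < length(rate)) (peakBin + 1):length(rate)
           else integer(0)
  for (i in after) {
    if (isTrough(i)) { t1 <- psth@binEdges[i + 1]; break }
  }
  win <- c(max(0, t0), min(0.8, t1))
  attr(win, "fallback") <- FALSE
  win
}

#' Standard response windows around an event
#'
#' Packs the analysis windows: a 300 ms pre-movement baseline, the
#' transient window, a 300 ms sustained window starting one second after
#' the transient window ends, the 50 ms post-touch GoW window and the
#' 500 ms pre/post modulation windows anchored at movement onset.
#'
#' @param transient numeric \code{c(t0, t1)} transient window (s)
#' @return named list of \code{c(start, end)} windows (s, relative to
#'   event onset)
#' @export
responseWindows <- function(transient = c(0, 0.3)) {
  if (transient[1] >= transient[2])
    inputError("transient window must satisfy t0 < t1")
  list(baseline = c(-0.3, 0),
       transient = transient,
       sustained = c(transient[2] + 1, transient[2] + 1.3),
       gow = c(0, 0.05),
       modulation_pre = c(-0.5, 0),
       modulation_post = c(0, 0.5))
}

#' Firing rates in analysis windows, per event
#'
#' @param spikes numeric spike times (s)
#' @param eventTimes event onsets (s)
#' @param windows named list of \code{c(start, end)} windows relative to
#'   onset (see \code{\link{responseWindows}})
#' @param duration recording duration (s); when given, events whose windows
#'   leave \code{[0, duration]} raise a boundary error naming them
#' @return matrix events x windows of rates (spikes/s)
#' @export
windowRates <- function(spikes, eventTimes, windows, duration = NULL) {
  if (!is.null(duration)) {
    lo <- min(vapply(windows, `[`, numeric(1), 1))
    hi <- max(vapply(windows, `[`, numeric(1), 2))
    bad <- which(eventTimes + lo < 0 | eventTimes + hi > duration)
    if (length(bad))
      inputError(paste("windows exceed the recording for events:",
                       paste(bad, collapse = ", ")))
  }
  out <- matrix(0, length(eventTimes), length(windows),
                dimnames = list(NULL, names(windows)))
  for (j in seq_along(windows)) {
    w <- windows[[j]]
    len <- w[2] - w[1]
    for (i in seq_along(eventTimes)) {
      rel <- spikes - eventTimes[i]
      out[i, j] <- sum(rel >= w[1] & rel < w[2]) / len
    }
  }
  out
}

#' Exclude events whose baseline is contaminated by a same-stream event
#'
#' @param eventTimes event onsets of one stream (s)
#' @param baselineWindow baseline window relative to onset (s)
#' @return logical mask of events to keep
#' @export
cleanBaselineEvents <- function(eventTimes, baselineWindow = c(-0.3, 0)) {
  vapply(seq_along(eventTimes), function(i) {
    others <- eventTimes[-i]
    !any(others >= eventTimes[i] + baselineWindow[1] &
           others < eventTimes[i] + baselineWindow[2])
  }, logical(1))
}
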