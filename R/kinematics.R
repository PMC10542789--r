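# Whisker kinematics: angle from labelled points, band-pass filtering,
# Menger curvature, cubic-window curvature derivative, whisk phase, and
# threshold-based touch detection.

#' Whisker angle from labelled points
#'
#' Angle of each labelled point about a fixed face reference point, measured
#' against the image's vertical axis: 0 degrees is vertically above the face
#' point and positive angles are rostral (toward +x).  Image coordinates
#' have y increasing downward.
#'
#' @param tracks data.frame with columns \code{frame}, \code{whisker_id},
#'   \code{label_index}, \code{x_px}, \code{y_px}; frames with missing
#'   labels yield \code{NA} angles (a gap), never an error
#' @param facePoint numeric (x, y) of the face reference point in pixels
#' @param nFrames number of frames on the session clock (inferred from the
#'   maximum frame index when omitted)
#' @return list with \code{perLabel} (data.frame frame, whisker_id,
#'   label_index, angle_deg) and \code{angle} (frames x whiskers matrix of
#'   the per-whisker mean-of-labels angle, degrees)
#' @export
whiskerAngle <- function(tracks, facePoint, nFrames = NULL) {
  if (!nrow(tracks)) inputError("empty whisker track table")
  dx <- tracks$x_px - facePoint[1]
  dy <- tracks$y_px - facePoint[2]
  ang <- atan2(dx, -dy) * 180 / pi
  perLabel <- data.frame(frame = tracks$frame,
                         whisker_id = tracks$whisker_id,
                         label_index = tracks$label_index,
                         angle_deg = ang)
  if (is.null(nFrames)) nFrames <- max(tracks$frame)
  wids <- sort(unique(tracks$whisker_id))
  angle <- matrix(NA_real_, nFrames, length(wids),
                  dimnames = list(NULL, as.character(wids)))
  agg <- tapply(ang, list(tracks$frame, tracks$whisker_id),
                mean, na.rm = TRUE)
  rows <- as.integer(rownames(agg))
  angle[rows, colnames(agg)] <- agg
  list(perLabel = perLabel, angle = angle)
}

#' Zero-phase band-pass filter for whisker angle
#'
#' Butterworth band-pass (default 1--30 Hz, order 4) applied forward and
#' backward (\code{signal::filtfilt}) so the output has no phase delay and
#' the DC component is removed.  Interior \code{NA} gaps up to
#' \code{maxGap} seconds are bridged by linear interpolation before
#' filtering; longer gaps stay \code{NA} in the output.
#'
#' @param angle numeric angle trace (degrees)
#' @param frameRate frames/s
#' @param low,high band edges (Hz)
#' @param order filter order
#' @param maxGap longest interpolatable gap (s)
#' @return filtered trace (degrees), zero-mean in the passband sense
#' @export
bandpassAngle <- function(angle, frameRate, low = 1, high = 30, order = 4,
                          maxGap = 0.02) {
  if (length(angle) < 3 * (2 * order + 1))
    inputError("trace too short for the band-pass filter warm-up")
  isna <- is.na(angle)
  x <- angle
  if (any(isna)) {
    if (all(isna)) return(angle)
    ok <- which(!isna)
    x <- approx(ok, angle[ok], xout = seq_along(angle), rule = 2)$y
    # re-blank gaps longer than maxGap
    r <- rle(isna)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    longGap <- which(r$values & r$lengths > maxGap * frameRate)
  }
  bf <- signal::butter(order, c(low, high) / (frameRate / 2), type = "pass")
  y <- signal::filtfilt(bf, x - mean(x))
  if (any(isna) && length(longGap)) {
    for (g in longGap) y[starts[g]:ends[g]] <- NA_real_
  }
  y
}

#' Menger curvature of a point triple
#'
#' Curvature of the circle through three points:
#' \eqn{\kappa = 4A / (|p_1p_2|\,|p_2p_3|\,|p_1p_3|)}, i.e. the inverse
#' circumradius, signed by the z-component of the cross product
#' \eqn{(p_2-p_1)\times(p_3-p_2)} (positive for a counter-clockwise,
#' i.e. rostrally concave, triple in image coordinates).
#'
#' @param p1,p2,p3 numeric (x, y) points, or matrices with one point per row
#'   for vectorised evaluation
#' @return signed curvature (1 / units of the input coordinates)
#' @examples
#' mengerCurvature(c(0, 0), c(1, 1), c(2, 0))  # |curvature| = 1
#' @export
mengerCurvature <- function(p1, p2, p3) {
  if (is.null(dim(p1))) {
    p1 <- matrix(p1, 1); p2 <- matrix(p2, 1); p3 <- matrix(p3, 1)
  }
  a <- sqrt(rowSums((p2 - p1)^2))
  b <- sqrt(rowSums((p3 - p2)^2))
  cc <- sqrt(rowSums((p3 - p1)^2))
  if (any(a == 0 | b == 0 | cc == 0))
    inputError("Menger curvature requires three distinct points")
  cross <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p2[, 2]) -
    (p2[, 2] - p1[, 2]) * (p3[, 1] - p2[, 1])
  kappa <- 2 * cross / (a * b * cc)   # 4 * (cross/2) / (a b c), signed
  drop(kappa)
}

#' Curvature derivative by local cubic fit
#'
#' The derivative at each frame is the slope at the window centre of a cubic
#' polynomial least-squares fit to the curvature within a centred moving
#' window (default 100 ms) — a Savitzky--Golay first-derivative filter of
#' polynomial order 3.  Edges use truncated-window fits.
#'
#' @param kappa curvature trace (1/mm)
#' @param frameRate frames/s
#' @param window window length (s)
#' @return derivative trace (1/mm/s)
#' @export
curvatureDerivative <- function(kappa, frameRate, window = 0.1) {
  nw <- round(window * frameRate)
  if (nw < 4) configError("derivative window must span at least 4 samples")
  if (nw %% 2 == 0) nw <- nw + 1
  if (length(kappa) < nw)
    inputError("curvature trace shorter than the fitting window")
  signal::sgolayfilt(kappa, p = 3, n = nw, m = 1, ts = 1 / frameRate)
}

#' Instantaneous whisk phase
#'
#' Analytic-signal phase of the band-limited angle (FFT Hilbert transform).
#' Convention: phase 0 at the rostral (protracted) peak of each whisk cycle;
#' protraction — the half-cycle of rostrally increasing angle — corresponds
#' to phase in \eqn{(-\pi, 0)}.
#'
#' @param filtered band-passed angle trace (degrees)
#' @param varTol variance floor below which the phase is undefined
#' @return list with \code{phase} (radians in (-pi, pi], \code{NA} when
#'   undefined) and \code{protraction} (logical mask)
#' @export
whiskPhase <- function(filtered, varTol = 1e-6) {
  x <- filtered
  n <- length(x)
  if (!n) inputError("empty angle trace")
  v <- if (all(is.na(x))) NA_real_ else var(x, na.rm = TRUE)
  if (is.na(v) || v < varTol)
    return(list(phase = rep(NA_real_, n), protraction = rep(FALSE, n)))
  nav <- is.na(x)
  if (any(nav)) {
    ok <- which(!nav)
    x <- approx(ok, x[ok], xout = seq_len(n), rule = 2)$y
  }
  x <- x - mean(x)
  # analytic signal: zero the negative frequencies
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- fft(fft(x) * h, inverse = TRUE) / n
  phase <- atan2(Im(z), Re(z))
  phase[nav] <- NA_real_
  list(phase = phase, protraction = !is.na(phase) & phase < 0 & phase >= -pi)
}

#' Compute the full kinematic series for a session
#'
#' Runs angle extraction, band-pass filtering, Menger curvature on the three
#' distal labels, the cubic-window curvature derivative and whisk phase for
#' every whisker.
#'
#' @param session a \linkS4class{Session} with rendered whisker tracks
#' @param pxPerMm pixel scale used to express curvature in 1/mm
#' @param low,high band-pass edges (Hz)
#' @return data.frame with columns frame, whisker_id, angle, filtered_angle,
#'   curvature, dkappa_dt, phase, protraction
#' @export
kinematicSeries <- function(session, pxPerMm = session@config@pxPerMm,
                            low = 1, high = 30) {
  tracks <- whiskerTracks(session)
  if (!nrow(tracks)) inputError("session has no rendered whisker tracks")
  fr <- frameRate(session)
  n <- nFrames(session)
  wa <- whiskerAngle(tracks, session@facePoint, nFrames = n)
  out <- vector("list", ncol(wa$angle))
  for (j in seq_len(ncol(wa$angle))) {
    wid <- as.integer(colnames(wa$angle)[j])
    ang <- wa$angle[, j]
    filt <- bandpassAngle(ang, fr, low = low, high = high)
    tw <- tracks[tracks$whisker_id == wid & tracks$label_index >= 1, ]
    tw <- tw[order(tw$frame, tw$label_index), ]
    p1 <- cbind(tw$x_px[tw$label_index == 1], tw$y_px[tw$label_index == 1])
    p2 <- cbind(tw$x_px[tw$label_index == 2], tw$y_px[tw$label_index == 2])
    p3 <- cbind(tw$x_px[tw$label_index == 3], tw$y_px[tw$label_index == 3])
    kappa <- mengerCurvature(p1, p2, p3) * pxPerMm   # 1/px -> 1/mm
    dk <- curvatureDerivative(kappa, fr)
    ph <- whiskPhase(filt)
    out[[j]] <- data.frame(frame = seq_len(n), whisker_id = wid,
                           angle = ang, filtered_angle = filt,
                           curvature = kappa, dkappa_dt = dk,
                           phase = ph$phase, protraction = ph$protraction)
  }
  do.call(rbind, out)
}

#' Detect touch onsets from curvature kinematics
#'
#' An onset is scored when |d\eqn{\kappa}/dt| exceeds \code{k} times the
#' median absolute deviation of its no-contact distribution and the
#' curvature excursion persists for at least \code{hold} seconds; onsets of
#' the same whisker closer than \code{deadTime} are merged.
#'
#' @param kin kinematic series from \code{\link{kinematicSeries}}
#' @param frameRate frames/s
#' @param k threshold in robust s.d. units (MAD-based)
#' @param hold minimum excursion duration (s)
#' @param deadTime minimum separation of successive onsets (s)
#' @param baselineMask optional logical no-contact mask used to estimate the
#'   null spread (defaults to the whole series)
#' @return data.frame with columns frame, time_s, whisker_id,
#'   phase_at_onset, score
#' @export
detectTouch <- function(kin, frameRate, k = 5, hold = 0.01, deadTime = 0.02,
                        baselineMask = NULL) {
  if (!nrow(kin)) inputError("empty kinematic series")
  res <- list()
  for (wid in unique(kin$whisker_id)) {
    kw <- kin[kin$whisker_id == wid, ]
    dk <- kw$dkappa_dt
    base <- if (is.null(baselineMask)) dk else dk[baselineMask]
    spread <- mad(base, na.rm = TRUE)
    if (!is.finite(spread) || spread == 0) next
    thr <- k * spread
    if (!is.finite(thr)) next
    above <- !is.na(dk) & abs(dk) > thr
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    holdN <- max(1L, round(hold * frameRate))
    qual <- which(r$values & r$lengths >= holdN)
    if (!length(qual)) next
    # onset = frame of peak |dkappa/dt| within each suprathreshold run
    # (the centred fitting window otherwise anticipates the rise)
    cand <- vapply(qual, function(q) {
      run <- starts[q]:ends[q]
      run[which.max(abs(dk[run]))]
    }, integer(1))
    # merge onsets within the dead time
    keep <- c(TRUE, diff(cand) >= deadTime * frameRate)
    cand <- cand[keep]
    res[[as.character(wid)]] <- data.frame(
      frame = kw$frame[cand], time_s = (kw$frame[cand] - 1) / frameRate,
      whisker_id = wid, phase_at_onset = kw$phase[cand],
      score = abs(dk[cand]) / spread)
  }
  if (!length(res)) {
    return(data.frame(frame = integer(), time_s = numeric(),
                      whisker_id = integer(), phase_at_onset = numeric(),
                      score = numeric()))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$time_s), ]
}
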