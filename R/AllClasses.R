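#' Configuration of a simulated whisker virtual-reality session
#'
#' Holds every tunable of the closed-loop generator.  Defaults reproduce the
#' behavioural statistics of head-fixed mice in the whisker virtual reality:
#' volitional running at 23.7 cm/s, rhythmic whisking at 19 Hz, a surface
#' translation of 1 cm triggered after every 200 cm of locomotion with equal
#' probability of a rostral, caudal or centre outcome.
#'
#' @slot duration session length (s)
#' @slot frameRate acquisition rate of the shared frame clock (frames/s)
#' @slot meanRunSpeed mean treadmill speed during running bouts (cm/s)
#' @slot runBoutMean,restBoutMean mean run/rest bout lengths (s)
#' @slot speedSd s.d. of the slow within-bout speed fluctuation (cm/s)
#' @slot whiskFreq whisking frequency (Hz)
#' @slot whiskAmplitude half-amplitude of the whisk cycle (degrees)
#' @slot whiskFreqJitterSd,whiskAmpJitterSd multiplicative per-cycle jitter s.d.
#' @slot whiskBoutMean,whiskRestMean mean whisking/quiescent bout lengths (s)
#' @slot whiskSetpointTracking setpoint shift per cm of surface position
#'   (degrees/cm); mice track the surface with their whiskers
#' @slot trialDistance locomotor distance that triggers a translation (cm)
#' @slot translationDistance surface excursion per translation (cm)
#' @slot translationDuration duration of the linear translation ramp (s)
#' @slot outcomeProbs named probabilities of each translation outcome
#' @slot nWhiskers,whiskerSetpoints,surfaceAzimuth0,surfaceHalfWidth,azimuthPerCm
#'   contact geometry: resting whisker setpoints (degrees), surface band centre
#'   at position 0, band half-width (degrees) and band shift per cm of surface
#'   position (degrees/cm)
#' @slot nNeurons number of simulated units
#' @slot pxPerMm camera scale used when rendering whisker point tracks
#' @slot seed master seed recorded with the session
#' @exportClass SessionConfig
setClass("SessionConfig", representation(
  duration = "numeric", frameRate = "numeric",
  meanRunSpeed = "numeric", runBoutMean = "numeric", restBoutMean = "numeric",
  speedSd = "numeric",
  whiskFreq = "numeric", whiskAmplitude = "numeric",
  whiskFreqJitterSd = "numeric", whiskAmpJitterSd = "numeric",
  whiskBoutMean = "numeric", whiskRestMean = "numeric",
  whiskSetpointTracking = "numeric",
  trialDistance = "numeric", translationDistance = "numeric",
  translationDuration = "numeric",
  outcomeProbs = "numeric",
  nWhiskers = "integer", whiskerSetpoints = "numeric",
  surfaceAzimuth0 = "numeric", surfaceHalfWidth = "numeric",
  azimuthPerCm = "numeric",
  nNeurons = "integer", pxPerMm = "numeric", seed = "integer"
))

setValidity("SessionConfig", function(object) {
  msgs <- character()
  if (object@duration <= 0) msgs <- c(msgs, "duration must be > 0")
  if (object@frameRate <= 0) msgs <- c(msgs, "frameRate must be > 0")
  if (object@trialDistance <= 0) msgs <- c(msgs, "trialDistance must be > 0")
  if (object@translationDistance <= 0)
    msgs <- c(msgs, "translationDistance must be > 0")
  if (abs(sum(object@outcomeProbs) - 1) > 1e-9)
    msgs <- c(msgs, "outcomeProbs must sum to 1 (tolerance 1e-9)")
  if (any(object@outcomeProbs < 0))
    msgs <- c(msgs, "outcomeProbs must be nonnegative")
  if (is.null(names(object@outcomeProbs)) ||
      !all(nzchar(names(object@outcomeProbs))))
    msgs <- c(msgs, "outcomeProbs must be a named vector")
  if (object@whiskFreq >= object@frameRate / 2)
    msgs <- c(msgs, "whiskFreq must be below the Nyquist frequency")
  if (length(object@whiskerSetpoints) != object@nWhiskers)
    msgs <- c(msgs, "whiskerSetpoints length must equal nWhiskers")
  if (object@meanRunSpeed <= 0) msgs <- c(msgs, "meanRunSpeed must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Create a session configuration
#'
#' @param duration session length in seconds
#' @param frameRate frame rate in frames/s
#' @param meanRunSpeed mean running speed (cm/s)
#' @param runBoutMean,restBoutMean mean run and rest bout lengths (s)
#' @param speedSd within-bout speed fluctuation s.d. (cm/s)
#' @param whiskFreq whisking frequency (Hz)
#' @param whiskAmplitude whisk half-amplitude (degrees)
#' @param whiskFreqJitterSd,whiskAmpJitterSd per-cycle multiplicative jitter
#' @param whiskBoutMean,whiskRestMean mean whisking and quiescent bout lengths (s)
#' @param whiskSetpointTracking whisker setpoint shift per cm of surface position
#' @param trialDistance locomotor distance per trial trigger (cm)
#' @param translationDistance surface translation distance (cm)
#' @param translationDuration translation ramp duration (s)
#' @param outcomeProbs named outcome probabilities (must sum to 1)
#' @param nWhiskers number of tracked whiskers
#' @param whiskerSetpoints resting setpoint angle per whisker (degrees)
#' @param surfaceAzimuth0 surface band centre azimuth at position 0 (degrees)
#' @param surfaceHalfWidth surface band half-width (degrees)
#' @param azimuthPerCm band azimuth shift per cm of surface position
#' @param nNeurons number of simulated neurons
#' @param pxPerMm camera scale (pixels per mm)
#' @param seed master seed stored with the configuration
#' @return a validated \linkS4class{SessionConfig}
#' @examples
#' cfg <- sessionConfig(duration = 60)
#' cfg
#' @export
sessionConfig <- function(duration = 600, frameRate = 500,
                          meanRunSpeed = 23.7, runBoutMean = 25,
                          restBoutMean = 4, speedSd = 3,
                          whiskFreq = 19, whiskAmplitude = 15,
                          whiskFreqJitterSd = 0.04, whiskAmpJitterSd = 0.1,
                          whiskBoutMean = 20, whiskRestMean = 2.5,
                          whiskSetpointTracking = 4,
                          trialDistance = 200, translationDistance = 1,
                          translationDuration = 0.25,
                          outcomeProbs = c(rostral = 1, caudal = 1,
                                           center = 1) / 3,
                          nWhiskers = 3L,
                          whiskerSetpoints = c(60, 90, 120),
                          surfaceAzimuth0 = 90, surfaceHalfWidth = 14,
                          azimuthPerCm = 12,
                          nNeurons = 50L, pxPerMm = 20, seed = 1L) {
  obj <- try(new("SessionConfig",
    duration = duration, frameRate = frameRate,
    meanRunSpeed = meanRunSpeed, runBoutMean = runBoutMean,
    restBoutMean = restBoutMean, speedSd = speedSd,
    whiskFreq = whiskFreq, whiskAmplitude = whiskAmplitude,
    whiskFreqJitterSd = whiskFreqJitterSd, whiskAmpJitterSd = whiskAmpJitterSd,
    whiskBoutMean = whiskBoutMean, whiskRestMean = whiskRestMean,
    whiskSetpointTracking = whiskSetpointTracking,
    trialDistance = trialDistance, translationDistance = translationDistance,
    translationDuration = translationDuration,
    outcomeProbs = outcomeProbs,
    nWhiskers = as.integer(nWhiskers), whiskerSetpoints = whiskerSetpoints,
    surfaceAzimuth0 = surfaceAzimuth0, surfaceHalfWidth = surfaceHalfWidth,
    azimuthPerCm = azimuthPerCm,
    nNeurons = as.integer(nNeurons), pxPerMm = pxPerMm,
    seed = as.integer(seed)), silent = TRUE)
  if (inherits(obj, "try-error"))
    configError(paste("invalid session configuration:",
                      attr(obj, "condition")$message))
  obj
}

#' A whisker virtual-reality recording session
#'
#' One recording on a shared frame clock: treadmill speed, surface axial
#' position, labelled whisker point tracks, per-neuron spike trains, the
#' trial table, and (for simulated sessions) ground truth about contact
#' events and generative neuron parameters.
#'
#' @slot speed treadmill speed (cm/s), one value per frame
#' @slot surface surface axial position (cm), one value per frame
#' @slot whiskerTracks data.frame of labelled points
#'   (frame, whisker_id, label_index, x_px, y_px); may have zero rows when
#'   track rendering is disabled
#' @slot facePoint the face reference point (x, y) in pixels
#' @slot spikes named list of numeric spike-time vectors (s), one per neuron
#' @slot trials trial table (see \code{\link{segmentTrials}})
#' @slot config the \linkS4class{SessionConfig} that produced the session
#' @slot groundTruth list with elements \code{events} (true contact events),
#'   \code{neurons} (generative parameters), \code{whisking} and
#'   \code{touching} per-frame masks, and \code{angles}
#'   (frames x whiskers matrix of true whisker angles, degrees)
#' @exportClass Session
setClass("Session", representation(
  speed = "numeric", surface = "numeric",
  whiskerTracks = "data.frame", facePoint = "numeric",
  spikes = "list", trials = "data.frame",
  config = "SessionConfig", groundTruth = "list"
))

setValidity("Session", function(object) {
  msgs <- character()
  n <- length(object@speed)
  if (length(object@surface) != n)
    msgs <- c(msgs, "speed and surface traces must share the frame clock")
  dur <- n / object@config@frameRate
  st <- unlist(object@spikes, use.names = FALSE)
  if (length(st) && (min(st) < 0 || max(st) > dur + 1e-9))
    msgs <- c(msgs, "spike times must lie within [0, duration]")
  if (any(object@speed < 0)) msgs <- c(msgs, "speeds must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' Peristimulus time histogram
#'
#' Event-aligned binned spike counts with trial-mean rate, s.e.m. and the
#' baseline statistics used for z-scoring.  Bins are half-open
#' \code{[t, t + width)} relative to event onset.
#'
#' @slot binEdges bin edges (s, relative to event; length bins + 1)
#' @slot counts events x bins matrix of spike counts
#' @slot rate mean firing rate per bin (spikes/s)
#' @slot sem standard error of the mean rate per bin (spikes/s)
#' @slot baselineMean,baselineSd baseline rate statistics (spikes/s) from the
#'   pre-event baseline window
#' @slot baselineWindow the baseline window (s, relative to event)
#' @exportClass PSTH
setClass("PSTH", representation(
  binEdges = "numeric", counts = "matrix", rate = "numeric", sem = "numeric",
  baselineMean = "numeric", baselineSd = "numeric", baselineWindow = "numeric"
))

setValidity("PSTH", function(object) {
  msgs <- character()
  nb <- length(object@binEdges) - 1
  if (ncol(object@counts) != nb) msgs <- c(msgs, "counts/binEdges mismatch")
  if (length(object@rate) != nb) msgs <- c(msgs, "rate length mismatch")
  w <- diff(object@binEdges)
  expect <- colSums(object@counts) / (nrow(object@counts) * w)
  if (max(abs(expect - object@rate)) > 1e-8)
    msgs <- c(msgs, "rate must equal total counts / (n_trials * bin width)")
  if (any(object@sem < 0)) msgs <- c(msgs, "sem must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' Time-resolved population decoding result
#'
#' @slot time prediction times (s, relative to movement onset)
#' @slot accuracy mean held-out zero-one accuracy per time (fraction)
#' @slot sem s.e.m. of accuracy over resample runs
#' @slot chance chance level (1 / number of classes under balanced labels)
#' @slot nClasses number of classes decoded
#' @slot nNeurons number of neurons in the feature matrix
#' @slot resamples number of resample runs averaged
#' @exportClass DecodingResult
setClass("DecodingResult", representation(
  time = "numeric", accuracy = "numeric", sem = "numeric",
  chance = "numeric", nClasses = "integer", nNeurons = "integer",
  resamples = "integer"
))

setValidity("DecodingResult", function(object) {
  msgs <- character()
  if (length(object@accuracy) != length(object@time))
    msgs <- c(msgs, "accuracy and time must have equal length")
  if (any(object@accuracy < 0 | object@accuracy > 1))
    msgs <- c(msgs, "accuracy must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})
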