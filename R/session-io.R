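# Session directory format: plain TSV tables plus a JSON header.
#
#   speed.tsv          frame, cm_per_s
#   surface.tsv        frame, position_cm
#   whiskers.tsv       frame, whisker_id, label_index, x_px, y_px
#   spikes.tsv         neuron_id, time_s
#   trials.tsv         trial table
#   events_truth.tsv   ground-truth contact events
#   neurons_truth.tsv  generative neuron parameters
#   session.json       config echo, format version, seed, face point

.sessionFormatVersion <- "1.0"

ioError <- function(msg, class) {
  stop(errorCondition(msg,
    class = c(class, "whiskerVR_io_error", "whiskerVR_error",
              "error", "condition")))
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.readTsv <- function(dir, name, required = TRUE) {
  path <- file.path(dir, name)
  if (!file.exists(path)) {
    if (required)
      ioError(paste0("session is missing required table '", name, "'"),
              "whiskerVR_schema_error")
    return(NULL)
  }
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write a session to a directory of plain-text tables
#'
#' @param session a \linkS4class{Session}
#' @param path directory to create/overwrite
#' @return \code{path}, invisibly
#' @seealso \code{\link{readSession}}, \code{\link{validateSession}}
#' @export
writeSession <- function(session, path) {
  stopifnot(is(session, "Session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  n <- nFrames(session)
  .writeTsv(data.frame(frame = seq_len(n), cm_per_s = session@speed),
            file.path(path, "speed.tsv"))
  .writeTsv(data.frame(frame = seq_len(n), position_cm = session@surface),
            file.path(path, "surface.tsv"))
  .writeTsv(session@whiskerTracks, file.path(path, "whiskers.tsv"))
  sp <- session@spikes
  .writeTsv(data.frame(
    neuron_id = rep(names(sp), vapply(sp, length, 1L)),
    time_s = unlist(sp, use.names = FALSE)),
    file.path(path, "spikes.tsv"))
  .writeTsv(session@trials, file.path(path, "trials.tsv"))
  .writeTsv(session@groundTruth$events, file.path(path, "events_truth.tsv"))
  .writeTsv(session@groundTruth$neurons, file.path(path, "neurons_truth.tsv"))
  cfg <- session@config
  slots <- slotNames(cfg)
  cfgList <- lapply(setNames(slots, slots), function(s) slot(cfg, s))
  cfgList$outcomeProbs <- as.list(cfg@outcomeProbs)
  jsonlite::write_json(
    list(format_version = .sessionFormatVersion,
         seed = cfg@seed,
         face_point = session@facePoint,
         neuron_ids = names(sp),
         config = cfgList),
    file.path(path, "session.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a session written by \code{\link{writeSession}}
#'
#' @param path session directory
#' @return a \linkS4class{Session}
#' @export
readSession <- function(path) {
  if (!dir.exists(path))
    ioError(paste0("session directory not found: ", path),
            "whiskerVR_not_found_error")
  hdrPath <- file.path(path, "session.json")
  if (!file.exists(hdrPath))
    ioError("session is missing required table 'session.json'",
            "whiskerVR_schema_error")
  hdr <- jsonlite::read_json(hdrPath, simplifyVector = TRUE)
  if (!identical(hdr$format_version, .sessionFormatVersion))
    ioError(paste0("unsupported session format version: ",
                   hdr$format_version), "whiskerVR_version_error")
  cl <- hdr$config
  cfg <- sessionConfig(
    duration = cl$duration, frameRate = cl$frameRate,
    meanRunSpeed = cl$meanRunSpeed, runBoutMean = cl$runBoutMean,
    restBoutMean = cl$restBoutMean, speedSd = cl$speedSd,
    whiskFreq = cl$whiskFreq, whiskAmplitude = cl$whiskAmplitude,
    whiskFreqJitterSd = cl$whiskFreqJitterSd,
    whiskAmpJitterSd = cl$whiskAmpJitterSd,
    whiskBoutMean = cl$whiskBoutMean, whiskRestMean = cl$whiskRestMean,
    whiskSetpointTracking = cl$whiskSetpointTracking,
    trialDistance = cl$trialDistance,
    translationDistance = cl$translationDistance,
    translationDuration = cl$translationDuration,
    outcomeProbs = unlist(cl$outcomeProbs),
    nWhiskers = cl$nWhiskers, whiskerSetpoints = cl$whiskerSetpoints,
    surfaceAzimuth0 = cl$surfaceAzimuth0,
    surfaceHalfWidth = cl$surfaceHalfWidth,
    azimuthPerCm = cl$azimuthPerCm,
    nNeurons = cl$nNeurons, pxPerMm = cl$pxPerMm, seed = cl$seed)
  speed <- .readTsv(path, "speed.tsv")
  surface <- .readTsv(path, "surface.tsv")
  tracks <- .readTsv(path, "whiskers.tsv")
  spikesTab <- .readTsv(path, "spikes.tsv")
  trials <- .readTsv(path, "trials.tsv")
  events <- .readTsv(path, "events_truth.tsv")
  neurons <- .readTsv(path, "neurons_truth.tsv")
  ids <- as.character(hdr$neuron_ids)
  spikes <- setNames(
    lapply(ids, function(id)
      sort(spikesTab$time_s[as.character(spikesTab$neuron_id) == id])),
    ids)
  new("Session",
      speed = speed$cm_per_s, surface = surface$position_cm,
      whiskerTracks = tracks, facePoint = as.numeric(hdr$face_point),
      spikes = spikes, trials = trials, config = cfg,
      groundTruth = list(events = events, neurons = neurons))
}

#' Validate a session directory
#'
#' Checks the on-disk schema, the shared frame clock, monotone spike times
#' and spike-time bounds, and lists all violations without fixing any.
#'
#' @param path session directory
#' @return character vector of violations (length 0 when the session is
#'   valid), with attribute \code{n_checked} counting checks performed
#' @export
validateSession <- function(path) {
  if (!dir.exists(path))
    ioError(paste0("cannot read session at ", path),
            "whiskerVR_not_found_error")
  v <- character()
  need <- c("speed.tsv", "surface.tsv", "whiskers.tsv", "spikes.tsv",
            "trials.tsv", "session.json")
  for (f in need) {
    if (!file.exists(file.path(path, f)))
      v <- c(v, paste0("missing required table: ", f))
  }
  nChecked <- length(need)
  if (all(c("speed.tsv", "surface.tsv") %in%
          list.files(path))) {
    sp <- read.delim(file.path(path, "speed.tsv"))
    su <- read.delim(file.path(path, "surface.tsv"))
    nChecked <- nChecked + 1
    if (nrow(sp) != nrow(su))
      v <- c(v, "speed.tsv and surface.tsv are not on a shared frame clock")
    if (file.exists(file.path(path, "spikes.tsv")) &&
        file.exists(file.path(path, "session.json"))) {
      hdr <- jsonlite::read_json(file.path(path, "session.json"),
                                 simplifyVector = TRUE)
      dur <- nrow(sp) / hdr$config$frameRate
      spk <- read.delim(file.path(path, "spikes.tsv"))
      nChecked <- nChecked + 2
      if (nrow(spk) && (min(spk$time_s) < 0 || max(spk$time_s) > dur + 1e-9))
        v <- c(v, "spike times outside [0, duration]")
      mono <- tapply(spk$time_s, spk$neuron_id, function(x) all(diff(x) >= 0))
      if (length(mono) && !all(mono))
        v <- c(v, "spike times are not sorted within neuron")
    }
  }
  attr(v, "n_checked") <- nChecked
  v
}
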