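# End-to-end pipeline: simulate (or load) -> kinematics -> alignment ->
# classification -> habituation -> decoding, with artifacts and a summary.

#' Run the full analysis pipeline
#'
#' Stages run in order: session simulation (or loading), whisker
#' kinematics, trial/event alignment and PSTHs, transient/sustained
#' classification, habituation regression, and population decoding.  Each
#' stage writes plain-text artifacts to \code{outDir}; a machine-readable
#' \code{summary.json} collects neuron counts per class, population test
#' results and the peak decoding accuracy.  Stage failures abort with the
#' stage name; artifacts of completed stages are retained.
#'
#' @param config a \linkS4class{SessionConfig}, or \code{NULL} when
#'   \code{sessionPath} is given (exactly one of the two)
#' @param sessionPath path of a stored session to load instead of
#'   simulating
#' @param outDir output directory (required, created if absent)
#' @param seed master seed; fans out to per-stage substreams
#' @param stages character vector of stages to run (subset of
#'   \code{c("kinematics", "align", "classify", "habituation", "decode")});
#'   simulation/loading always runs
#' @param decodeCfg decoding configuration; the default is scaled to small
#'   sessions (5 folds, 10 resamples)
#' @return the summary list, invisibly; artifacts are written to
#'   \code{outDir}
#' @export
runPipeline <- function(config = NULL, sessionPath = NULL, outDir,
                        seed = 1L,
                        stages = c("kinematics", "align", "classify",
                                   "habituation", "decode"),
                        decodeCfg = decodingConfig(folds = 5,
                                                   resamples = 10)) {
  if (missing(outDir) || is.null(outDir))
    configError("an output directory is required")
  if (is.null(config) == is.null(sessionPath))
    configError("exactly one of config or sessionPath must be given")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = seed, stages = stages)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(errorCondition(
        paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
        class = c("whiskerVR_stage_error", "whiskerVR_error", "error",
                  "condition"))))
  }
  session <- stage("simulate", {
    if (!is.null(config)) simulateSession(config, seed = seed)
    else readSession(sessionPath)
  })
  writeSession(session, file.path(outDir, "session"))
  fr <- frameRate(session)
  truth <- groundTruth(session)
  summary$n_neurons <- length(spikeTrains(session))
  summary$n_trials <- nrow(trialTable(session))
  summary$n_events <- nrow(truth$events)

  if ("kinematics" %in% stages && nrow(whiskerTracks(session))) {
    kin <- stage("kinematics", kinematicSeries(session))
    .writeTsv(kin, file.path(outDir, "kinematics.tsv"))
    touches <- stage("kinematics",
                     detectTouch(kin, fr,
                                 baselineMask = !truth$touching))
    .writeTsv(touches, file.path(outDir, "touches.tsv"))
    summary$n_touch_onsets <- nrow(touches)
  }

  ext <- truth$events[truth$events$origin == "external" &
                        truth$events$kind == "GoW", ]
  windows <- responseWindows(c(0, 0.3))
  if ("align" %in% stages && nrow(ext) > 1) {
    stage("align", {
      pooled <- sort(unlist(spikeTrains(session), use.names = FALSE))
      pop <- alignAndBin(pooled, ext$time_s, window = c(-0.5, 1.5),
                         binWidth = 0.05)
      tw <- findTransientWindow(pop)
      windows <- responseWindows(tw)
      .writeTsv(data.frame(bin_start = head(pop@binEdges, -1),
                           bin_end = tail(pop@binEdges, -1),
                           mean_rate = pop@rate, sem = pop@sem),
                file.path(outDir, "psth_external_gow.tsv"))
      jsonlite::write_json(windows, file.path(outDir, "windows.json"),
                           auto_unbox = FALSE, digits = NA)
      summary$transient_window <- unclass(windows$transient)
    })
  }

  classification <- NULL
  dur <- sessionDuration(session)
  usable <- ext[ext$time_s + windows$baseline[1] > 0 &
                  ext$time_s + windows$sustained[2] < dur, ]
  if ("classify" %in% stages && nrow(usable) >= 5) {
    classification <- stage("classify", {
      rates <- lapply(spikeTrains(session), function(st)
        windowRates(st, usable$time_s,
                    windows[c("baseline", "transient", "sustained")]))
      classifyPopulation(rates)
    })
    .writeTsv(classification, file.path(outDir, "neuron_class.tsv"))
    summary$class_counts <- as.list(table(classification$label))
    # modulation indices around movement onsets
    mods <- stage("classify", {
      do.call(rbind, lapply(names(spikeTrains(session)), function(id) {
        st <- spikeTrains(session)[[id]]
        wr <- windowRates(st, usable$time_s,
                          windows[c("modulation_pre", "modulation_post")])
        data.frame(neuron_id = id,
                   gow_mi = modulationIndex(mean(wr[, 1]), mean(wr[, 2])))
      }))
    })
    .writeTsv(mods, file.path(outDir, "modulation.tsv"))
  }

  if ("habituation" %in% stages && !is.null(classification) &&
      nrow(usable) >= 5) {
    stage("habituation", {
      transIds <- classification$neuron_id[
        classification$label %in% c("transient", "both")]
      slopes <- vapply(transIds, function(id) {
        ser <- repetitionSeries(spikeTrains(session)[[id]], usable,
                                windows$transient)
        if (sum(!is.na(ser$rate_corrected)) < 3) return(NA_real_)
        repetitionRegression(ser$rate_corrected, ser$repetition)$slope
      }, numeric(1))
      slopes <- slopes[!is.na(slopes)]
      if (length(slopes) >= 3 && var(slopes) > 0) {
        pt <- populationSlopeTest(slopes)
        summary$habituation <- list(mean_slope = pt$mean_slope,
                                     p = pt$p, n = pt$n)
      }
      .writeTsv(data.frame(neuron_id = names(slopes), slope = slopes),
                file.path(outDir, "slopes.tsv"))
    })
  }

  tr <- trialTable(session)
  move <- tr[!tr$is_return & tr$outcome %in%
               c("rostral", "caudal", "center"), ]
  if ("decode" %in% stages && nrow(move) >= 3 * decodeCfg$folds &&
      all(table(factor(move$outcome)) >= decodeCfg$folds)) {
    stage("decode", {
      feats <- featureMatrix(spikeTrains(session), move$time_s, decodeCfg)
      res <- crossValidatedDecode(feats, move$outcome, decodeCfg,
                                  seed = seed)
      .writeTsv(decodingAccuracy(res),
                file.path(outDir, "decode_accuracy.tsv"))
      summary$decoding <- list(peak_accuracy = max(res@accuracy),
                                chance = res@chance,
                                peak_time_s = res@time[
                                  which.max(res@accuracy)])
    })
  }

  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = 12)
  invisible(summary)
}
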