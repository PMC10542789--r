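# Accessors and show() methods for the S4 containers.

#' @rdname Session-class
#' @param object,x a \linkS4class{Session}
#' @export
setGeneric("speedTrace", function(x) standardGeneric("speedTrace"))
#' @rdname Session-class
#' @export
setGeneric("surfaceTrace", function(x) standardGeneric("surfaceTrace"))
#' @rdname Session-class
#' @export
setGeneric("spikeTrains", function(x) standardGeneric("spikeTrains"))
#' @rdname Session-class
#' @export
setGeneric("trialTable", function(x) standardGeneric("trialTable"))
#' @rdname Session-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname Session-class
#' @export
setGeneric("sessionConfigOf", function(x) standardGeneric("sessionConfigOf"))
#' @rdname Session-class
#' @export
setGeneric("whiskerTracks", function(x) standardGeneric("whiskerTracks"))
#' @rdname Session-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname Session-class
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname Session-class
#' @export
setGeneric("sessionDuration", function(x) standardGeneric("sessionDuration"))

#' @rdname Session-class
setMethod("speedTrace", "Session", function(x) x@speed)
#' @rdname Session-class
setMethod("surfaceTrace", "Session", function(x) x@surface)
#' @rdname Session-class
setMethod("spikeTrains", "Session", function(x) x@spikes)
#' @rdname Session-class
setMethod("trialTable", "Session", function(x) x@trials)
#' @rdname Session-class
setMethod("groundTruth", "Session", function(x) x@groundTruth)
#' @rdname Session-class
setMethod("sessionConfigOf", "Session", function(x) x@config)
#' @rdname Session-class
setMethod("whiskerTracks", "Session", function(x) x@whiskerTracks)
#' @rdname Session-class
setMethod("nFrames", "Session", function(x) length(x@speed))
#' @rdname Session-class
setMethod("frameRate", "Session", function(x) x@config@frameRate)
#' @rdname Session-class
setMethod("sessionDuration", "Session",
          function(x) length(x@speed) / x@config@frameRate)

setMethod("show", "Session", function(object) {
  cfg <- object@config
  cat("Session:", round(sessionDuration(object), 1), "s at",
      cfg@frameRate, "frames/s\n")
  cat("  neurons:", length(object@spikes),
      " whiskers:", cfg@nWhiskers,
      " trials:", nrow(object@trials), "\n")
  ev <- object@groundTruth$events
  if (!is.null(ev) && nrow(ev)) {
    cat("  ground-truth contact events:", nrow(ev),
        sprintf("(%d GoW, %d LoW)", sum(ev$kind == "GoW"),
                sum(ev$kind == "LoW")), "\n")
  }
  invisible(NULL)
})

setMethod("show", "SessionConfig", function(object) {
  cat("SessionConfig:", object@duration, "s,", object@frameRate, "fps;",
      "run", object@meanRunSpeed, "cm/s; whisk", object@whiskFreq, "Hz;",
      "trial every", object@trialDistance, "cm,",
      object@translationDistance, "cm translation\n")
  cat("  outcomes:", paste(sprintf("%s=%.3f", names(object@outcomeProbs),
                                   object@outcomeProbs), collapse = " "), "\n")
  invisible(NULL)
})

#' @rdname PSTH-class
#' @param x a \linkS4class{PSTH}
#' @export
setGeneric("psthRate", function(x) standardGeneric("psthRate"))
#' @rdname PSTH-class
#' @export
setGeneric("psthCounts", function(x) standardGeneric("psthCounts"))
#' @rdname PSTH-class
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @rdname PSTH-class
setMethod("psthRate", "PSTH", function(x) x@rate)
#' @rdname PSTH-class
setMethod("psthCounts", "PSTH", function(x) x@counts)
#' @rdname PSTH-class
setMethod("binCenters", "PSTH",
          function(x) (head(x@binEdges, -1) + tail(x@binEdges, -1)) / 2)

setMethod("show", "PSTH", function(object) {
  cat("PSTH:", nrow(object@counts), "events x",
      ncol(object@counts), "bins over",
      sprintf("[%.3g, %.3g] s;", min(object@binEdges), max(object@binEdges)),
      sprintf("peak rate %.2f spikes/s\n", max(object@rate)))
  invisible(NULL)
})

#' @rdname DecodingResult-class
#' @param x a \linkS4class{DecodingResult}
#' @export
setGeneric("decodingAccuracy", function(x) standardGeneric("decodingAccuracy"))
#' @rdname DecodingResult-class
#' @export
setGeneric("chanceLevel", function(x) standardGeneric("chanceLevel"))

#' @rdname DecodingResult-class
setMethod("decodingAccuracy", "DecodingResult", function(x) {
  data.frame(time_s = x@time, mean_acc = x@accuracy, sem = x@sem,
             chance = x@chance)
})
#' @rdname DecodingResult-class
setMethod("chanceLevel", "DecodingResult", function(x) x@chance)

setMethod("show", "DecodingResult", function(object) {
  cat("DecodingResult:", length(object@time), "prediction times,",
      object@nNeurons, "neurons,", object@nClasses, "classes;",
      sprintf("peak accuracy %.3f (chance %.3f)\n",
              max(object@accuracy), object@chance))
  invisible(NULL)
})
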