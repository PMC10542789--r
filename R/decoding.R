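# Time-resolved population decoding of surface location.
#
# Firing rates in 150 ms bins stepped every 20 ms feed a linear
# one-vs-rest maximum-margin classifier (binary machines from e1071::svm,
# cost 1); 10-fold stratified cross-validation with 50 resample runs
# (fresh stratified fold assignments) gives the zero-one accuracy and its
# s.e.m. over resamples.

#' Decoding configuration
#'
#' @param binWidth spike-count bin width (s)
#' @param step prediction step (s)
#' @param folds cross-validation folds
#' @param resamples resample runs (re-randomised stratified fold
#'   assignments)
#' @param epoch peri-onset epoch covered by prediction times (s)
#' @param cost SVM regularisation constant
#' @param classifier either \code{"linear-svm"} or a list with \code{fit(x,
#'   y)} returning a model and \code{predict(model, x)} returning decision
#'   values (columns = classes)
#' @return validated list of decoding settings
#' @export
decodingConfig <- function(binWidth = 0.15, step = 0.02, folds = 10,
                           resamples = 50, epoch = c(-0.5, 1.5),
                           cost = 1, classifier = "linear-svm") {
  if (folds < 2) configError("folds must be >= 2")
  if (step > binWidth) configError("step must not exceed binWidth")
  list(binWidth = binWidth, step = step, folds = folds,
       resamples = resamples, epoch = epoch, cost = cost,
       classifier = classifier)
}

#' Time-resolved feature matrices
#'
#' For each prediction time t the feature matrix holds, per trial and
#' neuron, the firing rate in the \code{binWidth} window centred at t
#' (successive windows overlap when \code{step < binWidth}).
#'
#' @param spikes named list of spike-time vectors
#' @param onsets trial onset times (s)
#' @param cfg a \code{\link{decodingConfig}}
#' @return list with \code{times} (prediction times, s) and
#'   \code{features} (list of trials x neurons matrices, one per time)
#' @export
featureMatrix <- function(spikes, onsets, cfg = decodingConfig()) {
  half <- cfg$binWidth / 2
  times <- seq(cfg$epoch[1] + half, cfg$epoch[2] - half, by = cfg$step)
  if (!length(times))
    inputError("epoch too short for one prediction bin")
  feats <- lapply(times, function(tc) {
    m <- vapply(spikes, function(st) {
      vapply(onsets, function(t0) {
        sum(st >= t0 + tc - half & st < t0 + tc + half) / cfg$binWidth
      }, numeric(1))
    }, numeric(length(onsets)))
    matrix(m, nrow = length(onsets))
  })
  list(times = times, features = feats)
}

#' z-score features on training statistics only
#'
#' Per-neuron mean and s.d. are estimated on the training split and applied
#' to both splits; zero-s.d. neurons pass through as zero columns.
#'
#' @param train,test trials x neurons matrices
#' @return list of scaled \code{train} and \code{test} matrices
#' @export
zscoreFeatures <- function(train, test) {
  if (!nrow(train)) inputError("training split is empty")
  mu <- colMeans(train)
  sdv <- apply(train, 2, sd)
  scale1 <- function(m) {
    out <- sweep(m, 2, mu)
    out <- sweep(out, 2, ifelse(sdv > 0, sdv, 1), "/")
    out[, sdv == 0] <- 0
    out
  }
  list(train = scale1(train), test = scale1(test))
}

# One-vs-rest linear maximum-margin classifier over binary e1071::svm
# machines; ties in decision values break to the lowest class index.
.fitOvr <- function(x, y, cost = 1) {
  classes <- levels(y)
  models <- lapply(classes, function(cl) {
    yy <- factor(ifelse(y == cl, "pos", "neg"), levels = c("pos", "neg"))
    if (length(unique(yy)) < 2) return(NULL)
    e1071::svm(x, yy, kernel = "linear", cost = cost, scale = FALSE)
  })
  list(classes = classes, models = models)
}

.predictOvr <- function(fit, x) {
  dec <- vapply(seq_along(fit$classes), function(j) {
    m <- fit$models[[j]]
    if (is.null(m)) return(rep(-Inf, nrow(x)))
    d <- attr(predict(m, x, decision.values = TRUE), "decision.values")
    # orient so larger = more "pos"
    if (grepl("^pos/", colnames(d)[1])) d[, 1] else -d[, 1]
  }, numeric(nrow(x)))
  dec <- matrix(dec, nrow = nrow(x))
  fit$classes[apply(dec, 1, which.max)]   # which.max takes lowest on ties
}

.stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated time-resolved decoding
#'
#' Per prediction time: stratified k-fold cross-validation of the
#' classifier on train-z-scored features, averaged over resample runs
#' (each a fresh stratified fold assignment), scored with zero-one loss.
#'
#' @param feats output of \code{\link{featureMatrix}}
#' @param labels factor (or coercible) of trial labels
#' @param cfg a \code{\link{decodingConfig}}
#' @param seed integer seed for fold assignments
#' @return a \linkS4class{DecodingResult}
#' @export
crossValidatedDecode <- function(feats, labels, cfg = decodingConfig(),
                                 seed = 1L) {
  y <- droplevels(as.factor(labels))
  counts <- table(y)
  if (any(counts < cfg$folds))
    inputError(paste0("class '", names(counts)[which.min(counts)],
                      "' has fewer trials (", min(counts),
                      ") than folds (", cfg$folds, ")"))
  nT <- length(feats$times)
  accR <- matrix(NA_real_, cfg$resamples, nT)
  withSubstream(seed, "decode", {
    for (r in seq_len(cfg$resamples)) {
      fold <- .stratifiedFolds(y, cfg$folds)
      for (ti in seq_len(nT)) {
        x <- feats$features[[ti]]
        correct <- 0L
        for (f in seq_len(cfg$folds)) {
          tr <- fold != f
          sc <- zscoreFeatures(x[tr, , drop = FALSE],
                               x[!tr, , drop = FALSE])
          fit <- if (is.list(cfg$classifier)) {
            cfg$classifier$fit(sc$train, y[tr])
          } else {
            .fitOvr(sc$train, y[tr], cost = cfg$cost)
          }
          pred <- if (is.list(cfg$classifier)) {
            cfg$classifier$predict(fit, sc$test)
          } else {
            .predictOvr(fit, sc$test)
          }
          correct <- correct + sum(pred == as.character(y[!tr]))
        }
        accR[r, ti] <- correct / length(y)
      }
    }
  })
  acc <- colMeans(accR)
  sem <- apply(accR, 2, sd) / sqrt(cfg$resamples)
  new("DecodingResult", time = feats$times, accuracy = acc, sem = sem,
      chance = 1 / nlevels(y), nClasses = nlevels(y),
      nNeurons = ncol(feats$features[[1]]),
      resamples = as.integer(cfg$resamples))
}

#' Decode with transient and sustained subpopulations separated
#'
#' Runs \code{\link{crossValidatedDecode}} independently per subpopulation
#' on identical trial splits (shared seed) so the accuracy curves are
#' directly comparable.
#'
#' @param feats output of \code{\link{featureMatrix}} for the full
#'   population
#' @param labels trial labels
#' @param classification data.frame with \code{neuron_id} and \code{label}
#'   (from \code{\link{classifyPopulation}}); neurons labelled
#'   \code{transient} or \code{both} form the transient subpopulation,
#'   \code{sustained} or \code{both} the sustained one
#' @param cfg a \code{\link{decodingConfig}}
#' @param seed shared seed for both subpopulation decodes
#' @return named list of \linkS4class{DecodingResult} objects
#'   (\code{transient}, \code{sustained})
#' @export
subpopulationDecode <- function(feats, labels, classification,
                                cfg = decodingConfig(), seed = 1L) {
  sel <- function(keepLabels) {
    keep <- which(classification$label %in% keepLabels)
    if (!length(keep)) inputError("empty subpopulation")
    list(times = feats$times,
         features = lapply(feats$features, function(m)
           m[, keep, drop = FALSE]))
  }
  list(
    transient = crossValidatedDecode(sel(c("transient", "both")), labels,
                                     cfg, seed = seed),
    sustained = crossValidatedDecode(sel(c("sustained", "both")), labels,
                                     cfg, seed = seed))
}
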