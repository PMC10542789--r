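# Habituation of the transient response across stimulus repetitions:
# drift screening, per-neuron linear slopes, population test, range
# normalization, and waveform-amplitude tracking.

#' Screen a neuron for baseline drift
#'
#' Compares the baseline firing rate of the first 10 trials with the last
#' 10 trials using a two-sided Wilcoxon signed-rank test (paired by trial
#' order within each block).  A neuron is flagged as drifting — and should
#' be excluded from habituation fits — when the test rejects.
#'
#' @param baselineRates per-trial baseline rates (spikes/s), in temporal
#'   order; at least 20 trials
#' @param alpha significance level
#' @param blockSize trials per block
#' @return list: drift_flag, p, skipped (TRUE with a reason when fewer than
#'   \code{2 * blockSize} trials are available)
#' @export
driftScreen <- function(baselineRates, alpha = 0.05, blockSize = 10) {
  n <- length(baselineRates)
  if (n < 2 * blockSize) {
    return(list(drift_flag = NA, p = NA_real_, skipped = TRUE,
                reason = paste0("needs >= ", 2 * blockSize, " trials, got ",
                                n)))
  }
  first <- head(baselineRates, blockSize)
  last <- tail(baselineRates, blockSize)
  d <- first - last
  if (all(d == 0)) {
    return(list(drift_flag = FALSE, p = 1, skipped = FALSE))
  }
  wt <- suppressWarnings(wilcox.test(first, last, paired = TRUE,
                                     exact = FALSE, correct = TRUE))
  list(drift_flag = wt$p.value < alpha, p = wt$p.value, skipped = FALSE)
}

#' Linear regression of response magnitude on repetition index
#'
#' Ordinary least squares of the per-repetition response rate on the
#' repetition index; the two-sided slope p-value comes from the
#' regression t-statistic.  Repetitions with no events are gaps
#' (\code{NA}), not zeros, and are dropped from the fit.
#'
#' @param rates response rate per repetition (spikes/s); \code{NA} = gap
#' @param repetitions repetition indices (defaults to \code{seq_along})
#' @return list: slope (spikes/s per repetition), intercept, p, se, n
#' @examples
#' repetitionRegression(10 - 0.5 * (1:20))  # slope -0.5
#' @export
repetitionRegression <- function(rates, repetitions = seq_along(rates)) {
  ok <- !is.na(rates)
  x <- repetitions[ok]
  y <- rates[ok]
  if (length(unique(x)) < 2)
    inputError("repetition regression requires >= 2 distinct repetitions")
  if (length(x) < 3)
    inputError("repetition regression requires >= 3 repetitions")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))$coefficients
  p <- if (nrow(sm) > 1 && !is.nan(sm[2, 4])) sm[2, 4] else NA_real_
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       p = p, se = unname(sm[2, 2]), n = length(x))
}

#' One-sided population test of habituation slopes
#'
#' One-sample t-test of the mean per-neuron slope against 0, one-sided for
#' negative slopes (habituation).
#'
#' @param slopes per-neuron fitted slopes (spikes/s per repetition)
#' @return list: p, t, mean_slope, n
#' @export
populationSlopeTest <- function(slopes) {
  slopes <- slopes[!is.na(slopes)]
  if (length(slopes) < 3)
    inputError("population slope test requires >= 3 slopes")
  if (var(slopes) == 0)
    inputError("degenerate input: all slopes identical")
  tt <- t.test(slopes, mu = 0, alternative = "less")
  list(p = tt$p.value, t = unname(tt$statistic),
       mean_slope = mean(slopes), n = length(slopes))
}

#' Scaling-to-range normalization
#'
#' \eqn{X_{norm} = (X - X_{min}) / (X_{max} - X_{min})}: the minimum maps
#' to 0, the maximum to 1, affinely in between.  Invariant under positive
#' affine transforms of the input.
#'
#' @param x numeric vector with \code{max(x) > min(x)}
#' @return normalized vector in [0, 1]
#' @examples
#' normalizeRange(c(2, 4, 6))  # 0, 0.5, 1
#' @export
normalizeRange <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (!is.finite(rng[1]) || rng[2] <= rng[1])
    inputError("range normalization undefined for a constant vector")
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Per-repetition response series for one neuron
#'
#' Response magnitude per stimulus repetition: the rate in the response
#' window, both raw and with that repetition's baseline-window rate
#' subtracted.  Repetitions with no event are gaps.
#'
#' @param spikes spike times (s)
#' @param events data.frame with \code{time_s} and \code{repetition} for
#'   one stimulus stream
#' @param window response window relative to onset (s)
#' @param baselineWindow baseline window relative to onset (s)
#' @return data.frame: repetition, rate, baseline_rate, rate_corrected
#' @export
repetitionSeries <- function(spikes, events, window,
                             baselineWindow = c(-0.3, 0)) {
  reps <- seq_len(max(events$repetition))
  rate <- rep(NA_real_, length(reps))
  base <- rep(NA_real_, length(reps))
  for (r in unique(events$repetition)) {
    tt <- events$time_s[events$repetition == r]
    rate[r] <- mean(vapply(tt, function(t0) {
      rel <- spikes - t0
      sum(rel >= window[1] & rel < window[2]) / (window[2] - window[1])
    }, numeric(1)))
    base[r] <- mean(vapply(tt, function(t0) {
      rel <- spikes - t0
      sum(rel >= baselineWindow[1] & rel < baselineWindow[2]) /
        (baselineWindow[2] - baselineWindow[1])
    }, numeric(1)))
  }
  data.frame(repetition = reps, rate = rate, baseline_rate = base,
             rate_corrected = rate - base)
}

#' Spike-waveform amplitude per repetition
#'
#' Mean spike amplitude over the spikes falling inside the response window
#' of each repetition, range-normalized across repetitions.  A repetition
#' with no spikes is a gap; a constant amplitude series is returned
#' unnormalized with status \code{"stable (degenerate range)"}.
#'
#' @param spikes spike times (s)
#' @param amplitudes per-spike amplitudes, parallel to \code{spikes}
#' @param events data.frame with \code{time_s} and \code{repetition}
#' @param window response window relative to onset (s)
#' @return list: series (data.frame repetition, mean_amp, norm_amp),
#'   status
#' @export
waveformAmplitudeSeries <- function(spikes, amplitudes, events,
                                    window = c(0, 0.3)) {
  stopifnot(length(spikes) == length(amplitudes))
  reps <- seq_len(max(events$repetition))
  amp <- rep(NA_real_, length(reps))
  for (r in unique(events$repetition)) {
    tt <- events$time_s[events$repetition == r]
    vals <- unlist(lapply(tt, function(t0) {
      rel <- spikes - t0
      amplitudes[rel >= window[1] & rel < window[2]]
    }))
    if (length(vals)) amp[r] <- mean(vals)
  }
  ok <- !is.na(amp)
  status <- "ok"
  norm <- rep(NA_real_, length(reps))
  nz <- tryCatch(normalizeRange(amp[ok]), error = function(e) NULL)
  if (is.null(nz)) {
    status <- "stable (degenerate range)"
  } else {
    norm[ok] <- nz
  }
  list(series = data.frame(repetition = reps, mean_amp = amp,
                           norm_amp = norm),
       status = status)
}
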