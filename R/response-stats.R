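# Transient/sustained neuron classification (one-way ANOVA + Tukey),
# GoW/LoW modulation indices, and external- vs self-GoW comparison.

#' Classify a neuron from baseline/transient/sustained window rates
#'
#' One-way ANOVA across the three windows followed by Tukey's honest
#' significant difference on the three pairwise comparisons (family
#' alpha = 0.05).  Labels: \emph{sustained} when baseline and sustained
#' rates differ significantly; \emph{transient} when the transient rate
#' differs significantly from baseline and exceeds both the baseline and
#' sustained means; \emph{both} when both rules fire; otherwise
#' \emph{nonresponsive}.
#'
#' @param baseline,transient,sustained numeric per-trial rates (spikes/s);
#'   at least \code{minTrials} each
#' @param alpha family-wise significance level
#' @param minTrials minimum trials per window
#' @return one-row data.frame: label, anova_p, p_bt (baseline--transient),
#'   p_bs (baseline--sustained), p_ts (transient--sustained), and the
#'   window means
#' @export
classifyNeuron <- function(baseline, transient, sustained, alpha = 0.05,
                           minTrials = 5) {
  if (min(length(baseline), length(transient), length(sustained)) <
      minTrials)
    inputError(paste("classification requires at least", minTrials,
                     "trials per window"))
  rates <- c(baseline, transient, sustained)
  grp <- factor(rep(c("baseline", "transient", "sustained"),
                    times = c(length(baseline), length(transient),
                              length(sustained))),
                levels = c("baseline", "transient", "sustained"))
  mB <- mean(baseline); mT <- mean(transient); mS <- mean(sustained)
  if (var(rates) == 0) {
    # exact ties carry no evidence of a response
    return(data.frame(label = "nonresponsive", anova_p = 1,
                      p_bt = 1, p_bs = 1, p_ts = 1,
                      mean_baseline = mB, mean_transient = mT,
                      mean_sustained = mS, stringsAsFactors = FALSE))
  }
  fit <- aov(rates ~ grp)
  anovaP <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- TukeyHSD(fit)$grp
  pOf <- function(a, b) {
    key <- paste0(b, "-", a)
    if (key %in% rownames(tk)) tk[key, "p adj"] else
      tk[paste0(a, "-", b), "p adj"]
  }
  pBT <- pOf("baseline", "transient")
  pBS <- pOf("baseline", "sustained")
  pTS <- pOf("transient", "sustained")
  isSust <- !is.na(pBS) && pBS < alpha
  isTran <- !is.na(pBT) && pBT < alpha && mT > mB && mT > mS
  label <- if (isTran && isSust) "both" else if (isTran) "transient" else
    if (isSust) "sustained" else "nonresponsive"
  data.frame(label = label, anova_p = anovaP, p_bt = pBT, p_bs = pBS,
             p_ts = pTS, mean_baseline = mB, mean_transient = mT,
             mean_sustained = mS, stringsAsFactors = FALSE)
}

#' Classify every neuron of a population
#'
#' @param rateList list (one element per neuron) of matrices with columns
#'   \code{baseline}, \code{transient}, \code{sustained} of per-trial rates
#'   (as from \code{\link{windowRates}})
#' @param alpha family-wise significance level
#' @param minTrials minimum trials per window; neurons below it are
#'   excluded with label \code{excluded}
#' @return data.frame with one row per neuron (neuron_id taken from list
#'   names)
#' @export
classifyPopulation <- function(rateList, alpha = 0.05, minTrials = 5) {
  rows <- lapply(seq_along(rateList), function(i) {
    m <- rateList[[i]]
    row <- if (nrow(m) < minTrials) {
      data.frame(label = "excluded", anova_p = NA_real_, p_bt = NA_real_,
                 p_bs = NA_real_, p_ts = NA_real_,
                 mean_baseline = NA_real_, mean_transient = NA_real_,
                 mean_sustained = NA_real_, stringsAsFactors = FALSE)
    } else {
      classifyNeuron(m[, "baseline"], m[, "transient"], m[, "sustained"],
                     alpha = alpha, minTrials = minTrials)
    }
    cbind(data.frame(neuron_id = if (!is.null(names(rateList)))
      names(rateList)[i] else as.character(i), stringsAsFactors = FALSE),
      row)
  })
  do.call(rbind, rows)
}

#' GoW/LoW modulation index
#'
#' \eqn{(post - pre) / (post + pre)} of the mean firing rates in the 500 ms
#' windows before and after movement onset; defined as 0 when both rates
#' are 0.  Bounded in [-1, 1]; antisymmetric under swapping pre and post.
#'
#' @param pre,post mean rates (spikes/s), nonnegative; vectorised
#' @return modulation index in [-1, 1]
#' @examples
#' modulationIndex(5, 15)   # 0.5
#' @export
modulationIndex <- function(pre, post) {
  if (any(pre < 0, na.rm = TRUE) || any(post < 0, na.rm = TRUE))
    inputError("modulation index requires nonnegative rates")
  s <- pre + post
  ifelse(s == 0, 0, (post - pre) / s)
}

#' Baseline-subtracted GoW responses for external and self touches
#'
#' The external-GoW response is the mean rate in the 50 ms post-touch
#' window minus the pre-touch (free-whisking) window; the self-GoW
#' response is the mean rate during self-GoW minus during self-motion
#' (whisking without touch).  A missing condition yields \code{NA} with a
#' \code{missing} flag.
#'
#' @param spikes numeric spike times (s)
#' @param externalTimes,selfTimes touch-onset times per condition (s)
#' @param window response window relative to touch onset (s)
#' @param preWindow condition baseline window relative to onset (s)
#' @return one-row data.frame: d_external, d_self, n_external, n_self,
#'   missing
#' @export
gowResponse <- function(spikes, externalTimes, selfTimes,
                        window = c(0, 0.05), preWindow = c(-0.25, -0.05)) {
  rateIn <- function(times, w) {
    if (!length(times)) return(NA_real_)
    mean(vapply(times, function(t0) {
      rel <- spikes - t0
      sum(rel >= w[1] & rel < w[2]) / (w[2] - w[1])
    }, numeric(1)))
  }
  dExt <- rateIn(externalTimes, window) - rateIn(externalTimes, preWindow)
  dSelf <- rateIn(selfTimes, window) - rateIn(selfTimes, preWindow)
  data.frame(d_external = dExt, d_self = dSelf,
             n_external = length(externalTimes),
             n_self = length(selfTimes),
             missing = !length(externalTimes) || !length(selfTimes))
}

#' Compare external- and self-GoW responses across a population
#'
#' Two-sided Wilcoxon signed-rank test on the paired per-neuron response
#' differences (zero differences dropped; exact distribution for n <= 25,
#' normal approximation with continuity correction above), plus a paired
#' t-test and the fraction of neurons above the unity line.
#'
#' @param dExternal,dSelf paired per-neuron responses (spikes/s)
#' @return list: wilcoxon_p, wilcoxon_V, t_p, median_external, median_self,
#'   fraction_external_greater, n
#' @export
compareExternalSelf <- function(dExternal, dSelf) {
  if (length(dExternal) != length(dSelf))
    inputError("paired vectors must have equal length")
  ok <- complete.cases(dExternal, dSelf)
  x <- dExternal[ok]; y <- dSelf[ok]
  d <- x - y
  nz <- d != 0
  wt <- if (any(nz)) {
    suppressWarnings(wilcox.test(x[nz], y[nz], paired = TRUE,
                                 exact = sum(nz) <= 25, correct = TRUE))
  } else list(p.value = 1, statistic = NA_real_)
  tt <- if (length(d) > 1 && var(d) > 0) {
    tryCatch(t.test(x, y, paired = TRUE),
             error = function(e) list(p.value = NA_real_))
  } else {
    list(p.value = 1)
  }
  list(wilcoxon_p = wt$p.value, wilcoxon_V = unname(wt$statistic),
       t_p = tt$p.value,
       median_external = median(x), median_self = median(y),
       fraction_external_greater = mean(x > y), n = length(x))
}
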