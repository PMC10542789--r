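# Trial segmentation, GoW/LoW labelling, PSTHs and response windows.

test_that("segmentTrials recovers simulator movement onsets", {
  s <- shortSession()
  tr <- segmentTrials(speedTrace(s), surfaceTrace(s), frameRate(s))
  truthTr <- trialTable(s)
  moved <- truthTr[truthTr$direction != "none", ]
  expect_equal(tr$frame, moved$frame)
  expect_equal(tr$direction, moved$direction)
  # constant surface -> zero trials
  empty <- segmentTrials(rep(10, 1000), rep(0, 1000), 500)
  expect_equal(nrow(empty), 0)
})

test_that("inter-onset distance matches the speed integral", {
  cfg <- sessionConfig(duration = 120, frameRate = 100,
                       outcomeProbs = c(rostral = 0.5, caudal = 0.5))
  res <- simulateSurface(rep(20, 12000), cfg, seed = 2)
  tr <- segmentTrials(rep(20, 12000), res$surface, 100)
  expect_gt(nrow(tr), 2)
  expect_true(all(abs(diff(tr$time_s) - 10) < 0.05))
})

test_that("movements are labelled GoW/LoW by contact changes", {
  # constructed events: movement 1 adds a whisker, movement 2 none,
  # movement 3 adds one and drops another
  trials <- data.frame(trial = 1:3, frame = c(100, 300, 500),
                       time_s = c(1, 3, 5))
  events <- data.frame(
    time_s = c(1.05, 5.02, 5.08),
    kind = c("GoW", "GoW", "LoW"),
    origin = "external",
    whisker_id = c(1, 2, 3))
  lab <- labelGowLow(trials, events)
  expect_equal(lab$gow, c(TRUE, FALSE, TRUE))
  expect_equal(lab$low, c(FALSE, FALSE, TRUE))
})

test_that("labelGowLow agrees with ground truth on synthetic sessions", {
  s <- shortSession()
  tr <- segmentTrials(speedTrace(s), surfaceTrace(s), frameRate(s))
  ev <- groundTruth(s)$events
  lab <- labelGowLow(tr, ev)
  # oracle straight from truth: any external event within the epoch
  for (i in seq_len(nrow(lab))) {
    inEpoch <- ev$origin == "external" & ev$time_s >= lab$time_s[i] &
      ev$time_s < lab$time_s[i] + 0.35
    expect_equal(lab$gow[i], any(ev$kind[inEpoch] == "GoW"))
    expect_equal(lab$low[i], any(ev$kind[inEpoch] == "LoW"))
  }
})

test_that("PSTH bins are half-open and conserve spike counts", {
  # spike exactly at event time falls in the first post-onset bin
  p <- alignAndBin(spikes = c(5), eventTimes = c(5), window = c(-0.5, 0.5),
                   binWidth = 0.1)
  ctr <- binCenters(p)
  expect_equal(psthCounts(p)[1, which(abs(ctr - 0.05) < 1e-9)], 1)
  expect_equal(sum(psthCounts(p)), 1)
  # count conservation on random data
  set.seed(4)
  spikes <- sort(runif(2000, 0, 100))
  evt <- seq(5, 95, by = 5)
  p2 <- alignAndBin(spikes, evt, window = c(-1, 2), binWidth = 0.05)
  aligned <- sum(vapply(evt, function(t0)
    sum(spikes - t0 >= -1 & spikes - t0 < 2), numeric(1)))
  expect_equal(sum(psthCounts(p2)), aligned)
  w <- diff(p2@binEdges)
  expect_equal(sum(psthRate(p2) * w) * length(evt), aligned)
})

test_that("PSTH rates match a homogeneous Poisson oracle", {
  set.seed(5)
  lambda <- 20
  dur <- 2000
  spikes <- sort(runif(rpois(1, lambda * dur), 0, dur))
  evt <- seq(10, dur - 10, length.out = 200)
  p <- alignAndBin(spikes, evt, window = c(-0.5, 0.5), binWidth = 0.05)
  # each bin's mean within lambda +/- 3 s.e. (s.e. ~ sqrt(lambda/(n w)))
  se <- sqrt(lambda / (200 * 0.05))
  expect_true(all(abs(psthRate(p) - lambda) < 3.5 * se))
  # two identical events -> zero s.e.m. everywhere
  p2 <- alignAndBin(spikes, c(100, 100), window = c(-0.5, 0.5),
                    binWidth = 0.05)
  expect_true(all(p2@sem == 0))
  expect_error(alignAndBin(spikes, numeric(0)),
               class = "whiskerVR_input_error")
})

test_that("z-scored PSTHs are location and scale invariant", {
  set.seed(6)
  spikes <- sort(runif(5000, 0, 500))
  evt <- seq(5, 495, by = 5)
  p <- alignAndBin(spikes, evt, window = c(-0.5, 1), binWidth = 0.05)
  z <- zscorePsth(p)
  base <- binCenters(p) >= -0.3 & binCenters(p) < 0
  expect_lt(abs(mean(z[base])), 0.5)
  # shifting all rates by a constant shifts z by constant/sd only through
  # the baseline; adding c to rate and baseline mean leaves z unchanged
  p2 <- p
  p2@rate <- p@rate + 7
  p2@baselineMean <- p@baselineMean + 7
  expect_equal(zscorePsth(p2), z)
  p3 <- p
  p3@rate <- p@rate * 3
  p3@baselineMean <- p@baselineMean * 3
  p3@baselineSd <- p@baselineSd * 3
  expect_equal(zscorePsth(p3), z)
  pBad <- p
  pBad@baselineSd <- 0
  expect_error(zscorePsth(pBad), class = "whiskerVR_input_error")
})

test_that("the transient window brackets the response peak", {
  mkPsth <- function(rate) {
    edges <- seq(-0.5, 1.5, by = 0.05)
    counts <- matrix(rep(rate, 10), nrow = 10, byrow = TRUE) * 0.05
    new("PSTH", binEdges = edges, counts = counts, rate = rate,
        sem = rep(0, length(rate)), baselineMean = rate[1],
        baselineSd = 1, baselineWindow = c(-0.3, 0))
  }
  ctr <- seq(-0.475, 1.475, by = 0.05)
  # boxcar response spanning 50-250 ms
  rate <- rep(5, length(ctr))
  rate[ctr > 0.05 & ctr < 0.25] <- 30
  win <- findTransientWindow(mkPsth(rate))
  expect_lte(win[1], 0.1)
  expect_gte(win[2], 0.2)
  expect_gte(win[1], 0)
  expect_lte(win[2], 0.6)
  # flat PSTH -> fallback window
  winFlat <- findTransientWindow(mkPsth(rep(5, length(ctr))))
  expect_equal(as.numeric(winFlat), c(0, 0.3))
  expect_true(attr(winFlat, "fallback"))
  # two peaks: the higher (second) one wins
  rate2 <- rep(5, length(ctr))
  rate2[ctr > 0.05 & ctr < 0.15] <- 20
  rate2[ctr > 0.35 & ctr < 0.45] <- 40
  win2 <- findTransientWindow(mkPsth(rate2))
  expect_gt(win2[1], 0.15)
  expect_lte(win2[1], 0.35)
  expect_gte(win2[2], 0.45)
  # invariant to adding a constant rate to every bin
  rate3 <- rate + 11
  p3 <- mkPsth(rate3)
  p3@baselineMean <- rate3[1]
  expect_equal(as.numeric(findTransientWindow(p3)), as.numeric(win))
})

test_that("window rates divide counts by window length", {
  # single spike in a 0.3 s window -> 3.33 spikes/s
  w <- list(transient = c(0, 0.3))
  r <- windowRates(spikes = c(10.1), eventTimes = 10, w)
  expect_equal(unname(r[1, 1]), 1 / 0.3)
  expect_equal(unname(windowRates(numeric(0), 10, w)[1, 1]), 0)
  # homogeneous Poisson rates recovered in every window
  set.seed(7)
  spikes <- sort(runif(20000, 0, 1000))
  evt <- seq(5, 995, by = 10)
  wr <- windowRates(spikes, evt, responseWindows(c(0, 0.3)))
  lens <- vapply(responseWindows(c(0, 0.3)), diff, numeric(1))
  tol <- 3.5 * sqrt(20 / (length(evt) * lens))
  expect_true(all(abs(colMeans(wr) - 20) < tol))
  # windows beyond the recording raise a boundary error naming events
  err <- tryCatch(windowRates(spikes, c(0.1, 500),
                              list(baseline = c(-0.3, 0)),
                              duration = 1000), error = identity)
  expect_s3_class(err, "whiskerVR_input_error")
  expect_match(conditionMessage(err), "1")
})

test_that("baseline-contaminated events are excluded from a stream", {
  tt <- c(1, 1.1, 5, 9, 9.2)
  keep <- cleanBaselineEvents(tt, c(-0.3, 0))
  expect_equal(keep, c(TRUE, FALSE, TRUE, TRUE, FALSE))
})
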