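# Session generator: locomotion, whisking, surface protocol, contact
# truth, and spike simulation.

test_that("locomotion matches the configured run speed and is seeded", {
  cfg <- sessionConfig(duration = 600)
  sp <- generateLocomotion(cfg, seed = 1)
  running <- attr(sp, "running")
  expect_true(all(sp >= 0))
  expect_gt(mean(running), 0.5)           # running dominates the session
  expect_lt(abs(mean(sp[running]) - 23.7), 2)
  # same seed -> identical trace; different seed -> different trace
  sp2 <- generateLocomotion(cfg, seed = 1)
  expect_identical(as.numeric(sp), as.numeric(sp2))
  sp3 <- generateLocomotion(cfg, seed = 2)
  expect_false(identical(as.numeric(sp), as.numeric(sp3)))
})

test_that("degenerate locomotion config gives a constant trace", {
  cfg <- sessionConfig(duration = 10, meanRunSpeed = 15, speedSd = 0,
                       restBoutMean = 0)
  sp <- generateLocomotion(cfg, seed = 1)
  expect_true(all(as.numeric(sp) == 15))
})

test_that("whisking oscillates at the configured frequency", {
  cfg <- sessionConfig(duration = 60, whiskRestMean = 0)
  w <- generateWhisking(cfg, 0, seed = 1)
  x <- w$angles[, 2] - mean(w$angles[, 2])
  spec <- spec.pgram(ts(x, frequency = 500), spans = 15, plot = FALSE)
  band <- spec$freq >= 5 & spec$freq <= 30
  peak <- spec$freq[band][which.max(spec$spec[band])]
  expect_true(peak >= 18 && peak <= 20)
})

test_that("quiescent bouts are flat and setpoints track the surface", {
  cfg <- sessionConfig(duration = 20, whiskBoutMean = 0.001,
                       whiskRestMean = 1e6)  # never whisking
  w <- generateWhisking(cfg, 0, seed = 2)
  quiet <- !w$whisking
  expect_gt(mean(quiet), 0.9)
  expect_lt(sd(w$angles[quiet, 1]), 0.5)
  # setpoint tracking: +1 cm surface at 10 deg/cm shifts bout-mean by ~10
  cfgT <- sessionConfig(duration = 40, whiskRestMean = 0,
                        whiskSetpointTracking = 10)
  n <- 40 * 500
  surface <- c(rep(0, n / 2), rep(1, n / 2))
  wt <- generateWhisking(cfgT, surface, seed = 3)
  m0 <- mean(wt$angles[1:(n / 2 - 500), 2])
  m1 <- mean(wt$angles[(n / 2 + 500):n, 2])
  expect_lt(abs((m1 - m0) - 10), 1)
})

test_that("whisk frequency above Nyquist is a configuration error", {
  expect_error(
    generateWhisking(sessionConfig(duration = 5, frameRate = 30,
                                   whiskFreq = 19), 0, seed = 1),
    class = "whiskerVR_config_error")
})

test_that("surface translations trigger on cumulative distance", {
  cfg <- sessionConfig(duration = 40, frameRate = 100)
  res <- simulateSurface(rep(20, 4000), cfg, seed = 1)
  # 200 cm at 20 cm/s -> onset at t = 10 s
  expect_equal(res$trials$time_s[1], 10, tolerance = 0.02)
  expect_true(all(diff(res$trials$frame) > 0))
  # distance since previous trigger conserves the speed integral
  expect_true(all(abs(res$trials$distance_cm - 200) < 200 * 1e-6 + 0.25))
  # zero speed -> zero trials
  res0 <- simulateSurface(rep(0, 4000), cfg, seed = 1)
  expect_equal(nrow(res0$trials), 0)
  expect_true(all(res0$surface == 0))
})

test_that("outcome frequencies match the configured probabilities", {
  cfg <- sessionConfig(duration = 1100, frameRate = 100)
  res <- simulateSurface(rep(1000, 110000), cfg, seed = 5)
  draws <- res$trials$outcome[!res$trials$is_return]
  draws <- head(draws, 3000)
  expect_gte(length(draws), 3000)
  freq <- table(factor(draws, levels = c("rostral", "caudal", "center")))
  expect_true(all(abs(freq / 3000 - 1 / 3) < 0.03))
  gof <- chisq.test(freq, p = rep(1 / 3, 3))
  expect_gt(gof$p.value, 0.01)
})

test_that("rostral/caudal excursions are followed by returns", {
  s <- shortSession()
  tr <- trialTable(s)
  disp <- which(tr$outcome %in% c("rostral", "caudal"))
  disp <- disp[disp < nrow(tr)]
  expect_true(all(tr$is_return[disp + 1]))
})

test_that("contact truth emits GoW/LoW with correct origins", {
  cfg <- sessionConfig(duration = 4, frameRate = 500,
                       whiskRestMean = 0)   # continuous whisking
  n <- 2000
  # surface steps into whisker 3's reach at frame 1000 (ramp 1 frame)
  surface <- c(rep(0, 999), rep(1, 1001))
  whisking <- rep(TRUE, n)
  truth <- deriveContactTruth(cfg, surface, whisking)
  gow <- truth$events[truth$events$kind == "GoW", ]
  expect_true(any(gow$whisker_id == 3 & gow$origin == "external" &
                    gow$direction == "rostral"))
  # a tiny translation inside the contacted span adds no events
  surface2 <- c(rep(0, 999), rep(0.01, 1001))
  truth2 <- deriveContactTruth(cfg, surface2, whisking)
  expect_equal(nrow(truth2$events), 0)
  # whisking pause against a stationary in-reach surface -> self GoW
  whisking3 <- c(rep(TRUE, 800), rep(FALSE, 400), rep(TRUE, 800))
  truth3 <- deriveContactTruth(cfg, rep(0, n), whisking3)
  ev3 <- truth3$events
  selfGow <- ev3[ev3$kind == "GoW" & ev3$origin == "self", ]
  expect_true(any(selfGow$frame == 1201))
  expect_true(all(ev3$direction[ev3$origin == "self"] == "none"))
})

test_that("repetition indices increment per stimulus stream", {
  s <- shortSession()
  ev <- groundTruth(s)$events
  for (str in split(ev, interaction(ev$kind, ev$origin, ev$direction,
                                    drop = TRUE))) {
    expect_equal(str$repetition[order(str$time_s)],
                 seq_len(nrow(str)))
  }
})

test_that("baseline-only spiking is Poisson with the right rate", {
  sp <- simulateSpikes(makeEventSchedule(0), FALSE, neuronSpec1(10),
                       duration = 100, frameRate = 500, seed = 1)
  n <- length(sp[[1]])
  expect_lt(abs(n - 1000), 3 * sqrt(1000))
  expect_true(all(diff(sp[[1]]) >= 0.002))   # refractory period
  # Fano factor of windowed counts across many baseline-only neurons
  specs <- do.call(rbind, replicate(500, neuronSpec1(10), simplify = FALSE))
  specs$neuron_id <- seq_len(500)
  spm <- simulateSpikes(makeEventSchedule(0), FALSE, specs,
                        duration = 2, frameRate = 500, seed = 2)
  counts <- vapply(spm, function(s) sum(s >= 0.5 & s < 1.5), numeric(1))
  expect_gt(var(counts) / mean(counts), 0.8)
  expect_lt(var(counts) / mean(counts), 1.2)
})

test_that("negative configured rates are a configuration error", {
  bad <- neuronSpec1(-5)
  expect_error(simulateSpikes(makeEventSchedule(0), FALSE, bad, 1, 500),
               class = "whiskerVR_config_error")
})

test_that("self-attenuation scales the self/external response ratio", {
  fr <- 200
  evE <- makeEventSchedule(100, spacing = 3, start = 2, frameRate = fr)
  evS <- makeEventSchedule(100, spacing = 3, start = 302, origin = "self",
                           frameRate = fr)
  ev <- rbind(evE, evS)
  spec <- neuronSpec1(8, tGain = 60, selfAtt = 0.5)
  sp <- simulateSpikes(ev, FALSE, spec, duration = 610, frameRate = fr,
                       seed = 3)
  w <- list(pre = c(-0.25, -0.05), resp = c(0, 0.15))
  rE <- windowRates(sp[[1]], evE$time_s, w)
  rS <- windowRates(sp[[1]], evS$time_s, w)
  ratio <- (mean(rS[, 2]) - mean(rS[, 1])) /
    (mean(rE[, 2]) - mean(rE[, 1]))
  expect_lt(abs(ratio - 0.5), 0.1)
})

test_that("habituation of the transient gain is recovered by regression", {
  fr <- 200
  ev <- makeEventSchedule(30, spacing = 6, start = 3, frameRate = fr)
  spec <- neuronSpec1(8, tGain = 40, habSlope = -0.02)
  expected <- -0.02 * 40 * kernelWindowMean(0.3)
  slopes <- vapply(1:8, function(s) {
    sp <- simulateSpikes(ev, FALSE, spec, duration = 185, frameRate = fr,
                         seed = s)
    ser <- repetitionSeries(sp[[1]], ev, c(0, 0.3))
    fit <- repetitionRegression(ser$rate_corrected, ser$repetition)
    c(fit$slope, fit$se)
  }, numeric(2))
  # mean fitted slope within its 95% CI of the kernel-arithmetic value
  m <- mean(slopes[1, ])
  se <- sd(slopes[1, ]) / sqrt(ncol(slopes))
  expect_lt(abs(m - expected), 2.2 * se + 0.02)
})

test_that("spike counts follow the rate integral around events", {
  fr <- 500
  ev <- makeEventSchedule(50, spacing = 2, start = 1, frameRate = fr)
  spec <- neuronSpec1(5, tGain = 50)
  sp <- simulateSpikes(ev, FALSE, spec, duration = 102, frameRate = fr,
                       seed = 9)
  # expected count = baseline*T + nEvents * gain * integral(kernel)
  kint <- kernelWindowMean(0.6) * 0.6
  expected <- 5 * 102 + 50 * 50 * kint
  expect_lt(abs(length(sp[[1]]) - expected) / expected, 0.1)
})

test_that("full session generation is deterministic under a fixed seed", {
  cfg <- sessionConfig(duration = 20, nNeurons = 4L, seed = 13L)
  s1 <- simulateSession(cfg)
  s2 <- simulateSession(cfg)
  expect_identical(speedTrace(s1), speedTrace(s2))
  expect_identical(spikeTrains(s1), spikeTrains(s2))
  expect_identical(whiskerTracks(s1)$x_px, whiskerTracks(s2)$x_px)
})

test_that("session invariants hold on simulated output", {
  s <- shortSession()
  expect_true(validObject(s))
  dur <- sessionDuration(s)
  st <- unlist(spikeTrains(s))
  expect_true(all(st >= 0 & st <= dur))
  # surface is piecewise constant except during translation ramps
  moving <- abs(diff(surfaceTrace(s))) > 0
  expect_lt(mean(moving), 0.1)
})
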