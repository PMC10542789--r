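# Time-resolved population decoding.


test_that("feature matrices count spikes in overlapping centred bins", {
  cfg <- decodingConfig(binWidth = 0.15, step = 0.1, folds = 2,
                        resamples = 1, epoch = c(-0.15, 0.2))
  spikes <- list(a = c(10.01, 10.10), b = numeric(0))
  f <- featureMatrix(spikes, onsets = 10, cfg)
  expect_equal(f$times, c(-0.075, 0.025, 0.125))
  # bin centred at 0.025 covers [-0.05, 0.1): contains 10.01 only
  expect_equal(f$features[[2]][1, 1], 1 / 0.15)
  # bin centred at 0.125 covers [0.05, 0.2): contains 10.10 only
  expect_equal(f$features[[3]][1, 1], 1 / 0.15)
  # a spike can appear in two overlapping bins
  spikes2 <- list(a = c(10.06))
  f2 <- featureMatrix(spikes2, 10, cfg)
  expect_equal(f2$features[[2]][1, 1], 1 / 0.15)
  expect_equal(f2$features[[3]][1, 1], 1 / 0.15)
  # empty spike train -> all-zero column
  expect_true(all(vapply(f$features, function(m) all(m[, 2] == 0),
                         logical(1))))
})

test_that("feature z-scoring uses training statistics only", {
  set.seed(31)
  train <- matrix(rnorm(200, 10, 3), 20)
  test <- matrix(rnorm(100, 20, 3), 10)
  sc <- zscoreFeatures(train, test)
  expect_equal(colMeans(sc$train), rep(0, 10), tolerance = 1e-10)
  expect_equal(apply(sc$train, 2, sd), rep(1, 10), tolerance = 1e-10)
  # test columns keep the train-referenced shift (leakage check)
  expect_gt(mean(colMeans(sc$test)), 1)
  # constant neuron passes through as zeros
  train2 <- cbind(train, 5)
  test2 <- cbind(test, 5)
  sc2 <- zscoreFeatures(train2, test2)
  expect_true(all(sc2$train[, 11] == 0))
  expect_true(all(sc2$test[, 11] == 0))
  expect_error(zscoreFeatures(train[0, ], test),
               class = "whiskerVR_input_error")
})

test_that("decoding is at chance before movement and high during it", {
  fx <- decodeFixture(seed = 32)
  cfg <- decodingConfig(folds = 5, resamples = 4, step = 0.15,
                        epoch = c(-0.45, 0.6))
  feats <- featureMatrix(fx$spikes, fx$onsets, cfg)
  res <- crossValidatedDecode(feats, fx$labels, cfg, seed = 33)
  acc <- decodingAccuracy(res)
  pre <- acc$mean_acc[acc$time_s < -0.05]
  during <- acc$mean_acc[acc$time_s > 0 & acc$time_s < 0.3]
  expect_true(all(abs(pre - 1 / 3) < 0.15))
  expect_gt(max(during), 0.6)
  # transient-only population returns toward chance late in the epoch
  cfgLate <- decodingConfig(folds = 5, resamples = 4, step = 0.3,
                            binWidth = 0.3, epoch = c(0.6, 1.8))
  featsLate <- featureMatrix(fx$spikes, fx$onsets, cfgLate)
  resLate <- crossValidatedDecode(featsLate, fx$labels, cfgLate,
                                  seed = 33)
  expect_true(all(abs(resLate@accuracy - 1 / 3) < 0.2))
})

test_that("label shuffling drives accuracy to chance", {
  fx <- decodeFixture(seed = 34)
  cfg <- decodingConfig(folds = 5, resamples = 2, step = 0.15,
                        epoch = c(0, 0.3))
  feats <- featureMatrix(fx$spikes, fx$onsets, cfg)
  set.seed(35)
  accs <- replicate(20, {
    res <- crossValidatedDecode(feats, sample(fx$labels), cfg,
                                seed = sample.int(1e6, 1))
    mean(res@accuracy)
  })
  sem <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 1 / 3), 3 * sem + 0.02)
})

test_that("linearly separable features decode perfectly", {
  set.seed(36)
  labels <- rep(c("rostral", "caudal", "center"), each = 10)
  x <- matrix(rnorm(30 * 4, 0, 0.05), 30)
  x[labels == "rostral", 1] <- x[labels == "rostral", 1] + 5
  x[labels == "caudal", 2] <- x[labels == "caudal", 2] + 5
  cfg <- decodingConfig(folds = 5, resamples = 2)
  feats <- list(times = 0, features = list(x))
  res <- crossValidatedDecode(feats, labels, cfg, seed = 37)
  expect_gte(res@accuracy, 0.95)
})

test_that("a class with fewer trials than folds is a named error", {
  labels <- c(rep("rostral", 12), rep("caudal", 12), rep("center", 3))
  feats <- list(times = 0, features = list(matrix(rnorm(27 * 3), 27)))
  err <- tryCatch(
    crossValidatedDecode(feats, labels, decodingConfig(folds = 5,
                                                       resamples = 2)),
    error = identity)
  expect_s3_class(err, "whiskerVR_input_error")
  expect_match(conditionMessage(err), "center")
})

test_that("subpopulation decoding separates transient and sustained", {
  fxS <- decodeFixture(seed = 38, kind = "sustained")
  cfg <- decodingConfig(folds = 5, resamples = 3, step = 0.4,
                        binWidth = 0.4, epoch = c(0.5, 2.2))
  feats <- featureMatrix(fxS$spikes, fxS$onsets, cfg)
  # identical subpopulations under a shared seed decode identically,
  # and a sustained population stays above chance late after movement
  clsBoth <- data.frame(neuron_id = names(fxS$spikes), label = "both")
  res2 <- subpopulationDecode(feats, fxS$labels, clsBoth, cfg, seed = 40)
  expect_identical(res2$transient@accuracy, res2$sustained@accuracy)
  expect_gt(mean(res2$sustained@accuracy), 1 / 3 + 0.1)
  # an empty subpopulation is an input error
  clsOnly <- data.frame(neuron_id = names(fxS$spikes), label = "sustained")
  expect_error(subpopulationDecode(feats, fxS$labels, clsOnly, cfg),
               class = "whiskerVR_input_error")
})

test_that("sustained populations keep decoding late; transient do not", {
  cfg <- decodingConfig(folds = 4, resamples = 2, step = 0.5,
                        binWidth = 0.5, epoch = c(1, 2.5))
  fxS <- decodeFixture(seed = 41, kind = "sustained", nPerClass = 12)
  featsS <- featureMatrix(fxS$spikes, fxS$onsets, cfg)
  accS <- crossValidatedDecode(featsS, fxS$labels, cfg, seed = 42)
  fxT <- decodeFixture(seed = 41, kind = "transient", nPerClass = 12)
  featsT <- featureMatrix(fxT$spikes, fxT$onsets, cfg)
  accT <- crossValidatedDecode(featsT, fxT$labels, cfg, seed = 42)
  expect_gt(mean(accS@accuracy), mean(accT@accuracy) + 0.1)
  expect_gt(mean(accS@accuracy), 0.6)
})

test_that("decoding accuracy grows with the transient gain", {
  fr <- 200
  med <- vapply(c(0, 5, 10, 20), function(g) {
    accs <- vapply(1:5, function(s) {
      set.seed(1000 + s)
      labels <- sample(rep(c("rostral", "caudal", "center"), each = 8))
      onsets <- seq(5, by = 4, length.out = 24)
      ev <- data.frame(time_s = onsets[labels == "rostral"],
                       frame = round(onsets[labels == "rostral"] * fr) + 1,
                       whisker_id = 1, kind = "GoW", origin = "external",
                       direction = "rostral",
                       repetition = seq_len(sum(labels == "rostral")))
      spikes <- simulateSpikes(
        ev, FALSE,
        do.call(rbind, lapply(1:8, function(i) {
          sp <- neuronSpec1(6, tGain = g); sp$neuron_id <- i; sp
        })),
        duration = max(onsets) + 3, frameRate = fr, seed = 2000 + s)
      cfg <- decodingConfig(folds = 4, resamples = 2, step = 0.2,
                            binWidth = 0.2, epoch = c(0, 0.2))
      feats <- featureMatrix(spikes, onsets, cfg)
      mean(crossValidatedDecode(feats, labels, cfg,
                                seed = 3000 + s)@accuracy)
    }, numeric(1))
    median(accs)
  }, numeric(1))
  expect_gte(med[4], med[1])
  expect_gt(med[4], 1 / 3 + 0.1)
})
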