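test_that("temporal attention matches the additive-score oracle", {
  # identical steps -> uniform weights, context = the common vector
  h <- matrix(rep(c(1, -2, 0.5), each = 6), 6, 3)
  out <- temporalAttention(h, attentionUnits = 4, seed = 2)
  expect_equal(out$weights, rep(1 / 6, 6))
  expect_equal(out$context, c(1, -2, 0.5))
  expect_equal(sum(out$weights), 1)
  expect_true(all(out$weights >= 0))

  # single step
  h1 <- matrix(c(3, 1), 1, 2)
  out1 <- temporalAttention(h1, seed = 1)
  expect_equal(out1$weights, 1)
  expect_equal(out1$context, c(3, 1))

  # T = 3 with fixed parameters vs hand-computed softmax of the scores
  withr::with_seed(4, {
    h3 <- matrix(rnorm(3 * 5), 3, 5)
    W <- matrix(rnorm(5 * 10), 5, 10)
    b <- rnorm(10); v <- rnorm(10)
  })
  out3 <- temporalAttention(h3, weights = list(W = W, b = b, v = v))
  e <- as.numeric(tanh(sweep(h3 %*% W, 2, b, "+")) %*% v)
  alpha <- exp(e) / sum(exp(e))
  expect_equal(out3$weights, alpha, tolerance = 1e-12)
  expect_equal(out3$context, as.numeric(t(h3) %*% alpha), tolerance = 1e-12)

  expect_error(temporalAttention(matrix(0, 0, 3)), "at least one")
})

test_that("deep model forward passes emit probability rows", {
  for (build in list(attentionLSTM, eegConformer)) {
    m <- build(c("SCD", "MCI", "AD"), seed = 3)
    z <- new("EpochSet", data = array(0, c(768, 19, 5)),
             labels = factor(rep("SCD", 5), levels = c("SCD", "MCI", "AD")),
             subjectIds = rep("S", 5), trialIndex = 1:5, condition = "SQT",
             channels = montage19(), samplingRate = 512,
             augmented = rep(FALSE, 5))
    p <- predictProba(m, z)
    expect_equal(dim(p), c(5L, 3L))
    expect_equal(unname(rowSums(p)), rep(1, 5), tolerance = 1e-6)
    expect_true(all(p >= 0))
    # inference is deterministic (dropout disabled)
    expect_identical(p, predictProba(m, z))
  }
})

test_that("attention weights form a distribution over the 768 time steps", {
  m <- attentionLSTM(c("SCD", "MCI"), seed = 5)
  withr::with_seed(6, {
    z <- new("EpochSet", data = array(rnorm(768 * 19 * 3), c(768, 19, 3)),
             labels = factor(rep("SCD", 3), levels = c("SCD", "MCI", "AD")),
             subjectIds = rep("S", 3), trialIndex = 1:3, condition = "SQT",
             channels = montage19(), samplingRate = 512,
             augmented = rep(FALSE, 3))
  })
  a <- attentionWeights(m, z)
  expect_equal(dim(a), c(3L, 768L))
  expect_equal(unname(rowSums(a)), rep(1, 3), tolerance = 1e-6)
  expect_true(all(a >= 0))
})

test_that("conformer geometry follows the token-count formula and adapts", {
  m <- eegConformer(c("A", "B"), seed = 1)
  expect_equal(m@config$nTokens, floor((768 - 75) / 15) + 1)
  expect_equal(m@config$nTokens, 47)
  # channel-count adaptation: 21 channels still forward cleanly
  m21 <- eegConformer(c("A", "B"), nChannels = 21, seed = 1)
  z <- new("EpochSet", data = array(0, c(768, 21, 2)),
           labels = factor(c("SCD", "SCD"), levels = c("SCD", "MCI", "AD")),
           subjectIds = c("S", "S"), trialIndex = 1:2, condition = "SQT",
           channels = paste0("C", 1:21), samplingRate = 512,
           augmented = c(FALSE, FALSE))
  p <- predictProba(m21, z)
  expect_equal(unname(rowSums(p)), c(1, 1), tolerance = 1e-6)
  expect_error(eegConformer(c("A", "B"), nSamples = 50, poolLen = 75),
               "token count")
  expect_error(eegConformer(c("A", "B"), embedDim = 39), "divisible")
})

test_that("segmentation-recombination augmentation honours its contracts", {
  tr <- toyEpochs(nPerClass = 50, seed = 9)
  aug <- augmentRecombine(tr, fraction = 0.2, nSegments = 8, seed = 2)
  expect_equal(nTrials(aug), 120L)          # floor(0.2 * 100) added
  expect_equal(sum(aug@augmented), 20L)
  expect_identical(augmentRecombine(tr, 0), tr)
  # labels preserved (only present classes), augmented ids quarantined by flag
  expect_setequal(unique(as.character(aug@labels[aug@augmented])),
                  c("SCD", "MCI"))
  expect_true(all(grepl("^AUG_", aug@subjectIds[aug@augmented])))

  # recombined content comes only from same-class source trials
  tiny <- toyEpochs(nPerClass = 4, nSamples = 16, nChannels = 1, seed = 3)
  tiny@data[] <- 0
  for (i in 1:8) tiny@data[, , i] <- ifelse(i <= 4, i, 100 + i)
  a2 <- augmentRecombine(tiny, fraction = 0.5, nSegments = 4, seed = 4)
  newTrials <- which(a2@augmented)
  for (i in newTrials) {
    vals <- unique(as.numeric(a2@data[, , i]))
    if (as.character(a2@labels[i]) == "SCD") expect_true(all(vals <= 4))
    else expect_true(all(vals > 100))
  }

  # a class with a single trial is skipped with a warning
  one <- subsetEpochs(tiny, c(1, 5, 6, 7, 8))
  expect_warning(a3 <- augmentRecombine(one, fraction = 0.6, seed = 1),
                 "fewer than 2")
  expect_false(any(a3@labels[a3@augmented] == "SCD"))
})

test_that("PCA+SVM baseline retains variance as specified and separates", {
  # variance concentrated on one axis -> a single component
  withr::with_seed(11, {
    n <- 60
    dat <- array(0, c(4, 2, n))
    dat[1, 1, ] <- rnorm(n, sd = 5)
    es <- new("EpochSet", data = dat,
              labels = factor(rep(c("SCD", "MCI"), each = n / 2),
                              levels = c("SCD", "MCI", "AD")),
              subjectIds = rep(c("a", "b"), each = n / 2), trialIndex = rep(1:30, 2),
              condition = "SQT", channels = c("C1", "C2"), samplingRate = 512,
              augmented = rep(FALSE, n))
  })
  m1 <- fitBaseline(es)
  expect_equal(m1@extra$nComponents, 1L)

  # isotropic 10-dim data cannot reach 95% with fewer than 10 components
  withr::with_seed(12, {
    iso <- new("EpochSet", data = array(rnorm(5 * 2 * 200), c(5, 2, 200)),
               labels = factor(rep(c("SCD", "MCI"), 100),
                               levels = c("SCD", "MCI", "AD")),
               subjectIds = rep(c("a", "b"), 100), trialIndex = rep(1:10, 20),
               condition = "SQT", channels = c("C1", "C2"),
               samplingRate = 512, augmented = rep(FALSE, 200))
  })
  m2 <- fitBaseline(iso)
  expect_equal(m2@extra$nComponents, 10L)

  # well-separated Gaussian classes are fit almost perfectly
  sep <- toyEpochs(nPerClass = 40, nSamples = 8, nChannels = 2, shift = 4,
                   seed = 13)
  m3 <- fitBaseline(sep)
  p <- predictProba(m3, sep)
  acc <- mean(m3@classes[max.col(p)] == as.character(sep@labels))
  expect_gte(acc, 0.95)
  expect_equal(unname(rowSums(p)), rep(1, nTrials(sep)), tolerance = 1e-6)
})
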