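test_that("cohort sampling respects sizes, ids and determinism", {
  co <- sampleCohort(20, 28, 10, seed = 9)
  expect_equal(nrow(co), 58L)
  expect_equal(unname(table(co$group)[c("SCD", "MCI", "AD")]),
               c(20L, 28L, 10L), ignore_attr = TRUE)
  expect_false(any(duplicated(co$subject_id)))
  expect_identical(co, sampleCohort(20, 28, 10, seed = 9))
  expect_false(identical(co$alpha_peak_hz,
                         sampleCohort(20, 28, 10, seed = 10)$alpha_peak_hz))
  expect_equal(nrow(sampleCohort(0, 0, 0, seed = 1)), 0L)
  expect_error(sampleCohort(-1, 5, 5, seed = 1), "non-negative")
  # physical bounds
  pw <- as.matrix(co[, c("p_delta", "p_theta", "p_alpha", "p_beta", "p_gamma")])
  expect_true(all(pw > 0))
  expect_equal(unname(rowSums(pw)), rep(1, 58))
  expect_true(all(co$alpha_peak_hz >= 6 & co$alpha_peak_hz <= 13))
})

test_that("effect size 0 collapses the group profiles to one distribution", {
  sp <- groupSignalProfiles(0)
  num <- vapply(sp, is.numeric, TRUE)
  for (k in names(sp)[num]) expect_equal(sd(sp[[k]]), 0)
  bp <- groupBehaviorProfiles(0)
  num <- vapply(bp, is.numeric, TRUE)
  for (k in names(bp)[num]) expect_equal(sd(bp[[k]]), 0)
  # and the dial widens differences monotonically
  s1 <- groupSignalProfiles(1); s3 <- groupSignalProfiles(3)
  expect_gt(diff(range(s3$alpha_peak_hz)), diff(range(s1$alpha_peak_hz)))
})

test_that("recording contracts: conditions, durations and event bookkeeping", {
  rest <- fxRest()
  expect_s4_class(rest, "RawRecording")
  expect_gte(ncol(signalMatrix(rest)) / samplingRate(rest), 60)
  expect_equal(nrow(eventTable(rest)), 0L)

  sqt <- fxSqt()
  ev <- eventTable(sqt)
  expect_equal(sum(ev$type == "question_offset"), 10L)
  q <- questionTable(fxProtocol())
  on <- ev$sample_index[ev$type == "question_onset"][order(ev$trial[ev$type == "question_onset"])]
  off <- ev$sample_index[ev$type == "question_offset"][order(ev$trial[ev$type == "question_offset"])]
  expect_identical(off - on,
                   as.integer(round(q$listening_time_ms * 512 / 1000)))
  # identical seeds give bit-identical recordings
  again <- synthesizeRecording(fxCohort()[1, ], "SQT", fxProtocol(), seed = 5,
                               channels = montage19(), samplingRate = 512)
  expect_identical(signalMatrix(sqt), signalMatrix(again))
  # out-of-bounds parameters are a generation error
  bad <- fxCohort()[1, ]; bad$p_alpha <- -0.1
  expect_error(synthesizeRecording(bad, "REST", fxProtocol()), "out of bounds")
})

test_that("rest spectra match the generator's analytic band powers", {
  co <- fxCohort()
  for (i in c(1, 5)) {   # an SCD and an AD subject
    rec <- synthesizeRecording(co[i, ], "REST", fxProtocol(), seed = 11,
                               channels = montage19(), samplingRate = 512)
    for (band in list(c(4, 8), c(8, 12), c(13, 30))) {
      est <- bandPower(rec, band[1], band[2])
      tgt <- analyticBandPower(co[i, ], band[1], band[2])
      expect_lt(abs(est - tgt) / tgt, 0.15)
    }
  }
})

test_that("alpha band power scales with the subject's alpha parameter", {
  co <- fxCohort()
  s1 <- co[1, ]
  s2 <- s1
  s2$p_alpha <- s1$p_alpha * 2      # k-fold alpha power, all else equal
  r1 <- synthesizeRecording(s1, "REST", fxProtocol(), seed = 13,
                            channels = montage19(), samplingRate = 512)
  r2 <- synthesizeRecording(s2, "REST", fxProtocol(), seed = 13,
                            channels = montage19(), samplingRate = 512)
  kAnalytic <- analyticBandPower(s2, 8, 12) / analyticBandPower(s1, 8, 12)
  kWelch <- bandPower(r2, 8, 12) / bandPower(r1, 8, 12)
  expect_gt(kAnalytic, 1.5)
  expect_lt(abs(kWelch - kAnalytic) / kAnalytic, 0.15)
})

test_that("artifact injection follows its rate and amplitude contracts", {
  rec <- fxRest()
  clean <- injectArtifacts(rec, 0, 0, seed = 1)
  expect_identical(signalMatrix(clean), signalMatrix(rec))

  dirty <- injectArtifacts(rec, 12, 0, seed = 2)
  nBlink <- length(dirty@misc$artifacts$blink_samples)
  expect_gt(nBlink, qpois(0.001, 12 * 62 / 60))
  expect_lt(nBlink, qpois(0.999, 12 * 62 / 60))

  # 60 Hz periodogram power tracks the analytic sinusoid power a^2/2
  lineA <- injectArtifacts(rec, 0, 10, seed = 3)
  lineB <- injectArtifacts(rec, 0, 20, seed = 3)
  pBase <- bandPower(rec, 59, 61)
  pA <- bandPower(lineA, 59, 61) - pBase
  pB <- bandPower(lineB, 59, 61) - pBase
  expect_lt(abs(pA - 10^2 / 2) / (10^2 / 2), 0.15)
  expect_lt(abs(pB / pA - 4), 0.5)
})

test_that("behavior sampling is calibrated, bounded and deterministic", {
  co <- fxCohort()
  b1 <- sampleBehavior(co[1, ], fxProtocol(), seed = 4)
  expect_identical(b1, sampleBehavior(co[1, ], fxProtocol(), seed = 4))
  expect_equal(nrow(b1), 10L)
  expect_true(all(is.na(b1$rt_ms) | (b1$rt_ms > 0 & b1$rt_ms <= 10000)))
  q <- questionTable(fxProtocol())
  responded <- b1$response_key != "none"
  expect_identical(b1$correct[responded],
                   (b1$response_key == q$correct_key)[responded])
  expect_true(all(!b1$correct[!responded]))
  expect_true(all(is.na(b1$rt_ms[!responded])))

  # a perfectly accurate, fast subject answers all 10 correctly
  sure <- co[1, ]
  sure$acc_prob <- 1; sure$rt_mean_ms <- 600; sure$rt_sd_ms <- 100
  expect_true(all(sampleBehavior(sure, fxProtocol(), seed = 8)$correct))
})
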