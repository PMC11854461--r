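test_that("decimation preserves duration, events and pass-band tones", {
  tone <- toneRecording(10, fs = 2048, seconds = 12)
  tone@events <- data.frame(type = "question_onset", trial = 1L,
                            sample_index = 20480L)
  tone@condition <- "REST"   # keep validity simple
  tone@events <- tone@events[0, ]
  d <- downsampleRecording(tone, 512)
  expect_equal(samplingRate(d), 512)
  expect_equal(ncol(signalMatrix(d)), ncol(signalMatrix(tone)) / 4)
  # central portion: amplitude preserved within 1%
  core <- signalMatrix(d)[1, 1000:5000]
  expect_lt(abs(rms(core) - 10 / sqrt(2)) / (10 / sqrt(2)), 0.01)
  expect_error(downsampleRecording(d, 2048), "exceeds")
  expect_error(downsampleRecording(toneRecording(1, fs = 500), 512), "exceeds")
})

test_that("event indices rescale under decimation", {
  rec <- fxSqt()   # 512 Hz already; decimate to 256 to exercise rescaling
  d <- downsampleRecording(rec, 256)
  expect_equal(d@events$sample_index,
               pmin(ncol(signalMatrix(d)) - 1L,
                    as.integer(round(rec@events$sample_index / 2))))
  # arithmetic example: sample 20480 at 4x decimation lands on 5120
  expect_equal(round(20480 / 4), 5120)
})

test_that("band-pass keeps 10 Hz and rejects 0.5 Hz", {
  lo <- bandpassFilter(toneRecording(0.5))
  mid <- bandpassFilter(toneRecording(10))
  z <- toneRecording(10); z@signal[] <- 0
  core <- 1000:3000
  expect_lt(rms(signalMatrix(lo)[1, core]) / (10 / sqrt(2)), 0.10)
  expect_lt(abs(rms(signalMatrix(mid)[1, core]) - 10 / sqrt(2)) / (10 / sqrt(2)), 0.05)
  expect_equal(max(abs(signalMatrix(bandpassFilter(z)))), 0)
  expect_error(bandpassFilter(toneRecording(10), 2, 300), "Nyquist")
})

test_that("notch removes 60 Hz and spares 10 Hz", {
  n60 <- notchFilter(toneRecording(60))
  n10 <- notchFilter(toneRecording(10))
  z <- toneRecording(10); z@signal[] <- 0
  core <- 1000:3000
  att <- 20 * log10(rms(signalMatrix(n60)[1, core]) / (10 / sqrt(2)))
  expect_lt(att, -20)
  expect_lt(abs(rms(signalMatrix(n10)[1, core]) - 10 / sqrt(2)) / (10 / sqrt(2)), 0.05)
  expect_equal(max(abs(signalMatrix(notchFilter(z)))), 0)
})

test_that("average reference zeroes the channel mean at every sample", {
  rec <- toneRecording(10, nch = 4)
  rec@signal <- rec@signal + c(5, -3, 2, 11)       # per-channel offsets
  r <- rereferenceAverage(rec)
  expect_lt(max(abs(colMeans(signalMatrix(r)))), 1e-9)
  # constant offset on identical channels -> all zero
  const <- toneRecording(10, nch = 3); const@signal[] <- 7
  expect_equal(max(abs(signalMatrix(rereferenceAverage(const)))), 0)
  # antisymmetric channels are already zero-mean -> unchanged
  anti <- toneRecording(10, nch = 2)
  anti@signal[2, ] <- -anti@signal[1, ]
  expect_equal(signalMatrix(rereferenceAverage(anti)), signalMatrix(anti))
  # random 64-channel matrix
  big <- new("RawRecording", subjectId = "R", condition = "REST",
             samplingRate = 512, channels = montage64(),
             signal = matrix(rnorm(64 * 256), 64),
             events = data.frame(type = character(), trial = integer(),
                                 sample_index = integer()), misc = list())
  expect_lt(max(abs(colMeans(signalMatrix(rereferenceAverage(big))))), 1e-9)
  one <- toneRecording(10, nch = 1)
  expect_error(rereferenceAverage(one), "2 channels")
})

test_that("channel selection returns the canonical 19 in order", {
  co <- fxCohort()
  rec64 <- synthesizeRecording(co[2, ], "REST", fxProtocol(), seed = 21,
                               channels = montage64(), samplingRate = 512)
  sel <- selectChannels(rec64)
  expect_identical(channelNames(sel), montage19())
  expect_equal(nrow(signalMatrix(sel)), 19L)
  # rows really are the matching source channels
  expect_equal(signalMatrix(sel)[10, ],
               signalMatrix(rec64)[match("Cz", channelNames(rec64)), ])
  expect_identical(signalMatrix(selectChannels(sel)), signalMatrix(sel))
  drop <- sel
  drop@channels[10] <- "XX"
  expect_error(selectChannels(drop), "missing channel Cz")
})

test_that("task epoching cuts the 1.5 s pre-offset window exactly", {
  pre <- fxSqtPre()
  es <- epochSQT(pre, label = "SCD")
  expect_equal(dim(es@data)[1:2], c(768L, 19L))
  expect_equal(nTrials(es), 10L)
  expect_true(all(is.finite(es@data)))
  # window arithmetic: a 0-based offset at sample o covers o-768 .. o-1
  off <- pre@events$sample_index[pre@events$type == "question_offset"][1]
  expect_equal(es@data[, , 1], t(pre@signal[, (off - 767):off]))
  # insufficient pre-offset data rejects the trial
  short <- pre
  short@events$sample_index[short@events$type == "question_offset"][1] <- 500L
  short@events$sample_index[short@events$type == "question_onset"][1] <- 100L
  expect_warning(out <- epochSQT(short, strict = FALSE), "rejected")
  expect_equal(nTrials(out), 9L)
  expect_error(suppressWarnings(epochSQT(short)), "10 usable")
})

test_that("rest epoching takes 10 contiguous central segments", {
  pre <- fxRestPre()
  er <- epochRest(pre, label = "SCD")
  expect_equal(dim(er@data), c(768L, 19L, 10L))
  n <- ncol(pre@signal)
  start0 <- (n - 7680L) %/% 2L
  expect_equal(er@data[, , 1], t(pre@signal[, (start0 + 1):(start0 + 768)]))
  expect_equal(er@data[, , 10],
               t(pre@signal[, (start0 + 9 * 768 + 1):(start0 + 7680)]))
  # exactly 15 s -> starts at zero
  quarter <- pre
  quarter@signal <- pre@signal[, 1:7680]
  e2 <- epochRest(quarter)
  expect_equal(e2@data[, , 1], t(quarter@signal[, 1:768]))
  tooShort <- pre
  tooShort@signal <- pre@signal[, 1:5000]
  expect_error(epochRest(tooShort), "15 s")
})

test_that("ICA flags and removes injected blinks but spares clean data", {
  rec <- fxRest()
  dirty <- injectArtifacts(rec, 12, 0, seed = 5)
  blinkSamples <- dirty@misc$artifacts$blink_samples
  len <- dirty@misc$artifacts$blink_len
  n <- ncol(signalMatrix(dirty))
  blink <- numeric(n)
  wave <- 0.5 - 0.5 * cos(2 * pi * seq_len(len) / (len + 1))
  for (b in blinkSamples) blink[b:(b + len - 1)] <- blink[b:(b + len - 1)] + wave

  pre <- rereferenceAverage(notchFilter(bandpassFilter(dirty)))
  cl <- removeArtifactComponents(pre, seed = 5)
  expect_gt(length(cl@misc$ica$flagged), 0)
  fr <- match(c("Fp1", "Fp2"), cl@channels)
  corAfter <- max(abs(cor(blink, t(cl@signal[fr, , drop = FALSE]))))
  expect_lt(corAfter, 0.2)

  pre0 <- rereferenceAverage(notchFilter(bandpassFilter(rec)))
  cl0 <- removeArtifactComponents(pre0, seed = 5)
  expect_equal(length(cl0@misc$ica$flagged), 0L)
  expect_lt(rms(cl0@signal - pre0@signal) / rms(pre0@signal), 0.05)
  expect_gt(length(cl@misc$ica$flagged), length(cl0@misc$ica$flagged))

  # rank < 2 is a diagnostic error
  flat <- pre0
  flat@signal <- matrix(rep(pre0@signal[1, ], 3), 3, byrow = TRUE)
  flat@channels <- c("A", "B", "C")
  expect_error(removeArtifactComponents(flat, seed = 1), "rank")
})

test_that("the preprocessing chain is deterministic end to end", {
  rec <- fxSqt()
  a <- preprocessRecording(rec, ica = TRUE, icaSeed = 3)
  b <- preprocessRecording(rec, ica = TRUE, icaSeed = 3)
  expect_identical(signalMatrix(a), signalMatrix(b))
  expect_identical(channelNames(a), montage19())
  expect_equal(samplingRate(a), 512)
})
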