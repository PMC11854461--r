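# Shared fixtures, built lazily once per test run and cached.
.fx <- new.env(parent = emptyenv())

fxGet <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fxProtocol <- function() fxGet("protocol", loadProtocol)

fxCohort <- function() fxGet("cohort", function() sampleCohort(2, 2, 2, seed = 3))

# one fast-profile REST recording (19 ch, 512 Hz)
fxRest <- function() fxGet("rest", function()
  synthesizeRecording(fxCohort()[1, ], "REST", fxProtocol(), seed = 5,
                      channels = montage19(), samplingRate = 512))

# one fast-profile SQT recording
fxSqt <- function() fxGet("sqt", function()
  synthesizeRecording(fxCohort()[1, ], "SQT", fxProtocol(), seed = 5,
                      channels = montage19(), samplingRate = 512))

fxRestPre <- function() fxGet("restPre", function()
  preprocessRecording(fxRest()))

fxSqtPre <- function() fxGet("sqtPre", function()
  preprocessRecording(fxSqt()))

# a pure-tone recording for filter contracts
toneRecording <- function(freq, fs = 512, seconds = 8, nch = 2, amp = 10) {
  t <- (0:(fs * seconds - 1)) / fs
  sig <- matrix(rep(amp * sin(2 * pi * freq * t), each = nch), nch)
  new("RawRecording", subjectId = "TONE", condition = "REST",
      samplingRate = fs, channels = paste0("CH", seq_len(nch)), signal = sig,
      events = data.frame(type = character(), trial = integer(),
                          sample_index = integer()),
      misc = list())
}

rms <- function(x) sqrt(mean(x^2))

# small synthetic EpochSet with class-dependent mean shift, for quick
# training-harness checks (geometry is configurable, not the analysis default)
toyEpochs <- function(nPerClass = 30, classes = c("SCD", "MCI"), nSamples = 64,
                      nChannels = 3, shift = 1.5, seed = 1, nSubj = 6) {
  withr::with_seed(seed, {
    n <- nPerClass * length(classes)
    dat <- array(rnorm(nSamples * nChannels * n), c(nSamples, nChannels, n))
    labs <- rep(classes, each = nPerClass)
    for (i in seq_len(n)) {
      k <- match(labs[i], classes) - 1
      dat[, , i] <- dat[, , i] + k * shift * sin(2 * pi * seq_len(nSamples) / 16)
    }
    subj <- paste0(labs, "_S", rep(rep(seq_len(nSubj / length(classes)),
                                       each = nPerClass / (nSubj / length(classes))),
                                   length(classes)))
    new("EpochSet", data = dat, labels = factor(labs, levels = c("SCD", "MCI", "AD")),
        subjectIds = subj, trialIndex = rep(seq_len(nPerClass), length(classes)),
        condition = "SQT", channels = paste0("CH", seq_len(nChannels)),
        samplingRate = 512, augmented = rep(FALSE, n))
  })
}
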