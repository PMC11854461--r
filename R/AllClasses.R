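#' @useDynLib adspectrum, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats approx coef cor fft lm median na.omit optim p.adjust
#'   pchisq pnorm prcomp predict qnorm quantile rbeta rbinom rlnorm rnorm
#'   rpois runif sd setNames shapiro.test kruskal.test var
#' @importFrom utils head read.delim write.csv
NULL

GROUPS <- c("SCD", "MCI", "AD")

#' Simple Question Task protocol
#'
#' Holds the fixed 10-question auditory yes/no protocol: question text, the
#' correct response key (\code{"O"} = yes, \code{"X"} = no) and the audio
#' duration ("listening time") of each question, plus the response window.
#'
#' @slot questions data.frame with columns \code{index}, \code{text},
#'   \code{correct_key}, \code{listening_time_ms}.
#' @slot responseWindowMs single numeric, the maximum time allowed for a
#'   button response after question audio offset (10000 ms).
#' @export
setClass("SQTProtocol",
  representation(questions = "data.frame", responseWindowMs = "numeric"))

setValidity("SQTProtocol", function(object) {
  q <- object@questions
  msg <- character()
  need <- c("index", "text", "correct_key", "listening_time_ms")
  if (!all(need %in% names(q))) {
    msg <- c(msg, paste("questions must have columns", paste(need, collapse = ", ")))
  } else {
    if (nrow(q) != 10L) msg <- c(msg, "protocol must contain exactly 10 questions")
    if (!all(q$correct_key %in% c("O", "X")))
      msg <- c(msg, "correct_key must be 'O' or 'X'")
    if (any(q$listening_time_ms > 2200))
      msg <- c(msg, "listening times must not exceed 2200 ms")
    if (any(q$listening_time_ms <= 0))
      msg <- c(msg, "listening times must be positive")
  }
  if (length(object@responseWindowMs) != 1L || object@responseWindowMs != 10000)
    msg <- c(msg, "responseWindowMs must be 10000")
  if (length(msg)) msg else TRUE
})

#' Continuous multichannel EEG recording
#'
#' A raw (or partially preprocessed) continuous recording for one subject and
#' one condition, with its event table. Signal is stored channels x samples in
#' microvolts. Event sample indices are 0-based offsets from the start of the
#' recording, so an event at index \code{k} occurred \code{k / samplingRate}
#' seconds in.
#'
#' @slot subjectId single character.
#' @slot condition \code{"REST"} or \code{"SQT"}.
#' @slot samplingRate sampling rate in Hz.
#' @slot channels ordered channel names.
#' @slot signal numeric matrix, channels x samples (microvolts).
#' @slot events data.frame with columns \code{type} (one of
#'   \code{question_onset}, \code{question_offset}, \code{response}),
#'   \code{trial}, \code{sample_index} (0-based).
#' @slot misc list of generator/preprocessing metadata (e.g. injected
#'   artifact times, ICA log).
#' @export
setClass("RawRecording",
  representation(subjectId = "character", condition = "character",
    samplingRate = "numeric", channels = "character", signal = "matrix",
    events = "data.frame", misc = "list"))

setValidity("RawRecording", function(object) {
  msg <- character()
  if (!object@condition %in% c("REST", "SQT"))
    msg <- c(msg, "condition must be 'REST' or 'SQT'")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a positive scalar")
  if (nrow(object@signal) != length(object@channels))
    msg <- c(msg, "signal must have one row per channel")
  ev <- object@events
  if (nrow(ev)) {
    if (!all(c("type", "trial", "sample_index") %in% names(ev)))
      msg <- c(msg, "events needs columns type, trial, sample_index")
    else {
      if (any(ev$sample_index < 0) || any(ev$sample_index >= ncol(object@signal)))
        msg <- c(msg, "event sample indices must lie within the signal")
      if (!all(ev$type %in% c("question_onset", "question_offset", "response")))
        msg <- c(msg, "unknown event type")
    }
  }
  if (object@condition == "SQT") {
    if (sum(ev$type == "question_offset") != 10L)
      msg <- c(msg, "SQT recordings must contain exactly 10 question_offset events")
  } else if (nrow(ev) && any(grepl("^question", ev$type))) {
    msg <- c(msg, "REST recordings must contain no question events")
  }
  if (length(msg)) msg else TRUE
})

#' Set of fixed-length EEG epochs
#'
#' Epoched trials as a 3-D array (samples x channels x trials) plus per-trial
#' labels, subject identifiers and trial indices. The analysis default is
#' 1.5 s epochs at 512 Hz over the 19-channel montage, i.e. 768 x 19 per
#' trial.
#'
#' @slot data numeric array samples x channels x trials, microvolts.
#' @slot labels factor of per-trial group labels.
#' @slot subjectIds character, per-trial subject identifiers.
#' @slot trialIndex integer, per-trial index (1..10 within subject).
#' @slot condition \code{"REST"} or \code{"SQT"}.
#' @slot channels channel names (column order of \code{data}).
#' @slot samplingRate sampling rate in Hz.
#' @slot augmented logical, per-trial flag marking synthetic augmented trials
#'   (must never enter validation or test sets).
#' @export
setClass("EpochSet",
  representation(data = "array", labels = "factor", subjectIds = "character",
    trialIndex = "integer", condition = "character", channels = "character",
    samplingRate = "numeric", augmented = "logical"))

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be a 3-D array (samples x channels x trials)")
  else {
    n <- d[3L]
    if (length(object@labels) != n) msg <- c(msg, "labels length must equal n trials")
    if (length(object@subjectIds) != n) msg <- c(msg, "subjectIds length must equal n trials")
    if (length(object@trialIndex) != n) msg <- c(msg, "trialIndex length must equal n trials")
    if (length(object@augmented) != n) msg <- c(msg, "augmented length must equal n trials")
    if (length(object@channels) != d[2L]) msg <- c(msg, "channels length must equal dim 2")
    if (n > 0 && !all(is.finite(object@data))) msg <- c(msg, "epoch data contains NaN/Inf")
  }
  if (!object@condition %in% c("REST", "SQT")) msg <- c(msg, "bad condition")
  if (length(msg)) msg else TRUE
})

#' Subject-wise train/test split with cross-validation folds
#'
#' @slot trainSubjects,testSubjects disjoint character vectors of subject ids.
#' @slot folds named integer vector (names = train subjects, values 1..nFolds).
#' @slot seed integer seed the plan was drawn with.
#' @export
setClass("SplitPlan",
  representation(trainSubjects = "character", testSubjects = "character",
    folds = "integer", seed = "integer"))

setValidity("SplitPlan", function(object) {
  msg <- character()
  if (length(intersect(object@trainSubjects, object@testSubjects)))
    msg <- c(msg, "train and test subject sets must be disjoint")
  if (!setequal(names(object@folds), object@trainSubjects))
    msg <- c(msg, "folds must cover exactly the train subjects")
  if (length(msg)) msg else TRUE
})

#' Training hyperparameters
#'
#' Adam optimisation with class-weighted cross-entropy, early stopping on
#' validation loss with best-weight restoration, and an optional
#' reduce-on-plateau learning-rate schedule.
#'
#' @slot learningRate initial Adam learning rate.
#' @slot batchSize minibatch size.
#' @slot maxEpochs maximum number of epochs.
#' @slot patience early-stopping patience (epochs without validation-loss
#'   improvement).
#' @slot minDelta minimum improvement counted as progress.
#' @slot classWeights named numeric per-class loss weights (empty = computed
#'   from the training labels with the balanced scheme).
#' @slot plateauFactor,plateauPatience learning-rate decay factor and patience
#'   (factor 1 disables the schedule).
#' @slot clipNorm global gradient-norm clipping threshold (Inf disables).
#' @slot seed integer seed for shuffling, initialisation and dropout.
#' @export
setClass("TrainSpec",
  representation(learningRate = "numeric", batchSize = "integer",
    maxEpochs = "integer", patience = "integer", minDelta = "numeric",
    classWeights = "numeric", plateauFactor = "numeric",
    plateauPatience = "integer", clipNorm = "numeric", seed = "integer"))

setValidity("TrainSpec", function(object) {
  msg <- character()
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be positive")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@maxEpochs < 1L) msg <- c(msg, "maxEpochs must be >= 1")
  if (object@patience >= object@maxEpochs)
    msg <- c(msg, "patience must be smaller than maxEpochs")
  if (length(msg)) msg else TRUE
})

#' Fitted (or freshly initialised) classifier
#'
#' @slot architecture one of \code{"attention_lstm"}, \code{"conformer"},
#'   \code{"pca_svm"}.
#' @slot config architecture hyperparameters.
#' @slot params named list of numeric parameter matrices (deep models) .
#' @slot classes class label ordering used by \code{predictProba}.
#' @slot history data.frame of per-epoch training/validation losses.
#' @slot extra architecture-specific fitted state (e.g. PCA rotation and the
#'   SVM object for the shallow baseline).
#' @export
setClass("TrainedModel",
  representation(architecture = "character", config = "list", params = "list",
    classes = "character", history = "data.frame", extra = "list"))

#' Evaluation results for one task/model/condition
#'
#' @slot task classification task label (e.g. "SCD-vs-MCI").
#' @slot condition EEG condition evaluated.
#' @slot model architecture tag.
#' @slot confusion true x predicted trial-count matrix.
#' @slot metrics named numeric: accuracy and class-support-weighted
#'   precision, recall, F1.
#' @slot auc named per-class one-vs-rest AUC.
#' @slot roc per-class ROC curve points (list of data.frames).
#' @slot votes participant-level vote table.
#' @slot meta seeds, config and bookkeeping.
#' @export
setClass("EvaluationReport",
  representation(task = "character", condition = "character",
    model = "character", confusion = "matrix", metrics = "numeric",
    auc = "numeric", roc = "list", votes = "data.frame", meta = "list"))

setValidity("EvaluationReport", function(object) {
  msg <- character()
  if (length(object@metrics) &&
      any(object@metrics < -1e-9 | object@metrics > 1 + 1e-9))
    msg <- c(msg, "metrics must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
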