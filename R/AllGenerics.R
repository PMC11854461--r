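#' Class probabilities for new epochs
#'
#' @param model a \linkS4class{TrainedModel}.
#' @param epochs an \linkS4class{EpochSet}.
#' @param ... passed to methods.
#' @return numeric matrix, one row per trial, one column per class; rows sum
#'   to 1.
#' @export
setGeneric("predictProba", function(model, epochs, ...) standardGeneric("predictProba"))

#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))
#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))
#' @rdname accessors
#' @export
setGeneric("epochArray", function(x) standardGeneric("epochArray"))
#' @rdname accessors
#' @export
setGeneric("epochLabels", function(x) standardGeneric("epochLabels"))
#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' Accessors for adspectrum objects
#'
#' Small accessor family: trial counts, channel names, sampling rates, signal
#' and epoch payloads, labels and events.
#'
#' @param x a \linkS4class{RawRecording} or \linkS4class{EpochSet}.
#' @name accessors
#' @return the corresponding slot content.
NULL

#' @rdname accessors
setMethod("nTrials", "EpochSet", function(x) dim(x@data)[3L])
#' @rdname accessors
setMethod("channelNames", "RawRecording", function(x) x@channels)
#' @rdname accessors
setMethod("channelNames", "EpochSet", function(x) x@channels)
#' @rdname accessors
setMethod("samplingRate", "RawRecording", function(x) x@samplingRate)
#' @rdname accessors
setMethod("samplingRate", "EpochSet", function(x) x@samplingRate)
#' @rdname accessors
setMethod("eventTable", "RawRecording", function(x) x@events)
#' @rdname accessors
setMethod("signalMatrix", "RawRecording", function(x) x@signal)
#' @rdname accessors
setMethod("epochArray", "EpochSet", function(x) x@data)
#' @rdname accessors
setMethod("epochLabels", "EpochSet", function(x) x@labels)
#' @rdname accessors
setMethod("subjectIds", "EpochSet", function(x) x@subjectIds)

setMethod("show", "SQTProtocol", function(object) {
  cat("SQTProtocol:", nrow(object@questions), "questions,",
      "response window", object@responseWindowMs, "ms\n")
  cat("  listening times", paste(range(object@questions$listening_time_ms),
      collapse = "-"), "ms\n")
})

setMethod("show", "RawRecording", function(object) {
  cat(sprintf("RawRecording %s [%s]: %d ch x %d samples @ %g Hz (%.1f s), %d events\n",
    object@subjectId, object@condition, nrow(object@signal),
    ncol(object@signal), object@samplingRate,
    ncol(object@signal) / object@samplingRate, nrow(object@events)))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet [%s]: %d trials of %d samples x %d channels @ %g Hz\n",
    object@condition, d[3L], d[1L], d[2L], object@samplingRate))
  if (d[3L]) {
    tab <- table(object@labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        sprintf(" (%d subjects, %d augmented)\n",
                length(unique(object@subjectIds)), sum(object@augmented)))
  }
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan: %d train / %d test subjects, %d folds (seed %d)\n",
    length(object@trainSubjects), length(object@testSubjects),
    length(unique(object@folds)), object@seed))
})

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel <%s>: classes [%s], %d training epochs recorded\n",
    object@architecture, paste(object@classes, collapse = ", "),
    nrow(object@history)))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport %s / %s / %s\n", object@task, object@condition,
              object@model))
  cat(sprintf("  accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f\n",
    object@metrics["accuracy"], object@metrics["precision"],
    object@metrics["recall"], object@metrics["f1"]))
  if (length(object@auc))
    cat("  AUC:", paste(sprintf("%s=%.3f", names(object@auc), object@auc),
        collapse = ", "), "\n")
})
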