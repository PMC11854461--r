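#' Epoch a task recording around question offsets
#'
#' Cuts, for every question trial, the 1.5 s window immediately preceding
#' the question audio offset: with 0-based event indexing the half-open
#' window \code{[offset - 1.5 s, offset)}, i.e. exactly
#' \code{round(1.5 * fs)} samples per channel (768 at the 512 Hz analysis
#' rate). Trials are epoched regardless of behavioral correctness.
#'
#' @param rec a preprocessed \code{SQT} \linkS4class{RawRecording}.
#' @param label group label attached to every trial (NA when unknown).
#' @param strict error unless exactly 10 usable trials result (the analysis
#'   assumes 10); with \code{strict = FALSE} trials without enough preceding
#'   signal are dropped with a warning.
#' @return an \linkS4class{EpochSet} with one epoch per usable trial.
#' @export
epochSQT <- function(rec, label = NA_character_, strict = TRUE) {
  if (rec@condition != "SQT") stop("epochSQT needs an SQT recording")
  fs <- rec@samplingRate
  win <- round(1.5 * fs)
  ev <- rec@events
  off <- ev[ev$type == "question_offset", ]
  off <- off[order(off$trial), ]
  usable <- off$sample_index >= win
  if (any(!usable))
    warning("rejected trial(s) ", paste(off$trial[!usable], collapse = ", "),
            ": fewer than ", win, " samples precede the question offset")
  if (strict && sum(usable) != 10L)
    stop("expected 10 usable trials, got ", sum(usable))
  off <- off[usable, , drop = FALSE]
  dat <- array(0, c(win, length(rec@channels), nrow(off)))
  for (i in seq_len(nrow(off))) {
    o <- off$sample_index[i]                 # 0-based offset sample
    dat[, , i] <- t(rec@signal[, (o - win + 1L):o, drop = FALSE])
  }
  newEpochSet(dat, rec, label, off$trial, "SQT")
}

#' Epoch a resting recording into 10 fixed segments
#'
#' Takes the central 15 s of the recording and cuts it into 10 contiguous,
#' non-overlapping 1.5 s epochs, matching the task trial count.
#'
#' @param rec a preprocessed \code{REST} \linkS4class{RawRecording}.
#' @param label group label attached to every trial.
#' @return an \linkS4class{EpochSet} with 10 epochs.
#' @export
epochRest <- function(rec, label = NA_character_) {
  if (rec@condition != "REST") stop("epochRest needs a REST recording")
  fs <- rec@samplingRate
  win <- round(1.5 * fs)
  need <- 10L * win
  n <- ncol(rec@signal)
  if (n < need)
    stop("recording too short: need at least 15 s, have ",
         sprintf("%.1f", n / fs), " s")
  start0 <- (n - need) %/% 2L              # 0-based start of the centre block
  dat <- array(0, c(win, length(rec@channels), 10L))
  for (i in 1:10) {
    s <- start0 + (i - 1L) * win
    dat[, , i] <- t(rec@signal[, (s + 1L):(s + win), drop = FALSE])
  }
  newEpochSet(dat, rec, label, 1:10, "REST")
}

newEpochSet <- function(dat, rec, label, trialIdx, condition) {
  n <- dim(dat)[3L]
  new("EpochSet", data = dat,
      labels = factor(rep(as.character(label), n), levels = GROUPS),
      subjectIds = rep(rec@subjectId, n),
      trialIndex = as.integer(trialIdx), condition = condition,
      channels = rec@channels, samplingRate = rec@samplingRate,
      augmented = rep(FALSE, n))
}

#' Combine epoch sets
#'
#' Concatenates trials from several \linkS4class{EpochSet}s with identical
#' geometry (samples, channels, rate, condition).
#'
#' @param ... \linkS4class{EpochSet} objects, or a single list of them.
#' @return the combined \linkS4class{EpochSet}.
#' @export
bindEpochs <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) && !is(sets[[1L]], "EpochSet"))
    sets <- sets[[1L]]
  stopifnot(length(sets) >= 1L)
  ref <- sets[[1L]]
  for (s in sets[-1L]) {
    stopifnot(identical(dim(s@data)[1:2], dim(ref@data)[1:2]),
              identical(s@channels, ref@channels),
              s@condition == ref@condition,
              s@samplingRate == ref@samplingRate)
  }
  dat <- array(0, c(dim(ref@data)[1:2], sum(vapply(sets, nTrials, 1L))))
  k <- 0L
  for (s in sets) {
    ns <- nTrials(s)
    if (ns) dat[, , (k + 1L):(k + ns)] <- s@data
    k <- k + ns
  }
  new("EpochSet", data = dat,
      labels = factor(unlist(lapply(sets, function(s) as.character(s@labels))),
                      levels = GROUPS),
      subjectIds = unlist(lapply(sets, slot, "subjectIds")),
      trialIndex = unlist(lapply(sets, slot, "trialIndex")),
      condition = ref@condition, channels = ref@channels,
      samplingRate = ref@samplingRate,
      augmented = unlist(lapply(sets, slot, "augmented")))
}

#' Subset an EpochSet by trial index
#'
#' @param x an \linkS4class{EpochSet}.
#' @param i integer or logical trial selector.
#' @return the subsetted \linkS4class{EpochSet}.
#' @export
subsetEpochs <- function(x, i) {
  if (is.logical(i)) i <- which(i)
  new("EpochSet", data = x@data[, , i, drop = FALSE],
      labels = factor(as.character(x@labels)[i], levels = levels(x@labels)),
      subjectIds = x@subjectIds[i], trialIndex = x@trialIndex[i],
      condition = x@condition, channels = x@channels,
      samplingRate = x@samplingRate, augmented = x@augmented[i])
}
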