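#' EEG preprocessing primitives
#'
#' The preprocessing chain follows a fixed order: downsample, band-pass,
#' notch, average reference, ICA artifact removal, channel selection,
#' epoching. All filters are applied forward-backward (zero phase) so epoch
#' timing is preserved.
#'
#' @name preprocessing
NULL

#' Downsample a recording by an integer factor
#'
#' Anti-alias filtered decimation: a zero-phase Butterworth low-pass at 80\%
#' of the target Nyquist frequency (maximally flat pass band, so in-band
#' tones keep their power), then every q-th sample. Event sample indices are
#' rescaled and rounded.
#'
#' @param rec a \linkS4class{RawRecording}.
#' @param targetRate target rate in Hz; must divide the current rate.
#' @return the downsampled recording.
#' @export
downsampleRecording <- function(rec, targetRate = 512) {
  fs <- rec@samplingRate
  if (targetRate > fs) stop("target rate exceeds the recording rate")
  if (targetRate == fs) return(rec)
  q <- fs / targetRate
  if (abs(q - round(q)) > 1e-9)
    stop("downsampling requires an integer decimation factor")
  q <- as.integer(round(q))
  aa <- signal::butter(4, 0.8 / q, type = "low")
  out <- t(apply(rec@signal, 1, function(x)
    signal::filtfilt(aa, x)[seq(1, length(x), by = q)]))
  ev <- rec@events
  if (nrow(ev)) {
    ev$sample_index <- pmin(ncol(out) - 1L, as.integer(round(ev$sample_index / q)))
  }
  initialize(rec, signal = out, samplingRate = targetRate, events = ev)
}

#' Band-pass filter a recording
#'
#' Fourth-order Butterworth band-pass, zero-phase (filtfilt).
#'
#' @param rec a \linkS4class{RawRecording}.
#' @param low,high cutoff frequencies in Hz.
#' @return the filtered recording.
#' @export
bandpassFilter <- function(rec, low = 2, high = 100) {
  fs <- rec@samplingRate
  ny <- fs / 2
  if (low <= 0 || high <= low) stop("need 0 < low < high")
  if (high >= ny) stop("high cutoff must be below the Nyquist frequency")
  bf <- signal::butter(2, c(low, high) / ny, type = "pass")
  rec@signal <- t(apply(rec@signal, 1, function(x)
    signal::filtfilt(bf, x)))
  rec
}

#' Notch filter a recording
#'
#' Second-order IIR notch (biquad, Q = 30 by default) centred on the line
#' frequency, zero-phase.
#'
#' @param rec a \linkS4class{RawRecording}.
#' @param freq notch centre frequency in Hz (default 60).
#' @param Q notch quality factor.
#' @return the filtered recording.
#' @export
notchFilter <- function(rec, freq = 60, Q = 30) {
  fs <- rec@samplingRate
  if (freq >= fs / 2) stop("notch frequency must be below the Nyquist frequency")
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  flt <- signal::Arma(b = b, a = a)
  rec@signal <- t(apply(rec@signal, 1, function(x) signal::filtfilt(flt, x)))
  rec
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean over channels from every channel, so the
#' channel mean is zero at every sample.
#'
#' @param rec a \linkS4class{RawRecording}.
#' @return the re-referenced recording.
#' @export
rereferenceAverage <- function(rec) {
  if (nrow(rec@signal) < 2) stop("average reference needs at least 2 channels")
  rec@signal <- sweep(rec@signal, 2, colMeans(rec@signal), "-")
  rec
}

#' Restrict a recording to the canonical montage
#'
#' @param rec a \linkS4class{RawRecording}.
#' @param montage ordered channel names to keep (default the canonical
#'   19-channel montage).
#' @return the recording with exactly the requested channels, in order.
#' @export
selectChannels <- function(rec, montage = montage19()) {
  miss <- setdiff(montage, rec@channels)
  if (length(miss))
    stop("missing channel ", paste(miss, collapse = ", "))
  idx <- match(montage, rec@channels)
  initialize(rec, signal = rec@signal[idx, , drop = FALSE], channels = montage)
}

#' Run the full preprocessing chain on a recording
#'
#' Downsample to the analysis rate, band-pass 2-100 Hz, 60 Hz notch, average
#' reference, optional ICA artifact removal, channel selection — in that
#' fixed order.
#'
#' @param rec a \linkS4class{RawRecording}.
#' @param targetRate analysis sampling rate (Hz).
#' @param low,high band-pass cutoffs (Hz).
#' @param notch notch frequency (Hz), \code{NA} to skip.
#' @param ica logical, run ICA-based artifact removal.
#' @param montage channel subset to keep (\code{NULL} to keep all).
#' @param icaSeed seed for the ICA initialisation.
#' @return the preprocessed recording.
#' @export
preprocessRecording <- function(rec, targetRate = 512, low = 2, high = 100,
                                notch = 60, ica = FALSE,
                                montage = montage19(), icaSeed = 1) {
  rec <- downsampleRecording(rec, targetRate)
  rec <- bandpassFilter(rec, low, high)
  if (!is.na(notch)) rec <- notchFilter(rec, notch)
  rec <- rereferenceAverage(rec)
  if (isTRUE(ica)) rec <- removeArtifactComponents(rec, seed = icaSeed)
  if (!is.null(montage)) rec <- selectChannels(rec, montage)
  rec
}
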