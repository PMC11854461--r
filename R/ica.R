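#' ICA-based artifact removal
#'
#' Decomposes the (filtered, referenced) recording into independent
#' components with a symmetric fixed-point ICA (tanh contrast) on the
#' PCA-whitened signal, automatically flags artifact components, and
#' reconstructs the recording without them. Two automatic flags are applied:
#' components whose time course correlates with the frontal blink template
#' (the low-passed Fp1/Fp2 average) at \code{|r| >=} \code{blinkThreshold},
#' and components whose spectrum is line-noise dominated (more than
#' \code{lineFraction} of total power inside 58-62 Hz). Whitening drops
#' directions with negligible variance, so the average-referenced (rank
#' deficient) signal is handled; a recording with fewer than two informative
#' directions is rejected with a diagnostic suggesting a channel check.
#'
#' @param rec a \linkS4class{RawRecording}.
#' @param blinkThreshold absolute correlation with the blink template above
#'   which a component is flagged.
#' @param lineFraction fraction of component power inside 58-62 Hz above
#'   which it is flagged as line noise.
#' @param maxIter,tol fixed-point iteration budget and convergence tolerance.
#' @param seed seed for the random orthogonal initialisation.
#' @return the cleaned recording; \code{rec@misc$ica} records the number of
#'   components, flagged indices and convergence info.
#' @export
removeArtifactComponents <- function(rec, blinkThreshold = 0.8,
                                     lineFraction = 0.5, maxIter = 200,
                                     tol = 1e-4, seed = 1) {
  X <- rec@signal
  nch <- nrow(X)
  n <- ncol(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  cv <- tcrossprod(Xc) / n
  eg <- eigen(cv, symmetric = TRUE)
  keepDim <- which(eg$values > max(eg$values) * 1e-9 & eg$values > 0)
  if (length(keepDim) < 2)
    stop("ICA decomposition failed: signal rank < 2; check for flat or ",
         "duplicated channels")
  E <- eg$vectors[, keepDim, drop = FALSE]
  d <- eg$values[keepDim]
  Z <- crossprod(E, Xc) / sqrt(d)        # whitened, ncomp x n
  ncomp <- length(keepDim)

  W <- withSeed(childSeed(seed, "ica"), {
    w0 <- matrix(rnorm(ncomp * ncomp), ncomp)
    symDecorrelate(w0)
  })
  iter <- 0L; delta <- Inf
  while (iter < maxIter && delta > tol) {
    iter <- iter + 1L
    WZ <- W %*% Z
    G <- tanh(WZ)
    Wnew <- G %*% t(Z) / n - diag(rowMeans(1 - G^2)) %*% W
    Wnew <- symDecorrelate(Wnew)
    delta <- max(abs(abs(rowSums(Wnew * W)) - 1))
    W <- Wnew
  }
  S <- W %*% Z                            # sources, ncomp x n
  A <- E %*% (sqrt(d) * t(W))             # mixing, nch x ncomp

  tmpl <- blinkTemplate(rec)
  blinkR <- if (is.null(tmpl)) rep(0, ncomp) else
    abs(apply(S, 1, function(s) suppressWarnings(cor(s, tmpl))))
  blinkR[is.na(blinkR)] <- 0
  lineF <- apply(S, 1, function(s) linePowerFraction(s, rec@samplingRate))
  flagged <- which(blinkR >= blinkThreshold | lineF > lineFraction)

  keep <- setdiff(seq_len(ncomp), flagged)
  rec@signal <- A[, keep, drop = FALSE] %*% S[keep, , drop = FALSE] + mu
  rec@misc$ica <- list(n_components = ncomp, flagged = flagged,
                       blink_correlation = blinkR, line_fraction = lineF,
                       iterations = iter, converged = delta <= tol)
  rec
}

symDecorrelate <- function(W) {
  s <- svd(W)
  s$u %*% t(s$v)
}

# low-passed frontal average; NULL when no frontal channel is present
blinkTemplate <- function(rec) {
  fr <- intersect(c("Fp1", "Fp2", "Fpz"), rec@channels)
  if (!length(fr)) return(NULL)
  x <- colMeans(rec@signal[match(fr, rec@channels), , drop = FALSE])
  lp <- signal::butter(2, min(5 / (rec@samplingRate / 2), 0.9), type = "low")
  as.numeric(signal::filtfilt(lp, x))
}

linePowerFraction <- function(x, fs, centre = 60, half = 2) {
  n <- length(x)
  p <- Mod(fft(x))^2
  f <- (0:(n - 1)) * fs / n
  sel <- f <= fs / 2
  inBand <- sel & f >= centre - half & f <= centre + half
  sum(p[inBand]) / max(sum(p[sel & f > 0]), .Machine$double.eps)
}
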