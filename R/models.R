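#' Additive temporal attention
#'
#' Scores every time step of a hidden-state sequence through a small tanh
#' projection (\code{e_t = v . tanh(W h_t + b)}), normalises the scores with
#' a softmax into attention weights, and collapses the sequence into a
#' context vector \code{sum_t alpha_t h_t}. This is the attention head used
#' on top of the second LSTM layer; exposed standalone for inspection and
#' testing.
#'
#' @param hiddenSeq numeric matrix, time steps x hidden dimension.
#' @param attentionUnits width of the scoring projection.
#' @param weights optional list with entries \code{W} (d x units), \code{b}
#'   (units), \code{v} (units); random Glorot draws (seeded) when NULL.
#' @param seed seed used when \code{weights} is NULL.
#' @return list with \code{context} (length-d vector), \code{weights}
#'   (length-T softmax vector) and the \code{params} used.
#' @export
temporalAttention <- function(hiddenSeq, attentionUnits = 10, weights = NULL,
                              seed = 1) {
  hiddenSeq <- as.matrix(hiddenSeq)
  if (nrow(hiddenSeq) < 1L) stop("hidden sequence must have at least one step")
  d <- ncol(hiddenSeq)
  if (is.null(weights)) {
    weights <- withSeed(seed, list(
      W = glorot(d, attentionUnits),
      b = rep(0, attentionUnits),
      v = as.numeric(glorot(attentionUnits, 1))))
  }
  scores <- tanh(sweep(hiddenSeq %*% weights$W, 2, weights$b, "+")) %*% weights$v
  e <- as.numeric(scores)
  alpha <- exp(e - max(e))
  alpha <- alpha / sum(alpha)
  list(context = as.numeric(crossprod(hiddenSeq, alpha)), weights = alpha,
       params = weights)
}

glorot <- function(fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(runif(fanIn * fanOut, -lim, lim), fanIn, fanOut)
}

orthogonalInit <- function(n) {
  qr.Q(qr(matrix(rnorm(n * n), n)))
}

#' Build an (untrained) attention-LSTM classifier
#'
#' Two stacked LSTM layers returning full sequences (128 then 64 units),
#' each followed by dropout (rates 0.9 and 0.8), an additive temporal
#' attention head with a 10-unit scoring projection, and a dense softmax
#' output. Inputs are 1.5 s epochs (768 samples x 19 channels by default),
#' standardised per trial and channel before entering the network.
#'
#' @param classes character vector of class labels (2 or 3).
#' @param nChannels,nSamples input geometry.
#' @param lstm1,lstm2 LSTM layer widths.
#' @param dropout1,dropout2 dropout rates applied to each LSTM output
#'   sequence.
#' @param attentionUnits scoring projection width.
#' @param seed initialisation seed.
#' @return a \linkS4class{TrainedModel} with freshly initialised parameters.
#' @export
attentionLSTM <- function(classes, nChannels = 19, nSamples = 768,
                          lstm1 = 128, lstm2 = 64, dropout1 = 0.9,
                          dropout2 = 0.8, attentionUnits = 10, seed = 1) {
  stopifnot(length(classes) >= 2, dropout1 >= 0, dropout1 < 1,
            dropout2 >= 0, dropout2 < 1, lstm1 > 0, lstm2 > 0,
            attentionUnits > 0)
  K <- length(classes)
  params <- withSeed(childSeed(seed, "attlstm-init"), {
    list(
      W1 = glorot(nChannels, 4 * lstm1),
      U1 = do.call(cbind, replicate(4, orthogonalInit(lstm1), simplify = FALSE)),
      b1 = c(rep(0, lstm1), rep(1, lstm1), rep(0, 2 * lstm1)),  # forget bias 1
      W2 = glorot(lstm1, 4 * lstm2),
      U2 = do.call(cbind, replicate(4, orthogonalInit(lstm2), simplify = FALSE)),
      b2 = c(rep(0, lstm2), rep(1, lstm2), rep(0, 2 * lstm2)),
      Wa = glorot(lstm2, attentionUnits),
      ba = rep(0, attentionUnits),
      va = as.numeric(glorot(attentionUnits, 1)),
      Wd = glorot(lstm2, K),
      bd = rep(0, K))
  })
  new("TrainedModel", architecture = "attention_lstm",
      config = list(nChannels = nChannels, nSamples = nSamples,
                    keep1 = 1 - dropout1, keep2 = 1 - dropout2,
                    standardize = TRUE, batchDefault = 64L),
      params = params, classes = as.character(classes),
      history = emptyHistory(), extra = list())
}

#' Build an (untrained) convolution-transformer classifier
#'
#' Stage 1 applies a factorized spatio-temporal convolution: shared temporal
#' kernels along time followed by spatial filters spanning all channels,
#' then ELU, average pooling along time (length 75, stride 15) into a token
#' sequence, dropout, and a linear projection to the embedding. Stage 2 is a
#' stack of pre-norm multi-head self-attention blocks with residual
#' connections and feed-forward sublayers. Stage 3 flattens the tokens
#' through a small dense stack to a softmax output.
#'
#' @param classes character vector of class labels.
#' @param nChannels,nSamples input geometry.
#' @param kernel temporal kernel length (samples).
#' @param nFilters number of convolutional filters.
#' @param poolLen,poolStride average-pooling window and stride (samples).
#' @param embedDim token embedding width (divisible by \code{nHeads}).
#' @param nBlocks,nHeads transformer depth and head count.
#' @param ffDim feed-forward sublayer width.
#' @param fc1,fc2 dense head widths.
#' @param dropoutPool,dropoutFc1,dropoutFc2 dropout rates.
#' @param seed initialisation seed.
#' @return a \linkS4class{TrainedModel}.
#' @export
eegConformer <- function(classes, nChannels = 19, nSamples = 768,
                         kernel = 25, nFilters = 40, poolLen = 75,
                         poolStride = 15, embedDim = 40, nBlocks = 6,
                         nHeads = 10, ffDim = 160, fc1 = 256, fc2 = 32,
                         dropoutPool = 0.5, dropoutFc1 = 0.5,
                         dropoutFc2 = 0.3, seed = 1) {
  stopifnot(length(classes) >= 2)
  if (embedDim %% nHeads != 0)
    stop("embedDim (", embedDim, ") must be divisible by nHeads (", nHeads, ")")
  nTokens <- floor((nSamples - poolLen) / poolStride) + 1
  if (nTokens < 1)
    stop("pooled token count < 1: nSamples=", nSamples, ", poolLen=", poolLen,
         ", poolStride=", poolStride)
  K <- length(classes)
  params <- withSeed(childSeed(seed, "conformer-init"), {
    p <- list(
      Wt = glorot(nFilters, kernel) , # stored F x KT
      Wsp = glorot(nFilters, nFilters * nChannels),
      bsp = rep(0, nFilters),
      Wproj = glorot(nFilters, embedDim),
      bproj = rep(0, embedDim))
    for (l in seq_len(nBlocks)) {
      pre <- sprintf("b%d_", l)
      p[[paste0(pre, "ln1g")]] <- rep(1, embedDim)
      p[[paste0(pre, "ln1b")]] <- rep(0, embedDim)
      p[[paste0(pre, "Wq")]] <- glorot(embedDim, embedDim)
      p[[paste0(pre, "bq")]] <- rep(0, embedDim)
      p[[paste0(pre, "Wk")]] <- glorot(embedDim, embedDim)
      p[[paste0(pre, "bk")]] <- rep(0, embedDim)
      p[[paste0(pre, "Wv")]] <- glorot(embedDim, embedDim)
      p[[paste0(pre, "bv")]] <- rep(0, embedDim)
      p[[paste0(pre, "Wo")]] <- glorot(embedDim, embedDim)
      p[[paste0(pre, "bo")]] <- rep(0, embedDim)
      p[[paste0(pre, "ln2g")]] <- rep(1, embedDim)
      p[[paste0(pre, "ln2b")]] <- rep(0, embedDim)
      p[[paste0(pre, "Wf1")]] <- glorot(embedDim, ffDim)
      p[[paste0(pre, "bf1")]] <- rep(0, ffDim)
      p[[paste0(pre, "Wf2")]] <- glorot(ffDim, embedDim)
      p[[paste0(pre, "bf2")]] <- rep(0, embedDim)
    }
    p$Wh1 <- glorot(nTokens * embedDim, fc1)
    p$bh1 <- rep(0, fc1)
    p$Wh2 <- glorot(fc1, fc2)
    p$bh2 <- rep(0, fc2)
    p$Wh3 <- glorot(fc2, K)
    p$bh3 <- rep(0, K)
    p
  })
  new("TrainedModel", architecture = "conformer",
      config = list(nChannels = nChannels, nSamples = nSamples,
                    poolLen = as.integer(poolLen),
                    poolStride = as.integer(poolStride),
                    nHeads = as.integer(nHeads),
                    nBlocks = as.integer(nBlocks), nTokens = nTokens,
                    keepPool = 1 - dropoutPool, keepFc1 = 1 - dropoutFc1,
                    keepFc2 = 1 - dropoutFc2,
                    standardize = TRUE, batchDefault = 100L),
      params = params, classes = as.character(classes),
      history = emptyHistory(), extra = list())
}

emptyHistory <- function() {
  data.frame(epoch = integer(), train_loss = numeric(), val_loss = numeric(),
             val_accuracy = numeric(), lr = numeric())
}

# per-trial, per-channel z-scoring; constant channels are left centred
standardizeEpochs <- function(x) {
  for (i in seq_len(dim(x)[3L])) {
    m <- colMeans(x[, , i])
    s <- sqrt(colMeans(sweep(x[, , i], 2, m, "-")^2))
    s[s < 1e-12] <- 1
    x[, , i] <- sweep(sweep(x[, , i], 2, m, "-"), 2, s, "/")
  }
  x
}

modelInput <- function(model, epochs) {
  x <- epochs@data
  d <- dim(x)
  if (d[1] != model@config$nSamples || d[2] != model@config$nChannels)
    stop("epoch geometry ", d[1], "x", d[2], " does not match the model (",
         model@config$nSamples, "x", model@config$nChannels, ")")
  if (isTRUE(model@config$standardize)) x <- standardizeEpochs(x)
  x
}

deepForward <- function(model, x, y = integer(0), w = numeric(0),
                        training = FALSE, wantGrad = FALSE,
                        wantAttention = FALSE) {
  cfg <- model@config
  if (model@architecture == "attention_lstm") {
    attlstm_run(x, model@params, as.integer(y), as.numeric(w), training,
                cfg$keep1, cfg$keep2, wantGrad, wantAttention)
  } else {
    conformer_run(x, model@params, as.integer(y), as.numeric(w), training,
                  wantGrad, cfg$poolLen, cfg$poolStride, cfg$nHeads,
                  cfg$nBlocks, cfg$keepPool, cfg$keepFc1, cfg$keepFc2)
  }
}

#' @describeIn predictProba deep sequence models (inference mode: dropout
#'   disabled, deterministic).
setMethod("predictProba", "TrainedModel", function(model, epochs,
                                                   chunk = 64L, ...) {
  if (model@architecture == "pca_svm") return(svmPredictProba(model, epochs))
  x <- modelInput(model, epochs)
  n <- dim(x)[3L]
  out <- matrix(0, n, length(model@classes),
                dimnames = list(NULL, model@classes))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    fw <- deepForward(model, x[, , s:e, drop = FALSE])
    out[s:e, ] <- fw$probs
  }
  out
})

#' Per-time-step attention weights for epochs
#'
#' @param model a trained attention-LSTM \linkS4class{TrainedModel}.
#' @param epochs an \linkS4class{EpochSet}.
#' @return matrix trials x time steps; rows sum to 1.
#' @export
attentionWeights <- function(model, epochs) {
  stopifnot(model@architecture == "attention_lstm")
  x <- modelInput(model, epochs)
  n <- dim(x)[3L]
  out <- matrix(0, n, dim(x)[1L])
  for (s in seq(1L, n, by = 64L)) {
    e <- min(n, s + 63L)
    fw <- deepForward(model, x[, , s:e, drop = FALSE], wantAttention = TRUE)
    out[s:e, ] <- fw$attention
  }
  out
}

#' Segmentation-and-recombination data augmentation
#'
#' Creates \code{floor(fraction * nTrials)} synthetic training trials. Each
#' new trial of class c is assembled by cutting the time axis into
#' \code{nSegments} equal segments and drawing, for every segment position,
#' that segment from a randomly chosen class-c source trial. Augmented
#' trials are flagged so the training harness can keep them out of
#' validation and test sets.
#'
#' @param train an \linkS4class{EpochSet} of training trials.
#' @param fraction proportion of synthetic trials to add (default 0.2).
#' @param nSegments number of time segments.
#' @param seed integer seed.
#' @return the input set with augmented trials appended.
#' @export
augmentRecombine <- function(train, fraction = 0.2, nSegments = 8, seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1, nSegments >= 1)
  n <- nTrials(train)
  if (n == 0L) stop("empty training set")
  nNew <- floor(fraction * n)
  if (nNew == 0L) return(train)
  withSeed(childSeed(seed, "augment"), {
    lab <- as.character(train@labels)
    counts <- table(lab)
    # per-class share proportional to class frequency, largest-remainder
    share <- nNew * as.numeric(counts) / n
    take <- floor(share)
    rem <- nNew - sum(take)
    if (rem > 0) {
      ord <- order(share - take, decreasing = TRUE)
      take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
    }
    names(take) <- names(counts)
    win <- dim(train@data)[1L]
    bounds <- round(seq(0, win, length.out = nSegments + 1))
    newDat <- list(); newLab <- character()
    for (cl in names(take)) {
      idx <- which(lab == cl)
      if (take[[cl]] > 0L && length(idx) < 2L) {
        warning("class ", cl, " has fewer than 2 trials; skipping augmentation")
        next
      }
      for (j in seq_len(take[[cl]])) {
        trial <- matrix(0, win, dim(train@data)[2L])
        for (s in seq_len(nSegments)) {
          src <- idx[sample.int(length(idx), 1L)]
          rows <- (bounds[s] + 1L):bounds[s + 1L]
          trial[rows, ] <- train@data[rows, , src]
        }
        newDat[[length(newDat) + 1L]] <- trial
        newLab <- c(newLab, cl)
      }
    }
    if (!length(newDat)) return(train)
    add <- array(0, c(win, dim(train@data)[2L], length(newDat)))
    for (i in seq_along(newDat)) add[, , i] <- newDat[[i]]
    aug <- new("EpochSet", data = add,
               labels = factor(newLab, levels = levels(train@labels)),
               subjectIds = sprintf("AUG_%s_%03d", newLab, seq_along(newLab)),
               trialIndex = rep(0L, length(newLab)),
               condition = train@condition, channels = train@channels,
               samplingRate = train@samplingRate,
               augmented = rep(TRUE, length(newLab)))
    bindEpochs(train, aug)
  })
}

#' Fit the PCA+SVM shallow baseline
#'
#' Flattens each trial to a vector, projects onto the smallest number of
#' principal components explaining at least \code{varianceRetained} of the
#' training variance (capped at the data rank), and fits a radial-basis SVM
#' (default regularisation, no class weighting) on the projected data.
#'
#' @param train an \linkS4class{EpochSet}.
#' @param varianceRetained cumulative explained-variance threshold.
#' @param seed seed for the SVM's internal probability calibration.
#' @return a \linkS4class{TrainedModel} with architecture \code{"pca_svm"};
#'   \code{extra$nComponents} records the retained dimensionality.
#' @export
fitBaseline <- function(train, varianceRetained = 0.95, seed = 1) {
  stopifnot(varianceRetained > 0, varianceRetained <= 1)
  n <- nTrials(train)
  if (n < 2L) stop("need at least 2 training trials")
  X <- flattenEpochs(train)
  y <- droplevels(train@labels)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-9)
  ncomp <- min(which(cumsum(evr) >= varianceRetained - 1e-12), rank)
  scores <- pc$x[, seq_len(ncomp), drop = FALSE]
  fit <- withSeed(childSeed(seed, "svm"), {
    e1071::svm(scores, y, kernel = "radial", probability = TRUE)
  })
  new("TrainedModel", architecture = "pca_svm",
      config = list(nChannels = dim(train@data)[2L],
                    nSamples = dim(train@data)[1L],
                    varianceRetained = varianceRetained),
      params = list(), classes = levels(y), history = emptyHistory(),
      extra = list(center = pc$center,
                   rotation = pc$rotation[, seq_len(ncomp), drop = FALSE],
                   nComponents = ncomp, svm = fit))
}

flattenEpochs <- function(epochs) {
  d <- dim(epochs@data)
  t(matrix(epochs@data, d[1L] * d[2L], d[3L]))
}

svmPredictProba <- function(model, epochs) {
  X <- flattenEpochs(epochs)
  sc <- sweep(X, 2, model@extra$center, "-") %*% model@extra$rotation
  pr <- predict(model@extra$svm, sc, probability = TRUE)
  pb <- attr(pr, "probabilities")
  pb[, model@classes, drop = FALSE]
}
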