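#' Subject-wise train/test split with cross-validation folds
#'
#' Per group, draws round-half-up(testFraction x nGroup) subjects (at least
#' one where the group is non-empty) into the test set, then partitions the
#' remaining subjects into \code{nFolds} subject-wise cross-validation
#' folds. Trials from one subject can therefore never appear on both sides
#' of any split.
#'
#' @param cohort data.frame with \code{subject_id} and \code{group} columns
#'   (a \code{\link{sampleCohort}} result, possibly task-subsetted).
#' @param testFraction per-group test proportion (default 0.2).
#' @param nFolds number of cross-validation folds over the training side.
#' @param seed integer seed.
#' @return a \linkS4class{SplitPlan}.
#' @export
subjectWiseSplit <- function(cohort, testFraction = 0.2, nFolds = 5, seed = 1) {
  stopifnot(testFraction > 0, testFraction < 1, nFolds >= 2)
  groups <- split(cohort$subject_id, cohort$group, drop = TRUE)
  withSeed(childSeed(seed, "split"), {
    testS <- character(); trainS <- character()
    for (g in names(groups)) {
      ids <- groups[[g]]
      nTest <- max(1L, floor(testFraction * length(ids) + 0.5))  # round half-up
      if (nTest >= length(ids))
        stop("group ", g, " too small for a ", testFraction, " test split")
      pick <- sample(ids, nTest)
      testS <- c(testS, pick)
      trainS <- c(trainS, setdiff(ids, pick))
    }
    shuffled <- sample(trainS)
    folds <- setNames(rep(seq_len(nFolds), length.out = length(shuffled)),
                      shuffled)
    new("SplitPlan", trainSubjects = sort(trainS), testSubjects = sort(testS),
        folds = folds[sort(trainS)], seed = as.integer(seed))
  })
}

#' Balanced class weights
#'
#' \code{w_c = N / (K n_c)} for K classes over N samples, the balanced
#' weighting scheme used against class imbalance.
#'
#' @param labels vector of class labels.
#' @return named numeric vector of weights.
#' @examples
#' computeClassWeights(c(rep("SCD", 40), rep("MCI", 60)))
#' @export
computeClassWeights <- function(labels) {
  labels <- as.character(labels)
  labels <- labels[!is.na(labels)]
  if (!length(labels)) stop("no labels supplied")
  tab <- table(labels)
  w <- length(labels) / (length(tab) * as.numeric(tab))
  setNames(w, names(tab))
}

#' Construct a training specification
#'
#' @param learningRate Adam learning rate (default 0.001).
#' @param batchSize minibatch size (64 for the attention-LSTM, 100 for the
#'   conformer).
#' @param maxEpochs epoch budget (default 1000).
#' @param patience early-stopping patience on validation loss (10).
#' @param minDelta minimum improvement counted as progress (0).
#' @param classWeights optional named per-class weights; computed from the
#'   training labels when empty.
#' @param plateauFactor learning-rate decay factor on validation plateau
#'   (1 = schedule off; the conformer uses 0.5).
#' @param plateauPatience epochs without improvement before decaying.
#' @param clipNorm global gradient-norm clipping threshold; gradients whose
#'   joint L2 norm exceeds it are rescaled (stabilises the transformer's
#'   early epochs). \code{Inf} disables clipping.
#' @param seed training seed (shuffling, dropout).
#' @return a \linkS4class{TrainSpec}.
#' @export
trainSpec <- function(learningRate = 0.001, batchSize = 64L,
                      maxEpochs = 1000L, patience = 10L, minDelta = 0,
                      classWeights = numeric(), plateauFactor = 1,
                      plateauPatience = 5L, clipNorm = 1, seed = 1L) {
  new("TrainSpec", learningRate = learningRate,
      batchSize = as.integer(batchSize), maxEpochs = as.integer(maxEpochs),
      patience = as.integer(patience), minDelta = minDelta,
      classWeights = classWeights, plateauFactor = plateauFactor,
      plateauPatience = as.integer(plateauPatience), clipNorm = clipNorm,
      seed = as.integer(seed))
}

#' Weighted categorical cross-entropy
#'
#' @param probs matrix of predicted class probabilities (columns named by
#'   class).
#' @param labels true labels.
#' @param classWeights optional named per-class weights (1 when missing).
#' @return mean (weighted) negative log-likelihood.
#' @export
crossEntropy <- function(probs, labels, classWeights = NULL) {
  labels <- as.character(labels)
  idx <- cbind(seq_along(labels), match(labels, colnames(probs)))
  if (anyNA(idx)) stop("labels outside the model's class set")
  w <- if (is.null(classWeights)) rep(1, length(labels)) else
    classWeights[labels]
  mean(w * -log(pmax(probs[idx], 1e-12)))
}

#' Train a deep model with early stopping
#'
#' Minimises class-weighted categorical cross-entropy with Adam. Training
#' stops when the validation loss has not improved by more than
#' \code{minDelta} for \code{patience} consecutive epochs (or at
#' \code{maxEpochs}), and the parameters of the best validation epoch are
#' restored. Validation loss is unweighted. Augmented trials may appear only
#' on the training side; the harness enforces subject disjointness.
#'
#' @param model an untrained deep \linkS4class{TrainedModel}.
#' @param trainEpochs,valEpochs subject-disjoint \linkS4class{EpochSet}s.
#' @param spec a \linkS4class{TrainSpec}.
#' @param verbose print per-epoch progress.
#' @return the trained \linkS4class{TrainedModel} with history filled in.
#' @export
trainModel <- function(model, trainEpochs, valEpochs, spec = trainSpec(),
                       verbose = FALSE) {
  stopifnot(is(model, "TrainedModel"),
            model@architecture %in% c("attention_lstm", "conformer"))
  realTrain <- trainEpochs@subjectIds[!trainEpochs@augmented]
  if (length(intersect(realTrain, valEpochs@subjectIds)))
    stop("training and validation subjects overlap")
  if (any(valEpochs@augmented))
    stop("augmented trials must not enter the validation set")

  classes <- model@classes
  yTr <- match(as.character(trainEpochs@labels), classes) - 1L
  if (anyNA(yTr)) stop("training labels outside the model's class set")
  cw <- spec@classWeights
  if (!length(cw)) cw <- computeClassWeights(trainEpochs@labels)
  cw <- cw[classes]
  cw[is.na(cw)] <- 1
  names(cw) <- classes
  wTr <- as.numeric(cw[yTr + 1L])

  xTr <- modelInput(model, trainEpochs)
  xVal <- modelInput(model, valEpochs)
  yValChr <- as.character(valEpochs@labels)

  params <- model@params
  numIdx <- which(vapply(params, is.numeric, TRUE))
  mSt <- vSt <- lapply(params[numIdx], function(p) p * 0)
  lr <- spec@learningRate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; adamT <- 0

  best <- list(loss = Inf, params = params, epoch = 0L)
  plateauWait <- 0L
  valLosses <- numeric()
  hist <- emptyHistory()
  n <- dim(xTr)[3L]

  withSeed(childSeed(spec@seed, "train", model@architecture), {
    for (epoch in seq_len(spec@maxEpochs)) {
      ord <- sample.int(n)
      epochLoss <- 0; nb <- 0
      for (s in seq(1L, n, by = spec@batchSize)) {
        take <- ord[s:min(n, s + spec@batchSize - 1L)]
        model@params <- params
        fw <- deepForward(model, xTr[, , take, drop = FALSE], yTr[take],
                          wTr[take], training = TRUE, wantGrad = TRUE)
        if (!is.finite(fw$loss))
          stop("training loss is not finite (diverged); lower the learning rate")
        epochLoss <- epochLoss + fw$loss; nb <- nb + 1
        adamT <- adamT + 1
        g <- fw$grads
        if (is.finite(spec@clipNorm)) {
          gn <- sqrt(sum(vapply(g, function(x) sum(x^2), numeric(1))))
          if (gn > spec@clipNorm)
            g <- lapply(g, function(x) x * (spec@clipNorm / gn))
        }
        for (k in names(mSt)) {
          mSt[[k]] <- beta1 * mSt[[k]] + (1 - beta1) * g[[k]]
          vSt[[k]] <- beta2 * vSt[[k]] + (1 - beta2) * g[[k]]^2
          mHat <- mSt[[k]] / (1 - beta1^adamT)
          vHat <- vSt[[k]] / (1 - beta2^adamT)
          params[[k]] <- params[[k]] - lr * mHat / (sqrt(vHat) + eps)
        }
      }
      model@params <- params
      valP <- predictChunks(model, xVal)
      colnames(valP) <- classes
      valLoss <- crossEntropy(valP, yValChr)
      valAcc <- mean(classes[max.col(valP)] == yValChr)
      if (!is.finite(valLoss)) stop("validation loss is NaN; aborting")
      hist <- rbind(hist, data.frame(epoch = epoch,
        train_loss = epochLoss / nb, val_loss = valLoss,
        val_accuracy = valAcc, lr = lr))
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f",
                        epoch, epochLoss / nb, valLoss, valAcc))
      valLosses <- c(valLosses, valLoss)
      es <- earlyStopState(valLosses, spec@patience, spec@minDelta)
      if (es$improved) {
        best <- list(loss = valLoss, params = params, epoch = epoch)
        plateauWait <- 0L
      } else {
        plateauWait <- plateauWait + 1L
        if (spec@plateauFactor < 1 && plateauWait >= spec@plateauPatience) {
          lr <- max(lr * spec@plateauFactor, 1e-5)
          plateauWait <- 0L
        }
      }
      if (es$stop) break
    }
  })
  model@params <- best$params
  model@history <- hist
  model@extra$bestEpoch <- best$epoch
  model@extra$stoppedEpoch <- nrow(hist)
  model@extra$classWeights <- cw
  model
}

predictChunks <- function(model, x, chunk = 64L) {
  n <- dim(x)[3L]
  out <- matrix(0, n, length(model@classes))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    out[s:e, ] <- deepForward(model, x[, , s:e, drop = FALSE])$probs
  }
  out
}

#' Pick the best cross-validation fold model
#'
#' Highest validation accuracy wins; ties break to the lower validation
#' loss.
#'
#' @param models list of fitted \linkS4class{TrainedModel}s.
#' @param valMetrics data.frame with columns \code{val_accuracy} and
#'   \code{val_loss}, one row per model.
#' @return the selected \linkS4class{TrainedModel}.
#' @export
selectBestFoldModel <- function(models, valMetrics) {
  if (!length(models)) stop("no fold models supplied")
  stopifnot(nrow(valMetrics) == length(models))
  ord <- order(-valMetrics$val_accuracy, valMetrics$val_loss)
  models[[ord[1L]]]
}

#' Subject-wise cross-validated training
#'
#' Trains one model per fold (validation = the held-out fold's subjects,
#' training = the rest), optionally augmenting the training side of each
#' fold, and returns all fold models with their validation metrics plus the
#' selected best model.
#'
#' @param builder zero-argument function returning a fresh untrained model.
#' @param epochs all training-side trials (no test subjects).
#' @param plan a \linkS4class{SplitPlan}.
#' @param spec a \linkS4class{TrainSpec}.
#' @param augmentFraction segmentation-recombination fraction applied to the
#'   training fold (0 disables).
#' @param nSegments augmentation segment count.
#' @param verbose print per-epoch progress.
#' @return list with \code{models}, \code{metrics} (data.frame) and
#'   \code{best}.
#' @export
crossValidate <- function(builder, epochs, plan, spec = trainSpec(),
                          augmentFraction = 0, nSegments = 8,
                          verbose = FALSE) {
  stopifnot(!length(intersect(epochs@subjectIds, plan@testSubjects)))
  folds <- sort(unique(plan@folds))
  models <- list(); rows <- list()
  for (f in folds) {
    valSub <- names(plan@folds)[plan@folds == f]
    isVal <- epochs@subjectIds %in% valSub
    tr <- subsetEpochs(epochs, !isVal)
    va <- subsetEpochs(epochs, isVal)
    if (augmentFraction > 0)
      tr <- augmentRecombine(tr, augmentFraction, nSegments,
                             seed = childSeed(spec@seed, "aug", f))
    m <- builder()
    m <- trainModel(m, tr, va, spec, verbose = verbose)
    h <- m@history[m@extra$bestEpoch, ]
    models[[length(models) + 1L]] <- m
    rows[[length(rows) + 1L]] <- data.frame(fold = f,
      val_accuracy = h$val_accuracy, val_loss = h$val_loss,
      best_epoch = m@extra$bestEpoch, epochs_run = m@extra$stoppedEpoch)
  }
  metrics <- do.call(rbind, rows)
  list(models = models, metrics = metrics,
       best = selectBestFoldModel(models, metrics))
}

#' Early-stopping bookkeeping
#'
#' Pure decision function over the validation-loss trace: an epoch improves
#' when its loss undercuts the best previous loss by more than
#' \code{minDelta}; training stops once \code{patience} consecutive epochs
#' have passed without improvement, restoring the best epoch.
#'
#' @param valLosses validation losses for epochs 1..t.
#' @param patience consecutive non-improving epochs tolerated.
#' @param minDelta minimum improvement counted as progress.
#' @return list with \code{improved} (last epoch improved), \code{stop}
#'   (stop after this epoch), \code{bestEpoch}.
#' @export
earlyStopState <- function(valLosses, patience = 10L, minDelta = 0) {
  stopifnot(length(valLosses) >= 1L)
  bestEpoch <- 1L
  bestLoss <- valLosses[1L]
  wait <- 0L
  stop <- FALSE
  improved <- TRUE
  for (t in seq_along(valLosses)[-1L]) {
    improved <- valLosses[t] < bestLoss - minDelta
    if (improved) {
      bestLoss <- valLosses[t]; bestEpoch <- t; wait <- 0L
    } else {
      wait <- wait + 1L
    }
    if (wait >= patience) { stop <- TRUE; break }
  }
  list(improved = if (length(valLosses) == 1L) TRUE else improved,
       stop = stop, bestEpoch = bestEpoch)
}
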