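#' Confusion matrix and weighted classification metrics
#'
#' Computes the true x predicted confusion matrix and, from per-class
#' one-vs-rest TP/TN/FP/FN counts, accuracy
#' \eqn{(TP+TN)/(TP+TN+FP+FN)} (equivalently trace/total for multi-class),
#' recall \eqn{TP/(TP+FN)}, precision \eqn{TP/(TP+FP)} and
#' \eqn{F1 = 2PR/(P+R)}, with precision/recall/F1 averaged using class
#' supports as weights (classes absent from the truth get zero weight).
#'
#' @param yTrue,yPred equal-length label vectors.
#' @param classes class label ordering; defaults to the sorted union.
#' @return list with \code{confusion}, \code{accuracy}, \code{precision},
#'   \code{recall}, \code{f1} and the \code{perClass} breakdown.
#' @examples
#' computeMetrics(rep(c("MCI", "AD"), c(60, 20)),
#'                rep(c("MCI", "AD", "MCI"), c(59, 1, 20)))
#' @export
computeMetrics <- function(yTrue, yPred, classes = NULL) {
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  stopifnot(length(yTrue) == length(yPred))
  if (is.null(classes)) classes <- sort(unique(c(yTrue, yPred)))
  if (!all(c(yTrue, yPred) %in% classes))
    stop("labels outside the declared class set")
  cm <- table(factor(yTrue, classes), factor(yPred, classes))
  cm <- matrix(as.integer(cm), length(classes), length(classes),
               dimnames = list(true = classes, predicted = classes))
  total <- sum(cm)
  per <- lapply(classes, function(cl) {
    tp <- cm[cl, cl]
    fn <- sum(cm[cl, ]) - tp
    fp <- sum(cm[, cl]) - tp
    tn <- total - tp - fn - fp
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = cl, support = tp + fn, tp = tp, tn = tn, fp = fp,
               fn = fn, precision = prec, recall = rec, f1 = f1)
  })
  per <- do.call(rbind, per)
  wts <- per$support / sum(per$support)
  list(confusion = cm,
       accuracy = sum(diag(cm)) / total,
       precision = sum(wts * per$precision),
       recall = sum(wts * per$recall),
       f1 = sum(wts * per$f1),
       perClass = per)
}

#' One-vs-rest ROC curves and AUC
#'
#' For every class, sweeps thresholds over the predicted probability of that
#' class against the rest, collecting (FPR, TPR) points, and integrates the
#' curve by the trapezoidal rule (equivalent to the Mann-Whitney
#' pair-counting statistic, with ties counted half).
#'
#' @param yTrue true labels.
#' @param scores matrix of per-class probabilities with named columns.
#' @return list with \code{auc} (named per-class vector; NA with a warning
#'   for classes absent from or filling the truth) and \code{curves} (named
#'   list of data.frames with \code{threshold}, \code{fpr}, \code{tpr}).
#' @export
rocAuc <- function(yTrue, scores) {
  yTrue <- as.character(yTrue)
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) stop("scores must have class-named columns")
  classes <- colnames(scores)
  auc <- setNames(rep(NA_real_, length(classes)), classes)
  curves <- setNames(vector("list", length(classes)), classes)
  for (cl in classes) {
    pos <- yTrue == cl
    if (!any(pos) || all(pos)) {
      warning("AUC undefined for class ", cl, ": one-class truth")
      next
    }
    s <- scores[, cl]
    thr <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
    tpr <- fpr <- numeric(length(thr))
    for (i in seq_along(thr)) {
      call <- s >= thr[i]
      tpr[i] <- sum(call & pos) / sum(pos)
      fpr[i] <- sum(call & !pos) / sum(!pos)
    }
    o <- order(fpr, tpr)
    auc[cl] <- sum(diff(fpr[o]) * (head(tpr[o], -1) + tpr[o][-1]) / 2)
    curves[[cl]] <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  }
  list(auc = auc, curves = curves)
}

#' Participant-level majority vote
#'
#' Aggregates the 10 per-trial predictions of each participant into class
#' fractions and calls the class predicted for more than 50\% of trials; if
#' no class exceeds 50\% the participant is marked indeterminate (no call;
#' scored incorrect when participant-level accuracy is computed).
#'
#' @param predictions per-trial predicted labels.
#' @param subjects per-trial subject identifiers (10 trials per subject).
#' @param classes class set for the fraction columns.
#' @param truth optional named vector of true group per subject.
#' @return data.frame with one row per participant: per-class fractions,
#'   \code{call}, \code{indeterminate}, and \code{correct} when truth is
#'   given.
#' @export
participantVote <- function(predictions, subjects, classes = NULL,
                            truth = NULL) {
  predictions <- as.character(predictions)
  stopifnot(length(predictions) == length(subjects))
  if (is.null(classes)) classes <- sort(unique(predictions))
  bad <- names(which(table(subjects) != 10L))
  if (length(bad))
    stop("subjects without exactly 10 trials: ", paste(bad, collapse = ", "))
  ids <- unique(subjects)
  rows <- lapply(ids, function(id) {
    p <- predictions[subjects == id]
    fr <- vapply(classes, function(cl) mean(p == cl), numeric(1))
    winner <- which(fr > 0.5)
    call <- if (length(winner) == 1L) classes[winner] else NA_character_
    out <- data.frame(subject = id, t(fr), call = call,
                      indeterminate = is.na(call), stringsAsFactors = FALSE)
    names(out)[2:(1 + length(classes))] <- paste0("frac_", classes)
    out
  })
  votes <- do.call(rbind, rows)
  if (!is.null(truth)) {
    votes$true <- as.character(truth[votes$subject])
    votes$correct <- !votes$indeterminate & votes$call == votes$true
  }
  votes
}

#' Evaluate a trained model on held-out trials
#'
#' Runs inference, then assembles the full report: confusion matrix,
#' accuracy and support-weighted precision/recall/F1, per-class one-vs-rest
#' AUC with curve points, and the participant-level vote table.
#'
#' @param model a \linkS4class{TrainedModel}.
#' @param testEpochs an \linkS4class{EpochSet} of held-out subjects.
#' @param task,conditionTag labels recorded in the report.
#' @return an \linkS4class{EvaluationReport}.
#' @export
evaluateModel <- function(model, testEpochs, task = "", conditionTag = NULL) {
  stopifnot(!any(testEpochs@augmented))
  probs <- predictProba(model, testEpochs)
  classes <- model@classes
  yTrue <- as.character(testEpochs@labels)
  yPred <- classes[max.col(probs, ties.method = "first")]
  met <- computeMetrics(yTrue, yPred, classes)
  roc <- rocAuc(yTrue, probs)
  truth <- tapply(yTrue, testEpochs@subjectIds, function(v) v[1])
  votes <- participantVote(yPred, testEpochs@subjectIds, classes, truth)
  new("EvaluationReport", task = task,
      condition = if (is.null(conditionTag)) testEpochs@condition else conditionTag,
      model = model@architecture,
      confusion = met$confusion,
      metrics = c(accuracy = met$accuracy, precision = met$precision,
                  recall = met$recall, f1 = met$f1),
      auc = roc$auc, roc = roc$curves, votes = votes,
      meta = list(n_trials = nTrials(testEpochs),
                  subjects = unique(testEpochs@subjectIds),
                  participant_accuracy = mean(votes$correct %in% TRUE)))
}
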