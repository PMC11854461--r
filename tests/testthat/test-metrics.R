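# independent counting oracle for per-class one-vs-rest metrics
bruteMetrics <- function(yTrue, yPred, classes) {
  n <- length(yTrue)
  acc <- sum(yTrue == yPred) / n
  prec <- rec <- f1 <- sup <- numeric(length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- sum(yTrue == cl & yPred == cl)
    fp <- sum(yTrue != cl & yPred == cl)
    fn <- sum(yTrue == cl & yPred != cl)
    sup[i] <- tp + fn
    prec[i] <- if (tp + fp) tp / (tp + fp) else 0
    rec[i] <- if (tp + fn) tp / (tp + fn) else 0
    f1[i] <- if (prec[i] + rec[i]) 2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  w <- sup / sum(sup)
  list(accuracy = acc, precision = sum(w * prec), recall = sum(w * rec),
       f1 = sum(w * f1))
}

test_that("the printed MCI-vs-AD worked example is reproduced exactly", {
  yTrue <- rep(c("MCI", "AD"), c(60, 20))
  yPred <- c(rep("MCI", 59), "AD", rep("AD", 12), rep("MCI", 8))
  m <- computeMetrics(yTrue, yPred, classes = c("MCI", "AD"))
  expect_equal(m$accuracy, 71 / 80)
  expect_equal(m$accuracy, 0.8875)
  expect_equal(m$confusion["MCI", "MCI"], 59L)
  expect_equal(m$confusion["AD", "AD"], 12L)
  expect_equal(sum(m$confusion), 80L)

  # the companion case: 60/60 and 11/20 correct -> weighted F1 ~ 0.875
  yPred2 <- c(rep("MCI", 60), rep("AD", 11), rep("MCI", 9))
  m2 <- computeMetrics(yTrue, yPred2, classes = c("MCI", "AD"))
  f1MCI <- 2 * (60 / 69) * 1 / ((60 / 69) + 1)
  f1AD <- 2 * 1 * 0.55 / (1 + 0.55)
  expect_equal(m2$f1, 0.75 * f1MCI + 0.25 * f1AD)
  expect_equal(m2$f1, 0.875, tolerance = 1e-3)

  perfect <- computeMetrics(yTrue, yTrue)
  expect_equal(unname(unlist(perfect[c("accuracy", "precision", "recall", "f1")])),
               rep(1, 4))
  expect_error(computeMetrics(yTrue, yPred, classes = "MCI"), "outside")
})

test_that("metric formulas agree with a brute-force counting oracle", {
  withr::with_seed(17, {
    for (i in 1:200) {
      K <- sample(2:4, 1)
      classes <- LETTERS[1:K]
      n <- sample(5:60, 1)
      yTrue <- sample(classes, n, replace = TRUE)
      yPred <- sample(classes, n, replace = TRUE)
      m <- computeMetrics(yTrue, yPred, classes)
      o <- bruteMetrics(yTrue, yPred, classes)
      expect_equal(m$accuracy, o$accuracy)
      expect_equal(m$precision, o$precision)
      expect_equal(m$recall, o$recall)
      expect_equal(m$f1, o$f1)
      # 2-class identity: weighted recall equals accuracy
      if (K == 2) expect_equal(m$recall, m$accuracy, tolerance = 1e-12)
    }
  })
})

test_that("ROC/AUC matches pair counting and the hand-computed case", {
  s <- cbind(P = c(0.9, 0.8, 0.4, 0.3), N = c(0.1, 0.2, 0.6, 0.7))
  y <- c("P", "N", "P", "N")
  r <- rocAuc(y, s)
  expect_equal(unname(r$auc["P"]), 0.75)
  expect_equal(unname(r$auc["N"]), 0.75)   # symmetric 2-class

  perf <- rocAuc(c("P", "P", "N"), cbind(P = c(.9, .8, .1), N = c(.1, .2, .9)))
  expect_equal(unname(perf$auc["P"]), 1)
  inv <- rocAuc(c("P", "P", "N"), cbind(P = c(.1, .2, .9), N = c(.9, .8, .1)))
  expect_equal(unname(inv$auc["P"]), 0)

  expect_warning(expect_warning(
    one <- rocAuc(c("P", "P"), cbind(P = c(.3, .6), N = c(.7, .4))),
    "undefined"), "undefined")
  expect_true(is.na(one$auc["N"]))

  # Mann-Whitney pair-counting equivalence (ties count half), random cases
  withr::with_seed(23, {
    for (i in 1:50) {
      n <- sample(8:40, 1)
      y <- sample(c("pos", "neg"), n, replace = TRUE, prob = c(.4, .6))
      if (length(unique(y)) < 2) next
      sc <- round(runif(n), 2)   # coarse grid forces ties
      auc <- rocAuc(y, cbind(pos = sc, neg = 1 - sc))$auc["pos"]
      pos <- sc[y == "pos"]; neg <- sc[y == "neg"]
      pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
      expect_equal(unname(auc), mean(pairs), tolerance = 1e-12)
    }
  })
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(29, {
    y <- sample(c("a", "b"), 60, replace = TRUE)
    sc <- runif(60)
    ours <- rocAuc(y, cbind(a = sc, b = 1 - sc))$auc["a"]
    ref <- suppressMessages(pROC::auc(pROC::roc(y == "a", sc, direction = "<")))
    expect_equal(unname(ours), as.numeric(ref), tolerance = 1e-12)
  })
})

test_that("participant votes follow the >50% rule with indeterminate ties", {
  preds <- c(rep("SCD", 8), rep("MCI", 2),      # 80/20 -> SCD
             rep("SCD", 1), rep("MCI", 9),      # 10/90 -> MCI (misclassified)
             rep("SCD", 5), rep("MCI", 5))      # 50/50 -> indeterminate
  subj <- rep(c("s1", "s2", "s3"), each = 10)
  truth <- c(s1 = "SCD", s2 = "SCD", s3 = "AD")
  v <- participantVote(preds, subj, classes = c("SCD", "MCI", "AD"), truth)
  expect_equal(v$frac_SCD, c(0.8, 0.1, 0.5))
  expect_equal(v$call, c("SCD", "MCI", NA))
  expect_equal(v$indeterminate, c(FALSE, FALSE, TRUE))
  expect_equal(v$correct, c(TRUE, FALSE, FALSE))
  rowFr <- as.matrix(v[, c("frac_SCD", "frac_MCI", "frac_AD")])
  expect_equal(unname(rowSums(rowFr)), rep(1, 3))
  expect_error(participantVote(preds[1:25], subj[1:25]), "exactly 10")
})

test_that("evaluateModel assembles a coherent report", {
  ep <- toyEpochs(nPerClass = 30, nSamples = 8, nChannels = 2, shift = 4,
                  seed = 33)
  m <- fitBaseline(ep)
  rep <- evaluateModel(m, ep, task = "SCD-vs-MCI")
  expect_s4_class(rep, "EvaluationReport")
  expect_equal(sum(rep@confusion), nTrials(ep))
  expect_true(all(rep@metrics >= 0 & rep@metrics <= 1))
  expect_equal(nrow(rep@votes), length(unique(ep@subjectIds)))
  expect_equal(sum(rep@confusion), 60L)
})
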