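#' Experiment configuration
#'
#' Assembles (and validates) the single configuration object that fully
#' determines an end-to-end run: cohort composition and separability,
#' acquisition profile, preprocessing toggles, task, model and training
#' settings. Identical configurations yield identical reports.
#'
#' @param nScd,nMci,nAd cohort sizes (study default 20/28/10).
#' @param effectSize generator separability dial.
#' @param condition \code{"SQT"} or \code{"REST"}.
#' @param task \code{"SCD-vs-MCI"}, \code{"MCI-vs-AD"} or \code{"3-class"}.
#' @param model \code{"attention_lstm"}, \code{"conformer"} or
#'   \code{"pca_svm"}.
#' @param channels,samplingRate acquisition profile (defaults to the fast
#'   19-channel 512 Hz profile; use \code{montage64()} and 2048 to emulate
#'   the full acquisition chain).
#' @param ica run ICA artifact removal during preprocessing.
#' @param injectBlinkRate,injectLineAmp artifact injection settings for the
#'   synthetic recordings (0 = clean).
#' @param testFraction,nFolds split geometry.
#' @param spec a \linkS4class{TrainSpec} (batch size defaults per model).
#' @param augmentFraction training-fold augmentation (conformer default
#'   0.2, others 0).
#' @param seed master seed; all stage seeds derive from it.
#' @param outDir optional output directory for report artifacts.
#' @return a named list (class \code{"adspectrumConfig"}).
#' @export
experimentConfig <- function(nScd = 20, nMci = 28, nAd = 10, effectSize = 1,
                             condition = c("SQT", "REST"),
                             task = c("SCD-vs-MCI", "MCI-vs-AD", "3-class"),
                             model = c("attention_lstm", "conformer", "pca_svm"),
                             channels = montage19(), samplingRate = 512,
                             ica = FALSE, injectBlinkRate = 0,
                             injectLineAmp = 0, testFraction = 0.2,
                             nFolds = 5, spec = NULL,
                             augmentFraction = NULL, seed = 1,
                             outDir = NULL) {
  condition <- match.arg(condition)
  task <- match.arg(task)
  model <- match.arg(model)
  if (is.null(augmentFraction))
    augmentFraction <- if (model == "conformer") 0.2 else 0
  if (is.null(spec)) {
    spec <- trainSpec(batchSize = if (model == "conformer") 100L else 64L,
                      plateauFactor = if (model == "conformer") 0.5 else 1,
                      seed = seed)
  }
  cfg <- list(nScd = nScd, nMci = nMci, nAd = nAd, effectSize = effectSize,
              condition = condition, task = task, model = model,
              channels = channels, samplingRate = samplingRate, ica = ica,
              injectBlinkRate = injectBlinkRate,
              injectLineAmp = injectLineAmp, testFraction = testFraction,
              nFolds = nFolds, spec = spec,
              augmentFraction = augmentFraction, seed = as.integer(seed),
              outDir = outDir)
  class(cfg) <- "adspectrumConfig"
  cfg
}

#' Continuous-integration profile
#'
#' A small, fast configuration (6 subjects per group, 19 channels at
#' 512 Hz, ICA off, reduced epoch budget) for full-pipeline checks.
#'
#' @param ... overrides passed to \code{\link{experimentConfig}}.
#' @export
ciProfile <- function(...) {
  over <- list(...)
  base <- list(nScd = 6, nMci = 6, nAd = 6, channels = montage19(),
               samplingRate = 512, ica = FALSE,
               spec = trainSpec(maxEpochs = 50L, patience = 10L,
                                seed = if (!is.null(over$seed)) over$seed else 1))
  do.call(experimentConfig, utils::modifyList(base, over))
}

taskGroups <- function(task) {
  switch(task,
         "SCD-vs-MCI" = c("SCD", "MCI"),
         "MCI-vs-AD" = c("MCI", "AD"),
         "3-class" = GROUPS,
         stop("unknown task ", task))
}

#' Build labeled epochs for a cohort
#'
#' Synthesizes, preprocesses and epochs one condition for every subject in
#' the cohort, returning a single labeled \linkS4class{EpochSet}.
#'
#' @param cohort a \code{\link{sampleCohort}} data.frame.
#' @param condition \code{"SQT"} or \code{"REST"}.
#' @param protocol an \linkS4class{SQTProtocol}.
#' @param channels,samplingRate acquisition profile.
#' @param ica run ICA artifact removal.
#' @param injectBlinkRate,injectLineAmp artifact injection settings.
#' @param seed master seed.
#' @return an \linkS4class{EpochSet}.
#' @export
cohortEpochs <- function(cohort, condition, protocol = loadProtocol(),
                         channels = montage19(), samplingRate = 512,
                         ica = FALSE, injectBlinkRate = 0,
                         injectLineAmp = 0, seed = 1) {
  sets <- lapply(seq_len(nrow(cohort)), function(i) {
    sub <- cohort[i, ]
    rec <- synthesizeRecording(sub, condition, protocol, seed = seed,
                               channels = channels,
                               samplingRate = samplingRate)
    if (injectBlinkRate > 0 || injectLineAmp > 0)
      rec <- injectArtifacts(rec, injectBlinkRate, injectLineAmp, seed = seed)
    rec <- preprocessRecording(rec, targetRate = 512, ica = ica,
                               icaSeed = childSeed(seed, sub$subject_id, "ica"))
    if (condition == "SQT") epochSQT(rec, label = sub$group)
    else epochRest(rec, label = sub$group)
  })
  bindEpochs(sets)
}

#' Run a full experiment from a configuration
#'
#' Executes the complete chain: synthesize the cohort, preprocess and epoch
#' the selected condition, split subject-wise, run subject-wise 5-fold
#' cross-validated training, select the best fold model, evaluate it on the
#' held-out subjects, and summarize behavior. All randomness derives from
#' the configuration seed, so identical configurations give identical
#' reports.
#'
#' @param cfg an \code{\link{experimentConfig}}.
#' @param verbose print training progress.
#' @return an \linkS4class{EvaluationReport}; \code{meta} carries the
#'   resolved configuration hash, seeds, fold metrics, behavioral table and
#'   statistics.
#' @export
runExperiment <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "adspectrumConfig"))
  protocol <- loadProtocol()
  cohort <- sampleCohort(cfg$nScd, cfg$nMci, cfg$nAd, seed = cfg$seed,
                         effectSize = cfg$effectSize)
  keep <- cohort$group %in% taskGroups(cfg$task)
  taskCohort <- cohort[keep, , drop = FALSE]
  if (!nrow(taskCohort)) stop("task ", cfg$task, " has no subjects in cohort")

  epochs <- cohortEpochs(taskCohort, cfg$condition, protocol,
                         channels = cfg$channels,
                         samplingRate = cfg$samplingRate, ica = cfg$ica,
                         injectBlinkRate = cfg$injectBlinkRate,
                         injectLineAmp = cfg$injectLineAmp, seed = cfg$seed)
  plan <- subjectWiseSplit(taskCohort, cfg$testFraction, cfg$nFolds,
                           seed = cfg$seed)
  isTest <- epochs@subjectIds %in% plan@testSubjects
  testEpochs <- subsetEpochs(epochs, isTest)
  trainEpochs <- subsetEpochs(epochs, !isTest)

  classes <- taskGroups(cfg$task)
  report <-
    if (cfg$model == "pca_svm") {
      model <- fitBaseline(trainEpochs, seed = cfg$seed)
      evaluateModel(model, testEpochs, task = cfg$task)
    } else {
      builder <- if (cfg$model == "attention_lstm") {
        function() attentionLSTM(classes, nChannels = length(epochs@channels),
                                 nSamples = dim(epochs@data)[1L],
                                 seed = cfg$seed)
      } else {
        function() eegConformer(classes, nChannels = length(epochs@channels),
                                nSamples = dim(epochs@data)[1L],
                                seed = cfg$seed)
      }
      cv <- crossValidate(builder, trainEpochs, plan, cfg$spec,
                          augmentFraction = cfg$augmentFraction,
                          verbose = verbose)
      rep <- evaluateModel(cv$best, testEpochs, task = cfg$task)
      rep@meta$fold_metrics <- cv$metrics
      rep
    }

  beh <- do.call(rbind, lapply(seq_len(nrow(taskCohort)), function(i)
    sampleBehavior(taskCohort[i, ], protocol,
                   seed = childSeed(cfg$seed, taskCohort$subject_id[i], "beh"))))
  behTable <- summarizeBehavior(beh, taskCohort)

  report@meta$config_hash <- configHash(cfg)
  report@meta$seed <- cfg$seed
  report@meta$cohort_subjects <- taskCohort$subject_id
  report@meta$split <- list(train = plan@trainSubjects,
                            test = plan@testSubjects)
  report@meta$behavior <- behTable
  report@meta$behavior_stats <- lapply(
    c(accuracy = "accuracy", rt = "mean_rt_ms", std_rt = "std_rt_ms"),
    function(m) compareBehavior(behTable, m))

  if (!is.null(cfg$outDir)) writeReport(report, cfg)
  report
}

configHash <- function(cfg) {
  cfg$outDir <- NULL
  s <- jsonlite::serializeJSON(cfg)
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%d", h)
}

writeReport <- function(report, cfg) {
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  tag <- paste(cfg$task, cfg$condition, cfg$model, sep = "_")
  write.csv(as.data.frame(report@confusion),
            file.path(cfg$outDir, paste0("confusion_", tag, ".csv")))
  write.csv(report@votes,
            file.path(cfg$outDir, paste0("votes_", tag, ".csv")),
            row.names = FALSE)
  write.csv(report@meta$behavior,
            file.path(cfg$outDir, paste0("behavior_", tag, ".csv")),
            row.names = FALSE)
  jsonlite::write_json(list(
    task = report@task, condition = report@condition, model = report@model,
    metrics = as.list(report@metrics), auc = as.list(report@auc),
    participant_accuracy = report@meta$participant_accuracy,
    config_hash = report@meta$config_hash, seed = report@meta$seed),
    file.path(cfg$outDir, paste0("report_", tag, ".json")),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}

#' Compare task-based and resting-state reports
#'
#' Per-metric difference (SQT minus REST) for two reports produced from the
#' same cohort and split; purely descriptive.
#'
#' @param reportSqt,reportRest \linkS4class{EvaluationReport}s for the same
#'   task, model, cohort and split.
#' @return data.frame of metric deltas.
#' @export
compareConditions <- function(reportSqt, reportRest) {
  if (!identical(reportSqt@meta$cohort_subjects,
                 reportRest@meta$cohort_subjects) ||
      !identical(reportSqt@meta$split, reportRest@meta$split))
    stop("reports come from different cohorts or splits")
  if (reportSqt@task != reportRest@task ||
      reportSqt@model != reportRest@model)
    stop("reports compare different tasks or models")
  m <- union(names(reportSqt@metrics), names(reportRest@metrics))
  data.frame(metric = m,
             sqt = as.numeric(reportSqt@metrics[m]),
             rest = as.numeric(reportRest@metrics[m]),
             delta = as.numeric(reportSqt@metrics[m] - reportRest@metrics[m]))
}
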