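# End-to-end experiment harnesses: single runs, the ablation table, the
# recurrence-step sweep, and patient-wise k-fold cross-validation. All
# harnesses derive every stochastic choice (split, initialization, training)
# from one root seed so that comparisons are paired and any run directory can
# be reproduced bit-identically.

#' Assemble an experiment configuration
#'
#' @param data a [SliceSet-class] or a dataset directory for
#'   [readSliceSet()].
#' @param variant variant label (see [variantNames()]).
#' @param network named list of [networkConfig()] overrides (e.g.
#'   `baseChannels`, `tSteps`, `dropoutRate`).
#' @param train a [TrainConfig-class].
#' @param outDir optional run directory.
#' @param seed root seed.
#' @return list of class `experimentConfig`.
#' @export
experimentConfig <- function(data, variant = "Att+Rec+Res",
                             network = list(), train = trainConfig(),
                             outDir = NULL, seed = 1L) {
  structure(list(data = data, variant = variant, network = network,
                 train = train, outDir = outDir, seed = as.integer(seed)),
            class = "experimentConfig")
}

resolveData <- function(data) {
  if (is(data, "SliceSet")) data else readSliceSet(data)
}

writeRunMeta <- function(outDir, meta, seed) {
  if (is.null(outDir)) return(invisible(NULL))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(meta, file.path(outDir, "config.yaml"))
  writeLines(as.character(seed), file.path(outDir, "seed.txt"))
  invisible(outDir)
}

# Normalize according to the variant flag: dataset-wide statistics computed
# on the training indices only, applied everywhere (no test leakage).
applyNormalization <- function(set, split, useNormalization) {
  if (!useNormalization) {
    return(list(set = set, stats = NULL))
  }
  stats <- computeDatasetStats(set[split@train])
  list(set = normalizeSliceSet(set, stats), stats = stats)
}

#' Run one train/evaluate experiment
#'
#' Splits the slices 80/10/10, Z-score-normalizes them with training-split
#' statistics (unless the variant disables normalization), trains the variant
#' and evaluates on the held-out test slices.
#'
#' @param config an [experimentConfig()].
#' @param verbose print per-epoch progress.
#' @return list with `report` ([MetricsReport-class]), `history`
#'   ([TrainHistory-class]), `model`, `split`, and `variant`.
#' @export
runExperiment <- function(config, verbose = FALSE) {
  set <- resolveData(config$data)
  v <- do.call(makeVariant, c(list(config$variant), config$network))
  split <- splitDataset(length(set), seed = deriveSeed(config$seed, 101))
  norm <- applyNormalization(set, split, v$config@useNormalization)
  model <- buildModel(v$config, seed = deriveSeed(config$seed, 202))
  tc <- config$train
  tc@seed <- deriveSeed(config$seed, 303)
  logFile <- if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    file.path(config$outDir, "train.log")
  }
  fit <- trainModel(model, norm$set[split@train], norm$set[split@validation],
                    tc, verbose = verbose, logFile = logFile)
  report <- evaluateModel(fit$model, norm$set[split@test],
                          threshold = tc@threshold)
  if (!is.null(config$outDir)) {
    writeRunMeta(config$outDir,
                 list(variant = v$name, network = configAsList(v$config),
                      train = trainConfigAsList(tc)), config$seed)
    write.csv(fit$history@epochs,
              file.path(config$outDir, "history.csv"), row.names = FALSE)
    write.csv(metricsAsRow(v$name, report),
              file.path(config$outDir, "metrics.csv"), row.names = FALSE)
    saveCheckpoint(fit$model, file.path(config$outDir, "checkpoint"))
  }
  list(report = report, history = fit$history, model = fit$model,
       split = split, variant = v$name)
}

trainConfigAsList <- function(tc) {
  list(beta1 = tc@beta1, beta2 = tc@beta2, initialLr = tc@initialLr,
       lrDecayFactor = tc@lrDecayFactor, lrPatience = tc@lrPatience,
       weightDecay = tc@weightDecay, epochs = tc@epochs,
       batchSize = tc@batchSize, seed = tc@seed, threshold = tc@threshold)
}

metricsAsRow <- function(label, report) {
  m <- metricMeans(report); s <- metricSds(report)
  data.frame(model = label,
             dsc = fmtPM(m["dsc"], s["dsc"]),
             js = fmtPM(m["jaccard"], s["jaccard"]),
             pc = fmtPM(m["precision"], s["precision"]),
             sp = fmtPM(m["specificity"], s["specificity"]),
             se = fmtPM(m["sensitivity"], s["sensitivity"]),
             auc = sprintf("%.4f", prAuc(report)))
}

#' Run the full ablation study
#'
#' Trains and evaluates every variant (full model first) on identical data
#' splits and seeds, and reports the five metrics per variant plus the
#' Kruskal-Wallis p-value of each variant's per-slice Dice distribution
#' against the full model's.
#'
#' @param config an [experimentConfig()]; its `variant` field is ignored.
#' @param variants variant labels to run (default all nine).
#' @param verbose print per-epoch progress.
#' @return list with `table` (data.frame, one row per variant) and `reports`
#'   (named list of [MetricsReport-class]). When `config$outDir` is set the
#'   table is written to `ablation.csv`.
#' @export
runAblation <- function(config, variants = variantNames(), verbose = FALSE) {
  reports <- list()
  for (v in variants) {
    cfg_v <- config
    cfg_v$variant <- v
    cfg_v$outDir <- NULL
    r <- tryCatch(runExperiment(cfg_v, verbose = verbose), error = function(e) {
      stop("ablation variant '", v, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    reports[[v]] <- r$report
  }
  fullLabel <- if ("Att+Rec+Res" %in% names(reports)) {
    "Att+Rec+Res"
  } else {
    names(reports)[1]
  }
  full <- reports[[fullLabel]]
  rows <- lapply(names(reports), function(v) {
    row <- metricsAsRow(v, reports[[v]])
    row$p_vs_full <- if (v == fullLabel) NA_real_ else {
      signif(kruskalWallis(list(full@perSlice$dsc,
                                reports[[v]]@perSlice$dsc))$p.value, 3)
    }
    row
  })
  tab <- do.call(rbind, rows)
  if (!is.null(config$outDir)) {
    writeRunMeta(config$outDir,
                 list(harness = "ablation", variants = variants,
                      network = config$network,
                      train = trainConfigAsList(config$train)), config$seed)
    write.csv(tab, file.path(config$outDir, "ablation.csv"),
              row.names = FALSE)
  }
  list(table = tab, reports = reports)
}

#' Sweep the recurrence-step hyperparameter t
#'
#' Trains the full-mechanism model once per `t` on identical splits and
#' seeds. Recurrence reuses the convolution weights, so the parameter count
#' is identical across `t`; only compute changes.
#'
#' @param config an [experimentConfig()].
#' @param tValues integer recurrence steps to try (default 1:4).
#' @param verbose print per-epoch progress.
#' @return list with `table` (one row per t, plus a `parameters` column) and
#'   `reports`. Written to `t_sweep.csv` under `config$outDir` if set.
#' @export
runTSweep <- function(config, tValues = 1:4, verbose = FALSE) {
  if (length(tValues) == 0L) {
    stop("runTSweep: empty t list", call. = FALSE)
  }
  if (any(tValues < 1L)) stop("runTSweep: t values must be >= 1",
                              call. = FALSE)
  reports <- list()
  rows <- list()
  for (t in tValues) {
    cfg_t <- config
    cfg_t$network$tSteps <- as.integer(t)
    cfg_t$outDir <- NULL
    r <- runExperiment(cfg_t, verbose = verbose)
    reports[[as.character(t)]] <- r$report
    row <- metricsAsRow(sprintf("t=%d", t), r$report)
    row$parameters <- countParameters(r$model)
    rows[[as.character(t)]] <- row
  }
  tab <- do.call(rbind, rows)
  if (!is.null(config$outDir)) {
    writeRunMeta(config$outDir,
                 list(harness = "t-sweep", tValues = as.integer(tValues),
                      network = config$network,
                      train = trainConfigAsList(config$train)), config$seed)
    write.csv(tab, file.path(config$outDir, "t_sweep.csv"),
              row.names = FALSE)
  }
  list(table = tab, reports = reports)
}

#' Patient-wise k-fold cross-validation
#'
#' Partitions patients (not slices) into `k` folds; for each fold, trains on
#' the other folds (with a 90/10 train/validation split of their slices) and
#' evaluates Dice on the held-out fold's slices. No patient contributes
#' slices to both sides of any fold.
#'
#' @param config an [experimentConfig()].
#' @param k number of folds (default 5).
#' @param verbose print per-epoch progress.
#' @return list with `foldDsc` (numeric per-fold test Dice), `summary`
#'   (mean/sd via [foldSummary()]), `assignment` (the
#'   [FoldAssignment-class]), and `table` (Table-style one-row data.frame).
#'   Written to `crossval.csv` under `config$outDir` if set.
#' @export
runCrossval <- function(config, k = 5L, verbose = FALSE) {
  set <- resolveData(config$data)
  ids <- patientIds(set)
  fa <- assignPatientFolds(ids, k = k, seed = deriveSeed(config$seed, 404))
  foldOfSlice <- foldOf(fa)[ids]
  foldDsc <- numeric(k)
  for (f in seq_len(k)) {
    testIdx <- which(foldOfSlice == f)
    restIdx <- which(foldOfSlice != f)
    tv <- splitDataset(length(restIdx), fractions = c(0.9, 0.1, 0),
                       seed = deriveSeed(config$seed, 505, f))
    # splitDataset requires three non-empty sets only via its remainder rule;
    # with a zero test fraction the remainder is folded into validation.
    trainIdx <- restIdx[tv@train]
    valIdx <- restIdx[c(tv@validation, tv@test)]
    v <- do.call(makeVariant, c(list(config$variant), config$network))
    splitLike <- new("SplitPlan",
                     train = seq_along(trainIdx),
                     validation = length(trainIdx) + seq_along(valIdx),
                     test = length(trainIdx) + length(valIdx) +
                       seq_along(testIdx))
    ordered <- set[c(trainIdx, valIdx, testIdx)]
    norm <- applyNormalization(ordered, splitLike,
                               v$config@useNormalization)
    model <- buildModel(v$config, seed = deriveSeed(config$seed, 606, f))
    tc <- config$train
    tc@seed <- deriveSeed(config$seed, 707, f)
    fit <- trainModel(model, norm$set[splitLike@train],
                      norm$set[splitLike@validation], tc, verbose = verbose)
    rep <- evaluateModel(fit$model, norm$set[splitLike@test],
                         threshold = tc@threshold, prCurve = FALSE)
    foldDsc[f] <- metricMeans(rep)[["dsc"]]
  }
  fs <- foldSummary(foldDsc)
  tab <- data.frame(model = config$variant,
                    t(round(foldDsc, 4)),
                    mean = fmtPM(fs$mean, fs$sd))
  names(tab) <- c("model", paste0("fold", seq_len(k)), "mean")
  if (!is.null(config$outDir)) {
    writeRunMeta(config$outDir,
                 list(harness = "crossval", k = as.integer(k),
                      variant = config$variant, network = config$network,
                      train = trainConfigAsList(config$train)), config$seed)
    write.csv(tab, file.path(config$outDir, "crossval.csv"),
              row.names = FALSE)
  }
  list(foldDsc = foldDsc, summary = fs, assignment = fa, table = tab)
}

#' Reference scaled-down synthetic experiment configuration
#'
#' The package's canonical CPU-scale study conditions: a 24-patient phantom
#' cohort of 64x64 slices (about 200 in total) with lesion area between 2%
#' and 8% of pixels, three scanner profiles, a reduced network (base width 4,
#' t = 2, per-step batch-norm state, no dropout), and 25 epochs of Adam at
#' initial learning rate 3e-3. See the methods vignette for the rationale
#' behind each choice.
#'
#' @param seed root seed; drives cohort generation, splitting,
#'   initialization, and training.
#' @param variant variant label (default the full model).
#' @param epochs training epochs (default 25).
#' @param outDir optional run directory.
#' @return an [experimentConfig()] whose `data` field is the generated
#'   [SliceSet-class].
#' @export
scaledExperiment <- function(seed = 1L, variant = "Att+Rec+Res",
                             epochs = 25L, outDir = NULL) {
  ph <- phantomSpec(imageSide = 64L, lesionAreaFraction = c(0.02, 0.08),
                    seed = deriveSeed(seed, 11))
  cs <- cohortSpec(nPatients = 24L, slicesPerPatient = c(6L, 10L),
                   phantom = ph)
  experimentConfig(
    data = generateCohort(cs), variant = variant,
    network = list(baseChannels = 4L, tSteps = 2L, dropoutRate = 0,
                   bnPerStep = TRUE),
    train = trainConfig(epochs = as.integer(epochs), batchSize = 8L,
                        initialLr = 3e-3),
    outDir = outDir, seed = seed)
}
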