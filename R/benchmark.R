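#' Synthetic benchmark configuration bundle
#'
#' The stated world for the end-to-end feature-type benchmark: a screen
#' with high Cell Painting replicate noise (per-feature noise comparable
#' to signal), an informative low-noise transcriptomic modality, latent
#' dimensions visible only to TX, and bioactivity tasks mixing shared and
#' TX-only biology — the regime where learning from both modalities
#' should pay off for CP-only embeddings. Network widths are reduced so
#' the whole benchmark runs on one CPU in minutes; architecture shape,
#' masking, temperature and evaluation protocol follow the package
#' defaults.
#'
#' @param seed integer seed; all derived seeds come from it.
#' @param nCompounds screen size (default 2000).
#' @param clEpochs,mtEpochs training epochs for the contrastive model and
#'   the multitask classifiers (defaults 15 / 40).
#' @return list with components `screen` ([ScreenConfig-class]), `cl`
#'   ([CLConfig-class]), `mt` ([MultitaskConfig-class]) and `splitSeed`.
#' @seealso [runCrossModalBenchmark()]
#' @export
benchmarkConfig <- function(seed = 1, nCompounds = 2000,
                            clEpochs = 30, mtEpochs = 40) {
  seed <- as.integer(seed) %% 100000L
  list(
    screen = screenConfig(
      nCompounds = nCompounds, nMoaClasses = 12,
      dCp = 800, dTx = 4000,
      dLatentShared = 8, dLatentTxOnly = 6,
      replicateCountRange = c(3, 3),
      cpNoiseSd = 5, txNoiseSd = 0.3,
      moaCentroidSd = 1.5, moaWithinSd = 1,
      scaffoldMeanSize = 3,
      nTasks = 60, fracTxOnlyTasks = 0.1, taskMixing = "full",
      labelDensity = 1, taskNoiseSd = 0.5,
      seed = seed * 10L),
    cl = clConfig(
      cpHiddenSizes = 128, txHiddenSizes = 128,
      encoderOutputDim = 128, projectionDim = 64,
      temperature = 0.07, maskRate = 0.10,
      batchSize = 256, epochs = clEpochs, learningRate = 1e-3,
      seed = seed * 10L + 1L),
    mt = multitaskConfig(
      hiddenSize = 128, nLayers = 3, learningRate = 1e-3,
      weightDecay = 1e-5, batchSize = 128, epochs = mtEpochs,
      dropout = 0.3, schedulerPeriod = 10, seed = seed * 10L + 2L),
    splitSeed = seed * 10L + 3L)
}

#' End-to-end feature-type benchmark on a synthetic screen
#'
#' Runs the full pipeline once: generates a paired synthetic screen,
#' builds the scaffold-grouped 70/10/20 split and the (CP, TX) pairs,
#' pretrains the contrastive model on train + valid compounds, and
#' evaluates raw CP features against the learned CP-only embeddings (and
#' TX features where they apply) on the held-out test split:
#'
#' * replicate clustering and MoA clustering by kNN accuracy;
#' * multitask bioactivity classification (one model per feature type,
#'   bit-identical configuration) scored by AUROC and RIPtoP-AUPRC, with
#'   the TX-strong/CP-weak task subset and a paired Wilcoxon comparison;
#' * a label-permuted control model whose test AUROC should sit at
#'   chance.
#'
#' @param seed integer seed forwarded to [benchmarkConfig()].
#' @param config optional configuration bundle overriding the default
#'   (`benchmarkConfig(seed)`).
#' @param includePermuted run the label-permuted control? (default
#'   `TRUE`).
#' @return list with elements `replicateAcc` and `moaAcc` (named vectors
#'   with entries `cp`, `cl`), `taskMetrics` (per-feature-type
#'   `data.frame`s from [scoreTasks()]), `subsetTasks`,
#'   `subsetMeanAuroc` (named vector `cp`, `cl`, `tx`), `meanAuroc` and
#'   `meanRiptop` over all scored tasks, `clVsCp`
#'   ([ComparisonResult-class]), `permutedMeanAuroc`, and `config`.
#' @export
runCrossModalBenchmark <- function(seed = 1, config = NULL,
                                   includePermuted = TRUE) {
  cfg <- if (is.null(config)) benchmarkConfig(seed) else config
  screen <- generateScreen(cfg$screen)
  cp <- cpProfiles(screen)
  tx <- txProfiles(screen)
  compounds <- screenCompounds(screen)
  bio <- screenBioactivity(screen)
  split <- scaffoldSplit(compounds, ratios = c(0.7, 0.1, 0.2),
                         seed = cfg$splitSeed)
  pairs <- buildPairs(cp, tx)
  clModel <- trainContrastive(pairs, cp, tx, split, cfg$cl)

  # --- clustering on the test split -----------------------------------
  testCmp <- compoundsInSplit(split, "test")
  cpTest <- cp[, compoundIds(cp) %in% testCmp]
  rawTest <- profileValues(cpTest)
  embTest <- embedProfiles(clModel, rawTest)
  cmpTest <- unname(compoundIds(cpTest))
  # leave-one-out voting: with the nearest-neighbour tie-break the
  # self-inclusive mode lets every point's own vote win singleton ties,
  # which saturates the replicate score in the high-noise regime
  replicateAcc <- c(
    cp = replicateClusteringEval(rawTest, cmpTest, excludeSelf = TRUE,
                                 featureType = "CP")@knnAccuracy,
    cl = replicateClusteringEval(embTest, cmpTest, excludeSelf = TRUE,
                                 featureType = "CL Emb")@knnAccuracy)
  moa <- stats::setNames(compounds$moa, compounds$compound_id)
  rawAggT <- rowGroupAggregate(rawTest, cmpTest)
  embAggT <- rowGroupAggregate(embTest, cmpTest)
  moaAcc <- c(
    cp = moaClusteringEval(rawAggT, moa[rownames(rawAggT)], topM = 9,
                           excludeSelf = TRUE,
                           featureType = "CP")@knnAccuracy,
    cl = moaClusteringEval(embAggT, moa[rownames(embAggT)], topM = 9,
                           excludeSelf = TRUE,
                           featureType = "CL Emb")@knnAccuracy)

  # --- multitask bioactivity, identical protocol per feature type -----
  rawAll <- profileValues(cp)
  featCp <- rowGroupAggregate(rawAll, unname(compoundIds(cp)))
  featCl <- rowGroupAggregate(embedProfiles(clModel, rawAll),
                              unname(compoundIds(cp)))
  featTx <- profileValues(tx)
  rownames(featTx) <- unname(compoundIds(tx))
  trainTasks <- filterTrainTasks(bio, split)
  evalTasks <- intersect(filterEvalTasks(bio, split), trainTasks)
  featureSets <- list(cp = featCp, cl = featCl, tx = featTx)
  taskMetrics <- lapply(featureSets, function(f) {
    model <- trainMultitask(f, bio, split, cfg$mt, taskIds = trainTasks)
    stopifnot(identical(model@config, cfg$mt))  # protocol invariance
    scoreTasks(model, f, bio, split, taskIds = evalTasks)
  })
  subsetTasks <- selectTxStrongCpWeak(taskMetrics$tx, taskMetrics$cp)
  subMean <- function(m) mean(m$auroc[m$task_id %in% subsetTasks])
  subsetMeanAuroc <- vapply(taskMetrics, subMean, 0)
  meanAuroc <- vapply(taskMetrics, function(m) mean(m$auroc), 0)
  meanRiptop <- vapply(taskMetrics, function(m) mean(m$riptop_auprc), 0)
  clVsCp <- compareFeatureTypes(taskMetrics$cl, taskMetrics$cp,
                                metric = "auroc",
                                nameA = "CL Emb", nameB = "CP")

  # --- label-permuted control -----------------------------------------
  permutedMeanAuroc <- NA_real_
  if (includePermuted) {
    lab <- bioactivityLabels(bio)
    permLab <- withSeed(cfg$splitSeed + 1L,
                        lab[sample.int(nrow(lab)), , drop = FALSE])
    rownames(permLab) <- rownames(lab)
    permBio <- BioactivityMatrix(permLab, family = taskFamily(bio))
    permTasks <- intersect(filterEvalTasks(permBio, split),
                           filterTrainTasks(permBio, split))
    permModel <- trainMultitask(featCp, permBio, split, cfg$mt,
                                taskIds = permTasks)
    permMetrics <- scoreTasks(permModel, featCp, permBio, split,
                              taskIds = permTasks)
    permutedMeanAuroc <- mean(permMetrics$auroc)
  }

  list(replicateAcc = replicateAcc, moaAcc = moaAcc,
       taskMetrics = taskMetrics, subsetTasks = subsetTasks,
       subsetMeanAuroc = subsetMeanAuroc, meanAuroc = meanAuroc,
       meanRiptop = meanRiptop, clVsCp = clVsCp,
       permutedMeanAuroc = permutedMeanAuroc, config = cfg)
}
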