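#' Create a synthetic-screen configuration
#'
#' Defaults describe a mid-size screen in the conventions of the real
#' data: ~800 Z-scored morphological features per Cell Painting replicate,
#' gene-level Z-scored transcriptomics with one profile per compound,
#' several CP replicates per compound, mechanism-of-action cluster
#' structure shared across modalities, scaffold groups independent of MoA,
#' and bioactivity tasks a configurable share of which is visible only to
#' the transcriptomic modality.
#'
#' @param nCompounds number of compounds (default 500).
#' @param nMoaClasses number of mechanism-of-action classes (default 10).
#' @param dCp,dTx feature dimensions (defaults 800 / 4000).
#' @param dLatentShared latent dimensions seen by both modalities
#'   (default 10).
#' @param dLatentTxOnly latent dimensions seen only by TX (default 5).
#' @param replicateCountRange inclusive range of CP replicates per
#'   compound, drawn uniformly (default `c(2, 4)`).
#' @param cpNoiseSd,txNoiseSd additive feature noise in Z-score units
#'   (defaults 1 / 0.5 — CP replicates are the noisier modality).
#' @param moaCentroidSd,moaWithinSd between-class / within-class latent
#'   spread (defaults 3 / 1, well-separated MoA centroids).
#' @param scaffoldMeanSize mean scaffold-group size; sizes are
#'   1 + Geometric (default 3).
#' @param nTasks number of bioactivity tasks (default 30).
#' @param fracTxOnlyTasks share of tasks whose score reads only TX-only
#'   latent dimensions (default 0.3).
#' @param taskMixing dimensions read by the remaining tasks: `"shared"`
#'   (default) restricts them to the shared latent, so modality
#'   visibility is all-or-nothing per task; `"full"` lets them read the
#'   whole latent in standardised coordinates, giving a continuum of
#'   tasks whose Cell Painting visibility varies with the random weight
#'   draw.
#' @param labelDensity probability that a label is observed (default 0.9).
#' @param taskNoiseSd noise on the latent task score before thresholding
#'   (default 0.5).
#' @param taskFamilies protein-family labels recycled over tasks.
#' @param seed integer seed.
#' @return a validated [ScreenConfig-class].
#' @export
screenConfig <- function(nCompounds = 500, nMoaClasses = 10,
                         dCp = 800, dTx = 4000,
                         dLatentShared = 10, dLatentTxOnly = 5,
                         replicateCountRange = c(2, 4),
                         cpNoiseSd = 1, txNoiseSd = 0.5,
                         moaCentroidSd = 3, moaWithinSd = 1,
                         scaffoldMeanSize = 3,
                         nTasks = 30, fracTxOnlyTasks = 0.3,
                         taskMixing = c("shared", "full"),
                         labelDensity = 0.9, taskNoiseSd = 0.5,
                         taskFamilies = c("Cell Proliferation",
                                          "GPCR Transmembrane Receptor",
                                          "Hydrolase", "Ion Channel",
                                          "Transferase (Kinase)"),
                         seed = 1) {
  taskMixing <- match.arg(taskMixing)
  new("ScreenConfig",
      nCompounds = as.integer(nCompounds),
      nMoaClasses = as.integer(nMoaClasses),
      dCp = as.integer(dCp), dTx = as.integer(dTx),
      dLatentShared = as.integer(dLatentShared),
      dLatentTxOnly = as.integer(dLatentTxOnly),
      replicateCountRange = as.integer(replicateCountRange),
      cpNoiseSd = cpNoiseSd, txNoiseSd = txNoiseSd,
      moaCentroidSd = moaCentroidSd, moaWithinSd = moaWithinSd,
      scaffoldMeanSize = scaffoldMeanSize,
      nTasks = as.integer(nTasks), fracTxOnlyTasks = fracTxOnlyTasks,
      taskMixing = taskMixing,
      labelDensity = labelDensity, taskNoiseSd = taskNoiseSd,
      taskFamilies = taskFamilies, seed = as.integer(seed))
}

#' Sample compounds, MoA classes, scaffolds and latent vectors
#'
#' Each compound receives an MoA class, a latent vector equal to its class
#' centroid plus a within-class perturbation on the shared dimensions plus
#' independent TX-only dimensions, and a scaffold key drawn from the
#' configured geometric group-size distribution (independent of MoA).
#'
#' @param cfg a [ScreenConfig-class].
#' @return list with `compounds` (`data.frame`: `compound_id`, `smiles`,
#'   `scaffold_key`, `moa`) and `latents` (compound-by-latent matrix,
#'   shared dimensions first).
#' @export
sampleCompounds <- function(cfg) {
  validObject(cfg)
  withSeed(cfg@seed, {
    n <- cfg@nCompounds
    nMoa <- cfg@nMoaClasses
    ids <- sprintf("CPD%05d", seq_len(n))
    moaLevels <- sprintf("MOA%02d", seq_len(nMoa))
    # every class occupied, remainder uniform, order shuffled
    moaIdx <- sample(c(seq_len(nMoa),
                       if (n > nMoa) sample.int(nMoa, n - nMoa,
                                                replace = TRUE)))
    centroids <- matrix(stats::rnorm(nMoa * cfg@dLatentShared,
                                     sd = cfg@moaCentroidSd),
                        nMoa, cfg@dLatentShared)
    shared <- centroids[moaIdx, , drop = FALSE] +
      matrix(stats::rnorm(n * cfg@dLatentShared, sd = cfg@moaWithinSd),
             n, cfg@dLatentShared)
    txOnly <- matrix(stats::rnorm(n * cfg@dLatentTxOnly),
                     n, cfg@dLatentTxOnly)
    latents <- cbind(shared, txOnly)
    rownames(latents) <- ids
    colnames(latents) <- c(sprintf("shared%02d",
                                   seq_len(cfg@dLatentShared)),
                           if (cfg@dLatentTxOnly > 0)
                             sprintf("txonly%02d",
                                     seq_len(cfg@dLatentTxOnly)))
    # geometric scaffold-group sizes, assignment independent of MoA
    sizes <- integer(0)
    while (sum(sizes) < n)
      sizes <- c(sizes, 1L + stats::rgeom(max(64L, n %/% 2),
                                          prob = 1 / cfg@scaffoldMeanSize))
    sizes <- sizes[cumsum(sizes) - sizes < n]
    key <- rep(sprintf("SCAF%05d", seq_along(sizes)), times = sizes)[seq_len(n)]
    key <- key[sample.int(n)]
    list(compounds = data.frame(compound_id = ids,
                                smiles = NA_character_,
                                scaffold_key = key,
                                moa = moaLevels[moaIdx],
                                stringsAsFactors = FALSE),
         latents = latents)
  })
}

#' Render CP and TX profile matrices from compound latents
#'
#' The single TX profile of a compound is a fixed linear image of its full
#' latent vector plus Gaussian noise; every CP replicate is a fixed linear
#' image of the shared latent dimensions only, plus independent noise —
#' encoding the premise that part of the biology is visible to
#' transcriptomics but not to Cell Painting. Loading matrices are fixed by
#' the configuration seed.
#'
#' @param latents compound-by-latent matrix from [sampleCompounds()].
#' @param cfg the same [ScreenConfig-class].
#' @return list with `cp` and `tx` ([ProfileMatrix-class]) and the
#'   loading matrices `cpLoading`, `txLoading`.
#' @export
renderProfiles <- function(latents, cfg) {
  validObject(cfg)
  .assert(is.matrix(latents) &&
          ncol(latents) == cfg@dLatentShared + cfg@dLatentTxOnly,
          "'latents' does not match the configuration dimensions")
  withSeed(cfg@seed + 1L, {
    n <- nrow(latents)
    dS <- cfg@dLatentShared
    dL <- ncol(latents)
    cpLoading <- matrix(stats::rnorm(dS * cfg@dCp, sd = 1 / sqrt(dS)),
                        dS, cfg@dCp)
    txLoading <- matrix(stats::rnorm(dL * cfg@dTx, sd = 1 / sqrt(dL)),
                        dL, cfg@dTx)
    cpFeat <- sprintf("cp%04d", seq_len(cfg@dCp))
    txFeat <- sprintf("g%05d", seq_len(cfg@dTx))
    colnames(cpLoading) <- cpFeat
    colnames(txLoading) <- txFeat
    txVals <- latents %*% txLoading +
      matrix(stats::rnorm(n * cfg@dTx, sd = cfg@txNoiseSd), n, cfg@dTx)
    tx <- ProfileMatrix(txVals, compoundIds = rownames(latents),
                        modality = "TX", rowIds = rownames(latents),
                        featureNames = txFeat)
    lo <- cfg@replicateCountRange[1]
    hi <- cfg@replicateCountRange[2]
    counts <- if (hi > lo) sample(lo:hi, n, replace = TRUE)
              else rep(lo, n)
    ridx <- rep(seq_len(n), times = counts)
    cpVals <- latents[ridx, seq_len(dS), drop = FALSE] %*% cpLoading +
      matrix(stats::rnorm(length(ridx) * cfg@dCp, sd = cfg@cpNoiseSd),
             length(ridx), cfg@dCp)
    repNo <- unlist(lapply(counts, seq_len), use.names = FALSE)
    cpIds <- sprintf("%s_r%d", rownames(latents)[ridx], repNo)
    cp <- ProfileMatrix(cpVals, compoundIds = rownames(latents)[ridx],
                        modality = "CP", rowIds = cpIds,
                        featureNames = cpFeat)
    list(cp = cp, tx = tx, cpLoading = cpLoading, txLoading = txLoading)
  })
}

#' Sample the binarised bioactivity label matrix
#'
#' Each task thresholds a noisy linear score of the compound latent at the
#' task's median score (so the positive rate is ~0.5). A
#' `fracTxOnlyTasks` share of tasks weight only the TX-only latent
#' dimensions, so transcriptomics can excel where Cell Painting cannot.
#' Labels are observed with probability `labelDensity`; protein-family
#' annotations are assigned round-robin.
#'
#' @param latents compound-by-latent matrix from [sampleCompounds()].
#' @param cfg the same [ScreenConfig-class].
#' @return list with `bioactivity` ([BioactivityMatrix-class]),
#'   `taskWeights` (latent-by-task matrix), `taskTxOnly` (logical),
#'   `taskThresholds` (numeric).
#' @export
sampleBioactivity <- function(latents, cfg) {
  validObject(cfg)
  withSeed(cfg@seed + 2L, {
    n <- nrow(latents)
    dS <- cfg@dLatentShared
    dT <- cfg@dLatentTxOnly
    nT <- cfg@nTasks
    nTxOnly <- as.integer(round(cfg@fracTxOnlyTasks * nT))
    .assert(nTxOnly == 0 || dT > 0,
            "TX-only tasks require dLatentTxOnly > 0")
    taskIds <- sprintf("TASK%03d", seq_len(nT))
    txOnlyFlag <- seq_len(nT) <= nTxOnly
    # standardised coordinates for "full" mixing, so every latent
    # dimension contributes comparable score variance regardless of the
    # MoA spread configured for the shared block
    dimSd <- c(rep(sqrt(cfg@moaCentroidSd^2 + cfg@moaWithinSd^2), dS),
               rep(1, dT))
    W <- matrix(0, dS + dT, nT, dimnames = list(colnames(latents), taskIds))
    for (j in seq_len(nT)) {
      dims <- if (txOnlyFlag[j]) dS + seq_len(dT)
              else if (cfg@taskMixing == "full") seq_len(dS + dT)
              else seq_len(dS)
      w <- stats::rnorm(length(dims))
      if (cfg@taskMixing == "full" && !txOnlyFlag[j])
        w <- w / dimSd[dims]
      W[dims, j] <- w / sqrt(sum(w^2))
    }
    scores <- latents %*% W +
      matrix(stats::rnorm(n * nT, sd = cfg@taskNoiseSd), n, nT)
    thresholds <- apply(scores, 2, stats::median)
    lab <- (scores > rep(thresholds, each = n)) * 1
    observed <- matrix(stats::runif(n * nT) < cfg@labelDensity, n, nT)
    lab[!observed] <- NA_real_
    dimnames(lab) <- list(rownames(latents), taskIds)
    empty <- colSums(!is.na(lab)) == 0
    if (any(empty)) {
      warning(sum(empty), " task(s) had no observed label and were dropped")
      lab <- lab[, !empty, drop = FALSE]
      W <- W[, !empty, drop = FALSE]
      txOnlyFlag <- txOnlyFlag[!empty]
      thresholds <- thresholds[!empty]
      taskIds <- taskIds[!empty]
    }
    fam <- stats::setNames(rep_len(cfg@taskFamilies, length(taskIds)),
                           taskIds)
    list(bioactivity = BioactivityMatrix(lab, family = fam),
         taskWeights = W,
         taskTxOnly = stats::setNames(txOnlyFlag, taskIds),
         taskThresholds = stats::setNames(thresholds, taskIds))
  })
}

#' Generate a complete synthetic paired screen
#'
#' Composes [sampleCompounds()], [renderProfiles()] and
#' [sampleBioactivity()]; fully reproducible from the configuration (each
#' stage is seeded from `cfg@seed`).
#'
#' @param cfg a [ScreenConfig-class].
#' @return a [SyntheticScreen-class].
#' @examples
#' scr <- generateScreen(screenConfig(nCompounds = 20, nMoaClasses = 4,
#'                                    dCp = 12, dTx = 20, nTasks = 5,
#'                                    seed = 7))
#' scr
#' @export
generateScreen <- function(cfg) {
  validObject(cfg)
  smp <- sampleCompounds(cfg)
  prof <- renderProfiles(smp$latents, cfg)
  bio <- sampleBioactivity(smp$latents, cfg)
  new("SyntheticScreen",
      cp = prof$cp, tx = prof$tx, compounds = smp$compounds,
      bioactivity = bio$bioactivity, latents = smp$latents,
      generator = list(cpLoading = prof$cpLoading,
                       txLoading = prof$txLoading,
                       taskWeights = bio$taskWeights,
                       taskTxOnly = bio$taskTxOnly,
                       taskThresholds = bio$taskThresholds),
      config = cfg)
}

#' @describeIn SyntheticScreen accessors for the generated components.
#' @param x a `SyntheticScreen`.
#' @export
cpProfiles <- function(x) { .assert(is(x, "SyntheticScreen"), "not a SyntheticScreen"); x@cp }

#' @rdname SyntheticScreen-class
#' @export
txProfiles <- function(x) { .assert(is(x, "SyntheticScreen"), "not a SyntheticScreen"); x@tx }

#' @rdname SyntheticScreen-class
#' @export
screenCompounds <- function(x) { .assert(is(x, "SyntheticScreen"), "not a SyntheticScreen"); x@compounds }

#' @rdname SyntheticScreen-class
#' @export
screenBioactivity <- function(x) { .assert(is(x, "SyntheticScreen"), "not a SyntheticScreen"); x@bioactivity }

#' @rdname SyntheticScreen-class
#' @export
screenLatents <- function(x) { .assert(is(x, "SyntheticScreen"), "not a SyntheticScreen"); x@latents }

#' @rdname SyntheticScreen-class
#' @export
screenGenerator <- function(x) { .assert(is(x, "SyntheticScreen"), "not a SyntheticScreen"); x@generator }

#' @export
setMethod("show", "SyntheticScreen", function(object) {
  cat(sprintf(
    "SyntheticScreen: %d compounds, %d CP replicates x %d features, TX %d genes, %d tasks\n",
    nrow(object@latents), ncol(object@cp), nrow(object@cp),
    nrow(object@tx), ncol(bioactivityLabels(object@bioactivity))))
})

#' Write all screen components as plain-text files
#'
#' Writes `cp.csv` and `tx.csv` (wide profile matrices), `compounds.csv`,
#' `bioactivity.csv` (sparse triplets), `tasks.csv` (family annotation)
#' and `latents.csv` into a directory, in the formats the readers of this
#' package consume.
#'
#' @param x a [SyntheticScreen-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeScreen <- function(x, dir) {
  .assert(is(x, "SyntheticScreen"), "'x' must be a SyntheticScreen")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeProfileMatrix(x@cp, file.path(dir, "cp.csv"))
  writeProfileMatrix(x@tx, file.path(dir, "tx.csv"))
  data.table::fwrite(x@compounds, file.path(dir, "compounds.csv"))
  writeBioactivityMatrix(x@bioactivity, file.path(dir, "bioactivity.csv"),
                         familyPath = file.path(dir, "tasks.csv"))
  lat <- data.table::data.table(compound_id = rownames(x@latents))
  data.table::fwrite(cbind(lat, data.table::as.data.table(x@latents)),
                     file.path(dir, "latents.csv"))
  invisible(dir)
}
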