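#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame
NULL

#' ProfileMatrix: Z-scored perturbation profiles for one modality
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one assay
#' (`"profile"`) of Z-scored features (rows) by profiles (columns), plus a
#' `modality` tag. Columns are replicate measurements: for Cell Painting
#' (`"CP"`) a compound may have several columns; for transcriptomics
#' (`"TX"`) exactly one column per compound. `colData` carries the
#' `compound_id` of every column. Values are assumed already normalised
#' against vehicle control (robust Z-scores), so 0 means control-like.
#'
#' @slot modality either `"CP"` or `"TX"`.
#' @seealso [ProfileMatrix()], [profileValues()], [buildPairs()]
#' @export
setClass("ProfileMatrix",
  contains = "SummarizedExperiment",
  representation(modality = "character")
)

setValidity("ProfileMatrix", function(object) {
  msg <- character()
  if (length(object@modality) != 1L || !object@modality %in% c("CP", "TX"))
    msg <- c(msg, "modality must be one of 'CP', 'TX'")
  if (!"profile" %in% assayNames(object))
    msg <- c(msg, "assay 'profile' is required")
  else {
    a <- assay(object, "profile")
    if (!is.numeric(a)) msg <- c(msg, "profile values must be numeric")
    else if (anyNA(a) || !all(is.finite(a)))
      msg <- c(msg, "profile values must be finite with no missing entries")
  }
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "profile (column) identifiers must be present and unique")
  if (!"compound_id" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain 'compound_id'")
  else if (length(msg) == 0L && object@modality == "TX" &&
           anyDuplicated(colData(object)$compound_id))
    msg <- c(msg, "TX profiles must have exactly one row per compound")
  if (length(msg)) msg else TRUE
})

#' PairSet: matched (CP replicate, TX) pretraining pairs
#'
#' One pair per Cell Painting replicate of every compound present in both
#' modalities; each pair links a CP column identifier to the compound whose
#' single TX profile it is matched with.
#'
#' @slot pairs `data.frame` with columns `cp_row_id`, `compound_id`.
#' @slot nDroppedCp number of CP profiles discarded because their compound
#'   has no TX profile.
#' @slot nDroppedTx number of TX profiles discarded because their compound
#'   has no CP profile.
#' @seealso [buildPairs()]
#' @export
setClass("PairSet",
  representation(pairs = "data.frame", nDroppedCp = "integer",
                 nDroppedTx = "integer")
)

setValidity("PairSet", function(object) {
  p <- object@pairs
  if (!all(c("cp_row_id", "compound_id") %in% colnames(p)))
    return("pairs needs columns 'cp_row_id' and 'compound_id'")
  if (anyDuplicated(p$cp_row_id))
    return("each CP replicate may appear in at most one pair")
  TRUE
})

#' SplitAssignment: scaffold-grouped train/valid/test partition
#'
#' Maps every compound to exactly one of `train`, `valid`, `test`, with all
#' compounds sharing a Murcko scaffold kept in the same set.
#'
#' @slot assignment named character vector (names are compound identifiers,
#'   values in `train`/`valid`/`test`).
#' @slot ratios target proportions, e.g. `c(0.7, 0.1, 0.2)`.
#' @slot seed integer seed that produced the assignment.
#' @seealso [scaffoldSplit()], [compoundsInSplit()]
#' @export
setClass("SplitAssignment",
  representation(assignment = "character", ratios = "numeric",
                 seed = "integer")
)

setValidity("SplitAssignment", function(object) {
  msg <- character()
  if (is.null(names(object@assignment)) ||
      anyDuplicated(names(object@assignment)))
    msg <- c(msg, "assignment must be named by unique compound identifiers")
  if (!all(object@assignment %in% c("train", "valid", "test")))
    msg <- c(msg, "assignment values must be train/valid/test")
  if (length(object@ratios) != 3L || abs(sum(object@ratios) - 1) > 1e-8)
    msg <- c(msg, "ratios must be 3 proportions summing to 1")
  if (length(msg)) msg else TRUE
})

#' BioactivityMatrix: sparse binary compound-by-task labels
#'
#' Binarised bioactivity outcomes with missingness: entry `(i, j)` is 1
#' (active), 0 (inactive) or `NA` (not assayed) for compound `i` on task
#' `j`. Tasks may carry a protein-target-family annotation.
#'
#' @slot labels numeric matrix in \{0, 1, NA\}; rownames are compound
#'   identifiers, colnames task identifiers.
#' @slot family named character vector mapping task identifiers to protein
#'   target families (may be empty).
#' @seealso [readBioactivityMatrix()], [filterTrainTasks()]
#' @export
setClass("BioactivityMatrix",
  representation(labels = "matrix", family = "character")
)

setValidity("BioactivityMatrix", function(object) {
  lab <- object@labels
  msg <- character()
  if (is.null(rownames(lab)) || is.null(colnames(lab)))
    msg <- c(msg, "labels must have compound rownames and task colnames")
  obs <- lab[!is.na(lab)]
  if (!all(obs %in% c(0, 1)))
    msg <- c(msg, "observed labels must be 0 or 1")
  if (ncol(lab) > 0 && any(colSums(!is.na(lab)) == 0))
    msg <- c(msg, "every task needs at least one observed label")
  if (length(object@family) &&
      !all(names(object@family) %in% colnames(lab)))
    msg <- c(msg, "family annotations must name known tasks")
  if (length(msg)) msg else TRUE
})

#' ScreenConfig: parameters of the synthetic paired screen
#'
#' Stated world for the linear-Gaussian simulator: compounds carry a latent
#' vector made of shared dimensions (visible to both modalities) plus
#' TX-only dimensions (visible to transcriptomics alone). Cell Painting
#' replicates are noisy linear images of the shared latent; the single TX
#' profile is a less noisy linear image of the full latent. Bioactivity
#' tasks threshold noisy linear scores of the latent, a `fracTxOnlyTasks`
#' share of them reading only the TX-only dimensions.
#'
#' @slot nCompounds,nMoaClasses number of compounds / MoA classes.
#' @slot dCp,dTx feature dimensions (defaults 800 morphological features,
#'   4000 genes).
#' @slot dLatentShared,dLatentTxOnly latent dimensions.
#' @slot replicateCountRange integer range of CP replicates per compound.
#' @slot cpNoiseSd,txNoiseSd additive feature noise (Z-score units).
#' @slot moaCentroidSd,moaWithinSd between/within MoA-class latent spread.
#' @slot scaffoldMeanSize mean scaffold-group size (geometric distribution).
#' @slot nTasks,fracTxOnlyTasks,labelDensity,taskNoiseSd bioactivity layer.
#' @slot taskFamilies protein-family labels recycled over tasks.
#' @slot seed integer seed.
#' @seealso [screenConfig()], [generateScreen()]
#' @export
setClass("ScreenConfig",
  representation(
    nCompounds = "integer", nMoaClasses = "integer",
    dCp = "integer", dTx = "integer",
    dLatentShared = "integer", dLatentTxOnly = "integer",
    replicateCountRange = "integer",
    cpNoiseSd = "numeric", txNoiseSd = "numeric",
    moaCentroidSd = "numeric", moaWithinSd = "numeric",
    scaffoldMeanSize = "numeric",
    nTasks = "integer", fracTxOnlyTasks = "numeric",
    taskMixing = "character",
    labelDensity = "numeric", taskNoiseSd = "numeric",
    taskFamilies = "character", seed = "integer"
  )
)

setValidity("ScreenConfig", function(object) {
  msg <- character()
  pos <- c(nCompounds = object@nCompounds, nMoaClasses = object@nMoaClasses,
           dCp = object@dCp, dTx = object@dTx,
           dLatentShared = object@dLatentShared, nTasks = object@nTasks)
  if (any(pos < 1)) msg <- c(msg, "all dimensions must be positive")
  if (object@dLatentTxOnly < 0) msg <- c(msg, "dLatentTxOnly must be >= 0")
  if (object@nMoaClasses > object@nCompounds)
    msg <- c(msg, "nMoaClasses cannot exceed nCompounds")
  if (length(object@replicateCountRange) != 2L ||
      object@replicateCountRange[1] < 1L ||
      object@replicateCountRange[2] < object@replicateCountRange[1])
    msg <- c(msg, "replicateCountRange must be an increasing pair >= 1")
  if (object@cpNoiseSd < 0 || object@txNoiseSd < 0 || object@taskNoiseSd < 0)
    msg <- c(msg, "noise standard deviations must be >= 0")
  if (object@fracTxOnlyTasks < 0 || object@fracTxOnlyTasks > 1)
    msg <- c(msg, "fracTxOnlyTasks must lie in [0, 1]")
  if (object@labelDensity <= 0 || object@labelDensity > 1)
    msg <- c(msg, "labelDensity must lie in (0, 1]")
  if (!object@taskMixing %in% c("shared", "full"))
    msg <- c(msg, "taskMixing must be 'shared' or 'full'")
  if (object@scaffoldMeanSize < 1)
    msg <- c(msg, "scaffoldMeanSize must be >= 1")
  if (length(msg)) msg else TRUE
})

#' SyntheticScreen: generated paired CP/TX screen with ground truth
#'
#' Bundle produced by [generateScreen()]: both profile modalities, the
#' compound table (scaffold keys and MoA classes), the bioactivity label
#' matrix, the true compound latents, and the generator internals (loading
#' matrices, task weights) that tests use as ground truth.
#'
#' @slot cp,tx [ProfileMatrix-class] objects.
#' @slot compounds `data.frame` with `compound_id`, `smiles`,
#'   `scaffold_key`, `moa`.
#' @slot bioactivity [BioactivityMatrix-class].
#' @slot latents compound-by-latent matrix (shared dims first).
#' @slot generator list with `cpLoading`, `txLoading`, `taskWeights`,
#'   `taskTxOnly`, `taskThresholds`.
#' @slot config the [ScreenConfig-class] that produced the screen.
#' @export
setClass("SyntheticScreen",
  representation(cp = "ProfileMatrix", tx = "ProfileMatrix",
                 compounds = "data.frame", bioactivity = "BioactivityMatrix",
                 latents = "matrix", generator = "list",
                 config = "ScreenConfig")
)

#' CLConfig: contrastive pretraining hyperparameters
#'
#' Defaults follow the published architecture: CP encoder hidden layers
#' `[1024, 1024, 1024]`, TX encoder `[4096, 4096, 4096]`, encoder output
#' 512, linear projection to 256, 10\% input-feature masking. The softmax
#' temperature is a fixed configurable scalar (default 0.07).
#'
#' @slot cpHiddenSizes,txHiddenSizes encoder hidden-layer widths.
#' @slot encoderOutputDim embedding width kept after pretraining.
#' @slot projectionDim contrastive-space width (projection head, discarded
#'   at embedding time).
#' @slot temperature InfoNCE softmax temperature (> 0).
#' @slot maskRate fraction of input features zeroed per profile per batch.
#' @slot batchSize,epochs,learningRate optimisation parameters (Adam).
#' @slot seed integer seed.
#' @seealso [clConfig()], [trainContrastive()]
#' @export
setClass("CLConfig",
  representation(cpHiddenSizes = "integer", txHiddenSizes = "integer",
                 encoderOutputDim = "integer", projectionDim = "integer",
                 temperature = "numeric", maskRate = "numeric",
                 batchSize = "integer", epochs = "integer",
                 learningRate = "numeric", seed = "integer")
)

setValidity("CLConfig", function(object) {
  msg <- character()
  if (object@temperature <= 0) msg <- c(msg, "temperature must be > 0")
  if (object@maskRate < 0 || object@maskRate >= 1)
    msg <- c(msg, "maskRate must lie in [0, 1)")
  if (any(c(object@cpHiddenSizes, object@txHiddenSizes,
            object@encoderOutputDim, object@projectionDim,
            object@batchSize, object@epochs) < 1))
    msg <- c(msg, "layer sizes, batch size and epochs must be positive")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' BAEConfig: bimodal autoencoder hyperparameters
#'
#' Defaults follow the published architecture: CP encoder hidden layers
#' `[1024, 512, 512]` into a 512-dimensional embedding, CP decoder
#' `[512, 512, 1024]`, TX decoder `[1024, 2048, 4096]`, with 10\% masking
#' of the CP input (a masked autoencoder; targets stay unmasked).
#'
#' @slot encoderHidden,cpDecoderHidden,txDecoderHidden hidden-layer widths.
#' @slot embeddingDim latent width (the learned embedding).
#' @slot maskRate fraction of CP input features zeroed per profile.
#' @slot batchSize,epochs,learningRate optimisation parameters (Adam).
#' @slot reduce `"mean"` (average over rows and features per modality) or
#'   `"sum"` (raw summed squared residuals, as printed).
#' @slot seed integer seed.
#' @seealso [baeConfig()], [trainBAE()]
#' @export
setClass("BAEConfig",
  representation(encoderHidden = "integer", embeddingDim = "integer",
                 cpDecoderHidden = "integer", txDecoderHidden = "integer",
                 maskRate = "numeric", batchSize = "integer",
                 epochs = "integer", learningRate = "numeric",
                 reduce = "character", seed = "integer")
)

setValidity("BAEConfig", function(object) {
  msg <- character()
  if (object@embeddingDim < 1) msg <- c(msg, "embeddingDim must be positive")
  if (object@maskRate < 0 || object@maskRate >= 1)
    msg <- c(msg, "maskRate must lie in [0, 1)")
  if (!object@reduce %in% c("mean", "sum"))
    msg <- c(msg, "reduce must be 'mean' or 'sum'")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' MultitaskConfig: multitask bioactivity classifier hyperparameters
#'
#' Defaults are the published setting: a 3-layer MLP with hidden size 256,
#' Adam with learning rate 1e-4 and weight decay 1e-5, batch size 128, 100
#' epochs, dropout 0.3, cosine-annealing warm restarts every 10 epochs.
#' Final-epoch weights are used (no early stopping).
#'
#' @slot hiddenSize,nLayers hidden width and number of hidden layers.
#' @slot learningRate,weightDecay,batchSize,epochs optimisation parameters.
#' @slot dropout dropout probability on hidden activations.
#' @slot schedulerPeriod warm-restart period in epochs.
#' @slot seed integer seed.
#' @seealso [multitaskConfig()], [trainMultitask()]
#' @export
setClass("MultitaskConfig",
  representation(hiddenSize = "integer", nLayers = "integer",
                 learningRate = "numeric", weightDecay = "numeric",
                 batchSize = "integer", epochs = "integer",
                 dropout = "numeric", schedulerPeriod = "integer",
                 seed = "integer")
)

setValidity("MultitaskConfig", function(object) {
  msg <- character()
  if (any(c(object@hiddenSize, object@nLayers, object@batchSize,
            object@epochs, object@schedulerPeriod) < 1))
    msg <- c(msg, "sizes, epochs and scheduler period must be positive")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must lie in [0, 1)")
  if (object@learningRate <= 0 || object@weightDecay < 0)
    msg <- c(msg, "learningRate must be > 0 and weightDecay >= 0")
  if (length(msg)) msg else TRUE
})

#' CLModel: trained contrastive two-encoder model
#'
#' @slot cpEncoder,txEncoder,cpProjection,txProjection parameter lists of
#'   the two MLP encoders and their linear projection heads.
#' @slot config the [CLConfig-class] used for training.
#' @slot history per-epoch `data.frame` (`epoch`, `train_loss`,
#'   `valid_loss`).
#' @slot bestEpoch epoch whose validation loss selected the weights.
#' @slot cpFeatures,txFeatures feature names seen at training time.
#' @seealso [trainContrastive()], [embedProfiles()]
#' @export
setClass("CLModel",
  representation(cpEncoder = "list", txEncoder = "list",
                 cpProjection = "list", txProjection = "list",
                 config = "CLConfig", history = "data.frame",
                 bestEpoch = "integer",
                 cpFeatures = "character", txFeatures = "character")
)

#' BAEModel: trained bimodal autoencoder
#'
#' @slot encoder,cpDecoder,txDecoder parameter lists (CP encoder, CP
#'   decoder, TX decoder).
#' @slot config the [BAEConfig-class] used for training.
#' @slot history per-epoch `data.frame` (`epoch`, `train_loss`,
#'   `valid_loss`).
#' @slot bestEpoch epoch whose validation loss selected the weights.
#' @slot cpFeatures,txFeatures feature names seen at training time.
#' @seealso [trainBAE()], [embedProfiles()]
#' @export
setClass("BAEModel",
  representation(encoder = "list", cpDecoder = "list", txDecoder = "list",
                 config = "BAEConfig", history = "data.frame",
                 bestEpoch = "integer",
                 cpFeatures = "character", txFeatures = "character")
)

#' MultitaskModel: trained multitask bioactivity classifier
#'
#' @slot net parameter list of the MLP (one sigmoid output per task).
#' @slot taskIds tasks modelled, in output order.
#' @slot features input feature names seen at training time.
#' @slot config the [MultitaskConfig-class] used for training.
#' @slot history per-epoch `data.frame` (`epoch`, `train_loss`, `lr`).
#' @slot standardization per-feature `center`/`scale` learned on the
#'   training compounds and re-applied at prediction time.
#' @seealso [trainMultitask()], [scoreTasks()]
#' @export
setClass("MultitaskModel",
  representation(net = "list", taskIds = "character",
                 features = "character", config = "MultitaskConfig",
                 history = "data.frame", standardization = "list")
)

#' ClusterEvalResult: kNN-accuracy cluster quality record
#'
#' @slot featureType free-text name of the evaluated feature type.
#' @slot task `"replicates"` or `"moa"`.
#' @slot knnAccuracy fraction in \[0, 1\].
#' @slot k neighbour count.
#' @slot nPoints,nClasses evaluated points and distinct labels.
#' @slot excludeSelf whether each point was removed from its own
#'   neighbourhood (leave-one-out) before voting.
#' @seealso [knnAccuracy()], [replicateClusteringEval()],
#'   [moaClusteringEval()]
#' @export
setClass("ClusterEvalResult",
  representation(featureType = "character", task = "character",
                 knnAccuracy = "numeric", k = "integer",
                 nPoints = "integer", nClasses = "integer",
                 excludeSelf = "logical")
)

#' ComparisonResult: paired Wilcoxon signed-rank comparison
#'
#' One-sided comparison of a per-task metric between two feature types,
#' pairing by task and dropping zero differences.
#'
#' @slot featureTypeA,featureTypeB feature-type names (alternative:
#'   A greater than B).
#' @slot metric metric compared (e.g. `"auroc"`).
#' @slot nTasks pairs retained after dropping zero differences.
#' @slot pValue one-sided p-value (`NA` when degenerate).
#' @slot medianDifference median of A minus B over retained pairs.
#' @slot degenerate `TRUE` when every paired difference was zero.
#' @slot method description of the distribution used (exact or normal
#'   approximation).
#' @seealso [compareFeatureTypes()]
#' @export
setClass("ComparisonResult",
  representation(featureTypeA = "character", featureTypeB = "character",
                 metric = "character", nTasks = "integer",
                 pValue = "numeric", medianDifference = "numeric",
                 degenerate = "logical", method = "character")
)
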