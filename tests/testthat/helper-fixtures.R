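# Small screens and toy profile objects shared across test files.

tinyScreen <- function(seed = 1, nCompounds = 60, nMoa = 5,
                       dCp = 24, dTx = 40, nTasks = 6,
                       labelDensity = 1, cpNoiseSd = 1, txNoiseSd = 0.3,
                       dLatentTxOnly = 2, fracTxOnlyTasks = 1 / 3,
                       replicateCountRange = c(2, 3), ...) {
  generateScreen(screenConfig(
    nCompounds = nCompounds, nMoaClasses = nMoa, dCp = dCp, dTx = dTx,
    dLatentShared = 4, dLatentTxOnly = dLatentTxOnly,
    replicateCountRange = replicateCountRange,
    cpNoiseSd = cpNoiseSd, txNoiseSd = txNoiseSd,
    nTasks = nTasks, fracTxOnlyTasks = fracTxOnlyTasks,
    labelDensity = labelDensity, seed = seed, ...))
}

toyProfile <- function(values, compounds, modality = "CP", ...) {
  ProfileMatrix(values, compoundIds = compounds, modality = modality, ...)
}

# deterministic random matrix
rmat <- function(n, d, seed = 1, sd = 1) {
  set.seed(seed)
  matrix(rnorm(n * d, sd = sd), n, d)
}
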