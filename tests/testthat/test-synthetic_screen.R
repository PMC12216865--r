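# Generator properties: determinism, latent geometry, modality asymmetry,
# Z-score marginals, bioactivity layer.

test_that("one compound per class when classes equal compounds", {
  smp <- sampleCompounds(screenConfig(nCompounds = 9, nMoaClasses = 9,
                                      dCp = 4, dTx = 6, seed = 2))
  expect_equal(sort(as.vector(table(smp$compounds$moa))), rep(1L, 9))
})

test_that("the screen is bit-identical for a fixed config", {
  cfg <- screenConfig(nCompounds = 40, nMoaClasses = 4, dCp = 10,
                      dTx = 14, nTasks = 5, seed = 77)
  s1 <- generateScreen(cfg)
  s2 <- generateScreen(cfg)
  expect_identical(profileValues(cpProfiles(s1)),
                   profileValues(cpProfiles(s2)))
  expect_identical(profileValues(txProfiles(s1)),
                   profileValues(txProfiles(s2)))
  expect_identical(screenCompounds(s1), screenCompounds(s2))
  expect_identical(bioactivityLabels(screenBioactivity(s1)),
                   bioactivityLabels(screenBioactivity(s2)))
  # byte-for-byte after serialisation
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
  # and composing the samplers equals the composed generator
  smp <- sampleCompounds(cfg)
  expect_identical(smp$latents, screenLatents(s1))
})

test_that("within-MoA latent distances stay below between-class distances", {
  smp <- sampleCompounds(screenConfig(nCompounds = 1000, nMoaClasses = 10,
                                      dCp = 4, dTx = 6,
                                      dLatentShared = 6, seed = 3))
  lat <- smp$latents[, 1:6]
  moa <- smp$compounds$moa
  D <- as.matrix(dist(lat))
  same <- outer(moa, moa, "==") & upper.tri(D)
  diff <- (!outer(moa, moa, "==")) & upper.tri(D)
  expect_lt(mean(D[same]), mean(D[diff]))
})

test_that("replicate structure follows the configured range and noise", {
  # zero CP noise: all replicates of a compound identical
  s0 <- tinyScreen(seed = 4, cpNoiseSd = 0, nCompounds = 20)
  v <- profileValues(cpProfiles(s0))
  cmp <- compoundIds(cpProfiles(s0))
  for (cc in unique(cmp)[1:5]) {
    rows <- v[cmp == cc, , drop = FALSE]
    expect_equal(max(stats::dist(rows)), 0)
  }
  # replicate counts within range
  cfg <- screenConfig(nCompounds = 100, nMoaClasses = 5, dCp = 8, dTx = 10,
                      replicateCountRange = c(2, 4), seed = 5)
  scr <- generateScreen(cfg)
  counts <- table(compoundIds(cpProfiles(scr)))
  expect_true(all(counts >= 2 & counts <= 4))
  nRows <- ncol(cpProfiles(scr))
  expect_true(nRows >= 200 && nRows <= 400)
  # pair count equals the brute-force per-compound recount
  ps <- buildPairs(cpProfiles(scr), txProfiles(scr))
  expect_equal(length(ps), sum(counts))
})

test_that("deterministic linear images when all noise is off", {
  cfg <- screenConfig(nCompounds = 15, nMoaClasses = 3, dCp = 6, dTx = 8,
                      dLatentShared = 3, dLatentTxOnly = 0,
                      fracTxOnlyTasks = 0,
                      cpNoiseSd = 0, txNoiseSd = 0, seed = 6)
  scr <- generateScreen(cfg)
  gen <- screenGenerator(scr)
  lat <- screenLatents(scr)
  expect_equal(unname(profileValues(txProfiles(scr))),
               unname(lat %*% gen$txLoading), tolerance = 1e-12)
  cpv <- profileValues(cpProfiles(scr))
  cmp <- compoundIds(cpProfiles(scr))
  expect_equal(unname(cpv),
               unname(lat[cmp, 1:3, drop = FALSE] %*% gen$cpLoading),
               tolerance = 1e-12)
})

test_that("same-compound CP/TX latent projections correlate across modalities", {
  for (seed in 0:2) {
    cfg <- screenConfig(nCompounds = 200, nMoaClasses = 8, dCp = 40,
                        dTx = 60, dLatentShared = 5, dLatentTxOnly = 2,
                        cpNoiseSd = 1, txNoiseSd = 0.3,
                        replicateCountRange = c(1, 1), seed = seed)
    scr <- generateScreen(cfg)
    gen <- screenGenerator(scr)
    # recover shared-latent estimates by least squares through the
    # known loadings, then correlate matched vs mismatched compounds
    recover <- function(v, loading) {
      t(solve(tcrossprod(loading), loading %*% t(v)))
    }
    latCp <- recover(profileValues(cpProfiles(scr)), gen$cpLoading)
    latTx <- recover(profileValues(txProfiles(scr)),
                     gen$txLoading)[, 1:5]
    rownames(latCp) <- unname(compoundIds(cpProfiles(scr)))
    latTx <- latTx[rownames(latCp), , drop = FALSE]
    matched <- mean(diag(cor(t(latCp), t(latTx))))
    mism <- cor(t(latCp), t(latTx))
    diag(mism) <- NA
    expect_gt(matched, mean(mism, na.rm = TRUE) + 0.5)
  }
})

test_that("profiles follow the Z-score convention of near-zero feature means", {
  # with every compound its own class the latents are iid zero-mean, so
  # per-feature means shrink like 1/sqrt(n) times the feature scale (with
  # few MoA classes the class centroids dominate the population mean and
  # the CLT tolerance is governed by the class count instead)
  cfg <- screenConfig(nCompounds = 800, nMoaClasses = 800, dCp = 20,
                      dTx = 30, seed = 8)
  scr <- generateScreen(cfg)
  txv <- profileValues(txProfiles(scr))
  cpv <- profileValues(cpProfiles(scr))
  expect_lt(max(abs(colMeans(txv)) / apply(txv, 2, sd)), 5 / sqrt(800))
  expect_lt(max(abs(colMeans(cpv)) / apply(cpv, 2, sd)),
            5 / sqrt(nrow(cpv)))
})

test_that("bioactivity layer: density, prevalence, TX-only weights", {
  scr <- tinyScreen(seed = 9, nCompounds = 200, labelDensity = 1,
                    nTasks = 9)
  lab <- bioactivityLabels(screenBioactivity(scr))
  expect_false(anyNA(lab))
  # median threshold: positive rate 0.5 up to binomial wobble
  rates <- colMeans(lab)
  expect_true(all(abs(rates - 0.5) < 3 * sqrt(0.25 / 200)))
  # frac 0: no task touches TX-only latent dimensions
  scr0 <- tinyScreen(seed = 10, fracTxOnlyTasks = 0, nTasks = 6)
  W <- screenGenerator(scr0)$taskWeights
  expect_true(all(W[grep("txonly", rownames(W)), ] == 0))
  expect_false(any(screenGenerator(scr0)$taskTxOnly))
  # partial missingness
  scrM <- tinyScreen(seed = 11, labelDensity = 0.5, nCompounds = 100)
  labM <- bioactivityLabels(screenBioactivity(scrM))
  expect_gt(mean(is.na(labM)), 0.4)
  expect_lt(mean(is.na(labM)), 0.6)
})

test_that("TX-only task scores are predictable from TX but not from CP", {
  for (seed in 0:2) {
    cfg <- screenConfig(nCompounds = 1000, nMoaClasses = 10, dCp = 60,
                        dTx = 80, dLatentShared = 4, dLatentTxOnly = 3,
                        cpNoiseSd = 0.5, txNoiseSd = 0.3,
                        replicateCountRange = c(1, 1),
                        nTasks = 6, fracTxOnlyTasks = 0.5,
                        labelDensity = 1, seed = seed)
    scr <- generateScreen(cfg)
    gen <- screenGenerator(scr)
    lat <- screenLatents(scr)
    scores <- lat %*% gen$taskWeights  # noiseless task scores
    cpv <- profileValues(cpProfiles(scr))
    txv <- profileValues(txProfiles(scr))
    rownames(cpv) <- unname(compoundIds(cpProfiles(scr)))
    cpv <- cpv[rownames(lat), ]
    txv <- txv[rownames(lat), ]
    ridgeR2 <- function(X, y, ntrain = 700) {
      tr <- seq_len(ntrain); te <- (ntrain + 1):nrow(X)
      Xt <- scale(X[tr, ], scale = FALSE)
      G <- crossprod(Xt) + diag(1e-2, ncol(X))
      beta <- solve(G, crossprod(Xt, y[tr] - mean(y[tr])))
      pred <- scale(X[te, ], center = colMeans(X[tr, ]),
                    scale = FALSE) %*% beta + mean(y[tr])
      1 - sum((y[te] - pred)^2) / sum((y[te] - mean(y[te]))^2)
    }
    txOnlyTasks <- which(gen$taskTxOnly)
    for (j in txOnlyTasks[1]) {
      expect_gt(ridgeR2(txv, scores[, j]), ridgeR2(cpv, scores[, j]) + 0.3)
    }
  }
})
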