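# Task filters, AUROC/AUPRC against exhaustive threshold sweeps, RIPtoP,
# task-subset selection, Wilcoxon comparisons, family grouping, and the
# multitask classifier on separable / permuted tasks.

# exhaustive threshold-sweep oracles built from explicit confusion counts
aurocOracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}
auprcOracle <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  prec <- rec <- numeric(length(th))
  for (i in seq_along(th)) {
    sel <- scores >= th[i]
    prec[i] <- sum(labels[sel] == 1) / sum(sel)
    rec[i] <- sum(labels[sel] == 1) / sum(labels == 1)
  }
  sum(diff(c(0, rec)) * prec)
}

test_that("task filters reproduce brute-force recounts", {
  scr <- tinyScreen(seed = 21, nCompounds = 400, nTasks = 12,
                    labelDensity = 0.4)
  bio <- screenBioactivity(scr)
  sp <- scaffoldSplit(screenCompounds(scr), seed = 3)
  lab <- bioactivityLabels(bio)
  tv <- lab[rownames(lab) %in% compoundsInSplit(sp, c("train", "valid")), ]
  te <- lab[rownames(lab) %in% compoundsInSplit(sp, "test"), ]
  # thresholds scaled to the fixture so both filters bite
  got <- filterTrainTasks(bio, sp, minPos = 65, minNeg = 60,
                          minTotal = 128)
  want <- colnames(lab)[colSums(tv == 1, na.rm = TRUE) >= 65 &
                        colSums(tv == 0, na.rm = TRUE) >= 60 &
                        colSums(!is.na(tv)) >= 128]
  expect_identical(got, want)
  expect_gt(length(got), 0)
  expect_lt(length(got), ncol(lab))
  gotE <- filterEvalTasks(bio, sp, minPos = 16, minNeg = 14)
  wantE <- colnames(lab)[colSums(te == 1, na.rm = TRUE) >= 16 &
                         colSums(te == 0, na.rm = TRUE) >= 14]
  expect_identical(gotE, wantE)
  expect_gt(length(gotE), 0)
  expect_lt(length(gotE), ncol(lab))
})

test_that("filter thresholds are inclusive and all criteria bind", {
  # 24 positives fails the 25-positive rule; 30/30 with 60 observed
  # fails the 100-datapoint floor; 25/25 with 100 observed passes
  mk <- function(npos, nneg, nobs, n = 120) {
    v <- c(rep(1, npos), rep(0, nneg), rep(NA, n - npos - nneg))
    stopifnot(npos + nneg <= nobs)
    v[!is.na(v)][seq_len(0)] <- NA  # no-op, clarity
    extra <- nobs - npos - nneg
    if (extra > 0) v[(npos + nneg + 1):(npos + nneg + extra)] <- 0.0
    v
  }
  lab <- cbind(
    t24 = c(rep(1, 24), rep(0, 80), rep(NA, 16)),
    t60 = c(rep(1, 30), rep(0, 30), rep(NA, 60)),
    t100 = c(rep(1, 25), rep(0, 75), rep(NA, 20)))
  rownames(lab) <- sprintf("c%03d", 1:120)
  bio <- BioactivityMatrix(lab)
  sp <- new("SplitAssignment",
            assignment = setNames(rep("train", 120), rownames(lab)),
            ratios = c(0.7, 0.1, 0.2), seed = 1L)
  expect_identical(filterTrainTasks(bio, sp), "t100")
  # eval filter: 25/25 in test retained (inclusive), one-class excluded
  labE <- cbind(ok = rep(c(1, 0), each = 25),
                onecls = rep(1, 50))
  rownames(labE) <- sprintf("e%02d", 1:50)
  spE <- new("SplitAssignment",
             assignment = setNames(rep("test", 50), rownames(labE)),
             ratios = c(0.7, 0.1, 0.2), seed = 1L)
  expect_identical(filterEvalTasks(BioactivityMatrix(labE), spE), "ok")
})

test_that("AUROC and AUPRC match exhaustive threshold-sweep oracles", {
  # perfect ordering
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(riptop(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 0.5), 1)
  # constant scores: AUROC 0.5, AUPRC equals prevalence
  expect_equal(auroc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(auprc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  # 20-point hand fixture with ties
  set.seed(31)
  s <- round(runif(20), 1)
  y <- rbinom(20, 1, 0.4)
  expect_equal(auroc(s, y), aurocOracle(s, y))
  expect_equal(auprc(s, y), auprcOracle(s, y))
  # random fixtures up to 50 points
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    s <- round(rnorm(n), sample(0:2, 1))  # coarse rounding forces ties
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    expect_equal(auroc(s, y), aurocOracle(s, y), tolerance = 1e-12)
    expect_equal(auprc(s, y), auprcOracle(s, y), tolerance = 1e-12)
  }
})

test_that("RIPtoP identities and monotonicity hold on a baseline grid", {
  b <- seq(0.01, 0.99, by = 0.01)
  expect_equal(riptop(b, b), rep(0, 99))
  expect_equal(riptop(rep(1, 99), b), rep(1, 99))
  expect_equal(riptop(0.5, 0.2), 0.375)
  set.seed(41)
  for (bb in sample(b, 10)) {
    a <- sort(runif(5))
    expect_true(all(diff(riptop(a, bb)) > 0))  # increasing in auprc
  }
  expect_error(riptop(0.5, 1), "strictly")
  expect_error(riptop(0.5, 0), "strictly")
})

test_that("TX-strong/CP-weak selection is strict on both boundaries", {
  tx <- data.frame(task_id = c("t1", "t2", "t3", "t4"),
                   auroc = c(0.70, 0.75, 0.90, 0.70001))
  cp <- data.frame(task_id = c("t1", "t2", "t3", "t4"),
                   auroc = c(0.50, 0.65, 0.70, 0.69999))
  expect_identical(selectTxStrongCpWeak(tx, cp), c("t2", "t4"))
  # brute-force filter on a random score table
  set.seed(51)
  ids <- sprintf("t%03d", 1:100)
  txr <- data.frame(task_id = ids, auroc = runif(100, 0.4, 1))
  cpr <- data.frame(task_id = ids, auroc = runif(100, 0.4, 1))
  want <- ids[txr$auroc > 0.7 & cpr$auroc < 0.7]
  expect_identical(selectTxStrongCpWeak(txr, cpr), want)
  expect_error(selectTxStrongCpWeak(txr[1:50, ], cpr), "identical task sets")
})

test_that("paired Wilcoxon comparison behaves under swap and degeneracy", {
  set.seed(61)
  ids <- sprintf("t%02d", 1:12)
  a <- setNames(runif(12, 0.5, 0.9), ids)
  b <- a - rnorm(12, 0.03, 0.02)
  cmpAB <- compareFeatureTypes(a, b, nameA = "A", nameB = "B")
  cmpBA <- compareFeatureTypes(b, a, nameA = "B", nameB = "A")
  expect_s4_class(cmpAB, "ComparisonResult")
  # one-sided p-values of the two directions are complementary around
  # the point mass at the observed statistic (exact test, no ties)
  expect_lt(cmpAB@pValue, 0.05)
  expect_gt(cmpBA@pValue, 0.95)
  expect_equal(cmpAB@medianDifference, -cmpBA@medianDifference)
  # identical inputs: degenerate, no p-value
  dg <- compareFeatureTypes(a, a)
  expect_true(dg@degenerate)
  expect_true(is.na(dg@pValue))
  expect_equal(dg@nTasks, 0L)
})

test_that("family grouping tallies tasks and runs within-family tests", {
  set.seed(71)
  n <- 20
  fams <- rep(c("Hydrolase", "Ion Channel", NA), length.out = n)
  mA <- data.frame(task_id = sprintf("t%02d", 1:n),
                   auroc = runif(n, 0.6, 0.9),
                   family = fams, stringsAsFactors = FALSE)
  mB <- mA
  mB$auroc <- mA$auroc - 0.05
  out <- groupByFamily(mA, mB, nameA = "CL", nameB = "CP")
  s <- out$summary
  expect_setequal(s$family, c("Hydrolase", "Ion Channel", "(unannotated)"))
  # counts against a brute-force tally
  expect_equal(s$n[s$family == "Hydrolase"], sum(fams == "Hydrolase", na.rm = TRUE))
  expect_equal(s$n[s$family == "(unannotated)"], sum(is.na(fams)))
  expect_equal(s$mean[s$family == "Ion Channel"],
               mean(mA$auroc[!is.na(fams) & fams == "Ion Channel"]))
  # uniform A > B shift: every within-family comparison is significant
  for (cmp in out$comparisons) expect_lt(cmp@pValue, 0.05)
  # an annotated family with too few tasks is omitted with a warning
  mA2 <- mA[1:4, ]; mB2 <- mB[1:4, ]
  w <- capture_warnings(groupByFamily(mA2, mB2, minTasks = 3))
  expect_true(any(grepl("fewer than", w)))
})

test_that("multitask classifier separates a linear task and not a permuted one", {
  for (seed in 0:2) {
    set.seed(100 + seed)
    n <- 400; d <- 20
    X <- matrix(rnorm(n * d), n, dimnames = list(sprintf("c%03d", 1:n)))
    w <- rnorm(d)
    sep <- as.numeric(X %*% w > 0)                 # linearly separable
    perm <- sample(sep)                            # label-permuted control
    lab <- cbind(sep = sep, perm = perm)
    rownames(lab) <- rownames(X)
    bio <- BioactivityMatrix(lab)
    asn <- setNames(rep(c("train", "valid", "test"), c(280, 40, 80)),
                    rownames(X))
    sp <- new("SplitAssignment", assignment = asn,
              ratios = c(0.7, 0.1, 0.2), seed = 1L)
    cfg <- multitaskConfig(hiddenSize = 32, nLayers = 2, epochs = 80,
                           learningRate = 3e-3, batchSize = 64,
                           dropout = 0.1, seed = seed)
    m <- trainMultitask(X, bio, sp, cfg, taskIds = c("sep", "perm"))
    expect_true(all(is.finite(m@history$train_loss)))
    expect_equal(nrow(m@history), 80L)
    sc <- scoreTasks(m, X, bio, sp, taskIds = c("sep", "perm"))
    expect_gt(sc$auroc[sc$task_id == "sep"], 0.95)
    expect_gt(sc$auroc[sc$task_id == "perm"], 0.35)
    expect_lt(sc$auroc[sc$task_id == "perm"], 0.65)
  }
})

test_that("scoreTasks reports baseline, riptop and family bookkeeping", {
  scr <- tinyScreen(seed = 81, nCompounds = 300, nTasks = 6,
                    labelDensity = 1)
  sp <- scaffoldSplit(screenCompounds(scr), seed = 2)
  bio <- screenBioactivity(scr)
  f <- profileValues(aggregateReplicates(cpProfiles(scr)))
  tasks <- filterTrainTasks(bio, sp, minPos = 10, minNeg = 10,
                            minTotal = 20)
  m <- trainMultitask(f, bio, sp,
                      multitaskConfig(hiddenSize = 16, nLayers = 2,
                                      epochs = 5, learningRate = 1e-3,
                                      seed = 1),
                      taskIds = tasks)
  sc <- scoreTasks(m, f, bio, sp, taskIds = tasks)
  expect_setequal(sc$task_id, tasks)
  lab <- bioactivityLabels(bio)
  te <- intersect(compoundsInSplit(sp, "test"), rownames(lab))
  for (i in seq_len(nrow(sc))) {
    y <- lab[te, sc$task_id[i]]
    y <- y[!is.na(y)]
    expect_equal(sc$baseline[i], mean(y))
    expect_equal(sc$n_pos[i], sum(y == 1))
    expect_equal(sc$riptop_auprc[i],
                 (sc$auprc[i] - sc$baseline[i]) / (1 - sc$baseline[i]))
  }
  expect_false(anyNA(sc$family))
})
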