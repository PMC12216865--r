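#' Multitask bioactivity classifier configuration
#'
#' @param hiddenSize hidden-layer width (default 256).
#' @param nLayers number of hidden layers (default 3).
#' @param learningRate Adam learning rate (default 1e-4).
#' @param weightDecay L2 weight decay (default 1e-5).
#' @param batchSize minibatch size (default 128).
#' @param epochs training epochs; final-epoch weights are used
#'   (default 100).
#' @param dropout dropout probability on hidden activations (default 0.3).
#' @param schedulerPeriod cosine-annealing warm-restart period in epochs
#'   (default 10).
#' @param seed integer seed.
#' @return a validated [MultitaskConfig-class].
#' @export
multitaskConfig <- function(hiddenSize = 256, nLayers = 3,
                            learningRate = 1e-4, weightDecay = 1e-5,
                            batchSize = 128, epochs = 100, dropout = 0.3,
                            schedulerPeriod = 10, seed = 1) {
  new("MultitaskConfig",
      hiddenSize = as.integer(hiddenSize), nLayers = as.integer(nLayers),
      learningRate = learningRate, weightDecay = weightDecay,
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      dropout = dropout, schedulerPeriod = as.integer(schedulerPeriod),
      seed = as.integer(seed))
}

.taskCounts <- function(labels, compounds) {
  lab <- labels[rownames(labels) %in% compounds, , drop = FALSE]
  data.frame(task_id = colnames(lab),
             n_pos = colSums(lab == 1, na.rm = TRUE),
             n_neg = colSums(lab == 0, na.rm = TRUE),
             n_obs = colSums(!is.na(lab)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tasks eligible for multitask training
#'
#' Retains tasks with at least `minPos` positives, `minNeg` negatives and
#' `minTotal` observed labels among train + valid compounds (the
#' published 25/25/100 filter).
#'
#' @param labels a [BioactivityMatrix-class].
#' @param split a [SplitAssignment-class].
#' @param minPos,minNeg,minTotal inclusive thresholds (defaults 25, 25,
#'   100).
#' @return character vector of retained task identifiers (possibly empty,
#'   with a warning).
#' @export
filterTrainTasks <- function(labels, split, minPos = 25, minNeg = 25,
                             minTotal = 100) {
  .assert(is(labels, "BioactivityMatrix"), "'labels' must be a BioactivityMatrix")
  cnt <- .taskCounts(bioactivityLabels(labels),
                     compoundsInSplit(split, c("train", "valid")))
  keep <- cnt$n_pos >= minPos & cnt$n_neg >= minNeg & cnt$n_obs >= minTotal
  if (!any(keep)) warning("no task passes the training filter")
  cnt$task_id[keep]
}

#' Tasks eligible for test-set evaluation
#'
#' Retains tasks with at least `minPos` positives and `minNeg` negatives
#' among test compounds (the published 25/25 test filter).
#'
#' @param labels a [BioactivityMatrix-class].
#' @param split a [SplitAssignment-class].
#' @param minPos,minNeg inclusive thresholds (defaults 25, 25).
#' @return character vector of retained task identifiers.
#' @export
filterEvalTasks <- function(labels, split, minPos = 25, minNeg = 25) {
  .assert(is(labels, "BioactivityMatrix"), "'labels' must be a BioactivityMatrix")
  cnt <- .taskCounts(bioactivityLabels(labels),
                     compoundsInSplit(split, "test"))
  keep <- cnt$n_pos >= minPos & cnt$n_neg >= minNeg
  if (!any(keep)) warning("no task passes the evaluation filter")
  cnt$task_id[keep]
}

#' Train the multitask bioactivity classifier
#'
#' A single MLP with one sigmoid output per task, trained jointly on all
#' retained tasks over train + valid compounds. The loss is binary
#' cross-entropy averaged over observed labels only (missing entries
#' contribute nothing). Adam with L2 weight decay, dropout on hidden
#' activations, cosine-annealing warm restarts of the learning rate, and
#' final-epoch weights (the published setting fixes the epoch count
#' rather than early-stopping).
#'
#' @param features compound-by-feature matrix; rownames are compound
#'   identifiers. Use compound-level features (aggregate CP replicates
#'   first).
#' @param labels a [BioactivityMatrix-class].
#' @param split a [SplitAssignment-class]; training uses train + valid
#'   compounds.
#' @param cfg a [MultitaskConfig-class].
#' @param taskIds tasks to model; defaults to [filterTrainTasks()].
#' @return a trained [MultitaskModel-class].
#' @seealso [scoreTasks()]
#' @export
trainMultitask <- function(features, labels, split, cfg = multitaskConfig(),
                           taskIds = NULL) {
  validObject(cfg)
  .assert(is.matrix(features) && !is.null(rownames(features)),
          "'features' must be a matrix with compound rownames")
  .assert(is(labels, "BioactivityMatrix"), "'labels' must be a BioactivityMatrix")
  if (is.null(taskIds)) taskIds <- filterTrainTasks(labels, split)
  .assert(length(taskIds) > 0, "no tasks to train on")
  lab <- bioactivityLabels(labels)
  .assert(all(taskIds %in% colnames(lab)), "unknown task identifiers")
  trainCmp <- intersect(compoundsInSplit(split, c("train", "valid")),
                        rownames(features))
  trainCmp <- intersect(trainCmp, rownames(lab))
  Y <- lab[trainCmp, taskIds, drop = FALSE]
  keep <- rowSums(!is.na(Y)) > 0
  trainCmp <- trainCmp[keep]
  .assert(length(trainCmp) >= 2, "too few labelled training compounds")
  X <- features[trainCmp, , drop = FALSE]
  Y <- Y[keep, , drop = FALSE]
  nT <- length(taskIds)
  # per-feature standardisation on the training compounds, so every
  # feature type (Z-scored profiles or unnormalised embeddings) enters
  # the classifier on the same scale; the identical transform is applied
  # at prediction time
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-8] <- 1
  X <- scale(X, center = ctr, scale = scl)

  withSeed(cfg@seed, {
    net <- mlpNew(c(ncol(X), rep(cfg@hiddenSize, cfg@nLayers), nT))
    opt <- adamNew(net)
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          lr = numeric())
    n <- nrow(X)
    for (epoch in seq_len(cfg@epochs)) {
      lr <- cosineRestartLr(cfg@learningRate, epoch, cfg@schedulerPeriod)
      perm <- sample.int(n)
      starts <- seq(1L, n, by = cfg@batchSize)
      epochLoss <- 0; nObsTotal <- 0
      for (s in starts) {
        idx <- perm[s:min(s + cfg@batchSize - 1L, n)]
        fw <- mlpForward(net, X[idx, , drop = FALSE], training = TRUE,
                         dropout = cfg@dropout)
        yb <- Y[idx, , drop = FALSE]
        obs <- !is.na(yb)
        nObs <- sum(obs)
        if (nObs == 0) next
        p <- 1 / (1 + exp(-fw$out))
        eps <- 1e-12
        ll <- ifelse(obs,
                     yb * log(p + eps) + (1 - yb) * log(1 - p + eps), 0)
        loss <- -sum(ll, na.rm = TRUE) / nObs
        if (!is.finite(loss))
          stop("non-finite multitask loss at epoch ", epoch, call. = FALSE)
        dOut <- matrix(0, nrow(p), ncol(p))
        dOut[obs] <- (p[obs] - yb[obs]) / nObs
        bw <- mlpBackward(net, fw, dOut)
        up <- adamStep(net, bw$grads, opt, lr,
                       weightDecay = cfg@weightDecay)
        net <- up$net; opt <- up$state
        epochLoss <- epochLoss + loss * nObs
        nObsTotal <- nObsTotal + nObs
      }
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_loss = epochLoss / nObsTotal,
                                  lr = lr))
    }
    new("MultitaskModel", net = net, taskIds = as.character(taskIds),
        features = colnames(X) %||% character(), config = cfg,
        history = history, standardization = list(center = ctr,
                                                  scale = scl))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
setMethod("show", "MultitaskModel", function(object) {
  cat(sprintf(
    "MultitaskModel: %d tasks, %d hidden layers x %d units, %d epochs\n",
    length(object@taskIds), object@config@nLayers,
    object@config@hiddenSize, nrow(object@history)))
})

#' Predicted activity probabilities
#'
#' @param model a trained [MultitaskModel-class].
#' @param features compound-by-feature matrix (same features as
#'   training).
#' @return compound-by-task matrix of probabilities.
#' @export
predictMultitask <- function(model, features) {
  .assert(is(model, "MultitaskModel"), "'model' must be a MultitaskModel")
  .assert(is.matrix(features), "'features' must be a matrix")
  if (length(model@features))
    .checkFeatures(features, model@features)
  features <- scale(features, center = model@standardization$center,
                    scale = model@standardization$scale)
  out <- mlpForward(model@net, features)$out
  p <- 1 / (1 + exp(-out))
  dimnames(p) <- list(rownames(features), model@taskIds)
  p
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with ties averaged; constant scores
#' give 0.5.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1 or logical).
#' @return AUROC in `[0, 1]`, or `NA` if only one class is present.
#' @export
auroc <- function(scores, labels) {
  labels <- as.numeric(labels)
  .assert(length(scores) == length(labels) && all(labels %in% c(0, 1)),
          "'labels' must be binary and match 'scores'")
  nPos <- sum(labels == 1)
  nNeg <- sum(labels == 0)
  if (nPos == 0 || nNeg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: precision is evaluated at every distinct
#' score threshold (ties handled as one block) and weighted by the recall
#' increment — no trapezoidal interpolation, which would be optimistic
#' for PR curves.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1 or logical).
#' @return AUPRC in `[0, 1]`, or `NA` if no positives are present.
#' @export
auprc <- function(scores, labels) {
  labels <- as.numeric(labels)
  .assert(length(scores) == length(labels) && all(labels %in% c(0, 1)),
          "'labels' must be binary and match 'scores'")
  nPos <- sum(labels == 1)
  if (nPos == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  block <- c(diff(s) != 0, TRUE)  # last index of each tied-score block
  prec <- tp[block] / (tp[block] + fp[block])
  rec <- tp[block] / nPos
  sum(diff(c(0, rec)) * prec)
}

#' RIPtoP correction of AUPRC
#'
#' Relative Improvement of Proximity to Perfection:
#' `(AUPRC - BASELINE) / (1 - BASELINE)`, where the baseline is the
#' positive prevalence of the scored set. Rescales AUPRC so 0 is the
#' random baseline and 1 a perfect model for every task, making tasks
#' with different prevalences comparable.
#'
#' @param auprc AUPRC value(s).
#' @param baseline positive prevalence in `(0, 1)` (recycled).
#' @return corrected value(s); 0 when `auprc == baseline`, 1 when
#'   `auprc == 1`.
#' @examples
#' riptop(0.5, 0.2)  # 0.375
#' @export
riptop <- function(auprc, baseline) {
  .assert(is.numeric(auprc) && is.numeric(baseline),
          "'auprc' and 'baseline' must be numeric")
  .assert(all(baseline > 0 & baseline < 1),
          "'baseline' must lie strictly in (0, 1)")
  (auprc - baseline) / (1 - baseline)
}

#' Per-task test-set metrics
#'
#' Scores the multitask model on test compounds: per task, AUROC,
#' average-precision AUPRC, the positive prevalence (baseline) of the
#' scored labels, and the RIPtoP-corrected AUPRC. Tasks with a single
#' observed class in the test set are skipped with a warning.
#'
#' @param model a trained [MultitaskModel-class].
#' @param features compound-by-feature matrix covering the test
#'   compounds.
#' @param labels a [BioactivityMatrix-class].
#' @param split a [SplitAssignment-class].
#' @param taskIds tasks to score; defaults to [filterEvalTasks()]
#'   intersected with the model's tasks.
#' @return `data.frame` with one row per scored task: `task_id`,
#'   `auroc`, `auprc`, `baseline`, `riptop_auprc`, `n_pos`, `n_neg`,
#'   `family`.
#' @export
scoreTasks <- function(model, features, labels, split, taskIds = NULL) {
  .assert(is(model, "MultitaskModel"), "'model' must be a MultitaskModel")
  .assert(is(labels, "BioactivityMatrix"), "'labels' must be a BioactivityMatrix")
  if (is.null(taskIds))
    taskIds <- intersect(filterEvalTasks(labels, split), model@taskIds)
  .assert(length(taskIds) > 0, "no tasks to score")
  .assert(all(taskIds %in% model@taskIds),
          "model does not cover all requested tasks")
  lab <- bioactivityLabels(labels)
  testCmp <- intersect(compoundsInSplit(split, "test"), rownames(features))
  testCmp <- intersect(testCmp, rownames(lab))
  .assert(length(testCmp) > 0, "no test compounds with features and labels")
  p <- predictMultitask(model, features[testCmp, , drop = FALSE])
  fam <- taskFamily(labels)
  rows <- lapply(taskIds, function(tid) {
    y <- lab[testCmp, tid]
    obs <- !is.na(y)
    y <- y[obs]
    if (length(unique(y)) < 2) {
      warning("task ", tid, " has a single observed class in the test ",
              "set; skipped")
      return(NULL)
    }
    s <- p[obs, tid]
    base <- mean(y)
    pr <- auprc(s, y)
    data.frame(task_id = tid, auroc = auroc(s, y), auprc = pr,
               baseline = base, riptop_auprc = riptop(pr, base),
               n_pos = sum(y == 1), n_neg = sum(y == 0),
               family = if (tid %in% names(fam)) fam[[tid]]
                        else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tasks where transcriptomics excels and Cell Painting does not
#'
#' The published task subset: TX AUROC strictly above 0.7 and CP AUROC
#' strictly below 0.7, computed on identical task sets.
#'
#' @param txMetrics,cpMetrics per-task metric `data.frame`s from
#'   [scoreTasks()] for the TX and CP feature types.
#' @param threshold AUROC cutoff (default 0.7).
#' @return character vector of selected task identifiers.
#' @export
selectTxStrongCpWeak <- function(txMetrics, cpMetrics, threshold = 0.7) {
  .assert(setequal(txMetrics$task_id, cpMetrics$task_id),
          "the two feature types must be scored on identical task sets")
  cpA <- cpMetrics$auroc[match(txMetrics$task_id, cpMetrics$task_id)]
  txMetrics$task_id[txMetrics$auroc > threshold & cpA < threshold]
}

#' Paired Wilcoxon signed-rank comparison of two feature types
#'
#' One-sided test that feature type A outperforms feature type B on a
#' per-task metric, pairing by task. Zero differences are dropped; the
#' exact distribution is used for fewer than 25 retained pairs (when no
#' ties among the absolute differences prevent it), otherwise the normal
#' approximation with continuity correction.
#'
#' @param metricsA,metricsB per-task `data.frame`s from [scoreTasks()],
#'   or plain named numeric vectors of per-task values.
#' @param metric column to compare when `data.frame`s are given
#'   (default `"auroc"`).
#' @param nameA,nameB feature-type names recorded in the result.
#' @return a [ComparisonResult-class].
#' @export
compareFeatureTypes <- function(metricsA, metricsB, metric = "auroc",
                                nameA = "A", nameB = "B") {
  pull <- function(m) {
    if (is.data.frame(m)) {
      .assert(metric %in% colnames(m), "metric '", metric, "' not found")
      stats::setNames(m[[metric]], m$task_id)
    } else {
      .assert(is.numeric(m) && !is.null(names(m)),
              "plain metric vectors must be named by task")
      m
    }
  }
  a <- pull(metricsA)
  b <- pull(metricsB)
  common <- intersect(names(a), names(b))
  .assert(length(common) > 0, "no common tasks to compare")
  d <- a[common] - b[common]
  d <- d[is.finite(d)]
  dnz <- d[d != 0]
  if (length(dnz) == 0) {
    return(new("ComparisonResult", featureTypeA = nameA,
               featureTypeB = nameB, metric = metric, nTasks = 0L,
               pValue = NA_real_, medianDifference = 0,
               degenerate = TRUE, method = "degenerate: all differences zero"))
  }
  n <- length(dnz)
  exact <- n < 25
  wt <- suppressWarnings(
    stats::wilcox.test(dnz, alternative = "greater", mu = 0,
                       exact = exact, correct = TRUE))
  method <- if (exact && !anyDuplicated(abs(dnz)))
    "exact signed-rank distribution"
  else if (exact)
    "normal approximation (ties prevent the exact distribution)"
  else "normal approximation with continuity correction"
  new("ComparisonResult", featureTypeA = nameA, featureTypeB = nameB,
      metric = metric, nTasks = as.integer(n),
      pValue = unname(wt$p.value),
      medianDifference = unname(stats::median(dnz)),
      degenerate = FALSE, method = method)
}

#' @export
setMethod("show", "ComparisonResult", function(object) {
  if (object@degenerate) {
    cat(sprintf("ComparisonResult [%s > %s, %s]: degenerate (all paired differences zero)\n",
                object@featureTypeA, object@featureTypeB, object@metric))
  } else {
    cat(sprintf(
      "ComparisonResult [%s > %s, %s]: one-sided p = %.3g over %d tasks (median diff %.4f; %s)\n",
      object@featureTypeA, object@featureTypeB, object@metric,
      object@pValue, object@nTasks, object@medianDifference,
      object@method))
  }
})

#' Per-family metric summaries and feature-type comparisons
#'
#' Groups per-task metrics by protein target family: mean, standard
#' deviation and task count per family, with unannotated tasks collected
#' in a `"(unannotated)"` remainder group. When a second feature type is
#' given, a within-family paired Wilcoxon comparison (A greater than B)
#' is run for every family with at least `minTasks` paired tasks.
#'
#' @param metricsA per-task `data.frame` from [scoreTasks()] (its
#'   `family` column drives the grouping).
#' @param metricsB optional second feature type to compare against.
#' @param metric metric column (default `"auroc"`).
#' @param nameA,nameB feature-type names for the comparisons.
#' @param minTasks minimum paired tasks for a within-family comparison
#'   (default 3).
#' @return list with `summary` (`data.frame`: family, n, mean, sd) and
#'   `comparisons` (list of [ComparisonResult-class], or `NULL`).
#' @export
groupByFamily <- function(metricsA, metricsB = NULL, metric = "auroc",
                          nameA = "A", nameB = "B", minTasks = 3) {
  .assert(is.data.frame(metricsA) && "family" %in% colnames(metricsA),
          "'metricsA' must carry a 'family' column")
  .assert(metric %in% colnames(metricsA), "metric '", metric, "' not found")
  fam <- metricsA$family
  fam[is.na(fam)] <- "(unannotated)"
  vals <- metricsA[[metric]]
  famLevels <- unique(fam)
  summary <- data.frame(
    family = famLevels,
    n = as.integer(tapply(vals, fam, length)[famLevels]),
    mean = as.numeric(tapply(vals, fam, mean)[famLevels]),
    sd = as.numeric(tapply(vals, fam, stats::sd)[famLevels]),
    stringsAsFactors = FALSE)
  summary <- summary[order(summary$family == "(unannotated)",
                           summary$family), , drop = FALSE]
  rownames(summary) <- NULL
  comparisons <- NULL
  if (!is.null(metricsB)) {
    comparisons <- list()
    for (f in summary$family) {
      tasksF <- metricsA$task_id[fam == f]
      sub <- intersect(tasksF, metricsB$task_id)
      if (length(sub) < minTasks) {
        warning("family '", f, "' has fewer than ", minTasks,
                " paired tasks; comparison omitted")
        next
      }
      comparisons[[f]] <- compareFeatureTypes(
        metricsA[metricsA$task_id %in% sub, , drop = FALSE],
        metricsB[metricsB$task_id %in% sub, , drop = FALSE],
        metric = metric, nameA = nameA, nameB = nameB)
    }
  }
  list(summary = summary, comparisons = comparisons)
}
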