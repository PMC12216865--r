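#' k-nearest-neighbour cluster accuracy
#'
#' Cluster-quality score: the fraction of points whose majority label
#' among the k nearest Euclidean neighbours equals their own label. With
#' `excludeSelf = FALSE` (default) the fitted set equals the queried set,
#' so every point is its own nearest neighbour — the behaviour of a
#' default kNN classifier fit and evaluated on the same points. With
#' `excludeSelf = TRUE` the vote is leave-one-out. Majority ties are
#' broken in favour of the tied class whose neighbour is closest;
#' equidistant neighbours are ordered by row index, so the score is
#' deterministic.
#'
#' @param x numeric matrix (points by features).
#' @param labels class label per row.
#' @param k neighbour count (default 5).
#' @param excludeSelf leave-one-out voting? (default `FALSE`).
#' @param metric `"euclidean"` (default) or `"cosine"` (Euclidean on
#'   L2-normalised rows, which preserves the cosine neighbour ordering).
#' @return fraction in `[0, 1]`.
#' @examples
#' x <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20) + 50, 10))
#' knnAccuracy(x, rep(c("a", "b"), each = 10), k = 5)  # 1
#' @export
knnAccuracy <- function(x, labels, k = 5, excludeSelf = FALSE,
                        metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  .assert(is.matrix(x) && is.numeric(x), "'x' must be a numeric matrix")
  if (metric == "cosine") {
    nrm <- sqrt(rowSums(x^2))
    .assert(all(nrm > 0), "cosine metric undefined for zero rows")
    x <- x / nrm
  }
  n <- nrow(x)
  .assert(length(labels) == n, "'labels' must have one entry per row")
  .assert(.is_count(k), "'k' must be a positive integer")
  labels <- as.character(labels)
  .assert(length(unique(labels)) >= 2,
          "labels are degenerate: at least 2 classes required")
  need <- k + as.integer(excludeSelf)
  .assert(n >= need, "need at least ", need, " rows for k = ", k,
          if (excludeSelf) " with self excluded" else "")
  D <- as.matrix(stats::dist(x))
  correct <- 0L
  for (i in seq_len(n)) {
    d <- D[i, ]
    if (excludeSelf) d[i] <- Inf
    ord <- order(d, seq_len(n))  # ties broken by row index
    nb <- ord[seq_len(k)]
    votes <- table(labels[nb])
    winners <- names(votes)[votes == max(votes)]
    pred <- if (length(winners) == 1L) winners else
      labels[nb[match(TRUE, labels[nb] %in% winners)]]
    if (pred == labels[i]) correct <- correct + 1L
  }
  correct / n
}

.clusterResult <- function(featureType, task, acc, k, n, nClasses,
                           excludeSelf) {
  new("ClusterEvalResult", featureType = featureType, task = task,
      knnAccuracy = acc, k = as.integer(k), nPoints = as.integer(n),
      nClasses = as.integer(nClasses), excludeSelf = excludeSelf)
}

#' @export
setMethod("show", "ClusterEvalResult", function(object) {
  cat(sprintf(
    "ClusterEvalResult [%s, %s]: kNN accuracy %.3f (k = %d%s, %d points, %d classes)\n",
    object@featureType, object@task, object@knnAccuracy, object@k,
    if (object@excludeSelf) ", self excluded" else "",
    object@nPoints, object@nClasses))
})

#' Replicate-clustering quality of replicate-level features
#'
#' Scores how well a feature type groups Cell Painting replicates of the
#' same compound: kNN accuracy with the compound identifier as the true
#' cluster label. Run it on the test-split replicates of raw CP profiles
#' or of learned embeddings (rows are replicates either way).
#'
#' @param features replicate-by-feature matrix.
#' @param compoundIds compound of each row (the cluster labels).
#' @param k neighbour count (default 5).
#' @param excludeSelf leave-one-out voting? (default `FALSE`); compounds
#'   with a single replicate can never be voted correctly in this mode,
#'   so a warning is raised when both conditions hold.
#' @param metric `"euclidean"` (default) or `"cosine"`.
#' @param featureType name recorded in the result (default `"features"`).
#' @return a [ClusterEvalResult-class] with `task = "replicates"`.
#' @export
replicateClusteringEval <- function(features, compoundIds, k = 5,
                                    excludeSelf = FALSE,
                                    metric = "euclidean",
                                    featureType = "features") {
  compoundIds <- as.character(compoundIds)
  if (excludeSelf && any(table(compoundIds) == 1L))
    warning("compounds with a single replicate can never be voted ",
            "correctly when the point itself is excluded")
  acc <- knnAccuracy(features, compoundIds, k = k,
                     excludeSelf = excludeSelf, metric = metric)
  .clusterResult(featureType, "replicates", acc, k, nrow(features),
                 length(unique(compoundIds)), excludeSelf)
}

#' Mechanism-of-action clustering quality of compound-level features
#'
#' Restricts to the `topM` most-populated annotated MoA classes (the
#' published analysis uses the 9 largest in the test split) and scores
#' kNN accuracy with the MoA class as the true cluster label. Features
#' must be compound-level; aggregate replicate-level features first with
#' [aggregateReplicates()] or [rowGroupAggregate()].
#'
#' @param features compound-by-feature matrix.
#' @param moa MoA annotation per row (`NA` for unannotated compounds).
#' @param topM number of largest classes to keep (default 9); clamped
#'   with a warning when fewer annotated classes exist.
#' @param k neighbour count (default 5).
#' @param excludeSelf leave-one-out voting? (default `FALSE`).
#' @param metric `"euclidean"` (default) or `"cosine"`.
#' @param featureType name recorded in the result.
#' @return a [ClusterEvalResult-class] with `task = "moa"`.
#' @export
moaClusteringEval <- function(features, moa, topM = 9, k = 5,
                              excludeSelf = FALSE, metric = "euclidean",
                              featureType = "features") {
  .assert(is.matrix(features), "'features' must be a matrix")
  moa <- as.character(moa)
  .assert(length(moa) == nrow(features),
          "'moa' must have one entry per row")
  keep <- !is.na(moa)
  .assert(any(keep), "no MoA annotations available")
  counts <- sort(table(moa[keep]), decreasing = TRUE)
  if (length(counts) < topM) {
    warning("only ", length(counts), " annotated MoA classes available; ",
            "using all of them (topM = ", topM, " requested)")
    topM <- length(counts)
  }
  # ties at the size cutoff broken alphabetically for determinism
  ord <- order(-as.vector(counts), names(counts))
  top <- names(counts)[ord][seq_len(topM)]
  sel <- keep & moa %in% top
  acc <- knnAccuracy(features[sel, , drop = FALSE], moa[sel], k = k,
                     excludeSelf = excludeSelf, metric = metric)
  .clusterResult(featureType, "moa", acc, k, sum(sel), topM, excludeSelf)
}
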