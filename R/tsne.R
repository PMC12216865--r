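# Exact (O(n^2)) t-SNE, sufficient for the small point sets the 2-D
# cluster figures use. Perplexity calibration by per-point binary search
# on the Gaussian bandwidth; standard early exaggeration, momentum and
# gain schedule; 'auto' learning rate n / earlyExaggeration bounded below
# by 50, matching the convention of the reference implementation.

.tsnePerplexityP <- function(D2, perplexity, tol = 1e-5, maxIter = 50L) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    betaMin <- -Inf
    betaMax <- Inf
    di <- D2[i, -i]
    for (iter in seq_len(maxIter)) {
      p <- exp(-di * beta)
      sumP <- sum(p)
      if (sumP == 0) sumP <- .Machine$double.xmin
      H <- log(sumP) + beta * sum(di * p) / sumP
      diff <- H - logU
      if (abs(diff) < tol) break
      if (diff > 0) {
        betaMin <- beta
        beta <- if (is.finite(betaMax)) (beta + betaMax) / 2 else beta * 2
      } else {
        betaMax <- beta
        beta <- if (is.finite(betaMin)) (beta + betaMin) / 2 else beta / 2
      }
    }
    P[i, -i] <- p / sumP
  }
  P
}

#' 2-D t-SNE embedding
#'
#' Embeds profiles or embeddings into two dimensions for visual cluster
#' inspection, with the parameter conventions of the published figures:
#' random initialisation, 'auto' learning rate, perplexity 10 for
#' replicate clustering and 20 for MoA clustering. Exact gradients (no
#' tree approximation), so intended for at most a few hundred points.
#'
#' @param x numeric matrix (points by features).
#' @param perplexity effective neighbourhood size; requires
#'   `nrow(x) > 3 * perplexity`.
#' @param seed integer seed (random initialisation makes the layout
#'   seed-dependent).
#' @param maxIter gradient-descent iterations (default 500).
#' @return `nrow(x)` by 2 coordinate matrix, rownames preserved.
#' @examples
#' x <- rbind(matrix(rnorm(60), 30), matrix(rnorm(60) + 20, 30))
#' head(embed2D(x, perplexity = 5, seed = 1))
#' @export
embed2D <- function(x, perplexity = 10, seed = 1, maxIter = 500L) {
  .assert(is.matrix(x) && is.numeric(x), "'x' must be a numeric matrix")
  n <- nrow(x)
  .assert(.is_scalar_num(perplexity) && perplexity >= 2,
          "'perplexity' must be a number >= 2")
  .assert(n > 3 * perplexity,
          "too few points (", n, ") for perplexity ", perplexity,
          "; need n > 3 * perplexity")
  D2 <- as.matrix(stats::dist(x))^2
  P <- .tsnePerplexityP(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  earlyExaggeration <- 12
  lr <- max(n / earlyExaggeration, 50)
  withSeed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    dY <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    Puse <- P * earlyExaggeration
    for (iter in seq_len(maxIter)) {
      if (iter == 101L) Puse <- P
      momentum <- if (iter <= 250L) 0.5 else 0.8
      sumY <- rowSums(Y^2)
      num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      W <- (Puse - Q) * num
      grad <- 4 * (diag(rowSums(W)) - W) %*% Y
      newGains <- ifelse(sign(grad) != sign(dY), gains + 0.2,
                         gains * 0.8)
      gains <- pmax(newGains, 0.01)
      dY <- momentum * dY - lr * gains * grad
      Y <- Y + dY
      Y <- sweep(Y, 2L, colMeans(Y), "-")
    }
    rownames(Y) <- rownames(x)
    colnames(Y) <- c("tsne1", "tsne2")
    Y
  })
}

#' Scatter plot of a 2-D embedding coloured by label
#'
#' @param coords n-by-2 coordinate matrix (e.g. from [embed2D()]).
#' @param labels class label per point (colours the points).
#' @param file optional PNG path; when given the plot is written there
#'   instead of the active device.
#' @param main plot title.
#' @return `coords`, invisibly.
#' @export
plotEmbedding <- function(coords, labels, file = NULL, main = "") {
  .assert(is.matrix(coords) && ncol(coords) == 2,
          "'coords' must be an n-by-2 matrix")
  .assert(length(labels) == nrow(coords),
          "'labels' must have one entry per point")
  labels <- factor(labels)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  pal <- grDevices::hcl.colors(max(3L, nlevels(labels)), "Dark 3")
  graphics::plot(coords[, 1], coords[, 2],
                 col = pal[as.integer(labels)], pch = 19, cex = 0.8,
                 xlab = "t-SNE 1", ylab = "t-SNE 2", main = main)
  graphics::legend("topright", legend = levels(labels),
                   col = pal[seq_len(nlevels(labels))], pch = 19,
                   cex = 0.7, bty = "n")
  invisible(coords)
}
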