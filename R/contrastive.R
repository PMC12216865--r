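#' Contrastive pretraining configuration
#'
#' @param cpHiddenSizes CP encoder hidden widths (default
#'   `c(1024, 1024, 1024)`).
#' @param txHiddenSizes TX encoder hidden widths (default
#'   `c(4096, 4096, 4096)`).
#' @param encoderOutputDim encoder output width, the embedding kept after
#'   pretraining (default 512).
#' @param projectionDim contrastive-space width of the linear projection
#'   head, discarded at embedding time (default 256).
#' @param temperature InfoNCE softmax temperature (default 0.07, fixed,
#'   not learned).
#' @param maskRate fraction of input features zeroed per profile per batch
#'   in both modalities (default 0.10).
#' @param batchSize,epochs,learningRate Adam optimisation parameters
#'   (defaults 256 / 50 / 1e-4).
#' @param seed integer seed.
#' @return a validated [CLConfig-class].
#' @export
clConfig <- function(cpHiddenSizes = c(1024, 1024, 1024),
                     txHiddenSizes = c(4096, 4096, 4096),
                     encoderOutputDim = 512, projectionDim = 256,
                     temperature = 0.07, maskRate = 0.10,
                     batchSize = 256, epochs = 50,
                     learningRate = 1e-4, seed = 1) {
  new("CLConfig",
      cpHiddenSizes = as.integer(cpHiddenSizes),
      txHiddenSizes = as.integer(txHiddenSizes),
      encoderOutputDim = as.integer(encoderOutputDim),
      projectionDim = as.integer(projectionDim),
      temperature = temperature, maskRate = maskRate,
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      learningRate = learningRate, seed = as.integer(seed))
}

#' Randomly mask a fixed fraction of features per row
#'
#' The augmentation used by both pretraining methods: per row, an
#' independent uniformly random subset of `floor(rate * ncol(x))` feature
#' positions is set to 0 (profiles are Z-scores, so 0 means
#' control-like); all other entries are unchanged.
#'
#' @param x numeric matrix (profiles by features).
#' @param rate masking fraction in `[0, 1)`.
#' @param seed optional integer seed for a reproducible mask; when `NULL`
#'   the current RNG stream is used (fresh masks every batch during
#'   training).
#' @return matrix of the same shape.
#' @examples
#' m <- matrix(1, 2, 10)
#' rowSums(maskFeatures(m, 0.2, seed = 1) == 0)  # 2 zeros per row
#' @export
maskFeatures <- function(x, rate, seed = NULL) {
  .assert(is.matrix(x) && is.numeric(x), "'x' must be a numeric matrix")
  .assert(.is_scalar_num(rate) && rate >= 0 && rate < 1,
          "'rate' must lie in [0, 1)")
  if (!is.null(seed)) return(withSeed(seed, maskFeatures(x, rate)))
  d <- ncol(x)
  nMask <- floor(rate * d)
  if (nMask == 0L) return(x)
  n <- nrow(x)
  cols <- vapply(seq_len(n), function(i) sample.int(d, nMask),
                 integer(nMask))
  x[cbind(rep(seq_len(n), each = nMask), as.vector(cols))] <- 0
  x
}

#' Cosine similarity of two vectors
#'
#' `sim(x, z) = x'z / (||x|| ||z||)`, the similarity entering the InfoNCE
#' softmax.
#'
#' @param x,z numeric vectors of equal length, both nonzero.
#' @return a number in `[-1, 1]`.
#' @examples
#' cosineSimilarity(c(1, 0), c(1, 1))  # 1/sqrt(2)
#' @export
cosineSimilarity <- function(x, z) {
  .assert(length(x) == length(z), "'x' and 'z' must have equal length")
  nx <- sqrt(sum(x^2))
  nz <- sqrt(sum(z^2))
  .assert(nx > 0 && nz > 0,
          "cosine similarity is undefined for zero-norm vectors")
  sum(x * z) / (nx * nz)
}

.rowNormalize <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  .assert(all(nrm > 0), "zero-norm row encountered in projected batch")
  list(xn = x / nrm, nrm = nrm)
}

# symmetric InfoNCE loss and its gradient w.r.t. the (unnormalised)
# projected batches. Both directional cross-entropy terms are summed, as
# in the printed objective (not averaged).
.infonceLossGrad <- function(x, z, temperature, wantGrad = TRUE) {
  N <- nrow(x)
  a <- .rowNormalize(x)
  b <- .rowNormalize(z)
  S <- tcrossprod(a$xn, b$xn)            # S[i, j] = sim(x_i, z_j)
  A <- S / temperature
  # row direction: softmax over z_j for each x_i
  rowMax <- apply(A, 1L, max)
  expRow <- exp(A - rowMax)
  Prow <- expRow / rowSums(expRow)
  # column direction: softmax over x_j for each z_i
  colMax <- apply(A, 2L, max)
  expCol <- exp(sweep(A, 2L, colMax, "-"))
  Pcol <- sweep(expCol, 2L, colSums(expCol), "/")
  dg <- seq_len(N)
  loss <- -mean(log(Prow[cbind(dg, dg)])) - mean(log(Pcol[cbind(dg, dg)]))
  if (!wantGrad) return(list(loss = loss))
  G <- (Prow + Pcol) / (N * temperature)
  diag(G) <- diag(G) - 2 / (N * temperature)
  dXn <- G %*% b$xn
  dZn <- crossprod(G, a$xn)
  # through row normalisation: d/dx of x/||x||
  dX <- (dXn - a$xn * rowSums(dXn * a$xn)) / a$nrm
  dZ <- (dZn - b$xn * rowSums(dZn * b$xn)) / b$nrm
  list(loss = loss, dX = dX, dZ = dZ)
}

#' Symmetric InfoNCE loss of a projected batch
#'
#' The contrastive objective: for a batch of `N` matched pairs, the sum of
#' the two directional cross-entropy terms
#' \deqn{-\frac1N\sum_i \ln\frac{e^{sim(x_i,z_i)/\tau}}{\sum_j
#'   e^{sim(x_i,z_j)/\tau}}
#'   -\frac1N\sum_i \ln\frac{e^{sim(x_i,z_i)/\tau}}{\sum_j
#'   e^{sim(x_j,z_i)/\tau}}}
#' where `sim` is cosine similarity and \eqn{\tau} the temperature. When
#' all pairwise similarities are equal the loss is exactly `2 log(N)`.
#'
#' @param x,z matched projected batches (`N` by projection dim, rows are
#'   pairs); `N >= 2`, no zero rows.
#' @param temperature softmax temperature, > 0.
#' @return non-negative scalar loss.
#' @examples
#' x <- matrix(rnorm(16), 4)
#' infoNCELoss(x, x, temperature = 0.07)
#' @export
infoNCELoss <- function(x, z, temperature = 0.07) {
  .assert(is.matrix(x) && is.matrix(z) && all(dim(x) == dim(z)),
          "'x' and 'z' must be matrices of identical shape")
  .assert(nrow(x) >= 2, "InfoNCE needs a batch of at least 2 pairs")
  .assert(.is_scalar_num(temperature) && temperature > 0,
          "'temperature' must be > 0")
  .assert(all(is.finite(x)) && all(is.finite(z)),
          "non-finite values in projected batch")
  .infonceLossGrad(x, z, temperature, wantGrad = FALSE)$loss
}

# encoder + projection forward for one modality
.clProject <- function(encoder, projection, x) {
  e <- mlpForward(encoder, x)
  p <- mlpForward(projection, e$out)
  list(enc = e, proj = p)
}

#' Contrastive pretraining of the CP and TX encoders
#'
#' CLIP-style training on (CP replicate, TX) pairs of the train split,
#' with the valid split monitoring the InfoNCE loss. Each batch, both
#' modalities are independently masked at `maskRate` before encoding; the
#' weights with the lowest validation loss are retained. Only compounds
#' assigned to `train` or `valid` are ever seen; the test split stays
#' untouched for downstream evaluation.
#'
#' @param pairs a [PairSet-class] from [buildPairs()].
#' @param cp,tx the [ProfileMatrix-class] objects the pairs refer to.
#' @param split a [SplitAssignment-class].
#' @param cfg a [CLConfig-class].
#' @return a trained [CLModel-class] with its training history.
#' @seealso [embedProfiles()] to generate CP-only embeddings.
#' @export
trainContrastive <- function(pairs, cp, tx, split, cfg) {
  validObject(cfg)
  .assert(is(pairs, "PairSet"), "'pairs' must be a PairSet")
  pt <- pairTable(pairs)
  asn <- splitAssignment(split)
  pt <- pt[pt$compound_id %in% names(asn), , drop = FALSE]
  pset <- asn[pt$compound_id]
  trainIdx <- which(pset == "train")
  validIdx <- which(pset == "valid")
  .assert(length(trainIdx) >= 2, "no (or too few) training pairs")
  cpV <- profileValues(cp)
  txV <- profileValues(tx)
  txByCompound <- match(pt$compound_id, compoundIds(tx))
  cpRow <- match(pt$cp_row_id, rownames(cpV))
  .assert(!anyNA(txByCompound) && !anyNA(cpRow),
          "pairs refer to unknown profiles")

  withSeed(cfg@seed, {
    cpEnc <- mlpNew(c(ncol(cpV), cfg@cpHiddenSizes, cfg@encoderOutputDim))
    txEnc <- mlpNew(c(ncol(txV), cfg@txHiddenSizes, cfg@encoderOutputDim))
    cpProj <- mlpNew(c(cfg@encoderOutputDim, cfg@projectionDim))
    txProj <- mlpNew(c(cfg@encoderOutputDim, cfg@projectionDim))
    opt <- list(cpEnc = adamNew(cpEnc), txEnc = adamNew(txEnc),
                cpProj = adamNew(cpProj), txProj = adamNew(txProj))
    validLoss <- function() {
      if (length(validIdx) < 2) return(NA_real_)
      tot <- 0; nb <- 0
      starts <- seq(1L, length(validIdx), by = cfg@batchSize)
      for (s in starts) {
        idx <- validIdx[s:min(s + cfg@batchSize - 1L, length(validIdx))]
        if (length(idx) < 2) next
        fx <- .clProject(cpEnc, cpProj, cpV[cpRow[idx], , drop = FALSE])
        fz <- .clProject(txEnc, txProj,
                         txV[txByCompound[idx], , drop = FALSE])
        tot <- tot + .infonceLossGrad(fx$proj$out, fz$proj$out,
                                      cfg@temperature,
                                      wantGrad = FALSE)$loss
        nb <- nb + 1
      }
      tot / nb
    }
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          valid_loss = numeric())
    best <- list(loss = Inf, epoch = 0L)
    for (epoch in seq_len(cfg@epochs)) {
      perm <- sample(trainIdx)
      starts <- seq(1L, length(perm), by = cfg@batchSize)
      epochLoss <- 0; nb <- 0
      for (s in starts) {
        idx <- perm[s:min(s + cfg@batchSize - 1L, length(perm))]
        if (length(idx) < 2) next
        Xc <- maskFeatures(cpV[cpRow[idx], , drop = FALSE], cfg@maskRate)
        Zt <- maskFeatures(txV[txByCompound[idx], , drop = FALSE],
                           cfg@maskRate)
        fx <- .clProject(cpEnc, cpProj, Xc)
        fz <- .clProject(txEnc, txProj, Zt)
        lg <- .infonceLossGrad(fx$proj$out, fz$proj$out, cfg@temperature)
        if (!is.finite(lg$loss))
          stop("non-finite InfoNCE loss at epoch ", epoch,
               " (batch starting at ", s, "); ",
               "reduce the learning rate or check the inputs",
               call. = FALSE)
        bpPx <- mlpBackward(cpProj, fx$proj, lg$dX)
        bpEx <- mlpBackward(cpEnc, fx$enc, bpPx$dX)
        bpPz <- mlpBackward(txProj, fz$proj, lg$dZ)
        bpEz <- mlpBackward(txEnc, fz$enc, bpPz$dX)
        up <- adamStep(cpProj, bpPx$grads, opt$cpProj, cfg@learningRate)
        cpProj <- up$net; opt$cpProj <- up$state
        up <- adamStep(cpEnc, bpEx$grads, opt$cpEnc, cfg@learningRate)
        cpEnc <- up$net; opt$cpEnc <- up$state
        up <- adamStep(txProj, bpPz$grads, opt$txProj, cfg@learningRate)
        txProj <- up$net; opt$txProj <- up$state
        up <- adamStep(txEnc, bpEz$grads, opt$txEnc, cfg@learningRate)
        txEnc <- up$net; opt$txEnc <- up$state
        epochLoss <- epochLoss + lg$loss
        nb <- nb + 1
      }
      vl <- validLoss()
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_loss = epochLoss / nb,
                                  valid_loss = vl))
      score <- if (is.na(vl)) -epoch else vl  # no valid set: keep last
      if (score < best$loss) {
        best <- list(loss = score, epoch = epoch, cpEnc = cpEnc,
                     txEnc = txEnc, cpProj = cpProj, txProj = txProj)
      }
    }
    new("CLModel",
        cpEncoder = best$cpEnc, txEncoder = best$txEnc,
        cpProjection = best$cpProj, txProjection = best$txProj,
        config = cfg, history = history, bestEpoch = as.integer(best$epoch),
        cpFeatures = colnames(cpV), txFeatures = colnames(txV))
  })
}

#' @export
setMethod("show", "CLModel", function(object) {
  cat(sprintf(
    "CLModel: CP encoder [%s] -> %d, projection %d, temperature %.3g; best epoch %d/%d\n",
    paste(object@config@cpHiddenSizes, collapse = ", "),
    object@config@encoderOutputDim, object@config@projectionDim,
    object@config@temperature, object@bestEpoch, nrow(object@history)))
})

.checkFeatures <- function(x, features) {
  .assert(ncol(x) == length(features),
          "feature dimension mismatch: model was trained on ",
          length(features), " features, input has ", ncol(x))
  if (!is.null(colnames(x)))
    .assert(identical(colnames(x), features),
            "input feature names do not match the training features")
  invisible(TRUE)
}

#' @rdname embedProfiles
#' @export
setMethod("embedProfiles", signature("CLModel", "matrix"),
  function(model, x) {
    .checkFeatures(x, model@cpFeatures)
    out <- mlpForward(model@cpEncoder, x)$out
    rownames(out) <- rownames(x)
    out
  })

#' @rdname embedProfiles
#' @export
setMethod("embedProfiles", signature("CLModel", "ProfileMatrix"),
  function(model, x) {
    .assert(modality(x) == "CP", "embeddings are generated from CP profiles")
    embedProfiles(model, profileValues(x))
  })
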