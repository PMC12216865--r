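#' Bimodal autoencoder configuration
#'
#' @param encoderHidden CP encoder hidden widths (default
#'   `c(1024, 512, 512)`).
#' @param embeddingDim latent width, the learned embedding (default 512).
#' @param cpDecoderHidden CP decoder hidden widths (default
#'   `c(512, 512, 1024)`).
#' @param txDecoderHidden TX decoder hidden widths (default
#'   `c(1024, 2048, 4096)`).
#' @param maskRate fraction of CP input features zeroed per profile per
#'   batch (default 0.10; reconstruction targets stay unmasked).
#' @param batchSize,epochs,learningRate Adam optimisation parameters
#'   (defaults 256 / 50 / 1e-4).
#' @param reduce `"mean"` (default): each reconstruction error is averaged
#'   over rows and features, keeping the two halves comparable across
#'   batch sizes and feature dimensions; `"sum"`: raw summed squared
#'   residuals as printed in the objective.
#' @param seed integer seed.
#' @return a validated [BAEConfig-class].
#' @export
baeConfig <- function(encoderHidden = c(1024, 512, 512),
                      embeddingDim = 512,
                      cpDecoderHidden = c(512, 512, 1024),
                      txDecoderHidden = c(1024, 2048, 4096),
                      maskRate = 0.10, batchSize = 256, epochs = 50,
                      learningRate = 1e-4, reduce = c("mean", "sum"),
                      seed = 1) {
  reduce <- match.arg(reduce)
  new("BAEConfig",
      encoderHidden = as.integer(encoderHidden),
      embeddingDim = as.integer(embeddingDim),
      cpDecoderHidden = as.integer(cpDecoderHidden),
      txDecoderHidden = as.integer(txDecoderHidden),
      maskRate = maskRate, batchSize = as.integer(batchSize),
      epochs = as.integer(epochs), learningRate = learningRate,
      reduce = reduce, seed = as.integer(seed))
}

#' Bimodal reconstruction loss
#'
#' Equally weighted reconstruction error of the two decoders:
#' \deqn{L = \tfrac12\,\mathrm{MSE}(u', u) + \tfrac12\,\mathrm{MSE}(v', v)}
#' where `u`/`u'` are original and reconstructed CP rows and `v`/`v'` the
#' TX counterparts. With `reduce = "mean"` (default) each MSE averages
#' over rows and features; `reduce = "sum"` returns the raw summed squared
#' residuals with the same 1/2 weights. Zero iff both reconstructions are
#' exact.
#'
#' @param u,uHat original and reconstructed CP batch (matching shapes).
#' @param v,vHat original and reconstructed TX batch (matching shapes,
#'   same row count as `u`).
#' @param reduce `"mean"` or `"sum"`.
#' @return non-negative scalar.
#' @examples
#' baeLoss(u = rbind(c(0, 0)), uHat = rbind(c(2, 0)),
#'         v = rbind(1), vHat = rbind(0))  # 0.5*(4/2) + 0.5*(1/1) = 1.5
#' @export
baeLoss <- function(u, uHat, v, vHat, reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  u <- as.matrix(u); uHat <- as.matrix(uHat)
  v <- as.matrix(v); vHat <- as.matrix(vHat)
  .assert(all(dim(u) == dim(uHat)), "CP batch and reconstruction shapes differ")
  .assert(all(dim(v) == dim(vHat)), "TX batch and reconstruction shapes differ")
  .assert(nrow(u) == nrow(v), "CP and TX batches must pair the same rows")
  ru <- sum((uHat - u)^2)
  rv <- sum((vHat - v)^2)
  if (reduce == "mean") {
    ru <- ru / length(u)
    rv <- rv / length(v)
  }
  0.5 * ru + 0.5 * rv
}

#' Train the bimodal masked autoencoder
#'
#' One CP encoder, two decoders: from a masked CP replicate the model
#' reconstructs both the unmasked CP profile and the compound's TX
#' profile. Training uses pairs of the train split (valid split monitors
#' the loss on unmasked input); the weights with the lowest validation
#' loss are retained. TX is never an input — embeddings for new compounds
#' need only CP data.
#'
#' @param pairs a [PairSet-class] from [buildPairs()].
#' @param cp,tx the [ProfileMatrix-class] objects the pairs refer to.
#' @param split a [SplitAssignment-class].
#' @param cfg a [BAEConfig-class].
#' @return a trained [BAEModel-class] with its training history.
#' @seealso [embedProfiles()], [baeLoss()]
#' @export
trainBAE <- function(pairs, cp, tx, split, cfg) {
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
  txRow <- match(pt$compound_id, compoundIds(tx))
  cpRow <- match(pt$cp_row_id, rownames(cpV))
  .assert(!anyNA(txRow) && !anyNA(cpRow), "pairs refer to unknown profiles")
  dCp <- ncol(cpV)
  dTx <- ncol(txV)

  withSeed(cfg@seed, {
    enc <- mlpNew(c(dCp, cfg@encoderHidden, cfg@embeddingDim))
    decCp <- mlpNew(c(cfg@embeddingDim, cfg@cpDecoderHidden, dCp))
    decTx <- mlpNew(c(cfg@embeddingDim, cfg@txDecoderHidden, dTx))
    opt <- list(enc = adamNew(enc), decCp = adamNew(decCp),
                decTx = adamNew(decTx))
    batchLoss <- function(idx, masked) {
      U <- cpV[cpRow[idx], , drop = FALSE]
      V <- txV[txRow[idx], , drop = FALSE]
      Xin <- if (masked) maskFeatures(U, cfg@maskRate) else U
      fe <- mlpForward(enc, Xin)
      fu <- mlpForward(decCp, fe$out)
      fv <- mlpForward(decTx, fe$out)
      loss <- baeLoss(U, fu$out, V, fv$out, reduce = cfg@reduce)
      list(loss = loss, fe = fe, fu = fu, fv = fv, U = U, V = V)
    }
    validLoss <- function() {
      if (length(validIdx) < 1) return(NA_real_)
      tot <- 0; nb <- 0
      starts <- seq(1L, length(validIdx), by = cfg@batchSize)
      for (s in starts) {
        idx <- validIdx[s:min(s + cfg@batchSize - 1L, length(validIdx))]
        tot <- tot + batchLoss(idx, masked = FALSE)$loss
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
        bl <- batchLoss(idx, masked = TRUE)
        if (!is.finite(bl$loss))
          stop("non-finite reconstruction loss at epoch ", epoch,
               call. = FALSE)
        # d(0.5*MSE)/dRecon = residual / n (mean) or residual (sum)
        dU <- bl$fu$out - bl$U
        dV <- bl$fv$out - bl$V
        if (cfg@reduce == "mean") {
          dU <- dU / length(bl$U)
          dV <- dV / length(bl$V)
        }
        bu <- mlpBackward(decCp, bl$fu, dU)
        bv <- mlpBackward(decTx, bl$fv, dV)
        be <- mlpBackward(enc, bl$fe, bu$dX + bv$dX)
        up <- adamStep(decCp, bu$grads, opt$decCp, cfg@learningRate)
        decCp <- up$net; opt$decCp <- up$state
        up <- adamStep(decTx, bv$grads, opt$decTx, cfg@learningRate)
        decTx <- up$net; opt$decTx <- up$state
        up <- adamStep(enc, be$grads, opt$enc, cfg@learningRate)
        enc <- up$net; opt$enc <- up$state
        epochLoss <- epochLoss + bl$loss
        nb <- nb + 1
      }
      vl <- validLoss()
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_loss = epochLoss / nb,
                                  valid_loss = vl))
      score <- if (is.na(vl)) -epoch else vl
      if (score < best$loss)
        best <- list(loss = score, epoch = epoch, enc = enc,
                     decCp = decCp, decTx = decTx)
    }
    new("BAEModel",
        encoder = best$enc, cpDecoder = best$decCp, txDecoder = best$decTx,
        config = cfg, history = history, bestEpoch = as.integer(best$epoch),
        cpFeatures = colnames(cpV), txFeatures = colnames(txV))
  })
}

#' @export
setMethod("show", "BAEModel", function(object) {
  cat(sprintf(
    "BAEModel: encoder [%s] -> %d; best epoch %d/%d\n",
    paste(object@config@encoderHidden, collapse = ", "),
    object@config@embeddingDim, object@bestEpoch, nrow(object@history)))
})

#' @rdname embedProfiles
#' @export
setMethod("embedProfiles", signature("BAEModel", "matrix"),
  function(model, x) {
    .checkFeatures(x, model@cpFeatures)
    out <- mlpForward(model@encoder, x)$out
    rownames(out) <- rownames(x)
    out
  })

#' @rdname embedProfiles
#' @export
setMethod("embedProfiles", signature("BAEModel", "ProfileMatrix"),
  function(model, x) {
    .assert(modality(x) == "CP", "embeddings are generated from CP profiles")
    embedProfiles(model, profileValues(x))
  })

#' Reconstruct both modalities from CP profiles
#'
#' Runs the full autoencoder (no masking): CP input through the encoder
#' and both decoders.
#'
#' @param model a trained [BAEModel-class].
#' @param x CP [ProfileMatrix-class] or replicate-by-feature matrix.
#' @return list with `cp` and `tx` reconstruction matrices.
#' @export
reconstructProfiles <- function(model, x) {
  .assert(is(model, "BAEModel"), "'model' must be a BAEModel")
  if (is(x, "ProfileMatrix")) x <- profileValues(x)
  .checkFeatures(x, model@cpFeatures)
  e <- mlpForward(model@encoder, x)$out
  list(cp = mlpForward(model@cpDecoder, e)$out,
       tx = mlpForward(model@txDecoder, e)$out)
}
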