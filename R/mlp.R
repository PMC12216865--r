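# Minimal fully-connected network engine used by all three trainers
# (contrastive, bimodal autoencoder, multitask classifier). Dense layers
# with ReLU hidden activations and a linear output layer; He-normal
# initialisation; optional inverted dropout on hidden activations; Adam
# with optional L2 weight decay added to the gradient (as in the reference
# deep-learning framework's Adam). All state lives in plain R lists so
# models serialise as text-free R objects; matrix products go through BLAS.

# net: list(sizes = integer vector, layers = list(list(W, b)))
mlpNew <- function(sizes) {
  L <- length(sizes) - 1L
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    fanIn <- sizes[l]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fanIn * sizes[l + 1L], sd = sqrt(2 / fanIn)),
                 fanIn, sizes[l + 1L]),
      b = numeric(sizes[l + 1L])
    )
  }
  list(sizes = as.integer(sizes), layers = layers)
}

relu <- function(x) (x > 0) * x

# forward pass; returns output and the cache needed for backprop.
# dropout is applied to hidden activations only, inverted scaling.
mlpForward <- function(net, X, training = FALSE, dropout = 0) {
  L <- length(net$layers)
  hs <- vector("list", L + 1L)  # hs[[l]] is the input to layer l
  masks <- vector("list", L)
  hs[[1L]] <- X
  for (l in seq_len(L)) {
    a <- hs[[l]] %*% net$layers[[l]]$W
    a <- sweep(a, 2L, net$layers[[l]]$b, "+")
    if (l < L) {
      h <- relu(a)
      if (training && dropout > 0) {
        m <- matrix(stats::runif(length(h)) >= dropout,
                    nrow(h), ncol(h)) / (1 - dropout)
        h <- h * m
        masks[[l]] <- m
      }
      hs[[l + 1L]] <- h
    } else {
      hs[[l + 1L]] <- a
    }
  }
  list(out = hs[[L + 1L]], hs = hs, masks = masks)
}

# backward pass from dOut = dLoss/dOutput; returns per-layer grads and
# the gradient w.r.t. the input (needed to chain encoder <- projection).
mlpBackward <- function(net, cache, dOut) {
  L <- length(net$layers)
  grads <- vector("list", L)
  delta <- dOut
  for (l in rev(seq_len(L))) {
    h <- cache$hs[[l]]
    grads[[l]] <- list(W = crossprod(h, delta), b = colSums(delta))
    delta <- tcrossprod(delta, net$layers[[l]]$W)
    if (l > 1L) {
      # through dropout then ReLU of the previous hidden layer
      if (!is.null(cache$masks[[l - 1L]]))
        delta <- delta * cache$masks[[l - 1L]]
      delta <- delta * (cache$hs[[l]] > 0)
    }
  }
  list(grads = grads, dX = delta)
}

adamNew <- function(net) {
  lapply(net$layers, function(ly)
    list(mW = ly$W * 0, vW = ly$W * 0,
         mb = ly$b * 0, vb = ly$b * 0, t = 0L))
}

adamStep <- function(net, grads, state, lr, weightDecay = 0,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(net$layers)) {
    gW <- grads[[l]]$W
    gb <- grads[[l]]$b
    if (weightDecay > 0) {
      gW <- gW + weightDecay * net$layers[[l]]$W
      gb <- gb + weightDecay * net$layers[[l]]$b
    }
    st <- state[[l]]
    st$t <- st$t + 1L
    st$mW <- beta1 * st$mW + (1 - beta1) * gW
    st$vW <- beta2 * st$vW + (1 - beta2) * gW^2
    st$mb <- beta1 * st$mb + (1 - beta1) * gb
    st$vb <- beta2 * st$vb + (1 - beta2) * gb^2
    c1 <- 1 - beta1^st$t
    c2 <- 1 - beta2^st$t
    net$layers[[l]]$W <- net$layers[[l]]$W -
      lr * (st$mW / c1) / (sqrt(st$vW / c2) + eps)
    net$layers[[l]]$b <- net$layers[[l]]$b -
      lr * (st$mb / c1) / (sqrt(st$vb / c2) + eps)
    state[[l]] <- st
  }
  list(net = net, state = state)
}

# cosine-annealing warm restarts: lr at 'epoch' (1-based) with restart
# period 'period' epochs
cosineRestartLr <- function(baseLr, epoch, period) {
  tcur <- (epoch - 1L) %% period
  baseLr * 0.5 * (1 + cos(pi * tcur / period))
}
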