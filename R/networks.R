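## Compact dense networks with hand-derived backpropagation.
##
## At desk scale the encoders operate on average-pooled RGB summaries of
## the augmented views (pool_features), so the whole model is a stack of
## dense layers: ReLU hidden layers, optional identity skip connections
## (the "compact residual" default), and a linear output layer. Gradients
## are verified against finite differences in the test suite.

#' Create a dense network
#'
#' @param dims integer vector of layer widths, length L + 1 (input first).
#' @param skips logical vector of length L; \code{skips[i]} adds an
#'   identity shortcut around layer i (requires equal in/out width). The
#'   final layer is linear, all others ReLU.
#' @param bn logical vector of length L; \code{bn[i]} standardises layer
#'   i's pre-activations over the batch (zero mean, unit variance per
#'   unit, no learned affine) before the ReLU. Used in the
#'   projection/prediction heads, where batch standardisation is the
#'   standard guard against collapsed embeddings; ignored on the final
#'   (linear) layer.
#' @param stream [rng_stream()] used for He initialisation.
#' @return an object of class \code{dense_net}.
#' @export
new_dense_net <- function(dims, skips = NULL, bn = NULL, stream) {
  L <- length(dims) - 1L
  stopifnot(L >= 1)
  if (is.null(skips)) skips <- rep(FALSE, L)
  if (is.null(bn)) bn <- rep(FALSE, L)
  stopifnot(length(skips) == L, length(bn) == L)
  W <- vector("list", L)
  b <- vector("list", L)
  for (i in seq_len(L)) {
    if (skips[i] && dims[i] != dims[i + 1]) {
      stop("skip connection requires equal layer widths", call. = FALSE)
    }
    sd <- sqrt(2 / dims[i])
    W[[i]] <- matrix(stream_rnorm(stream, dims[i] * dims[i + 1], sd = sd),
                     dims[i], dims[i + 1])
    b[[i]] <- numeric(dims[i + 1])
  }
  bn_stats <- vector("list", L)
  for (i in seq_len(L)) {
    if (bn[i]) {
      bn_stats[[i]] <- list(mean = numeric(dims[i + 1]),
                            var = rep(1, dims[i + 1]))
    }
  }
  structure(list(dims = as.integer(dims), skips = skips, bn = bn,
                 bn_stats = bn_stats, W = W, b = b),
            class = "dense_net")
}

#' Forward pass through a dense network
#'
#' Batch-standardised layers use batch statistics when \code{training}
#' (and update their running statistics, returned in \code{net}); in
#' evaluation mode they use the stored running statistics, so features
#' are deterministic per item.
#'
#' @param net a \code{dense_net}.
#' @param X input matrix (n x dims[1]).
#' @param training training mode? (batch statistics + running-stat
#'   update).
#' @return list with \code{out} (n x dims[L+1]), \code{cache} for
#'   [net_backward()], and \code{net} (running statistics updated when
#'   \code{training}).
#' @export
net_forward <- function(net, X, training = FALSE) {
  L <- length(net$W)
  inputs <- vector("list", L)
  pres <- vector("list", L)
  bns <- vector("list", L)
  H <- X
  for (i in seq_len(L)) {
    inputs[[i]] <- H
    pre <- H %*% net$W[[i]]
    pre <- sweep(pre, 2, net$b[[i]], "+")
    if (i < L) {
      if (net$bn[i]) {
        if (training) {
          mu <- colMeans(pre)
          xc <- sweep(pre, 2, mu)
          v <- colMeans(xc^2)
          sig <- sqrt(v + 1e-5)
          st <- net$bn_stats[[i]]
          net$bn_stats[[i]] <- list(mean = 0.9 * st$mean + 0.1 * mu,
                                    var = 0.9 * st$var + 0.1 * v)
        } else {
          st <- net$bn_stats[[i]]
          xc <- sweep(pre, 2, st$mean)
          sig <- sqrt(st$var + 1e-5)
        }
        pre <- sweep(xc, 2, sig, "/")
        bns[[i]] <- list(xn = pre, sig = sig)
      }
      pres[[i]] <- pre
      H <- pre * (pre > 0)
      if (net$skips[i]) H <- H + inputs[[i]]
    } else {
      pres[[i]] <- pre
      H <- pre
      if (net$skips[i]) H <- H + inputs[[i]]
    }
  }
  list(out = H, cache = list(inputs = inputs, pres = pres, bns = bns),
       net = net)
}

#' Backward pass: parameter gradients and input gradient
#'
#' Assumes the cache came from a \code{training = TRUE} forward pass
#' (batch-statistics normalisation), which is the only mode gradients are
#' needed in.
#'
#' @param net a \code{dense_net}.
#' @param cache cache from [net_forward()].
#' @param dOut gradient of the loss w.r.t. the network output.
#' @return list with \code{dW}, \code{db} (same shapes as \code{net$W},
#'   \code{net$b}) and \code{dX}.
#' @export
net_backward <- function(net, cache, dOut) {
  L <- length(net$W)
  dW <- vector("list", L)
  db <- vector("list", L)
  dH <- dOut
  for (i in rev(seq_len(L))) {
    dPre <- if (i < L) dH * (cache$pres[[i]] > 0) else dH
    if (i < L && net$bn[i]) {
      bn <- cache$bns[[i]]
      dPre <- sweep(dPre, 2, colMeans(dPre)) -
        bn$xn * rep(colMeans(dPre * bn$xn), each = nrow(dPre))
      dPre <- sweep(dPre, 2, bn$sig, "/")
    }
    dW[[i]] <- crossprod(cache$inputs[[i]], dPre)
    db[[i]] <- colSums(dPre)
    dX <- dPre %*% t(net$W[[i]])
    if (net$skips[i]) dX <- dX + dH
    dH <- dX
  }
  list(dW = dW, db = db, dX = dH)
}

#' Compact residual encoder over pooled view features
#'
#' The desk-scale default backbone: views are average-pooled to a
#' \code{pool_grid x pool_grid} RGB summary (a parameter-free front end),
#' then passed through a residual MLP producing a fixed-length
#' representation. Widths are configurable; larger backbones plug in by
#' supplying a different \code{dense_net}.
#'
#' @param pool_grid pooling grid for [pool_features()].
#' @param hidden hidden width.
#' @param rep_dim representation dimension.
#' @param stream [rng_stream()] for initialisation.
#' @return object of class \code{encoder}: the pooling front end plus a
#'   \code{dense_net}.
#' @export
make_encoder <- function(pool_grid = 8, hidden = 64, rep_dim = 32, stream) {
  d_in <- 3 * pool_grid^2
  net <- new_dense_net(c(d_in, hidden, hidden, rep_dim),
                       skips = c(FALSE, TRUE, FALSE),
                       bn = c(TRUE, TRUE, FALSE), stream = stream)
  structure(list(pool_grid = pool_grid, net = net, rep_dim = rep_dim),
            class = "encoder")
}

#' Encode a batch of views
#'
#' @param encoder an [make_encoder()] object.
#' @param views list of RGB arrays, or an already-pooled feature matrix.
#' @param with_cache also return the forward cache (for training).
#' @return representation matrix (n x rep_dim), or a list
#'   \code{(out, cache, X)} when \code{with_cache}.
#' @export
encode_views <- function(encoder, views, with_cache = FALSE) {
  X <- if (is.matrix(views)) views else pool_features(views,
                                                      encoder$pool_grid)
  f <- net_forward(encoder$net, X)
  if (with_cache) c(f, list(X = X)) else f$out
}

#' Projection / prediction heads
#'
#' Two-layer MLP heads (hidden batch-standardised ReLU, linear output) in
#' the joint-embedding convention: the projector maps representations into
#' the embedding space where the loss operates; the predictor (BYOL only)
#' maps online projections onto target projections. The hidden batch
#' standardisation is the standard guard against collapse to constant
#' embeddings.
#'
#' @param in_dim input width.
#' @param hidden hidden width (default 512).
#' @param out_dim output width (default 128).
#' @param stream [rng_stream()] for initialisation.
#' @export
make_head <- function(in_dim, hidden = 512, out_dim = 128, stream) {
  new_dense_net(c(in_dim, hidden, out_dim), bn = c(TRUE, FALSE),
                stream = stream)
}

## deterministic scalar fingerprint of all parameters; used to assert the
## frozen-encoder contract without hashing libraries
net_fingerprint <- function(net) {
  v <- unlist(c(net$W, net$b, net$bn_stats), use.names = FALSE)
  c(n = length(v), sum = sum(v), ssq = sum(v^2),
    dot = sum(v * seq_along(v)))
}

#' Fingerprint an encoder's parameters
#'
#' Deterministic summary (length, sum, sum of squares, indexed dot
#' product) of every parameter; equal fingerprints before and after a
#' procedure certify the parameters were untouched.
#'
#' @param encoder an encoder (or any \code{dense_net}).
#' @export
encoder_fingerprint <- function(encoder) {
  net <- if (inherits(encoder, "encoder")) encoder$net else encoder
  net_fingerprint(net)
}

## elementwise EMA over the parameter lists of two networks of identical
## shape: target <- m * target + (1 - m) * online
net_ema <- function(target, online, m) {
  for (i in seq_along(target$W)) {
    if (!all(dim(target$W[[i]]) == dim(online$W[[i]]))) {
      stop("parameter shape mismatch in EMA update", call. = FALSE)
    }
    target$W[[i]] <- m * target$W[[i]] + (1 - m) * online$W[[i]]
    target$b[[i]] <- m * target$b[[i]] + (1 - m) * online$b[[i]]
  }
  target
}
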