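#' Initialise a joint-embedding framework state
#'
#' Builds the online networks (encoder, projector, and for the bootstrap
#' framework a predictor plus an EMA target copy of encoder and
#' projector), the optimiser buffers, and the framework's loss
#' hyperparameters. All initialisation randomness comes from streams
#' derived from \code{seed}.
#'
#' @param framework one of \code{"byol"}, \code{"simclr"}, \code{"vicreg"}.
#' @param seed integer seed for parameter initialisation.
#' @param pool_grid encoder pooling grid (see [make_encoder()]).
#' @param encoder_hidden,rep_dim encoder widths.
#' @param proj_hidden,proj_dim projector (and predictor) widths.
#' @param ema_momentum EMA momentum for the target network (BYOL only).
#' @param temperature NT-Xent temperature (SimCLR only).
#' @param vicreg_coeffs numeric length 3: invariance, variance, covariance
#'   weights (VICReg only).
#' @param lars_momentum heavy-ball momentum used inside the LARS step.
#' @return an object of class \code{ssl_state}.
#' @export
ssl_state <- function(framework = c("byol", "simclr", "vicreg"), seed = 1,
                      pool_grid = 8, encoder_hidden = 64, rep_dim = 32,
                      proj_hidden = 512, proj_dim = 128,
                      ema_momentum = 0.99, temperature = 0.5,
                      vicreg_coeffs = c(25, 25, 1), lars_momentum = 0.9) {
  framework <- match.arg(framework)
  enc <- make_encoder(pool_grid, encoder_hidden, rep_dim,
                      rng_stream(seed, "init/encoder"))
  proj <- make_head(rep_dim, proj_hidden, proj_dim,
                    rng_stream(seed, "init/projector"))
  state <- list(framework = framework, encoder = enc, projector = proj,
                predictor = NULL, target = NULL,
                ema_momentum = ema_momentum, temperature = temperature,
                vicreg_coeffs = vicreg_coeffs,
                lars_momentum = lars_momentum, step = 0L,
                opt = list())
  if (framework == "byol") {
    state$predictor <- make_head(proj_dim, proj_hidden, proj_dim,
                                 rng_stream(seed, "init/predictor"))
    ## target starts as an exact copy of the online networks
    state$target <- list(encoder = enc$net, projector = proj)
  }
  class(state) <- "ssl_state"
  state
}

zero_like <- function(net) {
  list(W = lapply(net$W, function(w) w * 0),
       b = lapply(net$b, function(v) v * 0))
}

#' One LARS optimiser step on a dense network
#'
#' Layer-wise adaptive rate scaling: each weight matrix is updated with a
#' local learning rate \code{lr * ||w|| / (||g + wd * w|| + eps)} and
#' heavy-ball momentum. Biases are excluded from both the trust-ratio
#' adaptation and weight decay and take a plain momentum-SGD step, the
#' standard exclusion for normalisation/bias parameters.
#'
#' @param net a \code{dense_net}.
#' @param grads gradients (\code{dW}, \code{db}) from [net_backward()].
#' @param buf momentum buffers from a previous call (NULL to start).
#' @param lr global learning rate.
#' @param weight_decay L2 coefficient applied to weight matrices.
#' @param momentum heavy-ball momentum.
#' @param eps trust-ratio denominator floor.
#' @return list \code{(net, buf)} with updated parameters and buffers.
#' @export
lars_step <- function(net, grads, buf = NULL, lr, weight_decay = 0,
                      momentum = 0.9, eps = 1e-9) {
  if (any(!vapply(grads$dW, function(g) all(is.finite(g)), logical(1)))) {
    stop("non-finite gradient in LARS step", call. = FALSE)
  }
  if (is.null(buf)) buf <- zero_like(net)
  for (i in seq_along(net$W)) {
    g <- grads$dW[[i]] + weight_decay * net$W[[i]]
    wn <- sqrt(sum(net$W[[i]]^2))
    gn <- sqrt(sum(g^2))
    local_lr <- if (wn > 0 && gn > 0) lr * wn / (gn + eps) else lr
    buf$W[[i]] <- momentum * buf$W[[i]] + local_lr * g
    net$W[[i]] <- net$W[[i]] - buf$W[[i]]
    buf$b[[i]] <- momentum * buf$b[[i]] + lr * grads$db[[i]]
    net$b[[i]] <- net$b[[i]] - buf$b[[i]]
  }
  list(net = net, buf = buf)
}

#' EMA update of a target network
#'
#' Every target parameter becomes \code{m * target + (1 - m) * online}.
#' Target parameters are never touched by gradients; this recursion is
#' their only update path.
#'
#' @param target,online \code{dense_net}s (or lists of them) of identical
#'   shape.
#' @param m momentum in [0, 1]; \code{m = 1} freezes the target,
#'   \code{m = 0} copies the online network.
#' @export
ema_update <- function(target, online, m) {
  stopifnot(m >= 0, m <= 1)
  if (inherits(target, "dense_net")) return(net_ema(target, online, m))
  if (inherits(target, "encoder")) {
    target$net <- net_ema(target$net,
                          if (inherits(online, "encoder")) online$net
                          else online, m)
    return(target)
  }
  stopifnot(is.list(target), length(target) == length(online))
  for (k in seq_along(target)) {
    target[[k]] <- ema_update(target[[k]], online[[k]], m)
  }
  target
}

## forward one view through encoder+projector in training mode, threading
## the running-statistics updates back into the state
forward_branch <- function(state, X) {
  e <- net_forward(state$encoder$net, X, training = TRUE)
  state$encoder$net <- e$net
  p <- net_forward(state$projector, e$out, training = TRUE)
  state$projector <- p$net
  list(enc = e, proj = p, state = state)
}

## accumulate parameter grads from a projector-output gradient
backward_branch <- function(state, br, X, dProj) {
  gp <- net_backward(state$projector, br$proj$cache, dProj)
  ge <- net_backward(state$encoder$net, br$enc$cache, gp$dX)
  list(proj = gp, enc = ge)
}

add_grads <- function(a, b) {
  list(dW = Map(`+`, a$dW, b$dW), db = Map(`+`, a$db, b$db))
}

#' One training step of a joint-embedding framework
#'
#' Pools and encodes both views of a [generate_views()] batch, computes
#' the framework's loss over the full batch (labeled-permuted and
#' unlabeled items concatenated; every loss here is invariant to a common
#' positional reordering, so the composition order is irrelevant),
#' backpropagates, applies one LARS step, and for the bootstrap framework
#' updates the target by EMA.
#'
#' @param state an [ssl_state()].
#' @param views a \code{view_pair_batch} (or a list with \code{view1},
#'   \code{view2} lists of images / pooled feature matrices).
#' @param lr learning rate for this step (see [warmup_cosine_lr()]).
#' @param weight_decay L2 coefficient.
#' @return list \code{(state, loss, components)}.
#' @export
framework_step <- function(state, views, lr, weight_decay = 1e-6) {
  stopifnot(inherits(state, "ssl_state"))
  pg <- state$encoder$pool_grid
  X1 <- if (is.matrix(views$view1)) views$view1 else
    pool_features(views$view1, pg)
  X2 <- if (is.matrix(views$view2)) views$view2 else
    pool_features(views$view2, pg)
  br1 <- forward_branch(state, X1)
  state <- br1$state
  br2 <- forward_branch(state, X2)
  state <- br2$state
  components <- NULL
  if (state$framework == "byol") {
    pr1 <- net_forward(state$predictor, br1$proj$out, training = TRUE)
    state$predictor <- pr1$net
    pr2 <- net_forward(state$predictor, br2$proj$out, training = TRUE)
    state$predictor <- pr2$net
    ## target branch: batch statistics, no gradient, running stats
    ## discarded (the target is never used in evaluation mode)
    t1 <- net_forward(state$target$projector,
                      net_forward(state$target$encoder, X1,
                                  training = TRUE)$out,
                      training = TRUE)$out
    t2 <- net_forward(state$target$projector,
                      net_forward(state$target$encoder, X2,
                                  training = TRUE)$out,
                      training = TRUE)$out
    l <- byol_loss(pr1$out, pr2$out, t1, t2, grad = TRUE)
    loss <- l$loss
    gpr1 <- net_backward(state$predictor, pr1$cache, l$grad_pred1)
    gpr2 <- net_backward(state$predictor, pr2$cache, l$grad_pred2)
    g1 <- backward_branch(state, br1, X1, gpr1$dX)
    g2 <- backward_branch(state, br2, X2, gpr2$dX)
    grads <- list(encoder = add_grads(g1$enc, g2$enc),
                  projector = add_grads(g1$proj, g2$proj),
                  predictor = add_grads(gpr1, gpr2))
  } else if (state$framework == "simclr") {
    l <- nt_xent_loss(br1$proj$out, br2$proj$out, state$temperature,
                      grad = TRUE)
    loss <- l$loss
    g1 <- backward_branch(state, br1, X1, l$grad_z1)
    g2 <- backward_branch(state, br2, X2, l$grad_z2)
    grads <- list(encoder = add_grads(g1$enc, g2$enc),
                  projector = add_grads(g1$proj, g2$proj))
  } else {
    cf <- state$vicreg_coeffs
    l <- vicreg_loss(br1$proj$out, br2$proj$out, cf[1], cf[2], cf[3],
                     grad = TRUE)
    loss <- l$loss
    components <- l$components
    g1 <- backward_branch(state, br1, X1, l$grad_z1)
    g2 <- backward_branch(state, br2, X2, l$grad_z2)
    grads <- list(encoder = add_grads(g1$enc, g2$enc),
                  projector = add_grads(g1$proj, g2$proj))
  }
  if (!is.finite(loss)) {
    stop(sprintf("training diverged: non-finite %s loss at step %d",
                 state$framework, state$step), call. = FALSE)
  }
  up <- lars_step(state$encoder$net, grads$encoder, state$opt$encoder, lr,
                  weight_decay, state$lars_momentum)
  state$encoder$net <- up$net
  state$opt$encoder <- up$buf
  up <- lars_step(state$projector, grads$projector, state$opt$projector,
                  lr, weight_decay, state$lars_momentum)
  state$projector <- up$net
  state$opt$projector <- up$buf
  if (state$framework == "byol") {
    up <- lars_step(state$predictor, grads$predictor,
                    state$opt$predictor, lr, weight_decay,
                    state$lars_momentum)
    state$predictor <- up$net
    state$opt$predictor <- up$buf
    state$target <- ema_update(state$target,
                               list(encoder = state$encoder$net,
                                    projector = state$projector),
                               state$ema_momentum)
  }
  state$step <- state$step + 1L
  list(state = state, loss = loss, components = components)
}

#' Save / load a training checkpoint
#'
#' Single-file serialised state; reloading reproduces the next step's loss
#' exactly.
#'
#' @param state an [ssl_state()] (or any serialisable list).
#' @param path file path.
#' @export
save_checkpoint <- function(state, path) {
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
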