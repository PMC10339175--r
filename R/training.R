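#' Pretraining configuration
#'
#' Defaults follow the full-scale recipe: LARS for 50 epochs with a
#' 5-epoch linear warmup and cosine decay, base learning rate 0.45,
#' mini-batch 256, weight decay 1e-6, labeled fraction alpha = 0.75 (192
#' labeled + 64 unlabeled per batch). Desk-scale runs override the sizes,
#' not the structure.
#'
#' @param epochs,warmup_epochs schedule length in epochs.
#' @param base_lr peak learning rate reached at warmup end.
#' @param batch_size mini-batch size N.
#' @param weight_decay L2 coefficient.
#' @param alpha labeled fraction of each mini-batch in [0, 1].
#' @param histoperm apply the class-preserving permutation? FALSE runs the
#'   vanilla pipeline, in which the entire batch is treated as unlabeled
#'   (equivalent to alpha = 0).
#' @param framework \code{"byol"}, \code{"simclr"} or \code{"vicreg"}.
#' @param seed base seed; every random stream of the run derives from it.
#' @param policy an [augmentation_policy()].
#' @param ... model/framework overrides passed to [ssl_state()]
#'   (\code{pool_grid}, \code{encoder_hidden}, \code{rep_dim},
#'   \code{proj_hidden}, \code{proj_dim}, \code{ema_momentum},
#'   \code{temperature}, \code{vicreg_coeffs}, \code{lars_momentum}).
#' @return list of class \code{pretrain_config}.
#' @export
pretrain_config <- function(epochs = 50, warmup_epochs = 5, base_lr = 0.45,
                            batch_size = 256, weight_decay = 1e-6,
                            alpha = 0.75, histoperm = TRUE,
                            framework = "byol", seed = 1,
                            policy = augmentation_policy(), ...) {
  stopifnot(warmup_epochs < epochs, alpha >= 0, alpha <= 1)
  structure(list(epochs = epochs, warmup_epochs = warmup_epochs,
                 base_lr = base_lr, batch_size = batch_size,
                 weight_decay = weight_decay, alpha = alpha,
                 histoperm = histoperm, framework = framework,
                 seed = seed, policy = policy, model = list(...)),
            class = "pretrain_config")
}

#' Warmup-cosine learning-rate schedule
#'
#' Linear ramp from 0 to \code{base_lr} over the warmup steps, then cosine
#' decay \code{base_lr * 0.5 * (1 + cos(pi * progress))} where progress
#' runs from warmup end to the final step; the rate is exactly
#' \code{base_lr} at warmup end and exactly 0 at the last step.
#'
#' @param step current step in \code{[0, total_steps]}.
#' @param warmup_steps steps of linear warmup.
#' @param total_steps total steps of the run (> warmup_steps).
#' @param base_lr peak learning rate.
#' @export
warmup_cosine_lr <- function(step, warmup_steps, total_steps, base_lr) {
  if (total_steps <= warmup_steps) {
    stop("total_steps must exceed warmup_steps", call. = FALSE)
  }
  stopifnot(step >= 0, step <= total_steps)
  if (warmup_steps > 0 && step < warmup_steps) {
    return(base_lr * step / warmup_steps)
  }
  progress <- (step - warmup_steps) / (total_steps - warmup_steps)
  base_lr * 0.5 * (1 + cos(pi * progress))
}

#' Dynamic per-epoch labeled/unlabeled partition
#'
#' The labeled/unlabeled status of a patch is not a property of the data:
#' it is re-drawn every epoch. A random disjoint split assigns
#' \code{floor(alpha * n)} manifest rows to the labeled pool; the rest
#' form the unlabeled pool, whose labels are masked for the epoch.
#'
#' @param manifest patch manifest data.frame.
#' @param alpha labeled fraction in [0, 1].
#' @param epoch_seed integer seed for this epoch's split.
#' @return list with integer row indices \code{labeled} and
#'   \code{unlabeled} (disjoint, union = all rows).
#' @export
epoch_partition <- function(manifest, alpha, epoch_seed) {
  stopifnot(alpha >= 0, alpha <= 1)
  n <- nrow(manifest)
  n_l <- floor(alpha * n)
  stream <- rng_stream(epoch_seed, "epoch/partition")
  lab <- sort(stream_sample_int(stream, n, n_l))
  list(labeled = lab, unlabeled = setdiff(seq_len(n), lab))
}

#' Fetch one patch's pixels from a patch dataset
#'
#' @param dataset list with \code{manifest} and \code{images} (named list
#'   of slide arrays at target magnification), as produced by
#'   [patchify()] or [make_patch_dataset()].
#' @param i manifest row index.
#' @export
get_patch <- function(dataset, i) {
  m <- dataset$manifest[i, ]
  extract_patch(dataset$images[[m$slide_id]], m$x, m$y, m$patch_size)
}

## number of mini-batches an epoch supports under the composition spec,
## under-sampling the pool that runs out first
batches_per_epoch <- function(n_lab, n_unl, comp) {
  counts <- c(
    if (comp$n_labeled > 0) n_lab %/% comp$n_labeled,
    if (comp$n_unlabeled > 0) n_unl %/% comp$n_unlabeled)
  n <- min(counts)
  if (!is.finite(n) || n < 1) {
    stop("dataset too small for one mini-batch under this composition",
         call. = FALSE)
  }
  n
}

#' Self-supervised pretraining loop
#'
#' Runs the full pipeline: per epoch, a fresh labeled/unlabeled partition
#' of the manifest, shuffled pools sampled without replacement into
#' mini-batches of \code{floor(alpha * N)} labeled plus the rest unlabeled
#' items, two-view generation with the class-preserving permutation of the
#' second labeled view, and one framework step per batch under the
#' warmup-cosine LARS schedule. Fully reproducible from
#' \code{config$seed}.
#'
#' @param dataset patch dataset (\code{manifest} + \code{images}).
#' @param config a [pretrain_config()].
#' @return list with \code{state} (trained [ssl_state()]), \code{log}
#'   (data.frame step, epoch, lr, loss, components) and \code{config}.
#' @export
pretrain <- function(dataset, config) {
  stopifnot(inherits(config, "pretrain_config"),
            nrow(dataset$manifest) >= 1)
  alpha_eff <- if (config$histoperm) config$alpha else 0
  comp <- split_minibatch(config$batch_size, alpha_eff)
  state <- do.call(ssl_state, c(list(framework = config$framework,
                                     seed = derive_seed(config$seed,
                                                        "model")),
                                config$model))
  vrng <- view_rng(derive_seed(config$seed, "views"))
  sampling <- rng_stream(config$seed, "sampling")
  n <- nrow(dataset$manifest)
  nb <- batches_per_epoch(floor(alpha_eff * n), n - floor(alpha_eff * n),
                          comp)
  total_steps <- config$epochs * nb
  warmup_steps <- config$warmup_epochs * nb
  log <- vector("list", total_steps)
  step <- 0L
  for (epoch in seq_len(config$epochs)) {
    part <- epoch_partition(dataset$manifest, alpha_eff,
                            derive_seed(config$seed,
                                        paste0("epoch/", epoch)))
    ord_l <- if (length(part$labeled) > 0)
      stream_sample(sampling, part$labeled) else integer(0)
    ord_u <- if (length(part$unlabeled) > 0)
      stream_sample(sampling, part$unlabeled) else integer(0)
    for (b in seq_len(nb)) {
      li <- if (comp$n_labeled > 0)
        ord_l[((b - 1) * comp$n_labeled + 1):(b * comp$n_labeled)]
      else integer(0)
      ui <- if (comp$n_unlabeled > 0)
        ord_u[((b - 1) * comp$n_unlabeled + 1):(b * comp$n_unlabeled)]
      else integer(0)
      labeled <- lapply(li, function(k) get_patch(dataset, k))
      unlabeled <- lapply(ui, function(k) get_patch(dataset, k))
      views <- generate_views(labeled, dataset$manifest$label[li],
                              unlabeled, config$policy, vrng,
                              permute = config$histoperm)
      lr <- warmup_cosine_lr(step, warmup_steps, total_steps,
                             config$base_lr)
      res <- framework_step(state, views, lr, config$weight_decay)
      state <- res$state
      step <- step + 1L
      log[[step]] <- data.frame(
        step = step, epoch = epoch, lr = lr, loss = res$loss,
        invariance = if (is.null(res$components)) NA_real_
                     else res$components[["invariance"]],
        variance = if (is.null(res$components)) NA_real_
                   else res$components[["variance"]],
        covariance = if (is.null(res$components)) NA_real_
                     else res$components[["covariance"]])
    }
  }
  list(state = state, log = do.call(rbind, log), config = config)
}

#' Linear-probe evaluation configuration
#'
#' Defaults follow the full-scale recipe: SGD with Nesterov momentum for
#' 80 epochs, initial learning rate 0.2, mini-batch 256, cosine decay,
#' cross-entropy loss. Training inputs receive affine transformations
#' only (horizontal/vertical flips, small rotation and translation); no
#' crop-rescale, no blur.
#'
#' @param epochs,base_lr,batch_size optimisation schedule.
#' @param momentum SGD momentum.
#' @param nesterov use the Nesterov form?
#' @param affine apply the affine training augmentation?
#' @param max_rotate maximum absolute rotation in degrees.
#' @param max_translate maximum translation as a fraction of the side.
#' @param flip_probability per-axis flip probability.
#' @param seed base seed.
#' @export
linear_eval_config <- function(epochs = 80, base_lr = 0.2,
                               batch_size = 256, momentum = 0.9,
                               nesterov = TRUE, affine = TRUE,
                               max_rotate = 15, max_translate = 0.1,
                               flip_probability = 0.5, seed = 1) {
  structure(list(epochs = epochs, base_lr = base_lr,
                 batch_size = batch_size, momentum = momentum,
                 nesterov = nesterov, affine = affine,
                 max_rotate = max_rotate, max_translate = max_translate,
                 flip_probability = flip_probability, seed = seed),
            class = "linear_eval_config")
}

## affine-only training augmentation for the linear probe
affine_augment <- function(img, stream, cfg) {
  fl <- stream_runif(stream, 2)
  img <- flip_image(img, fl[1] < cfg$flip_probability,
                    fl[2] < cfg$flip_probability)
  d <- dim(img)
  angle <- stream_runif(stream, 1, -cfg$max_rotate, cfg$max_rotate)
  tx <- stream_runif(stream, 1, -cfg$max_translate, cfg$max_translate) *
    d[2]
  ty <- stream_runif(stream, 1, -cfg$max_translate, cfg$max_translate) *
    d[1]
  affine_warp(img, angle, tx, ty)
}

softmax_rows <- function(L) {
  M <- apply(L, 1, max)
  E <- exp(L - M)
  E / rowSums(E)
}

#' Train a linear probe on a frozen encoder
#'
#' Fits a single linear layer by cross-entropy on the representations of
#' the (affine-augmented) training patches; the encoder parameters are
#' bit-identical before and after. Evaluation features are computed
#' without augmentation.
#'
#' @param encoder a trained encoder (from \code{pretrain()$state$encoder})
#'   or an [ssl_state()].
#' @param train_dataset,eval_dataset patch datasets (\code{manifest} +
#'   \code{images}); predictions are emitted for \code{eval_dataset}.
#' @param config a [linear_eval_config()].
#' @return list with \code{head} (\code{W}, \code{b}, \code{classes}),
#'   \code{log} (per-epoch lr and training accuracy), \code{predictions}
#'   (see [predict_patches()]) and \code{encoder_unchanged} (TRUE).
#' @export
linear_eval <- function(encoder, train_dataset, eval_dataset = NULL,
                        config = linear_eval_config()) {
  if (inherits(encoder, "ssl_state")) encoder <- encoder$encoder
  stopifnot(inherits(encoder, "encoder"))
  fp0 <- encoder_fingerprint(encoder)
  classes <- sort(unique(train_dataset$manifest$label))
  k <- length(classes)
  if (k < 2) stop("linear probe needs at least 2 classes", call. = FALSE)
  y <- match(train_dataset$manifest$label, classes)
  n <- nrow(train_dataset$manifest)
  d <- encoder$rep_dim
  init <- rng_stream(config$seed, "probe/init")
  W <- matrix(stream_rnorm(init, d * k, sd = 0.01), d, k)
  bvec <- numeric(k)
  vW <- W * 0
  vb <- bvec * 0
  shuffle <- rng_stream(config$seed, "probe/shuffle")
  aug <- rng_stream(config$seed, "probe/affine")
  patches <- lapply(seq_len(n), function(i) get_patch(train_dataset, i))
  log <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    lr <- config$base_lr * 0.5 *
      (1 + cos(pi * (epoch - 1) / config$epochs))
    ord <- stream_sample(shuffle, seq_len(n))
    correct <- 0L
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      imgs <- patches[idx]
      if (config$affine) {
        imgs <- lapply(imgs, affine_augment, stream = aug, cfg = config)
      }
      f <- encode_views(encoder, imgs)
      logits <- sweep(f %*% W, 2, bvec, "+")
      P <- softmax_rows(logits)
      Y <- matrix(0, length(idx), k)
      Y[cbind(seq_along(idx), y[idx])] <- 1
      G <- (P - Y) / length(idx)
      gW <- crossprod(f, G)
      gb <- colSums(G)
      vW <- config$momentum * vW + gW
      vb <- config$momentum * vb + gb
      if (config$nesterov) {
        W <- W - lr * (gW + config$momentum * vW)
        bvec <- bvec - lr * (gb + config$momentum * vb)
      } else {
        W <- W - lr * vW
        bvec <- bvec - lr * vb
      }
      correct <- correct + sum(max.col(P, ties.method = "first") ==
                                 y[idx])
    }
    log[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                               train_accuracy = correct / n)
  }
  fp1 <- encoder_fingerprint(encoder)
  head <- list(W = W, b = bvec, classes = classes)
  preds <- if (!is.null(eval_dataset)) {
    predict_patches(encoder, head, eval_dataset)
  }
  list(head = head, log = do.call(rbind, log), predictions = preds,
       encoder_unchanged = identical(fp0, fp1))
}

#' Patch-level class probabilities from a frozen encoder + linear head
#'
#' No augmentation is applied at prediction time. Probability columns are
#' named \code{prob_<class>} in the head's class order.
#'
#' @param encoder a trained encoder.
#' @param head linear head from [linear_eval()].
#' @param dataset patch dataset to predict on.
#' @return data.frame with slide_id, x, y, true_label and one probability
#'   column per class.
#' @export
predict_patches <- function(encoder, head, dataset) {
  if (inherits(encoder, "ssl_state")) encoder <- encoder$encoder
  n <- nrow(dataset$manifest)
  imgs <- lapply(seq_len(n), function(i) get_patch(dataset, i))
  f <- encode_views(encoder, imgs)
  P <- softmax_rows(sweep(f %*% head$W, 2, head$b, "+"))
  colnames(P) <- paste0("prob_", head$classes)
  cbind(dataset$manifest[, c("slide_id", "x", "y")],
        data.frame(true_label = dataset$manifest$label),
        as.data.frame(P))
}
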