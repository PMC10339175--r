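#' Mini-batch composition under a labeled fraction alpha
#'
#' A mini-batch of size N is drawn from two pools: a labeled pool
#' contributing \code{floor(alpha * N)} items whose second view will be
#' permuted within class, and an unlabeled pool contributing the rest,
#' which passes through the standard two-view pipeline untouched. At
#' \code{alpha = 0} the whole batch is unlabeled and the pipeline reduces
#' to the vanilla scheme.
#'
#' @param N total mini-batch size (>= 1).
#' @param alpha labeled fraction in [0, 1].
#' @return list with \code{N}, \code{alpha}, \code{n_labeled},
#'   \code{n_unlabeled}.
#' @export
split_minibatch <- function(N, alpha) {
  stopifnot(N >= 1)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("alpha must be a single number in [0, 1]", call. = FALSE)
  }
  n_l <- as.integer(floor(alpha * N))
  list(N = as.integer(N), alpha = alpha, n_labeled = n_l,
       n_unlabeled = as.integer(N) - n_l)
}

#' Stochastic augmentation policy for view generation
#'
#' The two views of every patch are produced by the same family of
#' transforms with independent random draws: random resized crop rescaled
#' to \code{output_size} with bilinear interpolation, independent
#' horizontal and vertical flips (histology is rotation invariant), and
#' random Gaussian blur.
#'
#' @param output_size view side length in pixels (default 224).
#' @param crop_scale_range area fraction range of the random crop.
#' @param flip_probability per-axis flip probability.
#' @param blur_probability probability of applying the blur.
#' @param blur_sigma_range range the blur sigma is drawn from.
#' @param blur_kernel_size odd Gaussian kernel width.
#' @return an object of class \code{augmentation_policy}.
#' @export
augmentation_policy <- function(output_size = 224,
                                crop_scale_range = c(0.08, 1),
                                flip_probability = 0.5,
                                blur_probability = 0.5,
                                blur_sigma_range = c(0.1, 2),
                                blur_kernel_size = 23) {
  stopifnot(output_size >= 1,
            length(crop_scale_range) == 2, all(crop_scale_range > 0),
            crop_scale_range[1] <= crop_scale_range[2],
            flip_probability >= 0, flip_probability <= 1,
            blur_probability >= 0, blur_probability <= 1,
            all(blur_sigma_range > 0))
  structure(list(output_size = as.integer(output_size),
                 crop_scale_range = crop_scale_range,
                 flip_probability = flip_probability,
                 blur_probability = blur_probability,
                 blur_sigma_range = blur_sigma_range,
                 blur_kernel_size = as.integer(blur_kernel_size)),
            class = "augmentation_policy")
}

## torchvision-style random resized crop: sample an area fraction and a
## log-uniform aspect ratio, retry up to 10 times, fall back to a centred
## crop of the largest valid square.
sample_crop_box <- function(h, w, scale_range, stream) {
  for (attempt in 1:10) {
    area <- stream_runif(stream, 1, scale_range[1], scale_range[2]) * h * w
    log_ratio <- stream_runif(stream, 1, log(3 / 4), log(4 / 3))
    ratio <- exp(log_ratio)
    cw <- round(sqrt(area * ratio))
    ch <- round(sqrt(area / ratio))
    if (cw >= 1 && ch >= 1 && cw <= w && ch <= h) {
      x0 <- floor(stream_runif(stream, 1, 0, w - cw + 1))
      y0 <- floor(stream_runif(stream, 1, 0, h - ch + 1))
      x0 <- min(x0, w - cw)
      y0 <- min(y0, h - ch)
      return(list(x = x0, y = y0, w = cw, h = ch))
    }
  }
  side <- min(h, w)
  list(x = (w - side) %/% 2, y = (h - side) %/% 2, w = side, h = side)
}

#' Produce one augmented view of a patch
#'
#' Applies random resized crop (bilinear rescale to the policy's output
#' size), independent horizontal/vertical flips, and optional Gaussian
#' blur. The result is fully determined by the supplied random streams.
#'
#' @param patch RGB array.
#' @param policy an [augmentation_policy()].
#' @param rng a [view_rng()] bundle (streams \code{crop}, \code{flip},
#'   \code{blur} are consumed).
#' @return RGB array \code{output_size x output_size x 3}.
#' @export
augment <- function(patch, policy, rng) {
  assert_image(patch)
  stopifnot(inherits(policy, "augmentation_policy"))
  d <- dim(patch)
  box <- sample_crop_box(d[1], d[2], policy$crop_scale_range, rng$crop)
  v <- patch[(box$y + 1):(box$y + box$h), (box$x + 1):(box$x + box$w), ,
             drop = FALSE]
  v <- bilinear_resize(v, policy$output_size, policy$output_size)
  fl <- stream_runif(rng$flip, 2)
  v <- flip_image(v, horizontal = fl[1] < policy$flip_probability,
                  vertical = fl[2] < policy$flip_probability)
  bl <- stream_runif(rng$blur, 2)
  if (bl[1] < policy$blur_probability) {
    sigma <- policy$blur_sigma_range[1] +
      bl[2] * diff(policy$blur_sigma_range)
    v <- gaussian_blur_image(v, sigma, policy$blur_kernel_size)
  }
  v
}

#' Sample a class-preserving permutation plan
#'
#' Draws uniformly from the bijections \code{pi} of the labeled sub-batch
#' that satisfy \code{labels[pi[i]] == labels[i]}: the index list of each
#' class group is shuffled independently. Fixed points are allowed (a
#' within-class derangement need not exist, e.g. singleton classes).
#'
#' @param labels class labels of the labeled sub-batch.
#' @param rng a [view_rng()] bundle or a single [rng_stream()] (the
#'   \code{perm} stream is consumed).
#' @return list with \code{pi} (integer permutation, 1-based) and
#'   \code{labels}.
#' @export
sample_class_permutation <- function(labels, rng) {
  if (length(labels) == 0L) stop("labels must be non-empty", call. = FALSE)
  stream <- if (inherits(rng, "rng_stream")) rng else rng$perm
  pi <- seq_along(labels)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) > 1L) pi[idx] <- stream_sample(stream, idx)
  }
  list(pi = pi, labels = labels)
}

#' Apply a permutation plan to a batch of views
#'
#' Output item \code{i} is input item \code{plan$pi[i]}; the input is not
#' modified.
#'
#' @param view_batch list of views (or any list).
#' @param plan a plan from [sample_class_permutation()].
#' @export
apply_permutation <- function(view_batch, plan) {
  if (length(view_batch) != length(plan$pi)) {
    stop("batch length does not match permutation length", call. = FALSE)
  }
  view_batch[plan$pi]
}

#' Generate a two-view mini-batch with class-preserving permutation
#'
#' Every item (labeled first, then unlabeled) receives two independent
#' augmentations. When \code{permute} is TRUE and the labeled sub-batch is
#' non-empty, the second labeled view is reordered by a fresh
#' class-preserving permutation, so each labeled positive pair couples two
#' *different* patches of the same class. Unlabeled items are never
#' permuted. Pairing for the loss is positional: item i of view1 pairs
#' with item i of view2. Only one view is shuffled; shuffling both is
#' redundant, since a common reordering leaves the pairing multiset (and
#' any batch-symmetric loss) unchanged.
#'
#' @param labeled list of RGB patches forming the labeled sub-batch (may
#'   be empty).
#' @param labels class labels, one per labeled patch.
#' @param unlabeled list of RGB patches forming the unlabeled sub-batch.
#' @param policy an [augmentation_policy()].
#' @param rng a [view_rng()] bundle.
#' @param permute apply the class-preserving permutation to the second
#'   labeled view? FALSE gives the vanilla two-view pipeline.
#' @return list of class \code{view_pair_batch}: \code{view1},
#'   \code{view2} (lists of arrays, same length), \code{labels} (NA for
#'   unlabeled items), \code{n_labeled}, \code{plan} (NULL when no
#'   permutation was applied), \code{source2} (index of the source item of
#'   each view2 slot).
#' @export
generate_views <- function(labeled, labels, unlabeled, policy, rng,
                           permute = TRUE) {
  stopifnot(length(labeled) == length(labels))
  items <- c(labeled, unlabeled)
  n_l <- length(labeled)
  n <- length(items)
  view1 <- vector("list", n)
  view2 <- vector("list", n)
  for (i in seq_len(n)) {
    view1[[i]] <- augment(items[[i]], policy, rng)
    view2[[i]] <- augment(items[[i]], policy, rng)
  }
  plan <- NULL
  source2 <- seq_len(n)
  if (permute && n_l > 0L) {
    plan <- sample_class_permutation(labels, rng)
    view2[seq_len(n_l)] <- apply_permutation(view2[seq_len(n_l)], plan)
    source2[seq_len(n_l)] <- plan$pi
  }
  structure(
    list(view1 = view1, view2 = view2,
         labels = c(as.character(labels), rep(NA_character_,
                                              length(unlabeled))),
         n_labeled = n_l, plan = plan, source2 = source2),
    class = "view_pair_batch")
}
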