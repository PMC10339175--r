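#' Specification for deterministic pseudo-histology slides
#'
#' The generator emulates the weak-label regime of whole-slide images:
#' every slide carries a slide-level class label, but class-discriminative
#' texture (coloured blobs with a class-specific hue) is confined to a
#' region covering only \code{positive_fraction} of the slide area; the
#' rest is background texture common to all classes, so most patches of a
#' slide contain no class signal at all.
#'
#' @param n_classes number of classes (>= 2).
#' @param slides_per_class slides generated per class (>= 3, so the
#'   slide-disjoint train/dev/test split is possible).
#' @param slide_size c(width, height) in pixels.
#' @param positive_fraction fraction of slide area carrying class signal,
#'   in (0, 1]. Regions of interest in real slides can be as small as a
#'   few percent; the default 0.1 sits in that regime.
#' @param blob_density class blobs per signal-region pixel.
#' @param blob_radius_range radius range (pixels) of class blobs.
#' @param hue_width hue jitter width around each class's hue centre.
#' @param background_blob_density density of the class-independent
#'   background blobs (per slide pixel).
#' @param native_magnification,native_mpp metadata stamped on each slide.
#' @param seed base seed; all slides derive from it.
#' @return list of class \code{synthetic_spec}; \code{class_hues} are
#'   evenly spaced on the hue circle so class texture statistics are
#'   pairwise distinct.
#' @export
synthetic_spec <- function(n_classes = 2, slides_per_class = 6,
                           slide_size = c(256, 256),
                           positive_fraction = 0.1,
                           blob_density = 0.004,
                           blob_radius_range = c(2, 5),
                           hue_width = 0.06,
                           background_blob_density = 0.001,
                           native_magnification = 5, native_mpp = 2,
                           seed = 7) {
  stopifnot(n_classes >= 2, slides_per_class >= 1,
            positive_fraction > 0, positive_fraction <= 1,
            all(slide_size >= 32))
  structure(list(
    n_classes = n_classes, slides_per_class = slides_per_class,
    slide_size = as.integer(slide_size),
    positive_fraction = positive_fraction,
    blob_density = blob_density,
    blob_radius_range = blob_radius_range,
    hue_width = hue_width,
    background_blob_density = background_blob_density,
    class_hues = (seq_len(n_classes) - 1) / n_classes + 0.12,
    native_magnification = native_magnification,
    native_mpp = native_mpp, seed = seed),
    class = "synthetic_spec")
}

## numeric HSV -> RGB (h, s, v in [0,1]); avoids string colour round-trips
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  switch(as.character(i %% 6),
         "0" = c(v, t, p), "1" = c(q, v, p), "2" = c(p, v, t),
         "3" = c(p, q, v), "4" = c(p, t, v), "5" = c(v, p, q))
}

## alpha-blend filled discs onto an image, vectorised per disc
draw_blobs <- function(img, cx, cy, radius, colors, alpha = 0.85) {
  d <- dim(img)
  for (b in seq_along(cx)) {
    r <- radius[b]
    rows <- max(1, floor(cy[b] - r)):min(d[1], ceiling(cy[b] + r))
    cols <- max(1, floor(cx[b] - r)):min(d[2], ceiling(cx[b] + r))
    if (!length(rows) || !length(cols)) next
    dist2 <- outer((rows - cy[b])^2, (cols - cx[b])^2, `+`)
    inside <- dist2 <= r^2
    if (!any(inside)) next
    for (ch in 1:3) {
      plane <- img[rows, cols, ch]
      plane[inside] <- (1 - alpha) * plane[inside] + alpha *
        colors[ch, b]
      img[rows, cols, ch] <- plane
    }
  }
  img
}

#' Generate one pseudo-histology slide
#'
#' Background: a light eosin-like base with smooth brightness mottle and
#' sparse class-independent purple blobs everywhere. Class signal:
#' denser blobs with the class's hue, confined to a rectangular region
#' covering \code{positive_fraction} of the slide area at a random
#' position. The ground-truth signal mask is returned for test
#' assertions; pipelines only ever see the image and the slide label.
#'
#' @param class_id 1-based class index (<= \code{n_classes}).
#' @param spec a [synthetic_spec()].
#' @param slide_seed integer seed for this slide.
#' @return list with \code{image} (h x w x 3) and logical \code{mask}
#'   (h x w) marking the signal region.
#' @export
make_slide <- function(class_id, spec, slide_seed) {
  stopifnot(inherits(spec, "synthetic_spec"),
            class_id >= 1, class_id <= spec$n_classes)
  w <- spec$slide_size[1]
  h <- spec$slide_size[2]
  bg <- rng_stream(slide_seed, "slide/background")
  rg <- rng_stream(slide_seed, "slide/region")
  bl <- rng_stream(slide_seed, "slide/blobs")
  base <- hsv_to_rgb(0.95, 0.06, 0.94)
  img <- array(rep(base, each = h * w), c(h, w, 3))
  ## smooth brightness mottle: coarse noise upsampled bilinearly
  g <- 8
  noise <- matrix(stream_rnorm(bg, g * g, sd = 0.04), g, g)
  mottle <- bilinear_weights_1d(g, h) %*% noise %*%
    t(bilinear_weights_1d(g, w))
  for (ch in 1:3) img[, , ch] <- img[, , ch] + mottle
  ## class-independent background blobs
  n_bg <- round(spec$background_blob_density * w * h)
  if (n_bg > 0) {
    cx <- stream_runif(bg, n_bg, 1, w)
    cy <- stream_runif(bg, n_bg, 1, h)
    r <- stream_runif(bg, n_bg, 1.5, 3.5)
    hue <- 0.78 + stream_runif(bg, n_bg, -0.02, 0.02)
    cols <- vapply(hue, function(hh) hsv_to_rgb(hh, 0.35, 0.55),
                   numeric(3))
    img <- draw_blobs(img, cx, cy, r, cols, alpha = 0.6)
  }
  ## signal region: rectangle of area positive_fraction * w * h
  area <- spec$positive_fraction * w * h
  ratio <- stream_runif(rg, 1, 0.75, 4 / 3)
  rw <- min(w, max(4, round(sqrt(area * ratio))))
  rh <- min(h, max(4, round(area / rw)))
  rw <- min(w, max(4, round(area / rh))) # re-balance if a side clamped
  x0 <- floor(stream_runif(rg, 1, 0, w - rw + 1))
  y0 <- floor(stream_runif(rg, 1, 0, h - rh + 1))
  mask <- matrix(FALSE, h, w)
  mask[(y0 + 1):(y0 + rh), (x0 + 1):(x0 + rw)] <- TRUE
  ## class-discriminative blobs inside the region
  n_cl <- max(3, round(spec$blob_density * rw * rh))
  cx <- x0 + stream_runif(bl, n_cl, 1, rw)
  cy <- y0 + stream_runif(bl, n_cl, 1, rh)
  r <- stream_runif(bl, n_cl, spec$blob_radius_range[1],
                    spec$blob_radius_range[2])
  hue <- spec$class_hues[class_id] +
    stream_runif(bl, n_cl, -spec$hue_width / 2, spec$hue_width / 2)
  cols <- vapply(hue, function(hh) hsv_to_rgb(hh, 0.7, 0.65), numeric(3))
  img <- draw_blobs(img, cx, cy, r, cols, alpha = 0.85)
  list(image = pmin(pmax(img, 0), 1), mask = mask)
}

#' Generate a full synthetic slide dataset with splits
#'
#' Balanced classes, slide-disjoint train/dev/test splits (roughly
#' 55/15/30 per class, at least one slide each; the test share is kept
#' largest because held-out slides, not patches, are the scarce unit of
#' evaluation), deterministic from the spec's seed.
#'
#' @param spec a [synthetic_spec()] with \code{slides_per_class >= 3}.
#' @return list with \code{slides} (list of [slide_record()]),
#'   \code{masks} (named list of signal masks) and \code{labels}
#'   (data.frame slide_id, label, split).
#' @export
make_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  s <- spec$slides_per_class
  if (s < 3) stop("need at least 3 slides per class for disjoint splits",
                  call. = FALSE)
  n_test <- max(1, round(0.3 * s))
  n_dev <- max(1, round(0.15 * s))
  n_train <- s - n_test - n_dev
  stopifnot(n_train >= 1)
  splits <- c(rep("train", n_train), rep("dev", n_dev),
              rep("test", n_test))
  slides <- list()
  masks <- list()
  labels <- list()
  for (cl in seq_len(spec$n_classes)) {
    for (i in seq_len(s)) {
      sid <- sprintf("class%d_slide%02d", cl, i)
      sl <- make_slide(cl, spec,
                       derive_seed(spec$seed, paste0("slide/", sid)))
      slides[[sid]] <- slide_record(sid, sl$image,
                                    spec$native_magnification,
                                    spec$native_mpp,
                                    paste0("class", cl))
      masks[[sid]] <- sl$mask
      labels[[sid]] <- data.frame(slide_id = sid,
                                  label = paste0("class", cl),
                                  split = splits[i],
                                  stringsAsFactors = FALSE)
    }
  }
  labels <- do.call(rbind, labels)
  rownames(labels) <- NULL
  list(slides = unname(slides), masks = masks, labels = labels)
}

#' Synthetic patch dataset ready for pretraining
#'
#' Generates slides with [make_dataset()] and extracts patch manifests per
#' split with [patchify()]. Dev/test use the spec'd constant overlap;
#' the training split does too unless \code{train_target_count} is given,
#' in which case a per-class overlap is solved to reach that budget.
#'
#' @param spec a [synthetic_spec()].
#' @param grid a [patch_grid_spec()] (desk scale: 64-pixel patches,
#'   overlap 32).
#' @param train_target_count optional per-class training patch budget for
#'   [solve_training_overlap()].
#' @return list with \code{manifest} (all splits), \code{images} (named
#'   list of slide arrays at target magnification), \code{masks},
#'   \code{labels}.
#' @export
make_patch_dataset <- function(spec,
                               grid = patch_grid_spec(64, 32, 5),
                               train_target_count = NULL) {
  ds <- make_dataset(spec)
  split_of <- stats::setNames(ds$labels$split, ds$labels$slide_id)
  parts <- list()
  images <- list()
  for (sp in c("train", "dev", "test")) {
    recs <- Filter(function(r) split_of[[r$slide_id]] == sp, ds$slides)
    if (!length(recs)) next
    ov <- NULL
    if (sp == "train" && !is.null(train_target_count)) {
      ov <- sapply(split(recs, vapply(recs, `[[`, character(1),
                                      "label")), function(rr) {
        dims <- vapply(rr, function(r) dim(slide_image(r))[1:2],
                       numeric(2))
        fac <- downsample_factor(rr[[1]]$native_magnification,
                                 grid$target_magnification)
        solve_training_overlap(floor(dims[2, ] / fac),
                               floor(dims[1, ] / fac),
                               grid$patch_size,
                               train_target_count)$overlap
      })
    }
    p <- patchify(recs, grid, split = sp, class_overlaps = ov)
    parts[[sp]] <- p$manifest
    images <- c(images, p$images)
  }
  manifest <- do.call(rbind, parts)
  rownames(manifest) <- NULL
  list(manifest = manifest, images = images, masks = ds$masks,
       labels = ds$labels)
}

#' Subset a patch dataset to one split
#'
#' @param dataset output of [make_patch_dataset()] (or any
#'   manifest+images list).
#' @param split split tag to keep.
#' @export
dataset_split <- function(dataset, split) {
  keep <- dataset$manifest$split == split
  list(manifest = dataset$manifest[keep, , drop = FALSE],
       images = dataset$images)
}

#' Small worked mini-batch with index watermarks
#'
#' Builds a deterministic labeled (+ optionally unlabeled) batch of smooth
#' colour patches, each carrying its 1-based item index i as a one-pixel
#' corner watermark of value \code{(200 + i) / 255} in channel 1 -- far
#' above any background value, so [watermark_index()] can recover it from
#' whichever corner a flip moved it to, and a permutation applied to the
#' batch can be verified pixel-wise without trusting the code under test.
#'
#' @param label_pattern class labels of the labeled items, e.g.
#'   \code{c("A", "A", "B", "B")}.
#' @param seed integer seed.
#' @param n_unlabeled number of additional unlabeled items.
#' @param size patch side length in pixels.
#' @return list with \code{labeled} (list of arrays), \code{labels},
#'   \code{unlabeled} (list of arrays).
#' @export
make_worked_minibatch <- function(label_pattern, seed, n_unlabeled = 0,
                                  size = 32) {
  stopifnot(length(label_pattern) >= 1)
  stream <- rng_stream(seed, "worked_minibatch")
  mk <- function(i) {
    base <- stream_runif(stream, 3, 0.2, 0.6)
    img <- array(rep(base, each = size * size), c(size, size, 3))
    img <- img + array(stream_rnorm(stream, size * size * 3, sd = 0.02),
                       dim(img))
    img <- pmin(pmax(img, 0), 0.7)
    img[1, 1, 1] <- (200 + i) / 255
    img
  }
  n_l <- length(label_pattern)
  list(labeled = lapply(seq_len(n_l), mk),
       labels = as.character(label_pattern),
       unlabeled = if (n_unlabeled > 0)
         lapply(n_l + seq_len(n_unlabeled), mk) else list())
}

#' Recover the watermark index of a worked-mini-batch patch
#'
#' Reads the index back from whichever image corner carries the watermark
#' (flips move it between corners); returns NA if no corner holds one.
#'
#' @param img patch from [make_worked_minibatch()].
#' @export
watermark_index <- function(img) {
  d <- dim(img)
  corners <- c(img[1, 1, 1], img[1, d[2], 1], img[d[1], 1, 1],
               img[d[1], d[2], 1])
  v <- as.integer(round(255 * max(corners))) - 200L
  if (v < 1) NA_integer_ else v
}

#' Write a synthetic dataset to disk
#'
#' PNG slides plus a \code{labels.csv} (slide_id, label, split) compatible
#' with the patchify command-line entry point.
#'
#' @param dataset output of [make_dataset()].
#' @param dir output directory (created if missing).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in dataset$slides) {
    write_slide_image(slide_image(rec),
                      file.path(dir, paste0(rec$slide_id, ".png")))
  }
  utils::write.csv(dataset$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
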