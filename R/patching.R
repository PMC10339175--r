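#' Slide records
#'
#' A slide record couples an image (in-memory array or a file path) with its
#' scanning metadata and slide-level class label. Labels are weak: every
#' patch extracted from the slide inherits the slide's label even though
#' class-discriminative tissue may cover only a small fraction of it.
#'
#' @param slide_id character identifier.
#' @param image RGB array or a file path readable by [read_slide_image()].
#' @param native_magnification objective power of the scan (e.g. 20, 40).
#' @param native_mpp physical pixel size, micrometres per pixel.
#' @param label slide-level class label.
#' @return an object of class \code{slide_record}.
#' @export
slide_record <- function(slide_id, image, native_magnification, native_mpp,
                         label) {
  stopifnot(native_magnification > 0, native_mpp > 0)
  structure(
    list(slide_id = as.character(slide_id), image = image,
         native_magnification = native_magnification,
         native_mpp = native_mpp, label = as.character(label)),
    class = "slide_record")
}

slide_image <- function(rec) {
  if (is.character(rec$image)) read_slide_image(rec$image) else rec$image
}

#' Patch grid specification
#'
#' @param patch_size square patch side length in pixels (default 224).
#' @param overlap overlap between adjacent patches in pixels; the grid
#'   stride is \code{patch_size - overlap}. Development and test sets use a
#'   constant 112-pixel overlap; training overlaps are chosen per class by
#'   [solve_training_overlap()].
#' @param target_magnification magnification at which patches are taken
#'   (default 5, i.e. 2 um/pixel for a 20x/0.5 um scan).
#' @return an object of class \code{patch_grid_spec}.
#' @export
patch_grid_spec <- function(patch_size = 224, overlap = 112,
                            target_magnification = 5) {
  stopifnot(patch_size >= 1, overlap >= 0, overlap < patch_size,
            target_magnification > 0)
  structure(list(patch_size = as.integer(patch_size),
                 overlap = as.integer(overlap),
                 target_magnification = target_magnification),
            class = "patch_grid_spec")
}

#' Magnification downsampling factor
#'
#' Factor by which a slide must be shrunk to move from its native
#' magnification to the target one. Upsampling is refused: patching never
#' invents resolution.
#'
#' @param native_mag native objective power (> 0).
#' @param target_mag target objective power (> 0, <= native).
#' @return \code{native_mag / target_mag}.
#' @seealso [effective_mpp()]
#' @export
downsample_factor <- function(native_mag, target_mag) {
  stopifnot(native_mag > 0, target_mag > 0)
  if (target_mag > native_mag) {
    stop("target magnification exceeds native magnification; ",
         "upsampling refused", call. = FALSE)
  }
  native_mag / target_mag
}

#' Physical pixel size after downsampling
#'
#' mpp scales linearly with the downsampling factor, so 20x at 0.5 um/pixel
#' and 40x at 0.25 um/pixel both land at 2 um/pixel when brought to 5x.
#'
#' @param native_mpp native micrometres per pixel.
#' @param factor downsampling factor from [downsample_factor()].
#' @export
effective_mpp <- function(native_mpp, factor) {
  stopifnot(native_mpp > 0, factor >= 1)
  native_mpp * factor
}

## 0-based grid positions along one axis, stride steps plus one
## edge-aligned position when the last stride step overshoots the border.
grid_axis <- function(extent, patch_size, stride) {
  xs <- seq(0L, extent - patch_size, by = stride)
  last <- extent - patch_size
  if (xs[length(xs)] != last) xs <- c(xs, last)
  xs
}

#' Overlapping patch-grid coordinates
#'
#' Row-major list of 0-based top-left corners covering a slide with square
#' patches at stride \code{patch_size - overlap}. If the final stride step
#' does not align with the right/bottom edge, one extra edge-aligned
#' coordinate is appended per axis so no border tissue is dropped.
#'
#' @param width,height slide dimensions in pixels (post-downsampling).
#' @param spec a [patch_grid_spec()].
#' @return data.frame with 0-based columns \code{x}, \code{y}, row-major
#'   (y outer, x inner).
#' @export
grid_coordinates <- function(width, height, spec) {
  stopifnot(inherits(spec, "patch_grid_spec"))
  ps <- spec$patch_size
  if (width < ps || height < ps) {
    stop("slide smaller than patch size: no grid", call. = FALSE)
  }
  stride <- ps - spec$overlap
  xs <- grid_axis(as.integer(width), ps, stride)
  ys <- grid_axis(as.integer(height), ps, stride)
  data.frame(x = rep(xs, times = length(ys)),
             y = rep(ys, each = length(xs)))
}

grid_count <- function(width, height, patch_size, overlap) {
  patch_size <- as.integer(patch_size)
  if (width < patch_size || height < patch_size) return(0L)
  stride <- patch_size - as.integer(overlap)
  n_axis <- function(extent) {
    n <- (extent - patch_size) %/% stride + 1L
    if ((extent - patch_size) %% stride != 0L) n <- n + 1L
    n
  }
  n_axis(as.integer(width)) * n_axis(as.integer(height))
}

#' Smallest overlap reaching a per-class patch budget
#'
#' Training sets use a different overlap per class so that every class
#' contributes approximately the same number of patches (the budget, e.g.
#' 80 000). This solver returns the smallest integer overlap in
#' \code{[0, patch_size - 1]} whose summed grid size over the class's
#' slides reaches \code{target_count}; when even the maximum overlap falls
#' short it returns \code{patch_size - 1} with \code{shortfall = TRUE}.
#'
#' @param widths,heights integer vectors of slide dimensions (at target
#'   magnification) for one class.
#' @param patch_size patch side length.
#' @param target_count desired minimum number of patches for the class.
#' @return list with \code{overlap}, \code{count}, \code{shortfall}.
#' @export
solve_training_overlap <- function(widths, heights, patch_size,
                                   target_count) {
  stopifnot(length(widths) == length(heights), target_count > 0)
  if (length(widths) == 0L) stop("no slides for class", call. = FALSE)
  total <- function(o) {
    sum(vapply(seq_along(widths), function(i) {
      grid_count(widths[i], heights[i], patch_size, o)
    }, integer(1)))
  }
  ## grid count is non-decreasing in overlap, so binary search would do;
  ## the range is at most patch_size values, linear scan is plenty.
  for (o in 0:(patch_size - 1L)) {
    n <- total(o)
    if (n >= target_count) {
      return(list(overlap = o, count = n, shortfall = FALSE))
    }
  }
  list(overlap = patch_size - 1L, count = total(patch_size - 1L),
       shortfall = TRUE)
}

#' Tissue fraction of a patch by HSV saturation
#'
#' Fraction of pixels whose saturation exceeds a threshold; white/grey
#' background scores near zero. Used by the optional tissue filter in
#' [patchify()].
#'
#' @param patch RGB array.
#' @param sat_threshold minimum saturation counted as tissue.
#' @export
tissue_fraction <- function(patch, sat_threshold = 0.05) {
  assert_image(patch)
  rgb <- rbind(as.numeric(patch[, , 1]), as.numeric(patch[, , 2]),
               as.numeric(patch[, , 3]))
  s <- grDevices::rgb2hsv(rgb, maxColorValue = 1)[2, ]
  mean(s > sat_threshold)
}

#' Extract a labeled patch manifest from slides
#'
#' Downsamples each slide to the spec's target magnification (Lanczos),
#' lays an overlapping grid over it and records one manifest row per patch.
#' Labels are inherited from the slide; ordering is deterministic (slide
#' order, then row-major grid). Labeled/unlabeled status is never stored in
#' the manifest: it is assigned dynamically per epoch at training time.
#'
#' @param slides list of [slide_record()] objects.
#' @param spec a [patch_grid_spec()]; for training manifests, per-class
#'   overlaps from [solve_training_overlap()] can be supplied via
#'   \code{class_overlaps}.
#' @param split split tag recorded in every row ("train", "dev", "test").
#' @param class_overlaps optional named integer vector (class -> overlap)
#'   overriding \code{spec$overlap} per class.
#' @param min_tissue_fraction optional minimum [tissue_fraction()] a patch
#'   must reach to be kept (default NULL: filter off, every grid position
#'   is kept).
#' @param keep_images return the downsampled slide images alongside the
#'   manifest? (needed to extract pixels later without re-reading).
#' @return list with \code{manifest} (data.frame slide_id, x, y,
#'   patch_size, label, split) and, if requested, \code{images} (named list
#'   of downsampled arrays).
#' @export
patchify <- function(slides, spec, split = "train", class_overlaps = NULL,
                     min_tissue_fraction = NULL, keep_images = TRUE) {
  stopifnot(inherits(spec, "patch_grid_spec"), length(slides) >= 1)
  rows <- vector("list", length(slides))
  images <- if (keep_images) vector("list", length(slides)) else NULL
  for (i in seq_along(slides)) {
    rec <- slides[[i]]
    stopifnot(inherits(rec, "slide_record"))
    fac <- downsample_factor(rec$native_magnification,
                             spec$target_magnification)
    img <- resize_slide(slide_image(rec), fac)
    ov <- spec$overlap
    if (!is.null(class_overlaps) && rec$label %in% names(class_overlaps)) {
      ov <- as.integer(class_overlaps[[rec$label]])
    }
    sp <- patch_grid_spec(spec$patch_size, ov, spec$target_magnification)
    g <- grid_coordinates(dim(img)[2], dim(img)[1], sp)
    if (!is.null(min_tissue_fraction)) {
      keep <- vapply(seq_len(nrow(g)), function(k) {
        p <- extract_patch(img, g$x[k], g$y[k], sp$patch_size)
        tissue_fraction(p) >= min_tissue_fraction
      }, logical(1))
      g <- g[keep, , drop = FALSE]
    }
    rows[[i]] <- data.frame(
      slide_id = rec$slide_id, x = g$x, y = g$y,
      patch_size = sp$patch_size, label = rec$label, split = split,
      stringsAsFactors = FALSE)
    if (keep_images) images[[i]] <- img
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  out <- list(manifest = manifest)
  if (keep_images) {
    names(images) <- vapply(slides, `[[`, character(1), "slide_id")
    out$images <- images
  }
  out
}

#' Write / read a patch manifest CSV
#'
#' Plain UTF-8 CSV with header \code{slide_id,x,y,patch_size,label,split},
#' one row per patch; round-trips losslessly.
#'
#' @param manifest manifest data.frame.
#' @param path file path.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("slide_id", "x", "y", "patch_size", "label", "split")
                %in% names(manifest)))
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       fileEncoding = "UTF-8",
                       colClasses = c(slide_id = "character",
                                      label = "character"))
  m$x <- as.integer(m$x)
  m$y <- as.integer(m$y)
  m$patch_size <- as.integer(m$patch_size)
  m
}
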