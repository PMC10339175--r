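## Images are numeric arrays dim c(height, width, 3), values in [0, 1].
## All resampling is expressed as separable weight matrices so a resize is
## three small matrix products (one per channel); this keeps the whole
## augmentation pipeline vectorised.

assert_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L ||
      any(dim(img)[1:2] < 1L)) {
    stop("expected an RGB array with dim c(h, w, 3) and positive size",
         call. = FALSE)
  }
  invisible(img)
}

lanczos_kernel <- function(x, a = 3) {
  w <- numeric(length(x))
  inside <- abs(x) < a & x != 0
  w[x == 0] <- 1
  xi <- x[inside]
  w[inside] <- a * sin(pi * xi) * sin(pi * xi / a) / (pi^2 * xi^2)
  w
}

## Row-stochastic 1D resampling matrix (n_out x n_in) for a given kernel;
## built band-wise (vectorised over output positions) and memoised, since
## the augmentation loop requests the same few shapes thousands of times.
resample_weights_1d <- function(n_in, n_out, kernel, support) {
  scale <- n_in / n_out
  ss <- max(scale, 1)
  s <- (seq_len(n_out) - 0.5) * scale - 0.5 # centres, 0-based input coords
  r <- support * ss
  j0 <- floor(s - r)
  K <- as.integer(ceiling(2 * r)) + 1L
  W <- matrix(0, n_out, n_in)
  rows <- seq_len(n_out)
  for (k in seq_len(K)) {
    j <- j0 + (k - 1)
    w <- kernel((j - s) / ss)
    jc <- pmin(pmax(j, 0), n_in - 1) # clamp to the border pixel
    idx <- cbind(rows, jc + 1)
    W[idx] <- W[idx] + w
  }
  W / rowSums(W)
}

.weights_memo <- new.env(parent = emptyenv())

memo_weights <- function(key, build) {
  w <- get0(key, envir = .weights_memo, inherits = FALSE)
  if (is.null(w)) {
    w <- build()
    assign(key, w, envir = .weights_memo)
  }
  w
}

lanczos_weights_1d <- function(n_in, n_out, a = 3) {
  memo_weights(sprintf("lz_%d_%d_%d", n_in, n_out, a), function() {
    resample_weights_1d(n_in, n_out, function(x) lanczos_kernel(x, a), a)
  })
}

bilinear_weights_1d <- function(n_in, n_out) {
  memo_weights(sprintf("bl_%d_%d", n_in, n_out), function() {
    tri <- function(x) pmax(0, 1 - abs(x))
    resample_weights_1d(n_in, n_out, tri, 1)
  })
}

apply_separable <- function(img, Wh, Ww) {
  out <- array(0, c(nrow(Wh), nrow(Ww), 3))
  tWw <- t(Ww)
  for (ch in 1:3) out[, , ch] <- Wh %*% img[, , ch] %*% tWw
  out
}

#' Resize an image with Lanczos-3 resampling
#'
#' Separable Lanczos filter (a = 3) with a kernel support scaled by the
#' downsampling factor and border clamping; each output pixel's weights are
#' normalised to sum to one, so constant images are reproduced exactly.
#'
#' @param img RGB array (h, w, 3) in [0, 1].
#' @param out_h,out_w output size in pixels.
#' @return RGB array (out_h, out_w, 3).
#' @export
lanczos_resize <- function(img, out_h, out_w) {
  assert_image(img)
  d <- dim(img)
  if (out_h == d[1] && out_w == d[2]) return(img)
  apply_separable(img, lanczos_weights_1d(d[1], out_h),
                  lanczos_weights_1d(d[2], out_w))
}

#' Downsample a slide image by a magnification factor
#'
#' Reduces a slide from its native magnification to a lower one (e.g. 20x
#' to 5x is factor 4) using the Lanczos filter. Output dimensions are
#' \code{floor(input / factor)}; factor 1 returns the input unchanged.
#'
#' @param img RGB array (h, w, 3).
#' @param factor downsampling factor, >= 1 (see [downsample_factor()]).
#' @return the downsampled RGB array.
#' @export
resize_slide <- function(img, factor) {
  assert_image(img)
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1) {
    stop("factor must be a single number >= 1", call. = FALSE)
  }
  if (factor == 1) return(img)
  d <- dim(img)
  out_h <- floor(d[1] / factor)
  out_w <- floor(d[2] / factor)
  if (out_h < 1 || out_w < 1) stop("factor too large for image", call. = FALSE)
  lanczos_resize(img, out_h, out_w)
}

#' Resize an image with bilinear interpolation
#'
#' Half-pixel-centre bilinear resampling, the convention used when crops
#' are rescaled to the network input size.
#'
#' @inheritParams lanczos_resize
#' @export
bilinear_resize <- function(img, out_h, out_w) {
  assert_image(img)
  d <- dim(img)
  if (out_h == d[1] && out_w == d[2]) return(img)
  apply_separable(img, bilinear_weights_1d(d[1], out_h),
                  bilinear_weights_1d(d[2], out_w))
}

#' Flip an image along the horizontal and/or vertical axis
#'
#' @param img RGB array.
#' @param horizontal flip left-right?
#' @param vertical flip top-bottom?
#' @export
flip_image <- function(img, horizontal = FALSE, vertical = FALSE) {
  assert_image(img)
  if (horizontal) img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  if (vertical) img <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
  img
}

#' Gaussian-blur an image
#'
#' Separable truncated Gaussian; near the border the kernel is renormalised
#' over the pixels it covers, so constant images stay constant.
#'
#' @param img RGB array.
#' @param sigma standard deviation in pixels.
#' @param kernel_size odd kernel width in pixels.
#' @export
gaussian_blur_image <- function(img, sigma, kernel_size = 23) {
  assert_image(img)
  stopifnot(sigma > 0, kernel_size >= 1)
  half <- (kernel_size - 1) %/% 2
  off <- -half:half
  w <- exp(-off^2 / (2 * sigma^2))
  blur_mat <- function(n) {
    B <- matrix(0, n, n)
    rows <- seq_len(n)
    for (k in seq_along(off)) {
      j <- rows + off[k]
      keep <- j >= 1 & j <= n
      B[cbind(rows[keep], j[keep])] <- w[k]
    }
    B / rowSums(B)
  }
  d <- dim(img)
  apply_separable(img, blur_mat(d[1]), blur_mat(d[2]))
}

#' Extract a square patch from an image
#'
#' Coordinates are 0-based, top-left origin; the box is half-open
#' \code{[x, x + size) x [y, y + size)} and must lie inside the image.
#'
#' @param img RGB array.
#' @param x,y 0-based top-left corner (x = column, y = row).
#' @param size patch side length in pixels.
#' @export
extract_patch <- function(img, x, y, size) {
  assert_image(img)
  d <- dim(img)
  if (x < 0 || y < 0 || x + size > d[2] || y + size > d[1]) {
    stop("patch box outside image bounds", call. = FALSE)
  }
  img[(y + 1):(y + size), (x + 1):(x + size), , drop = FALSE]
}

## Inverse-mapped affine warp (rotation in degrees, translation in pixels)
## with bilinear sampling and border clamping. Used by the linear-probe
## training augmentation, where only affine transforms are applied.
affine_warp <- function(img, angle = 0, tx = 0, ty = 0) {
  assert_image(img)
  if (angle == 0 && tx == 0 && ty == 0) return(img)
  d <- dim(img)
  h <- d[1]; w <- d[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- angle * pi / 180
  co <- cos(th); si <- sin(th)
  grid <- memo_weights(sprintf("grid_%d_%d", h, w), function() {
    list(rr = as.vector(matrix(seq_len(h), h, w)),
         cc = as.vector(matrix(seq_len(w), h, w, byrow = TRUE)))
  })
  ## inverse map: undo translation, then rotate by -angle
  rr0 <- grid$rr - cy - ty
  cc0 <- grid$cc - cx - tx
  src_r <- co * rr0 + si * cc0 + cy
  src_c <- -si * rr0 + co * cc0 + cx
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  cl <- function(v, n) pmin(pmax(v, 1), n)
  r0c <- cl(r0, h); r1c <- cl(r0 + 1, h)
  c0c <- cl(c0, w); c1c <- cl(c0 + 1, w)
  i00 <- (c0c - 1) * h + r0c
  i01 <- (c1c - 1) * h + r0c
  i10 <- (c0c - 1) * h + r1c
  i11 <- (c1c - 1) * h + r1c
  w00 <- (1 - fr) * (1 - fc); w01 <- (1 - fr) * fc
  w10 <- fr * (1 - fc); w11 <- fr * fc
  np <- h * w
  chan <- rep.int(c(0, np, 2 * np), rep.int(np, 3))
  array(img[chan + i00] * w00 + img[chan + i01] * w01 +
          img[chan + i10] * w10 + img[chan + i11] * w11, d)
}

## Area-overlap average-pooling matrix (g x n); exact block means when
## n %% g == 0, fractional-overlap weights otherwise.
pool_weights_1d <- function(n, g) {
  memo_weights(sprintf("pool_%d_%d", n, g), function() {
    pool_weights_1d_build(n, g)
  })
}

pool_weights_1d_build <- function(n, g) {
  W <- matrix(0, g, n)
  cell <- n / g
  for (i in seq_len(g)) {
    lo <- (i - 1) * cell
    hi <- i * cell
    j <- seq(floor(lo), ceiling(hi) - 1)
    ov <- pmin(j + 1, hi) - pmax(j, lo)
    keep <- ov > 1e-12
    W[i, j[keep] + 1] <- ov[keep] / cell
  }
  W
}

#' Pool a batch of views into flat feature vectors
#'
#' Average-pools each view down to a \code{grid x grid} RGB summary and
#' flattens it; this is the fixed front end of the compact encoders used at
#' desk scale.
#'
#' @param views list of RGB arrays of identical size.
#' @param grid pooling grid side length.
#' @return numeric matrix, one row per view, \code{3 * grid^2} columns.
#' @export
pool_features <- function(views, grid = 8) {
  stopifnot(length(views) >= 1)
  d <- dim(views[[1]])
  Wh <- pool_weights_1d(d[1], grid)
  Ww <- pool_weights_1d(d[2], grid)
  t(vapply(views, function(v) {
    as.numeric(apply_separable(v, Wh, Ww))
  }, numeric(3 * grid * grid)))
}

#' Read a slide image from disk
#'
#' Reads PNG (and TIFF when the tiff package is installed) into the
#' package's (h, w, 3) array convention; grayscale and alpha channels are
#' expanded/dropped.
#'
#' @param path image file path.
#' @export
read_slide_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the tiff package", call. = FALSE)
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write a slide image to disk as PNG
#' @param img RGB array in [0, 1].
#' @param path output path.
#' @export
write_slide_image <- function(img, path) {
  assert_image(img)
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}
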