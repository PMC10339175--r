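# Shared fixtures, built in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  v <- get0(name, envir = .fixtures, inherits = FALSE)
  if (is.null(v)) {
    v <- build()
    assign(name, v, envir = .fixtures)
  }
  v
}

# small synthetic patch dataset: 2 classes x 6 slides of 96x96, 32-px
# patches at overlap 16 (25 per slide, 300 total)
tiny_patch_dataset <- function() {
  fixture("tiny_patch_dataset", function() {
    make_patch_dataset(synthetic_spec(slide_size = c(96, 96), seed = 3),
                       patch_grid_spec(32, 16, 5))
  })
}

tiny_policy <- function() {
  augmentation_policy(output_size = 32, crop_scale_range = c(0.2, 1),
                      blur_kernel_size = 9)
}

tiny_model <- list(pool_grid = 4, encoder_hidden = 16, rep_dim = 8,
                   proj_hidden = 16, proj_dim = 8)

tiny_pretrain_config <- function(...) {
  args <- list(...)
  defaults <- c(list(epochs = 2, warmup_epochs = 1, base_lr = 0.01,
                     batch_size = 8, alpha = 0.75, histoperm = TRUE,
                     framework = "byol", seed = 2,
                     policy = tiny_policy()),
                tiny_model)
  defaults[names(args)] <- args
  do.call(pretrain_config, defaults)
}

# uniform random test image
rand_image <- function(h, w, seed = 1) {
  s <- rng_stream(seed, "img")
  array(stream_runif(s, h * w * 3), c(h, w, 3))
}

# random embedding matrix
rand_mat <- function(n, d, seed = 1, name = "m") {
  matrix(stream_rnorm(rng_stream(seed, name), n * d), n, d)
}

# central finite-difference gradient of scalar f at x (vector access)
num_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(j) {
    x1 <- x; x1[j] <- x1[j] + eps
    x2 <- x; x2[j] <- x2[j] - eps
    (f(x1) - f(x2)) / (2 * eps)
  }, numeric(1))
}
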