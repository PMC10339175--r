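test_that("mini-batch composition floors the labeled share", {
  s <- split_minibatch(256, 0.75)
  expect_equal(s$n_labeled, 192L)
  expect_equal(s$n_unlabeled, 64L)
  s0 <- split_minibatch(256, 0)
  expect_equal(s0$n_labeled, 0L)
  expect_equal(s0$n_unlabeled, 256L)
  s1 <- split_minibatch(100, 1)
  expect_equal(s1$n_labeled, 100L)
  expect_equal(s1$n_unlabeled, 0L)
  # floor on non-divisible N, and the two parts always sum to N
  for (N in c(7, 31, 100)) for (a in c(0.1, 1 / 3, 0.5, 0.9)) {
    s <- split_minibatch(N, a)
    expect_equal(s$n_labeled, floor(a * N))
    expect_equal(s$n_labeled + s$n_unlabeled, N)
  }
  expect_error(split_minibatch(16, 1.2), "alpha")
  expect_error(split_minibatch(16, -0.1), "alpha")
})

test_that("augmentation is deterministic in the stream state and shaped", {
  img <- rand_image(40, 40, seed = 9)
  pol <- augmentation_policy(output_size = 24)
  v1 <- augment(img, pol, view_rng(123))
  v2 <- augment(img, pol, view_rng(123))
  expect_identical(v1, v2)
  expect_equal(dim(v1), c(24, 24, 3))
  v3 <- augment(img, pol, view_rng(124))
  expect_false(identical(v1, v3))
  expect_error(augment(matrix(0, 3, 3), pol, view_rng(1)), "RGB")
})

test_that("class permutations are bijective, class-preserving and complete", {
  # brute-force oracle: all valid permutations of [A,A,B,B]
  labels <- c("A", "A", "B", "B")
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  valid <- perms[apply(perms, 1, function(p) {
    length(unique(p)) == 4 && all(labels[p] == labels)
  }), , drop = FALSE]
  expect_equal(nrow(valid), 4)

  rng <- view_rng(7)
  for (k in 1:50) {
    plan <- sample_class_permutation(labels, rng)
    expect_true(any(apply(valid, 1, function(p) all(p == plan$pi))))
  }

  # all-distinct labels force the identity
  plan <- sample_class_permutation(c("a", "b", "c"), view_rng(1))
  expect_equal(plan$pi, 1:3)

  # a single class of 3 admits all 3! permutations; all get visited
  seen <- unique(t(replicate(200, {
    sample_class_permutation(c("A", "A", "A"), rng)$pi
  })))
  expect_equal(nrow(seen), 6)

  # bijectivity and class preservation on random label vectors
  set.seed(12)
  for (k in 1:200) {
    n <- sample(1:12, 1)
    lab <- sample(letters[1:3], n, replace = TRUE)
    plan <- sample_class_permutation(lab, rng)
    expect_identical(sort(plan$pi), 1:n)
    expect_identical(lab[plan$pi], lab)
  }
  expect_error(sample_class_permutation(character(0), rng), "non-empty")
})

test_that("apply_permutation reorders without touching the input", {
  batch <- as.list(letters[1:4])
  idp <- list(pi = 1:4, labels = rep("x", 4))
  expect_identical(apply_permutation(batch, idp), batch)
  plan <- list(pi = c(2L, 1L, 4L, 3L), labels = rep("x", 4))
  out <- apply_permutation(batch, plan)
  expect_identical(out, list("b", "a", "d", "c"))
  # round-trip through the inverse
  inv <- list(pi = order(plan$pi), labels = plan$labels)
  expect_identical(apply_permutation(out, inv), batch)
  # composition equals the composed permutation
  p2 <- list(pi = c(3L, 4L, 1L, 2L), labels = plan$labels)
  expect_identical(
    apply_permutation(apply_permutation(batch, plan), p2),
    apply_permutation(batch, list(pi = plan$pi[p2$pi],
                                  labels = plan$labels)))
  expect_error(apply_permutation(batch[1:3], plan), "length")
})

test_that("generated views permute only the second labeled view,
           class-preservingly", {
  wb <- make_worked_minibatch(c("A", "A", "B", "B"), seed = 5,
                              n_unlabeled = 2)
  # crops disabled (full-frame fallback), blur off: the corner watermark
  # survives up to flips, which leave it in one of the four corners
  pol <- augmentation_policy(output_size = 32,
                             crop_scale_range = c(1, 1),
                             blur_probability = 0)
  vb <- generate_views(wb$labeled, wb$labels, wb$unlabeled, pol,
                       view_rng(3))
  expect_equal(length(vb$view1), 6)
  # view1 is in source order
  expect_equal(vapply(vb$view1, watermark_index, integer(1)), 1:6)
  # the labeled part of view2 realises the plan; unlabeled untouched
  expect_equal(vapply(vb$view2, watermark_index, integer(1)),
               c(vb$plan$pi, 5L, 6L))
  # class preservation, pixel-verified
  src2 <- vapply(vb$view2[1:4], watermark_index, integer(1))
  expect_identical(wb$labels[src2], wb$labels)
  expect_identical(sort(vb$plan$pi), 1:4)
})

test_that("an empty labeled sub-batch reduces to the vanilla pipeline
           bit for bit", {
  wb <- make_worked_minibatch(c("A", "B"), seed = 8, n_unlabeled = 6)
  pol <- augmentation_policy(output_size = 16)
  a <- generate_views(list(), character(0), wb$unlabeled, pol,
                      view_rng(99), permute = TRUE)
  b <- generate_views(list(), character(0), wb$unlabeled, pol,
                      view_rng(99), permute = FALSE)
  expect_identical(a, b)
  expect_null(a$plan)
})

test_that("a singleton labeled batch degenerates to the standard pair", {
  wb <- make_worked_minibatch("A", seed = 2, n_unlabeled = 3)
  pol <- augmentation_policy(output_size = 16)
  vb <- generate_views(wb$labeled, wb$labels, wb$unlabeled, pol,
                       view_rng(4))
  expect_equal(vb$plan$pi, 1L)
  expect_equal(vb$source2, 1:4)
})

test_that("permuting both views equals permuting view2 by the composed
           permutation for batch-symmetric losses", {
  labels <- c("A", "A", "A", "B", "B", "B")
  rng <- view_rng(17)
  p1 <- sample_class_permutation(labels, rng)$pi
  p2 <- sample_class_permutation(labels, rng)$pi
  z1 <- rand_mat(6, 5, seed = 1, "z1")
  z2 <- rand_mat(6, 5, seed = 1, "z2")
  sigma <- p2[order(p1)] # pi1^{-1} then pi2
  for (lossf in list(
    function(a, b) nt_xent_loss(a, b, 0.5),
    function(a, b) vicreg_loss(a, b)$loss,
    function(a, b) cosine_alignment_loss(a, b))) {
    expect_equal(lossf(z1[p1, ], z2[p2, ]), lossf(z1, z2[sigma, ]),
                 tolerance = 1e-10)
  }
})

test_that("sampled class permutations are uniform over the valid set", {
  labels <- c("A", "A", "B", "B")
  rng <- view_rng(31)
  n_draws <- 4000
  codes <- replicate(n_draws, paste(
    sample_class_permutation(labels, rng)$pi, collapse = ""))
  counts <- table(codes)
  expect_equal(length(counts), 4L)
  expected <- n_draws / 4
  sigma <- sqrt(n_draws * (1 / 4) * (3 / 4))
  expect_true(all(abs(counts - expected) < 3 * sigma))
})
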