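# Independent reference implementations: plain double loops straight from
# the definitions, kept free of any code shared with the package.

ref_cosine_alignment <- function(P, Z) {
  n <- nrow(P)
  tot <- 0
  for (i in seq_len(n)) {
    phat <- P[i, ] / sqrt(sum(P[i, ]^2))
    zhat <- Z[i, ] / sqrt(sum(Z[i, ]^2))
    tot <- tot + sum((phat - zhat)^2) # normalised MSE = 2 - 2 cos
  }
  tot / n
}

ref_nt_xent <- function(z1, z2, tau) {
  Z <- rbind(z1, z2)
  M <- nrow(Z)
  N <- nrow(z1)
  sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  tot <- 0
  for (i in seq_len(M)) {
    j <- if (i <= N) i + N else i - N
    den <- 0
    for (k in seq_len(M)) {
      if (k != i) den <- den + exp(sim(Z[i, ], Z[k, ]) / tau)
    }
    tot <- tot - log(exp(sim(Z[i, ], Z[j, ]) / tau) / den)
  }
  tot / M
}

ref_vicreg <- function(z1, z2, sc = 25, vc = 25, cc = 1) {
  n <- nrow(z1)
  d <- ncol(z1)
  inv <- mean((z1 - z2)^2)
  var_of <- function(Z) {
    s <- 0
    for (j in seq_len(d)) {
      st <- sqrt(stats::var(Z[, j]) + 1e-4)
      s <- s + max(0, 1 - st)
    }
    s / d
  }
  cov_of <- function(Z) {
    C <- stats::cov(Z)
    s <- 0
    for (a in seq_len(d)) for (b in seq_len(d)) {
      if (a != b) s <- s + C[a, b]^2
    }
    s / d
  }
  sc * inv + vc * (var_of(z1) / 2 + var_of(z2) / 2) +
    cc * (cov_of(z1) + cov_of(z2))
}

test_that("cosine-alignment loss hits its closed-form boundary cases", {
  p <- rand_mat(5, 4, seed = 1, "p")
  # parallel: zero loss
  expect_equal(cosine_alignment_loss(p, 3.7 * p), 0, tolerance = 1e-12)
  # orthogonal: 2 per direction, 4 for the symmetrised sum
  a <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  b <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE)
  expect_equal(cosine_alignment_loss(a, b), 2)
  expect_equal(byol_loss(a, b, a, b), 4)
  expect_error(cosine_alignment_loss(matrix(0, 2, 2), a), "zero-norm")
})

test_that("the three losses match brute-force references on random
           batches", {
  set.seed(17)
  for (k in 1:100) {
    n <- sample(2:16, 1)
    d <- sample(2:8, 1)
    z1 <- rand_mat(n, d, seed = k, "a")
    z2 <- rand_mat(n, d, seed = k, "b")
    expect_equal(cosine_alignment_loss(z1, z2), ref_cosine_alignment(z1, z2),
                 tolerance = 1e-6)
    tau <- 0.5
    expect_equal(nt_xent_loss(z1, z2, tau), ref_nt_xent(z1, z2, tau),
                 tolerance = 1e-6)
    expect_equal(vicreg_loss(z1, z2)$loss, ref_vicreg(z1, z2),
                 tolerance = 1e-6)
  }
})

test_that("NT-Xent is reorder- and scale-invariant and needs negatives", {
  z1 <- rand_mat(6, 4, seed = 3, "a")
  z2 <- rand_mat(6, 4, seed = 3, "b")
  set.seed(8)
  p <- sample(6)
  expect_equal(nt_xent_loss(z1[p, ], z2[p, ], 0.7),
               nt_xent_loss(z1, z2, 0.7), tolerance = 1e-12)
  expect_equal(nt_xent_loss(5 * z1, 5 * z2, 0.7),
               nt_xent_loss(z1, z2, 0.7), tolerance = 1e-12)
  expect_error(nt_xent_loss(z1[1, , drop = FALSE], z2[1, , drop = FALSE]),
               "batch size")
})

test_that("VICReg components behave at their degenerate points", {
  z <- rand_mat(6, 4, seed = 5, "z")
  same <- vicreg_loss(z, z)
  expect_equal(unname(same$components["invariance"]), 0)
  # d = 1 has no off-diagonal covariance
  one <- vicreg_loss(rand_mat(6, 1, seed = 6, "c"),
                     rand_mat(6, 1, seed = 6, "d"))
  expect_equal(unname(one$components["covariance"]), 0)
  # component bookkeeping: total is the weighted sum
  full <- vicreg_loss(z, rand_mat(6, 4, seed = 7, "e"),
                      sim_coeff = 3, var_coeff = 5, cov_coeff = 2)
  expect_equal(full$loss,
               sum(c(3, 5, 2) * full$components), tolerance = 1e-12)
  expect_error(vicreg_loss(z[1, , drop = FALSE], z[1, , drop = FALSE]),
               "batch size")
})

test_that("analytic loss gradients match finite differences", {
  n <- 5; d <- 4
  z1 <- rand_mat(n, d, seed = 11, "a")
  z2 <- rand_mat(n, d, seed = 11, "b")

  g <- cosine_alignment_loss(z1, z2, grad = TRUE)
  num <- num_grad(function(v) {
    cosine_alignment_loss(matrix(v, n, d), z2)
  }, as.vector(z1))
  expect_equal(as.vector(g$grad_pred), num, tolerance = 1e-6)

  g <- nt_xent_loss(z1, z2, 0.5, grad = TRUE)
  num1 <- num_grad(function(v) nt_xent_loss(matrix(v, n, d), z2, 0.5),
                   as.vector(z1))
  num2 <- num_grad(function(v) nt_xent_loss(z1, matrix(v, n, d), 0.5),
                   as.vector(z2))
  expect_equal(as.vector(g$grad_z1), num1, tolerance = 1e-6)
  expect_equal(as.vector(g$grad_z2), num2, tolerance = 1e-6)

  g <- vicreg_loss(z1, z2, grad = TRUE)
  num1 <- num_grad(function(v) vicreg_loss(matrix(v, n, d), z2)$loss,
                   as.vector(z1))
  num2 <- num_grad(function(v) vicreg_loss(z1, matrix(v, n, d))$loss,
                   as.vector(z2))
  expect_equal(as.vector(g$grad_z1), num1, tolerance = 1e-5)
  expect_equal(as.vector(g$grad_z2), num2, tolerance = 1e-5)
})

test_that("all losses are invariant to a common positional reordering", {
  z1 <- rand_mat(8, 5, seed = 21, "a")
  z2 <- rand_mat(8, 5, seed = 21, "b")
  set.seed(9)
  p <- sample(8)
  expect_equal(byol_loss(z1[p, ], z2[p, ], z1[p, ], z2[p, ]),
               byol_loss(z1, z2, z1, z2), tolerance = 1e-12)
  expect_equal(nt_xent_loss(z1[p, ], z2[p, ]), nt_xent_loss(z1, z2),
               tolerance = 1e-12)
  expect_equal(vicreg_loss(z1[p, ], z2[p, ])$loss,
               vicreg_loss(z1, z2)$loss, tolerance = 1e-12)
})
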