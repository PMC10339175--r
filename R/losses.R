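## Joint-embedding objectives. Each loss can also return its analytic
## gradient with respect to the embeddings (grad = TRUE); the gradients
## are checked against finite differences and the values against
## brute-force double-loop references in the test suite.

row_norms <- function(Z) sqrt(rowSums(Z^2))

#' Directional cosine-alignment loss (normalised MSE)
#'
#' \code{mean_i (2 - 2 cos(p_i, z_i))}, the per-direction term of the
#' bootstrap objective; identical to the mean squared error between
#' L2-normalised vectors. The \code{target} branch receives no gradient
#' (stop-gradient contract).
#'
#' @param pred prediction matrix (n x d), online branch.
#' @param target target matrix (n x d), no gradient.
#' @param grad also return \code{d loss / d pred}.
#' @return scalar loss, or list \code{(loss, grad_pred)}.
#' @export
cosine_alignment_loss <- function(pred, target, grad = FALSE) {
  stopifnot(nrow(pred) == nrow(target), ncol(pred) == ncol(target))
  np <- row_norms(pred)
  nt <- row_norms(target)
  if (any(np == 0) || any(nt == 0)) {
    stop("zero-norm embedding cannot be normalised", call. = FALSE)
  }
  n <- nrow(pred)
  ph <- pred / np
  th <- target / nt
  cosd <- rowSums(ph * th)
  loss <- mean(2 - 2 * cosd)
  if (!grad) return(loss)
  g <- -2 * (th - cosd * ph) / np / n
  list(loss = loss, grad_pred = g)
}

#' Symmetrised bootstrap (BYOL-style) loss
#'
#' Sum of the two directional cosine-alignment terms: online predictions
#' of view 1 against target projections of view 2, plus online predictions
#' of view 2 against target projections of view 1. With all vectors
#' pairwise orthogonal each direction contributes 2, totalling 4.
#'
#' @param pred1,pred2 online predictor outputs for views 1 and 2 (n x d).
#' @param target1,target2 target projections for views 1 and 2 (n x d);
#'   never receive gradient.
#' @param grad also return gradients w.r.t. \code{pred1}, \code{pred2}.
#' @return scalar loss, or list \code{(loss, grad_pred1, grad_pred2)}.
#' @export
byol_loss <- function(pred1, pred2, target1, target2, grad = FALSE) {
  d1 <- cosine_alignment_loss(pred1, target2, grad = grad)
  d2 <- cosine_alignment_loss(pred2, target1, grad = grad)
  if (!grad) return(d1 + d2)
  list(loss = d1$loss + d2$loss,
       grad_pred1 = d1$grad_pred, grad_pred2 = d2$grad_pred)
}

#' Normalised-temperature cross-entropy (SimCLR-style) loss
#'
#' NT-Xent over the \code{2N x 2N} cosine-similarity matrix of the
#' concatenated embeddings, self-similarity masked, positional pairs
#' \code{(i, N + i)} as positives. Under the class-preserving permutation
#' the labeled positives are same-class different-instance pairs; the loss
#' itself is agnostic to that.
#'
#' @param z1,z2 embedding matrices (N x d), N >= 2.
#' @param temperature softmax temperature (> 0, default 0.5).
#' @param grad also return gradients w.r.t. \code{z1}, \code{z2}.
#' @return scalar loss, or list \code{(loss, grad_z1, grad_z2)}.
#' @export
nt_xent_loss <- function(z1, z2, temperature = 0.5, grad = FALSE) {
  stopifnot(nrow(z1) == nrow(z2), ncol(z1) == ncol(z2), temperature > 0)
  N <- nrow(z1)
  if (N < 2) stop("NT-Xent needs batch size >= 2 (no negatives)",
                  call. = FALSE)
  Z <- rbind(z1, z2)
  rn <- row_norms(Z)
  if (any(rn == 0)) stop("zero-norm embedding cannot be normalised",
                         call. = FALSE)
  Zh <- Z / rn
  M <- 2L * N
  S <- tcrossprod(Zh) / temperature
  diag(S) <- -Inf
  pos <- c((N + 1):M, 1:N)
  mx <- apply(S, 1, max)
  lse <- mx + log(rowSums(exp(S - mx)))
  loss <- mean(lse - S[cbind(1:M, pos)])
  if (!grad) return(loss)
  P <- exp(S - lse) # row-softmax with masked diagonal (exp(-Inf) = 0)
  Y <- matrix(0, M, M)
  Y[cbind(1:M, pos)] <- 1
  G <- (P - Y) / M
  dZh <- ((G + t(G)) %*% Zh) / temperature
  dZ <- (dZh - rowSums(dZh * Zh) * Zh) / rn
  list(loss = loss, grad_z1 = dZ[1:N, , drop = FALSE],
       grad_z2 = dZ[(N + 1):M, , drop = FALSE])
}

offdiag_ssq <- function(C) sum(C^2) - sum(diag(C)^2)

#' Variance-invariance-covariance (VICReg-style) loss
#'
#' Weighted sum of three terms: invariance (mean squared difference of
#' paired embeddings), variance (hinge \code{max(0, 1 - std)} averaged
#' over dimensions, averaged over the two branches; std uses an
#' \code{eps = 1e-4} floor inside the square root), and covariance (sum of
#' squared off-diagonal entries of each branch's covariance matrix,
#' divided by the dimension, summed over branches).
#'
#' @param z1,z2 embedding matrices (n x d), n >= 2.
#' @param sim_coeff,var_coeff,cov_coeff term weights (default 25, 25, 1).
#' @param grad also return gradients w.r.t. \code{z1}, \code{z2}.
#' @return list with \code{loss} and \code{components} (invariance,
#'   variance, covariance); gradients added when \code{grad}.
#' @export
vicreg_loss <- function(z1, z2, sim_coeff = 25, var_coeff = 25,
                        cov_coeff = 1, grad = FALSE) {
  stopifnot(nrow(z1) == nrow(z2), ncol(z1) == ncol(z2))
  n <- nrow(z1)
  d <- ncol(z1)
  if (n < 2) stop("variance/covariance undefined for batch size < 2",
                  call. = FALSE)
  eps <- 1e-4
  diffz <- z1 - z2
  inv <- mean(diffz^2)
  c1 <- sweep(z1, 2, colMeans(z1))
  c2 <- sweep(z2, 2, colMeans(z2))
  std1 <- sqrt(colSums(c1^2) / (n - 1) + eps)
  std2 <- sqrt(colSums(c2^2) / (n - 1) + eps)
  var_term <- mean(pmax(0, 1 - std1)) / 2 + mean(pmax(0, 1 - std2)) / 2
  C1 <- crossprod(c1) / (n - 1)
  C2 <- crossprod(c2) / (n - 1)
  cov_term <- if (d > 1) (offdiag_ssq(C1) + offdiag_ssq(C2)) / d else 0
  loss <- sim_coeff * inv + var_coeff * var_term + cov_coeff * cov_term
  components <- c(invariance = inv, variance = var_term,
                  covariance = cov_term)
  if (!grad) return(list(loss = loss, components = components))
  g_inv1 <- 2 * diffz / (n * d)
  branch_grad <- function(cc, std) {
    act <- std < 1
    g_var <- sweep(cc, 2, -act / (2 * d * (n - 1) * std), "*")
    C <- crossprod(cc) / (n - 1)
    Coff <- C
    diag(Coff) <- 0
    g_cov <- if (d > 1) (4 / ((n - 1) * d)) * cc %*% Coff else 0 * cc
    ## centring corrections vanish: the column sums of cc are zero
    list(g_var = g_var, g_cov = g_cov)
  }
  b1 <- branch_grad(c1, std1)
  b2 <- branch_grad(c2, std2)
  list(loss = loss, components = components,
       grad_z1 = sim_coeff * g_inv1 + var_coeff * b1$g_var +
         cov_coeff * b1$g_cov,
       grad_z2 = -sim_coeff * g_inv1 + var_coeff * b2$g_var +
         cov_coeff * b2$g_cov)
}
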