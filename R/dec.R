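#' Student's-t soft cluster assignment
#'
#' Computes the soft assignment matrix Q used by deep embedded clustering:
#' the similarity of each embedded point to each cluster centroid under a
#' student's-t kernel with one degree of freedom,
#' \deqn{q_{ij} = \frac{(1+\|z_i-\mu_j\|^2)^{-1}}{\sum_{j'}(1+\|z_i-\mu_{j'}\|^2)^{-1}}.}
#'
#' @param Z numeric matrix, n points x d dimensions (patient embeddings).
#' @param mu numeric matrix, K centroids x d dimensions.
#' @return An n x K matrix whose rows sum to 1.
#' @examples
#' Z <- rbind(c(0, 0), c(1, 1))
#' mu <- rbind(c(0, 0), c(1, 0))
#' soft_assign(Z, mu)
#' @export
soft_assign <- function(Z, mu) {
  Z <- as.matrix(Z); mu <- as.matrix(mu)
  if (nrow(mu) < 1L) stop("at least one centroid is required")
  if (ncol(Z) != ncol(mu)) stop("embedding and centroid dimensions differ")
  # squared distances via the expansion |z|^2 - 2 z.mu + |mu|^2
  d2 <- outer(rowSums(Z^2), rep(1, nrow(mu))) - 2 * Z %*% t(mu) +
    outer(rep(1, nrow(Z)), rowSums(mu^2))
  d2[d2 < 0] <- 0
  s <- 1 / (1 + d2)
  s / rowSums(s)
}

#' Auxiliary target distribution for self-supervised clustering
#'
#' Sharpens a soft assignment matrix Q into the self-training target
#' \deqn{p_{ij} = \frac{q_{ij}^2 / \sum_i q_{ij}}{\sum_{j'} (q_{ij'}^2/\sum_i q_{ij'})},}
#' which up-weights high-confidence assignments while normalizing by
#' cluster frequency so large clusters do not absorb everything.
#'
#' @param Q soft assignment matrix (rows sum to 1).
#' @return Matrix P of the same shape, rows summing to 1.
#' @export
target_distribution <- function(Q) {
  Q <- as.matrix(Q)
  f <- colSums(Q)
  if (any(f <= 0)) stop("degenerate cluster: a column of Q sums to zero")
  W <- sweep(Q^2, 2L, f, "/")
  W / rowSums(W)
}

#' Kullback-Leibler divergence between rows of two distribution matrices
#'
#' \eqn{KL(P \| R) = \sum_i \sum_u p_{iu} \log(p_{iu}/r_{iu})}, summed over
#' all rows. Zero entries of \code{R} facing positive mass in \code{P} are
#' clamped at \code{eps} (with a message) so the divergence stays finite.
#'
#' @param P,R matrices with rows that are probability distributions.
#' @param eps clamping constant for logs.
#' @return Non-negative scalar; 0 iff \code{P == R}.
#' @export
kl_divergence <- function(P, R, eps = 1e-7) {
  P <- as.matrix(P); R <- as.matrix(R)
  stopifnot(all(dim(P) == dim(R)))
  if (any(R < eps & P > 0)) {
    message("kl_divergence: clamping near-zero entries of the reference at eps")
    R <- pmax(R, eps)
  }
  idx <- P > 0
  sum(P[idx] * (log(P[idx]) - log(R[idx])))
}

#' Inner-product adjacency decoder
#'
#' Reconstructs graph connectivity from node embeddings as
#' \eqn{\hat A_{ij} = \mathrm{sigmoid}(z_i^\top z_j)}.
#'
#' @param Z node-embedding matrix (nodes x d).
#' @return Symmetric matrix of edge probabilities in (0, 1).
#' @export
decode_adjacency <- function(Z) {
  Z <- as.matrix(Z)
  1 / (1 + exp(-(Z %*% t(Z))))
}

#' Adjacency reconstruction loss
#'
#' Mean binary cross-entropy between the observed 0/1 adjacency and the
#' decoded edge probabilities, taken over unordered node pairs (the
#' diagonal is excluded: self-loops live only inside the encoder).
#'
#' @param A observed adjacency (0/1, symmetric, zero diagonal).
#' @param Ahat decoded adjacency from [decode_adjacency()].
#' @param eps probability clamp for the logs.
#' @return Non-negative scalar.
#' @export
adjacency_loss <- function(A, Ahat, eps = 1e-7) {
  A <- as.matrix(A); Ahat <- as.matrix(Ahat)
  stopifnot(all(dim(A) == dim(Ahat)))
  iu <- upper.tri(A)
  p <- pmin(pmax(Ahat[iu], eps), 1 - eps)
  y <- A[iu]
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Outcome supervision loss
#'
#' Mean binary cross-entropy over all (patient, time) outcome predictions,
#' the supervision signal that steers the clustering toward
#' prognosis-sensitive phenotypes.
#'
#' @param y observed binary labels (recycled across time columns if
#'   \code{yhat} is a matrix).
#' @param yhat predicted death probabilities, vector or n x T matrix.
#' @param eps probability clamp.
#' @return Non-negative scalar (natural-log units).
#' @export
outcome_loss <- function(y, yhat, eps = 1e-7) {
  yhat <- as.matrix(yhat)
  y <- matrix(y, nrow(yhat), ncol(yhat))
  p <- pmin(pmax(yhat, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Gaussian KL divergence to the standard-normal prior
#'
#' Closed form \eqn{\tfrac12 \sum (m^2 + s^2 - 1 - \log s^2)} averaged over
#' samples; the regularization term of the conditional variational
#' autoencoder's evidence lower bound.
#'
#' @param mean,logvar matrices of per-sample latent means and log-variances.
#' @return Non-negative scalar (mean per sample).
#' @export
gaussian_kl <- function(mean, logvar) {
  mean <- as.matrix(mean); logvar <- as.matrix(logvar)
  stopifnot(all(dim(mean) == dim(logvar)))
  if (any(!is.finite(logvar))) stop("non-finite log-variance")
  sum(0.5 * (mean^2 + exp(logvar) - 1 - logvar)) / nrow(mean)
}

#' Conditional VAE loss (reconstruction + prior regularization)
#'
#' @param x original inputs (matrix).
#' @param xhat decoder reconstruction of \code{x}.
#' @param mean,logvar encoder posterior parameters.
#' @return Scalar: mean squared reconstruction error plus the Gaussian KL
#'   term from [gaussian_kl()].
#' @export
cvae_elbo_loss <- function(x, xhat, mean, logvar) {
  mean((as.matrix(x) - as.matrix(xhat))^2) + gaussian_kl(mean, logvar)
}

#' Composite training loss
#'
#' Weighted sum \eqn{L = L_G + \alpha L_C + \beta L_{AR} + \gamma L_{CVAE} +
#' \sigma L_S}. Components disabled by an ablation flag contribute exactly
#' zero regardless of their value.
#'
#' @param components named numeric vector or list with elements
#'   \code{LG}, \code{LC}, \code{LAR}, \code{LCVAE}, \code{LS}.
#' @param weights named numeric vector \code{c(alpha=, beta=, gamma=, sigma=)}.
#' @param use named logical vector of ablation switches
#'   (\code{LC}, \code{LAR}, \code{LCVAE}, \code{LS}); missing names
#'   default to enabled.
#' @return Scalar loss.
#' @export
total_loss <- function(components,
                       weights = c(alpha = 1, beta = 1, gamma = 1, sigma = 1),
                       use = c(LC = TRUE, LAR = TRUE, LCVAE = TRUE, LS = TRUE)) {
  comp <- as.list(components)
  if (any(weights < 0)) stop("loss weights must be non-negative")
  on_ <- function(nm) isTRUE(is.na(use[nm])) || !identical(unname(use[nm]), FALSE)
  comp$LG +
    (if (on_("LC")) weights[["alpha"]] * comp$LC else 0) +
    (if (on_("LAR")) weights[["beta"]] * comp$LAR else 0) +
    (if (on_("LCVAE")) weights[["gamma"]] * comp$LCVAE else 0) +
    (if (on_("LS")) weights[["sigma"]] * comp$LS else 0)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to relabeling), about 0 for independent
#' ones. Used to score recovery of planted phenotypes.
#'
#' @param a,b label vectors of equal length.
#' @return Scalar in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sij <- sum(choose2(tab))
  si <- sum(choose2(rowSums(tab)))
  sj <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- si * sj / n2
  mx <- (si + sj) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}
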