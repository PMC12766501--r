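# Parameter-free clustering math: student's-t soft assignment, auxiliary
# target distribution, KL divergence, adjacency decoder and the loss
# building blocks, each checked against hand computations and naive
# double-loop oracles.

naive_soft_assign <- function(Z, mu) {
  n <- nrow(Z); K <- nrow(mu)
  q <- matrix(0, n, K)
  for (i in seq_len(n)) {
    s <- numeric(K)
    for (j in seq_len(K)) s[j] <- 1 / (1 + sum((Z[i, ] - mu[j, ])^2))
    q[i, ] <- s / sum(s)
  }
  q
}

naive_target <- function(Q) {
  n <- nrow(Q); K <- ncol(Q)
  f <- colSums(Q)
  P <- matrix(0, n, K)
  for (i in seq_len(n)) {
    w <- Q[i, ]^2 / f
    P[i, ] <- w / sum(w)
  }
  P
}

naive_kl <- function(P, R) {
  out <- 0
  for (i in seq_len(nrow(P))) for (u in seq_len(ncol(P))) {
    if (P[i, u] > 0) out <- out + P[i, u] * log(P[i, u] / R[i, u])
  }
  out
}

test_that("soft assignment reproduces hand-computed student's-t similarities", {
  # z at the first centroid, unit distance to the second: s = (1, 1/2)
  Z <- matrix(c(0, 0), 1)
  mu <- rbind(c(0, 0), c(1, 0))
  expect_equal(soft_assign(Z, mu)[1, ], c(2 / 3, 1 / 3), tolerance = 1e-12)
  # equidistant point splits evenly
  Zm <- matrix(c(0.5, 0), 1)
  expect_equal(soft_assign(Zm, mu)[1, ], c(0.5, 0.5), tolerance = 1e-12)
  # rows always normalize
  set.seed(1)
  Q <- soft_assign(matrix(rnorm(40), 10), matrix(rnorm(12), 3))
  expect_equal(rowSums(Q), rep(1, 10), tolerance = 1e-12)
  expect_true(all(Q > 0 & Q < 1))
})

test_that("target distribution matches the worked sharpening example exactly", {
  Q <- rbind(c(0.5, 0.5), c(0.9, 0.1))
  P <- target_distribution(Q)
  # column sums (1.4, 0.6); sharpen and renormalize -> exact fractions
  expect_equal(P, rbind(c(0.3, 0.7), c(0.972, 0.028)), tolerance = 1e-12)
  # symmetric Q is a fixed point
  Qs <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(target_distribution(Qs), Qs, tolerance = 1e-12)
  # degenerate cluster rejected
  expect_error(target_distribution(rbind(c(1, 0), c(1, 0))), "degenerate")
})

test_that("soft assignment, target distribution and KL match naive oracles", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(2:20, 1); K <- sample(2:4, 1); d <- sample(2:5, 1)
    Z <- matrix(rnorm(n * d), n)
    mu <- matrix(rnorm(K * d), K)
    Q <- soft_assign(Z, mu)
    expect_equal(Q, naive_soft_assign(Z, mu), tolerance = 1e-10)
    P <- target_distribution(Q)
    expect_equal(P, naive_target(Q), tolerance = 1e-10)
    expect_equal(kl_divergence(P, Q), naive_kl(P, Q), tolerance = 1e-10)
    expect_gte(kl_divergence(P, Q), 0)
  }
})

test_that("target distribution sharpens balanced soft assignments", {
  set.seed(7)
  for (rep in 1:50) {
    # balanced columns: draw rows and their per-column mirror
    half <- matrix(runif(10 * 3), 10)
    half <- half / rowSums(half)
    Q <- rbind(half, half[, c(2, 3, 1)], half[, c(3, 1, 2)])
    P <- target_distribution(Q)
    expect_true(all(apply(P, 1, max) >= apply(Q, 1, max) - 1e-12))
  }
})

test_that("KL divergence has the hand-computed values and Gibbs property", {
  P <- matrix(c(1, 0), 1)
  R <- matrix(c(0.5, 0.5), 1)
  expect_equal(kl_divergence(P, R), log(2), tolerance = 1e-12)
  expect_equal(kl_divergence(R, R), 0)
  set.seed(3)
  for (rep in 1:20) {
    A <- matrix(runif(8), 2); A <- A / rowSums(A)
    B <- matrix(runif(8), 2); B <- B / rowSums(B)
    expect_gte(kl_divergence(A, B), -1e-12)
  }
})

test_that("adjacency decoder and reconstruction loss behave as specified", {
  # orthogonal embeddings decode to 0.5; inner product ln 3 to 0.75
  Z <- rbind(c(1, 0), c(0, 1))
  expect_equal(decode_adjacency(Z)[1, 2], 0.5)
  Z2 <- rbind(c(sqrt(log(3)), 0), c(sqrt(log(3)), 0))
  expect_equal(decode_adjacency(Z2)[1, 2], 0.75, tolerance = 1e-12)
  # perfect reconstruction drives the loss to ~0
  A <- rbind(c(0, 1), c(1, 0))
  Ahat <- rbind(c(0.5, 1 - 1e-9), c(1 - 1e-9, 0.5))
  expect_lt(adjacency_loss(A, Ahat), 1e-6)
})

test_that("outcome loss is mean BCE with permutation invariance", {
  expect_lt(outcome_loss(1, 1 - 1e-9), 1e-6)
  expect_equal(outcome_loss(1, 0.5), log(2), tolerance = 1e-9)
  set.seed(5)
  y <- rbinom(20, 1, 0.4); p <- runif(20, 0.05, 0.95)
  i <- sample(20)
  expect_equal(outcome_loss(y, p), outcome_loss(y[i], p[i]))
})

test_that("Gaussian KL term has its closed-form values", {
  expect_equal(gaussian_kl(matrix(0), matrix(0)), 0)
  expect_equal(gaussian_kl(matrix(1), matrix(0)), 0.5)
  expect_error(gaussian_kl(matrix(0), matrix(Inf)), "non-finite")
  # perfect reconstruction leaves only the KL part
  x <- matrix(rnorm(6), 2)
  expect_equal(cvae_elbo_loss(x, x, matrix(0, 2, 2), matrix(0, 2, 2)), 0)
})

test_that("composite loss sums weighted components and honors ablations", {
  comp <- c(LG = 1, LC = 2, LAR = 3, LCVAE = 4, LS = 5)
  w1 <- c(alpha = 1, beta = 1, gamma = 1, sigma = 1)
  expect_equal(total_loss(comp, w1), 15)
  expect_equal(total_loss(comp, c(alpha = 2, beta = 0.5, gamma = 1, sigma = 0)),
               1 + 4 + 1.5 + 4, tolerance = 1e-12)
  expect_equal(total_loss(comp, w1, use = c(LC = FALSE, LAR = FALSE,
                                            LCVAE = FALSE, LS = FALSE)), 1)
  expect_error(total_loss(comp, c(alpha = -1, beta = 1, gamma = 1, sigma = 1)),
               "non-negative")
})

test_that("adjusted Rand index agrees with the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(9)
  for (rep in 1:20) {
    a <- sample(1:3, 40, replace = TRUE)
    b <- sample(1:4, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 6)), 1)
})
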