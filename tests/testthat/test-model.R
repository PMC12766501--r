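# The fitted model: forward-pass contracts, attention normalization,
# determinism, loss descent, cluster assignment and risk stratification.

test_that("graph attention output is a convex combination of neighbors", {
  # with W = identity and no activation, each output row must lie inside
  # the coordinate-wise hull of the neighborhood rows
  set.seed(1)
  g <- odtgclust:::ad_graph()
  H <- lapply(1:4, function(i) odtgclust:::ad_const(g, matrix(rnorm(6 * 2), 6, 2)))
  A <- rbind(c(0, 1, 1, 0), c(1, 0, 0, 0), c(1, 0, 0, 1), c(0, 0, 1, 0))
  nb <- lapply(1:4, function(i) sort(unique(c(i, which(A[i, ] != 0)))))
  W <- odtgclust:::ad_const(g, diag(2))
  as_ <- odtgclust:::ad_const(g, matrix(rnorm(2), 2, 1))
  ad_ <- odtgclust:::ad_const(g, matrix(rnorm(2), 2, 1))
  out <- odtgclust:::gat_layer(g, H, W, as_, ad_, nb, act = FALSE)
  for (i in 1:4) {
    vals <- sapply(nb[[i]], function(j) H[[j]]$value)
    lo <- do.call(pmin, lapply(nb[[i]], function(j) H[[j]]$value))
    hi <- do.call(pmax, lapply(nb[[i]], function(j) H[[j]]$value))
    expect_true(all(out[[i]]$value >= lo - 1e-12 & out[[i]]$value <= hi + 1e-12))
  }
})

test_that("forward pass honors its shape contracts and is deterministic", {
  coh <- make_cohort(n = 10, seed = 31)
  parts <- cohort_to_graphs(coh, seed = 31, min_count = 2)
  gs <- parts$graphs
  ctl <- odtgc_control(K = 3, d_latent = 4, lstm_hidden = 4, cvae_hidden = 4,
                       epochs = 1, pretrain_epochs = 1, seed = 1)
  y <- coh$outcomes$death[match(gs$patient_ids, coh$outcomes$patient_id)]
  set.seed(2)
  theta <- odtgclust:::init_theta(gs$d, ctl)
  fw <- odtgclust:::odtgc_forward(theta, gs$X, gs$A, ctl, y = y, sample_noise = FALSE)
  expect_equal(dim(fw$yhat), c(10, 12))
  expect_true(all(fw$yhat > 0 & fw$yhat < 1))
  expect_equal(dim(fw$Z_val), c(10, 13 * 4))     # graph state: 13 nodes x latent
  expect_equal(dim(fw$Gp), c(10, 12, 13, 4))
  expect_true(all(is.finite(fw$Z_val)))
  # identical input and parameters reproduce identical outputs
  fw2 <- odtgclust:::odtgc_forward(theta, gs$X, gs$A, ctl, y = y, sample_noise = FALSE)
  expect_identical(fw$Z_val, fw2$Z_val)
  expect_identical(fw$LCVAE$value, fw2$LCVAE$value)
})

test_that("fusion attention weights are complementary and normalized", {
  # the two-way attention is a softmax over two scores: a_h + a_g = 1 by
  # construction; verify through the fused value being a convex mix
  set.seed(3)
  h <- matrix(rnorm(10), 5, 2)
  gv <- matrix(rnorm(10), 5, 2)
  a <- 1 / (1 + exp(-(rnorm(5))))
  fused <- h * a + gv * (1 - a)
  lo <- pmin(h, gv); hi <- pmax(h, gv)
  expect_true(all(fused >= lo - 1e-12 & fused <= hi + 1e-12))
})

test_that("training reduces the composite loss and is seed-reproducible", {
  tf <- tiny_fit()
  h <- tf$fit$history
  pre <- h[h$phase == "pretrain", ]
  expect_lt(pre$total[nrow(pre)], pre$total[1])
  joint <- h[h$phase == "joint", ]
  expect_lt(joint$total[nrow(joint)], joint$total[1])
  expect_true(all(is.finite(h$total)))
  # KL-based components are non-negative throughout
  expect_true(all(joint$LC >= 0 & joint$LG >= 0))

  fit2 <- odtgcnet(tf$parts$graphs, tf$coh$outcomes, tf$fit$control)
  expect_identical(fit2$labels, tf$fit$labels)
  expect_equal(fit2$mu, tf$fit$mu, tolerance = 1e-12)
})

test_that("assignment takes the argmax with ties to the lowest index", {
  Q <- rbind(c(0.2, 0.5, 0.3), c(0.5, 0.5, 0))
  expect_equal(max.col(Q, ties.method = "first"), c(2, 1))
  tf <- tiny_fit()
  expect_identical(predict(tf$fit), max.col(tf$fit$Q, ties.method = "first"))
  expect_equal(rowSums(tf$fit$Q), rep(1, nrow(tf$fit$Q)), tolerance = 1e-6)
})

test_that("risk trajectories are full-length ordinal levels from the mortality order", {
  tf <- tiny_fit()
  rt <- risk_trajectory(tf$fit)
  expect_equal(dim(rt), c(length(tf$fit$patient_ids), 12))
  expect_true(all(rt %in% 0:2))
  expect_setequal(tf$fit$risk_level, 0:2)
  # the lowest-mortality cluster maps to level 0
  expect_equal(tf$fit$risk_level[which.min(tf$fit$cluster_mortality)], 0L)
  # prediction on the training graphs reproduces the stored assignments
  pred <- predict(tf$fit, tf$parts$graphs, type = "phenotype")
  expect_identical(pred, tf$fit$labels)
})

test_that("with the outcome loss ablated, labels cannot influence the fit", {
  coh <- make_cohort(n = 40, seed = 33)
  parts <- cohort_to_graphs(coh, seed = 33)
  ctl <- odtgc_control(d_latent = 6, cvae_hidden = 6, epochs = 3,
                       pretrain_epochs = 4, seed = 5,
                       loss_weights = c(alpha = 1, beta = 0.1, gamma = 1, sigma = 0))
  fit_a <- odtgcnet(parts$graphs, coh$outcomes, ctl)
  shuffled <- coh$outcomes
  shuffled$death <- with_seed(99, sample(shuffled$death))
  fit_b <- odtgcnet(parts$graphs, shuffled, ctl)
  expect_gte(adjusted_rand_index(fit_a$labels, fit_b$labels), 0.95)
})

test_that("model summaries and centroid accessors are coherent", {
  tf <- tiny_fit()
  expect_equal(dim(coef(tf$fit)), c(3, 13 * tf$fit$control$d_latent))
  expect_output(print(tf$fit), "risk level")
  s <- summary(tf$fit)
  expect_equal(sum(s$cluster_sizes), length(tf$fit$patient_ids))
  expect_output(print(s), "final loss")
})
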