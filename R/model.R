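# Network internals for the outcome-guided deep temporal graph clustering
# model: parameter initialization and the forward pass over the tape.
# Architecture per time step: an LSTM emits an outcome prediction that
# conditions a variational autoencoder over node features; a first
# graph-attention layer produces structural embeddings; the two are fused
# per node by a learned two-way attention into the joint embeddings g'.
# A second graph-attention layer on the fused embeddings serves as the
# structure-decoding head for adjacency reconstruction. The per-patient
# embedding z used for clustering and risk stratification is the
# concatenation of the 13 fused node embeddings at the final time step
# (the patient's graph state at 48 h).

init_theta <- function(d, control) {
  dl <- control$d_latent; m <- control$lstm_hidden; ch <- control$cvae_hidden
  gl <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
  z <- function(nc) matrix(0, 1, nc)
  list(
    W_x0 = gl(d, m), W_xg = gl(dl, m),                 # LSTM input projections
    Wl = gl(m, 4 * m), Ul = gl(m, 4 * m), bl = z(4 * m),
    w_y = gl(m, 1), b_y = z(1),
    We1 = gl(d + 1, ch), be1 = z(ch),                  # CVAE encoder (+1: outcome condition)
    Wmu = gl(ch, dl), bmu = z(dl),
    Wlv = matrix(0, ch, dl), blv = matrix(-2, 1, dl),  # start with small posterior variance
    Wd1 = gl(dl + 1, ch), bd1 = z(ch),                 # CVAE decoder
    Wd2 = gl(ch, d), bd2 = z(d),
    Wg1 = gl(d, dl), a1s = gl(dl, 1), a1d = gl(dl, 1), # graph attention layers
    Wg2 = gl(dl, dl), a2s = gl(dl, 1), a2d = gl(dl, 1),
    wfh = gl(dl, 1), bfh = z(1), wfg = gl(dl, 1), bfg = z(1))  # fusion attention
}

# one graph-attention layer over the 13-node graph, batched over patients;
# self-loops enter here (and only here) via the neighbor lists
gat_layer <- function(g, H, W, a_src, a_dst, nb, act = TRUE) {
  WH <- lapply(H, function(h) ad_mm(g, h, W))
  es <- lapply(WH, function(h) ad_mm(g, h, a_src))
  ed <- lapply(WH, function(h) ad_mm(g, h, a_dst))
  out <- vector("list", length(H))
  for (i in seq_along(H)) {
    js <- nb[[i]]
    sc <- lapply(js, function(j) ad_lrelu(g, ad_add(g, es[[i]], ed[[j]])))
    mx <- Reduce(pmax, lapply(sc, function(s) s$value))   # detached softmax shift
    ex <- lapply(sc, function(s) ad_exp(g, ad_add(g, s, ad_const(g, -mx))))
    den_inv <- ad_inv(g, Reduce(function(a, b) ad_add(g, a, b), ex))
    contrib <- lapply(seq_along(js), function(k) {
      ad_colmul(g, WH[[js[k]]], ad_mul(g, ex[[k]], den_inv))
    })
    s <- Reduce(function(a, b) ad_add(g, a, b), contrib)
    out[[i]] <- if (act) ad_elu(g, s) else s
  }
  out
}

# conditional VAE for one node's features; returns latent node and loss node
cvae_node <- function(g, x, yhat, th, eps, xval) {
  enc_in <- ad_cbind(g, list(x, yhat))
  e1 <- ad_tanh(g, ad_add_bias(g, ad_mm(g, enc_in, th$We1), th$be1))
  mn <- ad_add_bias(g, ad_mm(g, e1, th$Wmu), th$bmu)
  lv <- ad_add_bias(g, ad_mm(g, e1, th$Wlv), th$blv)
  h <- if (is.null(eps)) mn else
    ad_add(g, mn, ad_mul(g, ad_exp(g, ad_smul(g, lv, 0.5)), ad_const(g, eps)))
  dec_in <- ad_cbind(g, list(h, yhat))
  d1 <- ad_tanh(g, ad_add_bias(g, ad_mm(g, dec_in, th$Wd1), th$bd1))
  xhat <- ad_add_bias(g, ad_mm(g, d1, th$Wd2), th$bd2)
  recon <- ad_mse(g, xhat, xval)
  t1 <- ad_mul(g, mn, mn)
  ssum <- ad_sadd(g, ad_add(g, ad_add(g, t1, ad_exp(g, lv)), ad_smul(g, lv, -1)), -1)
  kl <- ad_smul(g, ad_sum(g, ssum), 0.5 / nrow(xval))
  list(h = h, loss = ad_add(g, recon, kl))
}

# student's-t soft assignment on the tape; returns list of K column nodes
ad_soft_assign <- function(g, Z, mu_nodes) {
  s <- lapply(mu_nodes, function(mu_j) {
    diff <- ad_add_bias(g, Z, ad_neg(g, mu_j))
    ad_inv(g, ad_sadd(g, ad_rowsums(g, ad_mul(g, diff, diff)), 1))
  })
  den_inv <- ad_inv(g, Reduce(function(a, b) ad_add(g, a, b), s))
  lapply(s, function(sj) ad_mul(g, sj, den_inv))
}

# KL(P || Q) / n with P constant, from the K column nodes of Q
ad_kl_const_p <- function(g, P, qcols) {
  cross <- Reduce(function(a, b) ad_add(g, a, b),
                  lapply(seq_along(qcols), function(j) {
                    ad_sum(g, ad_mul(g, ad_const(g, P[, j, drop = FALSE]),
                                     ad_log(g, qcols[[j]])))
                  }))
  plogp <- sum(P[P > 0] * log(P[P > 0]))
  ad_sadd(g, ad_smul(g, cross, -1 / nrow(P)), plogp / nrow(P))
}

# Full forward pass. X: patients x T x 13 x d array; A: 13 x 13 adjacency.
# y enables the outcome loss; mu=TRUE expects centroid rows mu1..muK in
# theta and P (constant target distribution) for the clustering losses;
# sample_noise draws fresh reparameterization noise from the current RNG.
odtgc_forward <- function(theta, X, A, control, y = NULL, use_mu = FALSE,
                          P = NULL, sample_noise = FALSE) {
  N <- dim(X)[1]; T <- dim(X)[2]; d <- dim(X)[4]
  dl <- control$d_latent; m <- control$lstm_hidden
  g <- ad_graph()
  th <- lapply(theta, function(v) ad_param(g, v))
  nb <- lapply(seq_len(13L), function(i) sort(unique(c(i, which(A[i, ] != 0)))))
  pooled1 <- apply(array(X[, 1, , ], dim = c(N, 13L, d)), c(1, 3), mean)

  h_prev <- ad_const(g, matrix(0, N, m)); c_prev <- h_prev
  gp_pool_prev <- NULL
  yhat_vals <- matrix(0, N, T)
  Gp_vals <- array(0, c(N, T, 13L, dl))
  ls_terms <- vector("list", T)
  cvae_sum <- NULL
  Ht <- NULL; gp <- NULL; g1 <- NULL

  for (t in seq_len(T)) {
    Xt <- lapply(seq_len(13L), function(i) ad_const(g, matrix(X[, t, i, ], N, d)))
    u <- if (t == 1L) ad_mm(g, ad_const(g, pooled1), th$W_x0)
         else ad_mm(g, gp_pool_prev, th$W_xg)
    gates <- ad_add_bias(g, ad_add(g, ad_mm(g, u, th$Wl), ad_mm(g, h_prev, th$Ul)), th$bl)
    ig <- ad_sigmoid(g, ad_cols(g, gates, 1:m))
    fg <- ad_sigmoid(g, ad_cols(g, gates, (m + 1):(2 * m)))
    og <- ad_sigmoid(g, ad_cols(g, gates, (2 * m + 1):(3 * m)))
    cand <- ad_tanh(g, ad_cols(g, gates, (3 * m + 1):(4 * m)))
    c_cur <- ad_add(g, ad_mul(g, fg, c_prev), ad_mul(g, ig, cand))
    h_cur <- ad_mul(g, og, ad_tanh(g, c_cur))
    zy <- ad_add_bias(g, ad_mm(g, h_cur, th$w_y), th$b_y)
    yhat <- ad_sigmoid(g, zy)
    yhat_vals[, t] <- yhat$value
    if (!is.null(y)) ls_terms[[t]] <- ad_bce_logits(g, zy, matrix(y, N, 1))

    g1 <- gat_layer(g, Xt, th$Wg1, th$a1s, th$a1d, nb, act = TRUE)
    hs <- vector("list", 13L)
    for (i in seq_len(13L)) {
      eps <- if (sample_noise) matrix(stats::rnorm(N * dl), N, dl) else NULL
      cv <- cvae_node(g, Xt[[i]], yhat, th, eps, matrix(X[, t, i, ], N, d))
      hs[[i]] <- cv$h
      cvae_sum <- if (is.null(cvae_sum)) cv$loss else ad_add(g, cvae_sum, cv$loss)
    }
    gp <- vector("list", 13L)
    for (i in seq_len(13L)) {
      sh <- ad_add_bias(g, ad_mm(g, hs[[i]], th$wfh), th$bfh)
      sg <- ad_add_bias(g, ad_mm(g, g1[[i]], th$wfg), th$bfg)
      a <- ad_sigmoid(g, ad_sub(g, sh, sg))       # two-way softmax attention
      b <- ad_smul(g, ad_sadd(g, a, -1), -1)      # 1 - a
      gp[[i]] <- ad_add(g, ad_colmul(g, hs[[i]], a), ad_colmul(g, g1[[i]], b))
      Gp_vals[, t, i, ] <- gp[[i]]$value
    }
    if (t == T) Ht <- gat_layer(g, gp, th$Wg2, th$a2s, th$a2d, nb, act = FALSE)
    gp_pool_prev <- ad_smul(g, Reduce(function(a, b) ad_add(g, a, b), gp), 1 / 13)
    h_prev <- h_cur; c_prev <- c_cur
  }

  Z <- ad_cbind(g, gp)  # graph state at the final step
  # adjacency reconstruction over unordered node pairs at the final step
  pairs <- which(upper.tri(A), arr.ind = TRUE)
  lar_sum <- NULL
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    logit <- ad_rowsums(g, ad_mul(g, Ht[[i]], Ht[[j]]))
    term <- ad_bce_logits(g, logit, matrix(A[i, j], N, 1))
    lar_sum <- if (is.null(lar_sum)) term else ad_add(g, lar_sum, term)
  }
  LAR <- ad_smul(g, lar_sum, 1 / nrow(pairs))
  LCVAE <- ad_smul(g, cvae_sum, 1 / (13 * T))
  LS <- if (!is.null(y)) ad_smul(g, Reduce(function(a, b) ad_add(g, a, b), ls_terms), 1 / T)
        else NULL

  LC <- LG <- NULL
  Q_val <- QG_val <- NULL
  if (use_mu) {
    K <- control$K
    mu_nodes <- lapply(seq_len(K), function(j) th[[paste0("mu", j)]])
    qc <- ad_soft_assign(g, Z, mu_nodes)
    Q_val <- do.call(cbind, lapply(qc, function(n) n$value))
    # structural pathway: the same graph state built from the pre-fusion
    # GAT embeddings, soft-assigned against the shared centroids
    qg <- ad_soft_assign(g, ad_cbind(g, g1), mu_nodes)
    QG_val <- do.call(cbind, lapply(qg, function(n) n$value))
    if (!is.null(P)) {
      LC <- ad_kl_const_p(g, P, qc)
      LG <- ad_kl_const_p(g, P, qg)
    }
  }

  list(g = g, th = th,
       LG = LG, LC = LC, LAR = LAR, LCVAE = LCVAE, LS = LS,
       Z_val = Z$value, yhat = yhat_vals, Gp = Gp_vals,
       Q_val = Q_val, QG_val = QG_val)
}

# weighted composite loss node from a forward pass, honoring ablations
compose_loss <- function(g, fw, control, clustering = FALSE) {
  lw <- control$loss_weights
  terms <- list()
  if (clustering && !is.null(fw$LG)) terms <- c(terms, list(fw$LG))
  if (clustering && control$use_LC && !is.null(fw$LC) && lw[["alpha"]] > 0)
    terms <- c(terms, list(ad_smul(g, fw$LC, lw[["alpha"]])))
  if (control$use_LAR && lw[["beta"]] > 0)
    terms <- c(terms, list(ad_smul(g, fw$LAR, lw[["beta"]])))
  if (control$use_CVAE && lw[["gamma"]] > 0)
    terms <- c(terms, list(ad_smul(g, fw$LCVAE, lw[["gamma"]])))
  if (control$use_LS && !is.null(fw$LS) && lw[["sigma"]] > 0)
    terms <- c(terms, list(ad_smul(g, fw$LS, lw[["sigma"]])))
  if (!length(terms)) stop("all loss components disabled")
  Reduce(function(a, b) ad_add(g, a, b), terms)
}

node_value <- function(nd) if (is.null(nd)) NA_real_ else nd$value
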