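# The user-facing model: odtgcnet() fits the outcome-guided deep temporal
# graph clustering network and returns a classed object with the usual
# modelling methods.

#' Control parameters for [odtgcnet()]
#'
#' @param K number of clusters (phenotypes); the elbow analysis on the
#'   development data selects 3.
#' @param d_latent embedding width of all latent representations.
#' @param gat_heads,gat_layers attention heads and layers of the graph
#'   encoder; this implementation supports the single-head, two-layer
#'   configuration.
#' @param lstm_hidden hidden width of the temporal recurrence.
#' @param cvae_hidden hidden width of the variational encoder/decoder.
#' @param loss_weights named vector (alpha, beta, gamma, sigma) weighting
#'   the clustering, adjacency-reconstruction, variational and outcome
#'   losses in the composite objective
#'   L = LG + alpha*LC + beta*LAR + gamma*LCVAE + sigma*LS.
#' @param lr Adam learning rate.
#' @param epochs joint-training epochs (phase 3).
#' @param pretrain_epochs reconstruction/outcome pretraining epochs before
#'   centroid initialization.
#' @param seed integer seed governing initialization, reparameterization
#'   noise and the K-Means restarts.
#' @param use_LC,use_LAR,use_LS,use_CVAE ablation switches; a disabled
#'   component contributes exactly zero to the objective.
#' @param p_update_every epochs between refreshes of the self-training
#'   target distribution P.
#' @param kmeans_restarts restarts of the centroid-initializing K-Means.
#' @param clip global gradient-norm clip.
#' @param verbose print per-epoch losses.
#' @return A list of class \code{odtgc_control}.
#' @export
odtgc_control <- function(K = 3, d_latent = 16, gat_heads = 1, gat_layers = 2,
                          lstm_hidden = 8, cvae_hidden = 16,
                          loss_weights = c(alpha = 1, beta = 0.1, gamma = 1, sigma = 2),
                          lr = 5e-3, epochs = 20, pretrain_epochs = 40,
                          seed = 1,
                          use_LC = TRUE, use_LAR = TRUE, use_LS = TRUE,
                          use_CVAE = TRUE,
                          p_update_every = 1, kmeans_restarts = 10, clip = 5,
                          verbose = FALSE) {
  if (K < 2) stop("K must be at least 2")
  if (epochs < 1 || pretrain_epochs < 0) stop("invalid epoch counts")
  if (any(loss_weights < 0)) stop("loss weights must be non-negative")
  if (!setequal(names(loss_weights), c("alpha", "beta", "gamma", "sigma"))) {
    stop("loss_weights must be named alpha, beta, gamma, sigma")
  }
  if (gat_heads != 1 || gat_layers != 2) {
    stop("only the single-head, two-layer graph encoder is implemented")
  }
  structure(list(K = as.integer(K), d_latent = as.integer(d_latent),
                 gat_heads = 1L, gat_layers = 2L,
                 lstm_hidden = as.integer(lstm_hidden),
                 cvae_hidden = as.integer(cvae_hidden),
                 loss_weights = loss_weights, lr = lr,
                 epochs = as.integer(epochs),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 seed = as.integer(seed),
                 use_LC = use_LC, use_LAR = use_LAR, use_LS = use_LS,
                 use_CVAE = use_CVAE,
                 p_update_every = as.integer(p_update_every),
                 kmeans_restarts = as.integer(kmeans_restarts),
                 clip = clip, verbose = verbose),
            class = "odtgc_control")
}

#' Fit the outcome-guided deep temporal graph clustering network
#'
#' Trains the model on per-patient temporal organ-graph sequences in
#' three phases: (1) reconstruction/outcome pretraining, (2) K-Means
#' initialization of the cluster centroids on the pretrained embeddings,
#' (3) joint self-supervised training of the full composite loss, with
#' the auxiliary target distribution P refreshed from the current soft
#' assignment. Cluster labels are the argmax of the student's-t soft
#' assignment of each patient's final-step embedding; clusters are also
#' ordered by training-split mortality into risk levels 0..K-1.
#'
#' @param graphs a \code{graph_sequences} object from
#'   [build_graph_sequences()].
#' @param outcomes data frame with patient_id and binary \code{death}.
#' @param control an [odtgc_control()] object.
#' @param train_ids patients used for gradient updates and for the
#'   mortality-based risk ordering (default: all).
#' @return An object of class \code{odtgcnet} with components including
#'   the trained parameters, centroids \code{mu}, per-patient embeddings,
#'   soft assignments \code{Q}, hard \code{labels}, per-time risk levels
#'   and the per-epoch training history.
#' @seealso [predict.odtgcnet()], [risk_trajectory()], [organ_embeddings()]
#' @export
odtgcnet <- function(graphs, outcomes, control = odtgc_control(), train_ids = NULL) {
  stopifnot(inherits(graphs, "graph_sequences"))
  ids <- graphs$patient_ids
  oi <- match(ids, outcomes$patient_id)
  if (any(is.na(oi))) stop("outcomes missing for some patients in graphs")
  y <- outcomes$death[oi]
  if (!all(y %in% c(0, 1))) stop("death must be binary 0/1")
  if (is.null(train_ids)) train_ids <- ids
  tr <- which(ids %in% train_ids)
  if (!length(tr)) stop("no training patients found")
  with_seed(control$seed,
            odtgcnet_impl(graphs, y, control, tr))
}

odtgcnet_impl <- function(graphs, y, control, tr) {
  A <- graphs$A
  Xtr <- graphs$X[tr, , , , drop = FALSE]
  ytr <- y[tr]
  K <- control$K
  theta <- init_theta(graphs$d, control)
  opt <- adam_init(theta)
  hist <- list()
  log_epoch <- function(phase, e, fw, total) {
    hist[[length(hist) + 1]] <<- data.frame(
      phase = phase, epoch = e,
      LG = node_value(fw$LG), LC = node_value(fw$LC),
      LAR = node_value(fw$LAR), LCVAE = node_value(fw$LCVAE),
      LS = node_value(fw$LS), total = total)
    if (control$verbose) {
      cat(sprintf("[%s %3d] total %.4f\n", phase, e, total))
    }
  }

  # phase 1: reconstruction + outcome pretraining
  for (e in seq_len(control$pretrain_epochs)) {
    fw <- odtgc_forward(theta, Xtr, A, control,
                        y = if (control$use_LS) ytr else NULL,
                        sample_noise = TRUE)
    loss <- compose_loss(fw$g, fw, control, clustering = FALSE)
    ad_backward(fw$g, loss)
    grads <- lapply(fw$th, function(p) if (is.null(p$grad)) p$value * 0 else p$grad)
    upd <- adam_step(theta, grads, opt, lr = control$lr, clip = control$clip)
    theta <- upd$theta; opt <- upd$state
    log_epoch("pretrain", e, fw, loss$value)
    if (!is.finite(loss$value)) stop("training diverged (non-finite loss) in pretraining")
  }

  # phase 2: K-Means centroid initialization on current embeddings
  ev <- odtgc_forward(theta, Xtr, A, control, sample_noise = FALSE)
  km <- stats::kmeans(ev$Z_val, centers = K, nstart = control$kmeans_restarts,
                      iter.max = 100)
  for (j in seq_len(K)) theta[[paste0("mu", j)]] <- matrix(km$centers[j, ], 1)
  opt <- adam_init(theta)
  Qcur <- soft_assign(ev$Z_val, km$centers)
  P <- NULL

  # phase 3: joint training on the full composite loss
  for (e in seq_len(control$epochs)) {
    if ((e - 1L) %% control$p_update_every == 0L) P <- target_distribution(Qcur)
    fw <- odtgc_forward(theta, Xtr, A, control,
                        y = if (control$use_LS) ytr else NULL,
                        use_mu = TRUE, P = P, sample_noise = TRUE)
    loss <- compose_loss(fw$g, fw, control, clustering = TRUE)
    ad_backward(fw$g, loss)
    grads <- lapply(fw$th, function(p) if (is.null(p$grad)) p$value * 0 else p$grad)
    upd <- adam_step(theta, grads, opt, lr = control$lr, clip = control$clip)
    theta <- upd$theta; opt <- upd$state
    Qcur <- fw$Q_val
    log_epoch("joint", e, fw, loss$value)
    if (!is.finite(loss$value)) stop("training diverged (non-finite loss) in joint phase")
  }

  mu <- do.call(rbind, lapply(seq_len(K), function(j) theta[[paste0("mu", j)]]))
  rownames(mu) <- paste0("cluster", seq_len(K))

  # final deterministic pass over the whole cohort
  fin <- odtgc_forward(theta, graphs$X, A, control, sample_noise = FALSE)
  Q <- soft_assign(fin$Z_val, mu)
  labels <- max.col(Q, ties.method = "first")

  # clusters ordered by training-split mortality -> risk levels 0..K-1
  mort <- rep(Inf, K)
  mtab <- tapply(y[tr], labels[tr], mean)
  mort[as.integer(names(mtab))] <- mtab
  risk_level <- integer(K)
  risk_level[order(mort)] <- seq_len(K) - 1L

  structure(list(theta = theta, mu = mu, risk_level = risk_level,
                 cluster_mortality = mort,
                 control = control, history = do.call(rbind, hist),
                 patient_ids = graphs$patient_ids, train_ids = graphs$patient_ids[tr],
                 y = y, labels = labels, Q = Q, Z = fin$Z_val,
                 embeddings = fin$Gp, yhat = fin$yhat,
                 schema = graphs$schema, T = graphs$T, d = graphs$d),
            class = "odtgcnet")
}

# graph state at bin t: concatenated fused node embeddings, in the same
# column order the forward pass uses for Z
flatten_graph_state <- function(Gp, t) {
  N <- dim(Gp)[1]; dl <- dim(Gp)[4]
  do.call(cbind, lapply(seq_len(13L), function(i) matrix(Gp[, t, i, ], N, dl)))
}

risk_from_embeddings <- function(Gp, mu, risk_level) {
  N <- dim(Gp)[1]; T <- dim(Gp)[2]
  out <- matrix(0L, N, T)
  for (t in seq_len(T)) {
    Qt <- soft_assign(flatten_graph_state(Gp, t), mu)
    out[, t] <- risk_level[max.col(Qt, ties.method = "first")]
  }
  out
}

#' Per-time risk stratification levels
#'
#' Soft-assigns the patient-node embedding at every 4-h interval against
#' the trained centroids and maps the winning cluster through the
#' mortality ordering, giving an ordinal risk level in 0..K-1 (0 = the
#' lowest-mortality cluster) at each time step.
#'
#' @param object a fitted [odtgcnet()] model.
#' @param graphs optional new \code{graph_sequences}; default uses the
#'   fitted cohort.
#' @return Integer matrix, patients x time steps.
#' @export
risk_trajectory <- function(object, graphs = NULL) {
  stopifnot(inherits(object, "odtgcnet"))
  if (is.null(graphs)) {
    return(risk_from_embeddings(object$embeddings, object$mu, object$risk_level))
  }
  fw <- odtgc_forward(object$theta, graphs$X, graphs$A, object$control,
                      sample_noise = FALSE)
  risk_from_embeddings(fw$Gp, object$mu, object$risk_level)
}

#' Predict method for fitted models
#'
#' @param object a fitted [odtgcnet()] model.
#' @param graphs optional new \code{graph_sequences}; default: the
#'   training cohort's stored results.
#' @param type \code{"phenotype"} for hard cluster labels (argmax of the
#'   soft assignment, ties to the lowest index), \code{"soft"} for the
#'   full soft-assignment matrix Q, \code{"risk"} for the per-time risk
#'   levels, \code{"embedding"} for the final patient embeddings.
#' @param ... unused.
#' @return See \code{type}.
#' @export
predict.odtgcnet <- function(object, graphs = NULL,
                             type = c("phenotype", "soft", "risk", "embedding"),
                             ...) {
  type <- match.arg(type)
  if (is.null(graphs)) {
    return(switch(type,
                  phenotype = object$labels,
                  soft = object$Q,
                  risk = risk_trajectory(object),
                  embedding = object$Z))
  }
  stopifnot(inherits(graphs, "graph_sequences"))
  fw <- odtgc_forward(object$theta, graphs$X, graphs$A, object$control,
                      sample_noise = FALSE)
  Q <- soft_assign(fw$Z_val, object$mu)
  switch(type,
         phenotype = max.col(Q, ties.method = "first"),
         soft = Q,
         risk = risk_from_embeddings(fw$Gp, object$mu, object$risk_level),
         embedding = fw$Z_val)
}

#' @export
print.odtgcnet <- function(x, ...) {
  K <- x$control$K
  cat("Outcome-guided deep temporal graph clustering model\n")
  cat(sprintf("  %d patients, %d time steps, K = %d clusters, latent width %d\n",
              length(x$patient_ids), x$T, K, x$control$d_latent))
  tab <- tabulate(x$labels, K)
  for (j in seq_len(K)) {
    cat(sprintf("  cluster %d: n = %d, training mortality %.1f%%, risk level %d\n",
                j, tab[j], 100 * x$cluster_mortality[j], x$risk_level[j]))
  }
  invisible(x)
}

#' @export
summary.odtgcnet <- function(object, ...) {
  out <- list(
    K = object$control$K,
    n = length(object$patient_ids),
    cluster_sizes = tabulate(object$labels, object$control$K),
    cluster_mortality = object$cluster_mortality,
    risk_level = object$risk_level,
    final_losses = utils::tail(object$history, 1),
    epochs = nrow(object$history))
  class(out) <- "summary.odtgcnet"
  out
}

#' @export
print.summary.odtgcnet <- function(x, ...) {
  cat(sprintf("odtgcnet fit: %d patients, K = %d (%d epochs incl. pretraining)\n",
              x$n, x$K, x$epochs))
  df <- data.frame(cluster = seq_len(x$K), size = x$cluster_sizes,
                   mortality = round(x$cluster_mortality, 4),
                   risk_level = x$risk_level)
  print(df, row.names = FALSE)
  cat("final loss components:\n")
  print(x$final_losses, row.names = FALSE)
  invisible(x)
}

#' @export
coef.odtgcnet <- function(object, ...) object$mu

#' @export
fitted.odtgcnet <- function(object, ...) object$Q

#' Plot training loss trajectories
#'
#' @param x a fitted [odtgcnet()] model.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.odtgcnet <- function(x, ...) {
  h <- x$history
  comp <- as.matrix(h[, c("LG", "LC", "LAR", "LCVAE", "LS", "total")])
  graphics::matplot(seq_len(nrow(h)), comp, type = "l", lty = 1,
                    xlab = "epoch", ylab = "loss", ...)
  graphics::abline(v = sum(h$phase == "pretrain") + 0.5, lty = 3)
  graphics::legend("topright", colnames(comp), col = seq_len(ncol(comp)),
                   lty = 1, cex = 0.8)
  invisible(x)
}
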