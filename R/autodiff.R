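# Minimal reverse-mode automatic differentiation on a tape of matrix ops.
# Internal machinery for the network in odtgcnet(); gradients are verified
# against central finite differences in the test suite.
#
# The tape is a singly linked list of environment nodes; backward functions
# are shared top-level closures (compiled once), with any per-node constants
# stored in nd$extra.

ad_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$last <- NULL
  g$n <- 0L
  g
}

ad_new <- function(g, value, parents = NULL, backward = NULL, requires = FALSE,
                   extra = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$requires <- requires
  nd$extra <- extra
  nd$prev <- g$last
  g$last <- nd
  g$n <- g$n + 1L
  nd
}

ad_param <- function(g, value) ad_new(g, value, requires = TRUE)
ad_const <- function(g, value) ad_new(g, value, requires = FALSE)

# accumulate gradient into a parent node
ad_acc <- function(p, grad) {
  if (p$requires) p$grad <- if (is.null(p$grad)) grad else p$grad + grad
  invisible(NULL)
}

ad_track <- function(a, b) a$requires || b$requires

ad_track_list <- function(nodes) {
  for (p in nodes) if (p$requires) return(TRUE)
  FALSE
}

ad_backward <- function(g, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- 1
  nd <- g$last
  while (!is.null(nd)) {
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
    nd <- nd$prev
  }
  invisible(NULL)
}

## ---- backward kernels (shared across nodes) -------------------------------

bw_mm <- function(nd) {
  ad_acc(nd$parents[[1L]], nd$grad %*% t(nd$parents[[2L]]$value))
  ad_acc(nd$parents[[2L]], t(nd$parents[[1L]]$value) %*% nd$grad)
}
bw_add <- function(nd) {
  ad_acc(nd$parents[[1L]], nd$grad)
  ad_acc(nd$parents[[2L]], nd$grad)
}
bw_add_bias <- function(nd) {
  ad_acc(nd$parents[[1L]], nd$grad)
  ad_acc(nd$parents[[2L]], matrix(colSums(nd$grad), 1L))
}
bw_neg <- function(nd) ad_acc(nd$parents[[1L]], -nd$grad)
bw_mul <- function(nd) {
  ad_acc(nd$parents[[1L]], nd$grad * nd$parents[[2L]]$value)
  ad_acc(nd$parents[[2L]], nd$grad * nd$parents[[1L]]$value)
}
bw_smul <- function(nd) ad_acc(nd$parents[[1L]], nd$grad * nd$extra)
bw_sadd <- function(nd) ad_acc(nd$parents[[1L]], nd$grad)
bw_colmul <- function(nd) {
  a <- nd$parents[[1L]]; v <- nd$parents[[2L]]
  ad_acc(a, nd$grad * as.vector(v$value))
  ad_acc(v, matrix(rowSums(nd$grad * a$value), ncol = 1L))
}
bw_inv <- function(nd) ad_acc(nd$parents[[1L]], -nd$grad * nd$value * nd$value)
bw_exp <- function(nd) ad_acc(nd$parents[[1L]], nd$grad * nd$value)
bw_log <- function(nd) ad_acc(nd$parents[[1L]], nd$grad / nd$parents[[1L]]$value)
bw_tanh <- function(nd) ad_acc(nd$parents[[1L]], nd$grad * (1 - nd$value^2))
bw_sigmoid <- function(nd) ad_acc(nd$parents[[1L]], nd$grad * nd$value * (1 - nd$value))
bw_lrelu <- function(nd) {
  x <- nd$parents[[1L]]$value
  g <- nd$grad
  neg <- x <= 0
  g[neg] <- g[neg] * nd$extra
  ad_acc(nd$parents[[1L]], g)
}
bw_elu <- function(nd) {
  x <- nd$parents[[1L]]$value
  g <- nd$grad
  neg <- x <= 0
  g[neg] <- g[neg] * (nd$value[neg] + 1)  # d/dx alpha(e^x - 1) = value + alpha
  ad_acc(nd$parents[[1L]], g)
}
bw_sum <- function(nd) {
  p <- nd$parents[[1L]]
  ad_acc(p, matrix(nd$grad, nrow(p$value), ncol(p$value)))
}
bw_rowsums <- function(nd) {
  p <- nd$parents[[1L]]
  ad_acc(p, matrix(nd$grad, nrow(p$value), ncol(p$value)))
}
bw_cbind <- function(nd) {
  offs <- nd$extra
  for (i in seq_along(nd$parents)) {
    ad_acc(nd$parents[[i]], nd$grad[, (offs[i] + 1L):offs[i + 1L], drop = FALSE])
  }
}
bw_cols <- function(nd) {
  p <- nd$parents[[1L]]
  gr <- matrix(0, nrow(p$value), ncol(p$value))
  gr[, nd$extra] <- nd$grad
  ad_acc(p, gr)
}
bw_bce_logits <- function(nd) {
  z <- nd$parents[[1L]]$value
  p <- 1 / (1 + exp(-z))
  ad_acc(nd$parents[[1L]], nd$grad * (p - nd$extra) / length(z))
}
bw_mse <- function(nd) {
  a <- nd$parents[[1L]]$value
  ad_acc(nd$parents[[1L]], nd$grad * 2 * (a - nd$extra) / length(a))
}

## ---- primitive operations -------------------------------------------------

ad_mm <- function(g, a, b) {
  ad_new(g, a$value %*% b$value, list(a, b), bw_mm, ad_track(a, b))
}

# elementwise add; shapes must match exactly (use ad_add_bias to broadcast)
ad_add <- function(g, a, b) {
  ad_new(g, a$value + b$value, list(a, b), bw_add, ad_track(a, b))
}

# mat (n x k) + row (1 x k) broadcast down rows
ad_add_bias <- function(g, a, b) {
  val <- a$value
  val <- val + rep(as.vector(b$value), each = nrow(val))
  ad_new(g, val, list(a, b), bw_add_bias, ad_track(a, b))
}

ad_neg <- function(g, a) ad_new(g, -a$value, list(a), bw_neg, a$requires)
ad_sub <- function(g, a, b) ad_add(g, a, ad_neg(g, b))

ad_mul <- function(g, a, b) {
  ad_new(g, a$value * b$value, list(a, b), bw_mul, ad_track(a, b))
}

# multiply / shift by a plain scalar constant
ad_smul <- function(g, a, s) ad_new(g, a$value * s, list(a), bw_smul, a$requires, extra = s)
ad_sadd <- function(g, a, s) ad_new(g, a$value + s, list(a), bw_sadd, a$requires)

# mat (n x k) * vec (n x 1) broadcast across columns
ad_colmul <- function(g, a, v) {
  ad_new(g, a$value * as.vector(v$value), list(a, v), bw_colmul, ad_track(a, v))
}

ad_inv <- function(g, a) ad_new(g, 1 / a$value, list(a), bw_inv, a$requires)
ad_exp <- function(g, a) ad_new(g, exp(a$value), list(a), bw_exp, a$requires)
ad_log <- function(g, a) ad_new(g, log(a$value), list(a), bw_log, a$requires)
ad_tanh <- function(g, a) ad_new(g, tanh(a$value), list(a), bw_tanh, a$requires)
ad_sigmoid <- function(g, a) {
  ad_new(g, 1 / (1 + exp(-a$value)), list(a), bw_sigmoid, a$requires)
}

ad_lrelu <- function(g, a, alpha = 0.2) {
  v <- a$value
  v[v < 0] <- v[v < 0] * alpha
  ad_new(g, v, list(a), bw_lrelu, a$requires, extra = alpha)
}

ad_elu <- function(g, a) {
  v <- a$value
  v[v < 0] <- exp(v[v < 0]) - 1
  ad_new(g, v, list(a), bw_elu, a$requires)
}

ad_sum <- function(g, a) ad_new(g, sum(a$value), list(a), bw_sum, a$requires)
ad_mean <- function(g, a) ad_smul(g, ad_sum(g, a), 1 / length(a$value))

# row sums of an n x k matrix -> n x 1
ad_rowsums <- function(g, a) {
  ad_new(g, matrix(rowSums(a$value), ncol = 1L), list(a), bw_rowsums, a$requires)
}

# column-bind nodes (all same number of rows)
ad_cbind <- function(g, nodes) {
  vals <- lapply(nodes, function(n) n$value)
  offs <- cumsum(c(0L, vapply(vals, ncol, 0L)))
  ad_new(g, do.call(cbind, vals), nodes, bw_cbind, ad_track_list(nodes), extra = offs)
}

# column slice
ad_cols <- function(g, a, idx) {
  ad_new(g, a$value[, idx, drop = FALSE], list(a), bw_cols, a$requires, extra = idx)
}

# mean binary cross-entropy on logits against a constant 0/1 target
ad_bce_logits <- function(g, z, y) {
  zv <- z$value
  val <- mean(pmax(zv, 0) - zv * y + log1p(exp(-abs(zv))))
  ad_new(g, val, list(z), bw_bce_logits, z$requires, extra = y)
}

# mean squared error against a constant target
ad_mse <- function(g, a, target) {
  ad_new(g, mean((a$value - target)^2), list(a), bw_mse, a$requires, extra = target)
}

## ---- optimizer ------------------------------------------------------------

adam_init <- function(theta) {
  list(m = lapply(theta, function(x) x * 0),
       v = lapply(theta, function(x) x * 0),
       t = 0L)
}

# Adam update with global-norm gradient clipping
adam_step <- function(theta, grads, state, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 5) {
  gnorm <- sqrt(sum(vapply(grads, function(x) sum(x^2), 0)))
  if (is.finite(gnorm) && gnorm > clip) grads <- lapply(grads, function(x) x * clip / gnorm)
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(theta)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    theta[[nm]] <- theta[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(theta = theta, state = state)
}
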