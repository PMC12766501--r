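# Model selection (elbow rule over the within-cluster SSE curve) and
# clustering quality metrics (silhouette coefficient, Davies-Bouldin
# index), all on Euclidean distances.

#' Within-cluster SSE over a range of cluster counts
#'
#' Runs seeded K-Means (with restarts) on the embedding matrix for every
#' k and records the total within-cluster sum of squared errors.
#'
#' @param Z numeric matrix, points x dimensions.
#' @param k_range increasing integer vector of cluster counts.
#' @param seed integer seed for the K-Means restarts.
#' @param nstart number of K-Means restarts per k.
#' @return An object of class \code{sse_curve}: list with \code{ks} and
#'   \code{sse}.
#' @export
sse_curve <- function(Z, k_range = 2:8, seed = 1, nstart = 10) {
  Z <- as.matrix(Z)
  if (max(k_range) > nrow(Z)) stop("k_range exceeds the number of points")
  sse <- with_seed(seed, vapply(k_range, function(k) {
    if (k == 1) return(sum(sweep(Z, 2, colMeans(Z))^2))   # total scatter
    if (k == nrow(Z)) return(0)                           # each point its own centroid
    stats::kmeans(Z, centers = k, nstart = nstart, iter.max = 100)$tot.withinss
  }, 0))
  structure(list(ks = as.integer(k_range), sse = sse), class = "sse_curve")
}

#' @export
print.sse_curve <- function(x, ...) {
  print(data.frame(k = x$ks, sse = x$sse), row.names = FALSE)
  invisible(x)
}

#' Select the cluster count at the SSE elbow
#'
#' Deterministic proxy for the visual elbow: the k maximizing the
#' discrete second difference of the SSE curve, i.e. the point after
#' which the rate of SSE reduction slows most sharply. Ties go to the
#' smallest k; a flat or linear curve returns the smallest k with a
#' warning.
#'
#' @param curve an [sse_curve()] object.
#' @return Integer k*.
#' @export
select_k_elbow <- function(curve) {
  stopifnot(inherits(curve, "sse_curve"))
  ks <- curve$ks; sse <- curve$sse
  if (length(ks) < 3) stop("need at least three points to locate an elbow")
  d2 <- sse[-c(length(sse) - 1, length(sse))] - 2 * sse[-c(1, length(sse))] +
    sse[-c(1, 2)]
  tol <- 1e-8 * max(abs(sse), 1)
  if (max(d2) <= tol) {
    warning("no elbow detected (flat or linear SSE curve); returning smallest k")
    return(ks[1])
  }
  ks[which.max(d2) + 1L]
}

#' Mean silhouette coefficient
#'
#' For each point, \eqn{s(i) = (b(i) - a(i)) / \max(a(i), b(i))} with
#' \eqn{a(i)} the mean distance to its own cluster and \eqn{b(i)} the
#' smallest mean distance to another cluster; singletons score 0.
#' Returns the mean over points, in [-1, 1]; higher means tighter,
#' better-separated clusters.
#'
#' @param Z numeric matrix, points x dimensions.
#' @param labels cluster labels.
#' @return Scalar mean silhouette width.
#' @export
silhouette_coef <- function(Z, labels) {
  Z <- as.matrix(Z)
  labels <- as.integer(factor(labels))
  K <- max(labels)
  if (K < 2) stop("silhouette requires at least two clusters")
  D <- as.matrix(stats::dist(Z))
  n <- nrow(D)
  sizes <- tabulate(labels, K)
  # mean distance from each point to each cluster
  md <- sapply(seq_len(K), function(k) rowSums(D[, labels == k, drop = FALSE]) / sizes[k])
  s <- numeric(n)
  for (i in seq_len(n)) {
    k <- labels[i]
    if (sizes[k] == 1) { s[i] <- 0; next }
    a <- md[i, k] * sizes[k] / (sizes[k] - 1)  # exclude the point itself
    b <- min(md[i, -k])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Davies-Bouldin index
#'
#' \eqn{DBI = \frac1K \sum_i \max_{j \ne i} (S_i + S_j)/M_{ij}} with
#' \eqn{S} the mean distance of a cluster's points to its centroid and
#' \eqn{M} the distance between centroids. Lower is better.
#'
#' @param Z numeric matrix, points x dimensions.
#' @param labels cluster labels.
#' @return Non-negative scalar.
#' @export
davies_bouldin <- function(Z, labels) {
  Z <- as.matrix(Z)
  labels <- as.integer(factor(labels))
  K <- max(labels)
  if (K < 2) stop("Davies-Bouldin requires at least two clusters")
  cent <- do.call(rbind, lapply(seq_len(K), function(k) {
    colMeans(Z[labels == k, , drop = FALSE])
  }))
  S <- vapply(seq_len(K), function(k) {
    mean(sqrt(rowSums(sweep(Z[labels == k, , drop = FALSE], 2, cent[k, ])^2)))
  }, 0)
  M <- as.matrix(stats::dist(cent))
  if (any(M[upper.tri(M)] == 0)) stop("coincident cluster centroids")
  R <- (outer(S, S, "+")) / M
  diag(R) <- -Inf
  mean(apply(R, 1, max))
}
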