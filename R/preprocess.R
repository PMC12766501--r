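# Preprocessing pipeline: time binning, missingness filters, IQR outlier
# censoring, forward/backward-fill imputation and train-statistic
# normalization. The fixed order is bin -> filter -> censor -> impute ->
# normalize, with every statistic computed on the training split only.

new_feature_tensor <- function(values, mask, bin_edges, feature_ids, patient_ids) {
  structure(list(values = values, mask = mask, bin_edges = bin_edges,
                 feature_ids = feature_ids, patient_ids = patient_ids),
            class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Feature tensor: %d patients x %d bins x %d features (%.1f%% observed)\n",
              d[1], d[2], d[3], 100 * mean(x$mask)))
  invisible(x)
}

#' Bin long-format events into a fixed-length feature tensor
#'
#' Aggregates a long event table (patient_id, t_hours, feature_id, value)
#' onto regular time bins: each cell holds the arithmetic mean of the
#' measurements falling in \code{[edge_t, edge_{t+1})} (the final bin is
#' closed at the window end), with a 0/1 observation mask. Rows with
#' negative timestamps or timestamps beyond the window are rejected with
#' a warning.
#'
#' @param events data frame with columns patient_id, t_hours, feature_id,
#'   value.
#' @param window_h observation window in hours.
#' @param bin_h bin width in hours; must divide \code{window_h}.
#' @param patient_ids,feature_ids optional orderings; defaults are the
#'   sorted unique values present in \code{events}.
#' @return A \code{feature_tensor}: list with \code{values} and
#'   \code{mask} arrays (patients x bins x features), \code{bin_edges},
#'   \code{feature_ids} and \code{patient_ids}. Empty cells are NA with
#'   mask 0.
#' @export
bin_events <- function(events, window_h = 48, bin_h = 4,
                       patient_ids = NULL, feature_ids = NULL) {
  if (window_h %% bin_h != 0) stop("window_h must be divisible by bin_h")
  bad <- events$t_hours < 0 | events$t_hours > window_h
  if (any(bad)) {
    warning(sum(bad), " event(s) outside [0, window_h] dropped")
    events <- events[!bad, ]
  }
  if (is.null(patient_ids)) patient_ids <- sort(unique(events$patient_id))
  if (is.null(feature_ids)) feature_ids <- sort(unique(events$feature_id))
  T <- window_h %/% bin_h
  N <- length(patient_ids); F <- length(feature_ids)
  p <- match(events$patient_id, patient_ids)
  f <- match(events$feature_id, feature_ids)
  ok <- !is.na(p) & !is.na(f)
  t <- pmin(floor(events$t_hours[ok] / bin_h) + 1L, T)
  idx <- p[ok] + N * (t - 1L) + N * T * (f[ok] - 1L)
  sums <- rowsum(events$value[ok], idx)
  cnts <- rowsum(rep(1, sum(ok)), idx)
  cell <- as.integer(rownames(sums))
  values <- array(NA_real_, dim = c(N, T, F))
  mask <- array(0, dim = c(N, T, F))
  values[cell] <- sums / cnts
  mask[cell] <- 1
  new_feature_tensor(values, mask, seq(0, window_h, by = bin_h),
                     feature_ids, patient_ids)
}

#' Per-feature training-split statistics
#'
#' Computes, from observed cells of the training patients only, each
#' feature's mean, standard deviation and quartiles, plus cohort missing
#' rates. These statistics drive outlier censoring, mean imputation and
#' normalization for every split, so no test-split value ever influences
#' a transform.
#'
#' @param tensor a \code{feature_tensor}.
#' @param train_ids patient ids of the training split (default: all).
#' @return An object of class \code{preprocess_stats}.
#' @export
preprocess_stats <- function(tensor, train_ids = NULL) {
  stopifnot(inherits(tensor, "feature_tensor"))
  if (is.null(train_ids)) train_ids <- tensor$patient_ids
  rows <- which(tensor$patient_ids %in% train_ids)
  if (!length(rows)) stop("no training patients found in tensor")
  F <- dim(tensor$values)[3]
  stat <- function(f) {
    v <- tensor$values[rows, , f][tensor$mask[rows, , f] == 1]
    if (!length(v)) return(c(mean = NA, sd = NA, q1 = NA, q3 = NA))
    c(mean = mean(v), sd = stats::sd(v),
      q1 = unname(stats::quantile(v, 0.25)), q3 = unname(stats::quantile(v, 0.75)))
  }
  m <- t(vapply(seq_len(F), stat, numeric(4)))
  structure(list(feature_ids = tensor$feature_ids,
                 mean = m[, "mean"], sd = m[, "sd"],
                 q1 = m[, "q1"], q3 = m[, "q3"],
                 missing_rate = 1 - apply(tensor$mask, 3, mean),
                 n_train = length(rows)),
            class = "preprocess_stats")
}

#' @export
print.preprocess_stats <- function(x, ...) {
  cat(sprintf("Preprocess statistics for %d features (computed on %d training patients)\n",
              length(x$feature_ids), x$n_train))
  invisible(x)
}

#' Drop features and patients with excessive missingness
#'
#' Applies the cohort filters in a fixed order: first features whose
#' cohort missing rate exceeds \code{feature_thresh}, then patients whose
#' missing fraction over the remaining features exceeds
#' \code{patient_thresh}, then patients with no observation of any
#' essential bedside feature within the first
#' \code{essential_window_h} hours.
#'
#' @param tensor a \code{feature_tensor}.
#' @param feature_thresh,patient_thresh missing-rate thresholds in (0, 1].
#' @param essential_features feature ids that must be observed early
#'   (e.g. heart rate, respiratory rate); NULL disables the check.
#' @param essential_window_h horizon for the essential-feature check.
#' @return List with the filtered \code{tensor} and the
#'   \code{dropped_features} / \code{dropped_patients} character vectors.
#' @export
filter_missing <- function(tensor, feature_thresh = 0.4, patient_thresh = 0.4,
                           essential_features = NULL, essential_window_h = 24) {
  stopifnot(inherits(tensor, "feature_tensor"))
  stopifnot(feature_thresh > 0, feature_thresh <= 1,
            patient_thresh > 0, patient_thresh <= 1)
  feat_missing <- 1 - apply(tensor$mask, 3, mean)
  keep_f <- feat_missing <= feature_thresh
  if (!any(keep_f)) stop("all features exceed the missing-rate threshold")
  dropped_features <- tensor$feature_ids[!keep_f]
  values <- tensor$values[, , keep_f, drop = FALSE]
  mask <- tensor$mask[, , keep_f, drop = FALSE]
  feature_ids <- tensor$feature_ids[keep_f]

  pat_missing <- 1 - apply(mask, 1, mean)
  keep_p <- pat_missing <= patient_thresh

  if (!is.null(essential_features)) {
    ess <- intersect(essential_features, feature_ids)
    if (length(ess) < length(essential_features)) {
      warning("essential feature(s) not present after feature filtering: ",
              paste(setdiff(essential_features, ess), collapse = ", "))
    }
    early_bins <- which(tensor$bin_edges[-length(tensor$bin_edges)] < essential_window_h)
    for (e in ess) {
      fe <- match(e, feature_ids)
      seen <- apply(mask[, early_bins, fe, drop = FALSE], 1, max)
      keep_p <- keep_p & seen > 0
    }
  }
  if (!any(keep_p)) stop("all patients removed by the missingness filters")
  dropped_patients <- tensor$patient_ids[!keep_p]
  out <- new_feature_tensor(values[keep_p, , , drop = FALSE],
                            mask[keep_p, , , drop = FALSE],
                            tensor$bin_edges, feature_ids,
                            tensor$patient_ids[keep_p])
  list(tensor = out, dropped_features = dropped_features,
       dropped_patients = dropped_patients)
}

#' Censor outliers by Tukey fences
#'
#' Observed values outside \code{[Q1 - k*IQR, Q3 + k*IQR]} (quartiles from
#' the training split; fences closed, so boundary values are retained)
#' are set back to missing before imputation. Features with zero IQR are
#' left untouched with a warning.
#'
#' @param tensor a \code{feature_tensor}.
#' @param stats a [preprocess_stats()] object.
#' @param k fence multiplier (1.5 = the standard Tukey rule).
#' @return The censored \code{feature_tensor}.
#' @export
censor_outliers_iqr <- function(tensor, stats, k = 1.5) {
  stopifnot(inherits(tensor, "feature_tensor"), inherits(stats, "preprocess_stats"))
  fi <- match(tensor$feature_ids, stats$feature_ids)
  if (any(is.na(fi))) stop("stats are missing some tensor features")
  flat <- sum(stats$q3[fi] - stats$q1[fi] == 0, na.rm = TRUE)
  if (flat > 0) warning(flat, " constant feature(s) skipped (zero IQR)")
  for (j in seq_along(tensor$feature_ids)) {
    q1 <- stats$q1[fi[j]]; q3 <- stats$q3[fi[j]]
    if (!is.finite(q1) || q3 - q1 == 0) next
    lo <- q1 - k * (q3 - q1); hi <- q3 + k * (q3 - q1)
    v <- tensor$values[, , j]
    out <- tensor$mask[, , j] == 1 & !is.na(v) & (v < lo | v > hi)
    v[out] <- NA_real_
    tensor$values[, , j] <- v
    m <- tensor$mask[, , j]; m[out] <- 0
    tensor$mask[, , j] <- m
  }
  tensor
}

na_fill <- function(x) {
  # forward fill then backward fill of a numeric vector
  obs <- which(!is.na(x))
  if (!length(obs)) return(x)
  idx <- cumsum(!is.na(x))
  filled <- x
  filled[idx > 0] <- x[obs][idx[idx > 0]]
  if (obs[1] > 1) filled[seq_len(obs[1] - 1)] <- x[obs[1]]
  filled
}

#' Impute missing cells by forward/backward filling
#'
#' Each patient-feature series is forward filled then backward filled;
#' series with no observation at all are set to the training-cohort mean
#' of the feature at every step. The observation mask is preserved, so
#' downstream code can still distinguish measured from imputed cells.
#'
#' @param tensor a \code{feature_tensor}.
#' @param stats a [preprocess_stats()] object (supplies cohort means).
#' @return The imputed \code{feature_tensor} (no NA values remain).
#' @export
impute_fill <- function(tensor, stats) {
  stopifnot(inherits(tensor, "feature_tensor"), inherits(stats, "preprocess_stats"))
  fi <- match(tensor$feature_ids, stats$feature_ids)
  d <- dim(tensor$values)
  for (j in seq_len(d[3])) {
    v <- tensor$values[, , j]
    has <- rowSums(!is.na(v)) > 0
    if (any(has)) v[has, ] <- t(apply(v[has, , drop = FALSE], 1, na_fill))
    if (any(!has)) v[!has, ] <- stats$mean[fi[j]]
    tensor$values[, , j] <- v
  }
  tensor
}

#' Normalize features with training-split z-scores
#'
#' Standardizes every feature using the training mean and standard
#' deviation; features with zero training sd map to 0.
#'
#' @param tensor a \code{feature_tensor}.
#' @param stats a [preprocess_stats()] object.
#' @return The normalized \code{feature_tensor}.
#' @export
normalize_features <- function(tensor, stats) {
  stopifnot(inherits(tensor, "feature_tensor"), inherits(stats, "preprocess_stats"))
  fi <- match(tensor$feature_ids, stats$feature_ids)
  d <- dim(tensor$values)
  for (j in seq_len(d[3])) {
    s <- stats$sd[fi[j]]; m <- stats$mean[fi[j]]
    tensor$values[, , j] <- if (!is.finite(s) || s == 0) 0 else
      (tensor$values[, , j] - m) / s
  }
  tensor
}

#' Random train/validation/test split
#'
#' Seed-deterministic disjoint and exhaustive partition of the patient
#' ids in the given proportions (default 6:2:2).
#'
#' @param patient_ids character vector of ids.
#' @param ratios positive weights, normalized to sum to 1.
#' @param seed integer seed.
#' @return Named list \code{train}, \code{validation}, \code{test}.
#' @export
split_cohort <- function(patient_ids, ratios = c(0.6, 0.2, 0.2), seed = 1) {
  if (any(ratios <= 0)) stop("ratios must be positive")
  ratios <- ratios / sum(ratios)
  n <- length(patient_ids)
  sizes <- diff(c(0, floor(cumsum(ratios) * n + 1e-9)))
  if (any(sizes == 0)) stop("cohort too small for a non-empty split")
  perm <- with_seed(seed, sample(patient_ids))
  grp <- rep(seq_along(sizes), sizes)
  out <- split(perm, grp)
  names(out) <- c("train", "validation", "test")[seq_along(out)]
  out
}

#' Run the full preprocessing pipeline
#'
#' Convenience wrapper applying the fixed order bin -> filter -> IQR
#' censor -> impute -> normalize, with all statistics taken from the
#' training split of a seed-deterministic 6:2:2 partition.
#'
#' @param events long event table (see [bin_events()]).
#' @param window_h,bin_h binning parameters.
#' @param feature_thresh,patient_thresh,essential_features,essential_window_h
#'   filter parameters (see [filter_missing()]).
#' @param iqr_k Tukey fence multiplier.
#' @param ratios split proportions.
#' @param seed split seed.
#' @return List with the processed \code{tensor}, the \code{stats}, the
#'   \code{splits} and the dropped features/patients.
#' @export
preprocess_pipeline <- function(events, window_h = 48, bin_h = 4,
                                feature_thresh = 0.4, patient_thresh = 0.4,
                                essential_features = NULL, essential_window_h = 24,
                                iqr_k = 1.5, ratios = c(0.6, 0.2, 0.2), seed = 1) {
  tensor <- bin_events(events, window_h, bin_h)
  filt <- filter_missing(tensor, feature_thresh, patient_thresh,
                         essential_features, essential_window_h)
  tensor <- filt$tensor
  splits <- split_cohort(tensor$patient_ids, ratios, seed)
  stats <- preprocess_stats(tensor, splits$train)
  tensor <- censor_outliers_iqr(tensor, stats, iqr_k)
  tensor <- impute_fill(tensor, stats)
  tensor <- normalize_features(tensor, stats)
  list(tensor = tensor, stats = stats, splits = splits,
       dropped_features = filt$dropped_features,
       dropped_patients = filt$dropped_patients)
}

#' Flatten a feature tensor to a patients x (bins * features) matrix
#'
#' @param tensor a \code{feature_tensor} (imputed, so no NAs).
#' @return Numeric matrix with one row per patient; columns ordered
#'   feature-major (\code{feature.bin}).
#' @export
flatten_trajectories <- function(tensor) {
  stopifnot(inherits(tensor, "feature_tensor"))
  d <- dim(tensor$values)
  out <- matrix(tensor$values, nrow = d[1])
  rownames(out) <- tensor$patient_ids
  colnames(out) <- as.vector(outer(seq_len(d[2]), tensor$feature_ids,
                                   function(t, f) paste0(f, ".", t)))
  out
}
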