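# Organ-state coupling analytics: cosine similarity between the fused
# organ-system embeddings of a fitted model, reported as synchronous
# matrices at chosen hours, temporal coupling series for a target system,
# and asynchronous (cross-time) coupling against a fixed reference state.

hours_to_bin <- function(object, hours) {
  bin_h <- 48 / object$T  # bins are regular over the observation window
  # map printed hours to 1-based bins (4 h -> bin 1, 48 h -> bin 12)
  b <- hours / bin_h
  if (any(abs(b - round(b)) > 1e-9)) stop("hours must be multiples of the bin width")
  b <- as.integer(round(b))
  if (any(b < 1 | b > object$T)) stop("time outside the observation window")
  b
}

#' Organ-system state embeddings of one patient at one time
#'
#' Returns the six fused system-node embedding vectors, the model's
#' representation of each organ system's functional state, at the given
#' time bin.
#'
#' @param object a fitted [odtgcnet()] model.
#' @param patient patient id (or integer index).
#' @param t time bin (1-based) or, if \code{hours} is given, ignored.
#' @param hours alternative time specification in hours post-diagnosis.
#' @return Numeric matrix, 6 systems x latent width, rownames the system
#'   names.
#' @export
organ_embeddings <- function(object, patient, t = NULL, hours = NULL) {
  stopifnot(inherits(object, "odtgcnet"))
  if (!is.null(hours)) t <- hours_to_bin(object, hours)
  if (is.null(t) || length(t) != 1) stop("give a single time bin or hour mark")
  if (t < 1 || t > object$T) stop("time bin outside the observation window")
  p <- if (is.character(patient)) match(patient, object$patient_ids) else patient
  if (is.na(p) || p < 1 || p > length(object$patient_ids)) stop("unknown patient")
  E <- object$embeddings[p, t, 2:7, , drop = TRUE]
  E <- matrix(E, 6, dim(object$embeddings)[4])
  rownames(E) <- object$schema$systems
  E
}

#' Coupling strength between two organ-state vectors
#'
#' Cosine similarity \eqn{u \cdot v / (\|u\| \|v\|)}; high values mean
#' similar, synchronous functional states.
#'
#' @param u,v non-zero numeric vectors of equal length.
#' @return Scalar in [-1, 1].
#' @export
coupling_strength <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("coupling is undefined for zero vectors")
  sum(u * v) / (nu * nv)
}

subset_index <- function(object, patients) {
  if (is.null(patients)) return(seq_along(object$patient_ids))
  idx <- if (is.character(patients)) match(patients, object$patient_ids) else patients
  if (any(is.na(idx))) stop("unknown patient id(s)")
  if (!length(idx)) stop("empty patient subset")
  idx
}

# mean pairwise cosine matrix over a patient subset at bins (tr, tc)
mean_cosine_matrix <- function(object, idx, tr, tc) {
  S <- 6L
  acc <- matrix(0, S, S)
  for (p in idx) {
    Er <- matrix(object$embeddings[p, tr, 2:7, ], S)
    Ec <- matrix(object$embeddings[p, tc, 2:7, ], S)
    nr <- sqrt(rowSums(Er^2)); nc_ <- sqrt(rowSums(Ec^2))
    acc <- acc + (Er %*% t(Ec)) / outer(nr, nc_)
  }
  acc / length(idx)
}

#' Synchronous organ-coupling matrix
#'
#' The 6 x 6 matrix of mean patient-level cosine similarities between
#' organ-system embeddings at one time point; diagonal 1, symmetric.
#' Typically computed at 4, 12 and 48 h and compared across phenotypes.
#'
#' @param object a fitted [odtgcnet()] model.
#' @param hours time point in hours.
#' @param patients optional subset of patient ids (e.g. one phenotype);
#'   default all fitted patients.
#' @return An object of class \code{coupling_matrix}.
#' @export
synchronous_matrix <- function(object, hours, patients = NULL) {
  stopifnot(inherits(object, "odtgcnet"))
  t <- hours_to_bin(object, hours)
  idx <- subset_index(object, patients)
  V <- mean_cosine_matrix(object, idx, t, t)
  V <- (V + t(V)) / 2
  diag(V) <- 1
  dimnames(V) <- list(object$schema$systems, object$schema$systems)
  structure(list(systems = object$schema$systems, t_row = hours, t_col = hours,
                 values = V, n = length(idx)),
            class = "coupling_matrix")
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat(sprintf("Organ coupling matrix at (%g h, %g h), averaged over %d patients\n",
              x$t_row, x$t_col, x$n))
  print(round(x$values, 3))
  invisible(x)
}

#' Mean off-diagonal coupling of a coupling matrix
#'
#' @param x a \code{coupling_matrix}.
#' @return Scalar summary of inter-organ synchrony.
#' @export
mean_offdiag <- function(x) {
  stopifnot(inherits(x, "coupling_matrix"))
  mean(x$values[upper.tri(x$values)])
}

#' Temporal coupling of a target organ system
#'
#' For each requested time point, the coupling strength of the target
#' system with each of the other five systems at that same time.
#'
#' @param object a fitted [odtgcnet()] model.
#' @param target_system one of the six system names.
#' @param hours vector of time points in hours.
#' @param patients optional patient subset.
#' @return Matrix, length(hours) x 5, rownames the hours.
#' @export
temporal_coupling <- function(object, target_system, hours, patients = NULL) {
  stopifnot(inherits(object, "odtgcnet"))
  s <- match(target_system, object$schema$systems)
  if (is.na(s)) stop("unknown organ system: ", target_system)
  idx <- subset_index(object, patients)
  out <- t(vapply(hours, function(hh) {
    t <- hours_to_bin(object, hh)
    mean_cosine_matrix(object, idx, t, t)[s, -s]
  }, numeric(5)))
  dimnames(out) <- list(paste0(hours, "h"), object$schema$systems[-s])
  out
}

#' Asynchronous (cross-time) organ coupling
#'
#' Fixes the target organ's state at a reference time (by default the
#' end of the window) and tracks its coupling strength with the other
#' systems at earlier time points.
#'
#' @param object a fitted [odtgcnet()] model.
#' @param target_system one of the six system names.
#' @param earlier_hours earlier time points in hours.
#' @param t_ref_hours reference time in hours (default 48).
#' @param patients optional patient subset.
#' @return Matrix, length(earlier_hours) x 5.
#' @export
asynchronous_coupling <- function(object, target_system, earlier_hours,
                                  t_ref_hours = 48, patients = NULL) {
  stopifnot(inherits(object, "odtgcnet"))
  s <- match(target_system, object$schema$systems)
  if (is.na(s)) stop("unknown organ system: ", target_system)
  tref <- hours_to_bin(object, t_ref_hours)
  if (tref != object$T) warning("reference time is not the final bin")
  if (any(earlier_hours > t_ref_hours)) stop("earlier_hours must not exceed the reference time")
  idx <- subset_index(object, patients)
  out <- t(vapply(earlier_hours, function(hh) {
    t <- hours_to_bin(object, hh)
    mean_cosine_matrix(object, idx, tref, t)[s, -s]
  }, numeric(5)))
  dimnames(out) <- list(paste0(earlier_hours, "h"), object$schema$systems[-s])
  out
}
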