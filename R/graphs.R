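# The fixed 13-node organ interaction graph (one patient node, six organ
# system nodes, six clinical feature nodes; star-of-stars topology) and the
# construction of per-patient temporal attributed graph sequences.

#' Build the 13-node organ interaction graph schema
#'
#' The topology is fixed: a patient node connected to all six organ
#' system nodes, and one clinical-feature node per system connected only
#' to its system — 13 nodes and 12 undirected edges. Node attributes vary
#' over time; the topology does not.
#'
#' @param systems character vector of exactly six organ system names.
#' @param feature_map named list mapping every system to the clinical
#'   feature ids aggregated into its feature node.
#' @return An object of class \code{organ_schema}: node table, edge list,
#'   13 x 13 adjacency matrix (zero diagonal) and the feature map.
#' @examples
#' sys <- c("circulatory", "urinary", "hematologic", "hepatic",
#'          "respiratory", "nervous")
#' sch <- organ_schema(sys, setNames(as.list(paste0(sys, "_f1")), sys))
#' sum(sch$adjacency) / 2  # 12 edges
#' @export
organ_schema <- function(systems, feature_map) {
  if (length(systems) != 6L) stop("exactly six organ systems are required")
  if (!all(systems %in% names(feature_map))) {
    stop("feature_map must name every system")
  }
  if (any(lengths(feature_map[systems]) == 0)) {
    stop("every system needs at least one mapped clinical feature")
  }
  nodes <- data.frame(
    id = seq_len(13L),
    name = c("patient", systems, paste0(systems, "_features")),
    role = c("patient", rep("system", 6), rep("feature", 6)),
    system = c(NA, systems, systems),
    stringsAsFactors = FALSE)
  edges <- rbind(cbind(1L, 2:7),        # patient -- systems
                 cbind(2:7, 8:13))      # system -- its feature node
  A <- matrix(0, 13, 13)
  A[edges] <- 1
  A <- A + t(A)
  structure(list(nodes = nodes, edges = edges, adjacency = A,
                 systems = systems, feature_map = feature_map[systems]),
            class = "organ_schema")
}

#' @export
print.organ_schema <- function(x, ...) {
  cat("Organ interaction graph: 13 nodes (1 patient, 6 systems, 6 feature nodes),",
      sum(x$adjacency) / 2, "edges\n")
  cat("  systems:", paste(x$systems, collapse = ", "), "\n")
  invisible(x)
}

#' Binary diagnosis encoding with a cohort frequency threshold
#'
#' Retains only diagnosis codes occurring more than \code{min_count}
#' times in the cohort (counting rows with \code{present == 1}) and
#' encodes each retained code as 0/1 per patient, grouped by organ
#' system. The vocabulary is shared across patients.
#'
#' @param diagnoses data frame with columns patient_id, system, code,
#'   present.
#' @param patient_ids patient ordering for the output matrices (default:
#'   sorted unique ids in \code{diagnoses}).
#' @param min_count frequency threshold; codes with count
#'   \code{<= min_count} are dropped (the cohort default is 1000).
#' @return List with \code{vectors} (per system, a patients x codes 0/1
#'   matrix; zero columns if no code survives), \code{vocabulary}
#'   (code, system, count) and \code{patient_ids}.
#' @export
encode_diagnoses <- function(diagnoses, patient_ids = NULL, min_count = 1000) {
  if (is.null(patient_ids)) patient_ids <- sort(unique(diagnoses$patient_id))
  pres <- diagnoses[diagnoses$present == 1, , drop = FALSE]
  counts <- table(pres$code)
  keep <- names(counts)[counts > min_count]
  if (!length(keep)) {
    warning("no diagnosis code occurs more than ", min_count,
            " times; all diagnosis vectors have zero length")
  }
  vocab <- unique(diagnoses[diagnoses$code %in% keep, c("code", "system")])
  vocab$count <- as.integer(counts[vocab$code])
  systems <- unique(diagnoses$system)
  vectors <- lapply(systems, function(s) {
    codes <- vocab$code[vocab$system == s]
    m <- matrix(0, length(patient_ids), length(codes),
                dimnames = list(patient_ids, codes))
    if (length(codes)) {
      sub <- pres[pres$code %in% codes, ]
      m[cbind(match(sub$patient_id, patient_ids), match(sub$code, codes))] <- 1
    }
    m
  })
  names(vectors) <- systems
  list(vectors = vectors, vocabulary = vocab, patient_ids = patient_ids)
}

#' Build per-patient temporal attributed graph sequences
#'
#' Assembles the model input: a single shared adjacency matrix plus a
#' time-varying node-feature array. The patient node carries (age,
#' gender, weight) constant over time (age and weight z-scored over the
#' supplied demographics); each system node carries its binary diagnosis
#' vector, constant over time; each feature node carries its system's
#' clinical measurements at the current bin. Heterogeneous attribute
#' widths are zero-padded to a common width and a 3-level node-role
#' one-hot is appended.
#'
#' @param tensor preprocessed \code{feature_tensor} (imputed/normalized).
#' @param demographics data frame with patient_id, age, gender, weight_kg.
#' @param diagnosis_vectors result of [encode_diagnoses()].
#' @param schema an [organ_schema()].
#' @return An object of class \code{graph_sequences}: adjacency \code{A},
#'   array \code{X} (patients x bins x 13 nodes x width), node metadata
#'   and ids.
#' @export
build_graph_sequences <- function(tensor, demographics, diagnosis_vectors, schema) {
  stopifnot(inherits(tensor, "feature_tensor"), inherits(schema, "organ_schema"))
  ids <- tensor$patient_ids
  di <- match(ids, demographics$patient_id)
  if (any(is.na(di))) stop("demographics missing for some patients")
  demo <- demographics[di, ]
  feat_idx <- lapply(schema$systems, function(s) {
    fi <- match(schema$feature_map[[s]], tensor$feature_ids)
    if (any(is.na(fi))) stop("schema maps features absent from the tensor (system ", s, ")")
    fi
  })
  diag_w <- vapply(schema$systems, function(s) {
    v <- diagnosis_vectors$vectors[[s]]
    if (is.null(v)) 0L else ncol(v)
  }, 0L)
  d_raw <- max(3L, max(lengths(feat_idx)), max(diag_w))
  d <- d_raw + 3L

  N <- length(ids); T <- dim(tensor$values)[2]
  X <- array(0, dim = c(N, T, 13L, d))

  zs <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
  pat_feat <- cbind(zs(demo$age), demo$gender, zs(demo$weight_kg))
  for (t in seq_len(T)) X[, t, 1L, 1:3] <- pat_feat
  X[, , 1L, d_raw + 1L] <- 1

  dmatch <- match(ids, diagnosis_vectors$patient_ids)
  for (s in seq_along(schema$systems)) {
    node <- 1L + s
    w <- diag_w[s]
    if (w > 0) {
      v <- diagnosis_vectors$vectors[[schema$systems[s]]][dmatch, , drop = FALSE]
      for (t in seq_len(T)) X[, t, node, seq_len(w)] <- v
    }
    X[, , node, d_raw + 2L] <- 1
    fnode <- 7L + s
    fi <- feat_idx[[s]]
    X[, , fnode, seq_along(fi)] <- tensor$values[, , fi, drop = FALSE]
    X[, , fnode, d_raw + 3L] <- 1
  }
  structure(list(A = schema$adjacency, X = X, schema = schema,
                 patient_ids = ids, T = T, d = d, d_raw = d_raw),
            class = "graph_sequences")
}

#' @export
print.graph_sequences <- function(x, ...) {
  cat(sprintf("Temporal graph sequences: %d patients, %d time steps, 13 nodes, width %d\n",
              length(x$patient_ids), x$T, x$d))
  invisible(x)
}
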