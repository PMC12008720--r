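as_weight_matrix <- function(W) {
  if (inherits(W, "connectivity_matrix")) W <- W$W
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("weight matrix must be square")
  if (max(abs(W - t(W))) > 1e-10) stop("weight matrix must be symmetric")
  if (any(W < 0)) stop("weights must be nonnegative")
  if (any(abs(diag(W)) > 1e-12)) stop("diagonal must be zero")
  diag(W) <- 0
  W
}

#' Weighted global clustering coefficient (Onnela variant)
#'
#' Weights are first scaled by the matrix maximum (\eqn{\hat w = w / \max w});
#' the node coefficient is the geometric-mean triangle intensity
#' \deqn{c_i = \frac{\sum_{j,h} (\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3}}{k_i (k_i - 1)}}
#' with \eqn{k_i} the number of nonzero-weight neighbours, and the global
#' coefficient is the mean of \eqn{c_i} over all nodes, nodes with
#' \eqn{k_i < 2} contributing 0 (the Brain Connectivity Toolbox convention).
#' The max-normalisation makes C invariant to uniform weight scaling. The
#' Barrat weighted variant is available behind `variant = "barrat"`.
#'
#' @param W A `connectivity_matrix` or a symmetric nonnegative matrix with
#'   zero diagonal.
#' @param variant `"onnela"` (default) or `"barrat"`.
#' @return Scalar C in \[0, 1\].
#' @export
clustering_coefficient_global <- function(W, variant = c("onnela", "barrat")) {
  variant <- match.arg(variant)
  W <- as_weight_matrix(W)
  if (all(W == 0)) stop("empty graph: all weights are zero")
  k <- rowSums(W > 0)
  if (variant == "onnela") {
    Wn <- W / max(W)
    W3 <- Wn^(1 / 3)
    tri <- diag(W3 %*% W3 %*% W3)          # 2 x triangle intensity sum
    ci <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  } else {
    A <- (W > 0) + 0
    s <- rowSums(W)
    n <- nrow(W)
    ci <- numeric(n)
    for (i in seq_len(n)) {
      if (k[i] < 2) next
      acc <- 0
      nb <- which(A[i, ] > 0)
      for (j in nb) for (h in nb) {
        if (h != j && A[j, h] > 0) acc <- acc + (W[i, j] + W[i, h]) / 2
      }
      ci[i] <- acc / (s[i] * (k[i] - 1))
    }
  }
  mean(ci)
}

#' Characteristic path length of a weighted connectivity graph
#'
#' Connection weights are mapped to edge lengths \eqn{\ell_{ij} = 1/w_{ij}}
#' (absent for zero weight; a `1 - w` alternative is available), shortest
#' paths are computed per source (Dijkstra, via [igraph::distances()]), and L
#' is the mean over all ordered pairs \eqn{i \ne j} with finite distance.
#' Unreachable pairs are excluded from the mean and counted in the
#' `"n_unreachable"` attribute (they cannot occur on dense wPLI graphs).
#'
#' @inheritParams clustering_coefficient_global
#' @param length_map `"inverse"` (default, \eqn{1/w}) or `"one_minus"`
#'   (\eqn{1 - w}).
#' @return Scalar L (units of 1/weight) with attribute `n_unreachable`
#'   (count of ordered unreachable pairs).
#' @export
characteristic_path_length <- function(W, length_map = c("inverse", "one_minus")) {
  length_map <- match.arg(length_map)
  W <- as_weight_matrix(W)
  if (all(W == 0)) stop("graph has no edges")
  L <- W
  pos <- W > 0
  L[pos] <- if (length_map == "inverse") 1 / W[pos] else 1 - W[pos]
  L[!pos] <- 0
  g <- igraph::graph_from_adjacency_matrix(L, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  D <- igraph::distances(g, algorithm = "dijkstra")
  off <- D[row(D) != col(D)]
  finite <- is.finite(off)
  if (!any(finite)) stop("graph has no connected pairs")
  out <- mean(off[finite])
  attr(out, "n_unreachable") <- sum(!finite)
  out
}

#' Graph metrics of one adjacency matrix
#'
#' Convenience wrapper returning both global measures plus provenance.
#'
#' @param cm A `connectivity_matrix`.
#' @param electrode_set Label for the electrode set used (e.g. `"128"`).
#' @return A one-row `data.frame`: subject_id, condition, band,
#'   electrode_set, C, L, n_unreachable.
#' @export
graph_metrics <- function(cm, electrode_set = NULL) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  if (is.null(electrode_set)) electrode_set <- as.character(nrow(cm$W))
  C <- clustering_coefficient_global(cm)
  L <- characteristic_path_length(cm)
  data.frame(subject_id = cm$subject_id, condition = cm$condition,
             band = paste(cm$band, collapse = "-"),
             electrode_set = as.character(electrode_set),
             C = C, L = as.numeric(L),
             n_unreachable = attr(L, "n_unreachable"),
             stringsAsFactors = FALSE)
}

#' Graph metrics on an electrode subset
#'
#' Restricts the adjacency matrix to the subset rows/columns (sensor-space
#' restriction; the wPLI needs no re-estimation) and recomputes C and L.
#'
#' @param cm A `connectivity_matrix` over the full montage.
#' @param subset An [electrode_subset()].
#' @return One-row `data.frame` as in [graph_metrics()].
#' @export
subset_metrics <- function(cm, subset) {
  stopifnot(inherits(cm, "connectivity_matrix"),
            inherits(subset, "electrode_subset"))
  missing <- setdiff(subset$labels, cm$channel_labels)
  if (length(missing) > 0) {
    stop("subset labels missing from the adjacency matrix: ",
         paste(missing, collapse = ", "))
  }
  idx <- match(subset$labels, cm$channel_labels)
  sub <- new_connectivity_matrix(cm$W[idx, idx], cm$band, subset$labels,
                                 cm$condition, cm$n_epochs, cm$subject_id)
  graph_metrics(sub, electrode_set = subset$name)
}
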