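#' Weighted functional-connectivity graph
#'
#' @param weights Square symmetric numeric matrix with entries in `[0, 1]`
#'   and zero diagonal; entry (i, j) is the connection strength between
#'   ROIs i and j.
#' @param roi_labels Node labels; defaults to the matrix column names.
#' @return An object of class `connectivity_graph`.
#' @examples
#' w <- matrix(c(0, 1, 1, 0), 2, 2)
#' g <- connectivity_graph(w)
#' @export
connectivity_graph <- function(weights, roi_labels = colnames(weights)) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("weights must be square")
  if (max(abs(weights - t(weights))) > 1e-12) stop("weights must be symmetric")
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) stop("diagonal must be exactly zero")
  if (any(weights < 0) || any(weights > 1)) stop("weights must lie in [0, 1]")
  if (is.null(roi_labels)) roi_labels <- sprintf("ROI%03d", seq_len(n))
  dimnames(weights) <- list(roi_labels, roi_labels)
  structure(list(weights = weights, roi_labels = roi_labels),
            class = "connectivity_graph")
}

as_weight_matrix <- function(g) {
  if (inherits(g, "connectivity_graph")) g$weights else connectivity_graph(g)$weights
}

#' Correlation-based connectivity graph from cleaned time series
#'
#' Edges are Pearson correlations between pre-whitened ROI residuals;
#' negative correlations are truncated to zero (keeping inverse-weight path
#' lengths well defined) and the diagonal is zeroed. Optionally only the
#' strongest proportion of edges is retained.
#'
#' @param cleaned Numeric timepoints x ROI matrix (e.g. from
#'   [preprocess_subject()]).
#' @param density Optional proportion in `(0, 1]` of strongest edges to
#'   keep; `NULL` (default) keeps all nonnegative correlations.
#' @return A [connectivity_graph()].
#' @examples
#' g <- correlation_graph(matrix(rnorm(500), 100, 5))
#' @export
correlation_graph <- function(cleaned, density = NULL) {
  x <- as.matrix(cleaned)
  if (nrow(x) < 3L) stop("need at least 3 timepoints")
  v <- apply(x, 2L, var)
  if (any(v <= 0)) {
    labels <- colnames(x)
    if (is.null(labels)) labels <- as.character(which(v <= 0))
    stop("zero-variance ROI column(s): ",
         paste(labels[v <= 0], collapse = ", "))
  }
  w <- cor(x)
  w <- (w + t(w)) / 2
  w[w < 0] <- 0
  w <- pmin(w, 1)
  diag(w) <- 0
  if (!is.null(density)) {
    if (density <= 0 || density > 1) stop("density must lie in (0, 1]")
    up <- upper.tri(w)
    e <- w[up]
    keep <- ceiling(density * length(e))
    thr <- sort(e, decreasing = TRUE)[keep]
    w[w < thr] <- 0
  }
  connectivity_graph(w, colnames(x))
}

# All-pairs shortest path lengths with additive edge lengths 1/weight
# (Brain Connectivity Toolbox convention); Inf for unreachable pairs.
shortest_path_lengths <- function(w) {
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, 0)
  g <- igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::distances(g, algorithm = "dijkstra")
}

#' Global efficiency of a weighted graph
#'
#' The mean over ordered node pairs of the inverse shortest-path length,
#' with path lengths additive in inverse edge weights and unreachable pairs
#' contributing zero. Equals 1 on a complete unit-weight graph and 0 on an
#' edgeless graph.
#'
#' @param g A [connectivity_graph()] or a symmetric weight matrix.
#' @return Scalar in `[0, 1]`.
#' @examples
#' w <- 1 - diag(4)
#' global_efficiency(w)  # complete unit graph: 1
#' @export
global_efficiency <- function(g) {
  w <- as_weight_matrix(g)
  n <- nrow(w)
  if (n < 2L) stop("global efficiency needs at least 2 nodes")
  d <- shortest_path_lengths(w)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency of a weighted graph
#'
#' For each node, the global efficiency of the subgraph induced by the
#' node's direct neighbors (nodes with a positive edge to it), the node
#' itself removed. Nodes with fewer than two neighbors get 0.
#'
#' @param g A [connectivity_graph()] or a symmetric weight matrix.
#' @return List with `le_per_node` (named vector) and `le_mean`.
#' @examples
#' w <- 1 - diag(4)
#' local_efficiency(w)$le_mean  # complete unit graph: 1
#' @export
local_efficiency <- function(g) {
  w <- as_weight_matrix(g)
  n <- nrow(w)
  if (n < 2L) stop("local efficiency needs at least 2 nodes")
  le <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) >= 2L) {
      le[i] <- global_efficiency(w[nb, nb, drop = FALSE])
    }
  }
  names(le) <- rownames(w)
  list(le_per_node = le, le_mean = mean(le))
}

#' Per-subject graph metrics from ROI time series
#'
#' Composition of [preprocess_subject()], [correlation_graph()],
#' [global_efficiency()] and [local_efficiency()]: one row of global
#' efficiency and mean local efficiency per subject.
#'
#' @param ts A `roi_timeseries_set` (from [generate_timeseries()]) or a
#'   single [roi_timeseries()].
#' @param density Optional edge-density threshold passed to
#'   [correlation_graph()].
#' @param keep_nodes If `TRUE`, attach the per-node local efficiencies as
#'   attribute `"le_per_node"` (subjects x ROI matrix).
#' @return Data frame with columns `subject_id`, `ge`, `le_mean`.
#' @examples
#' cohort <- generate_cohort(exposure_config(n_subjects = 2), seed = 1)
#' ts <- generate_timeseries(cohort, n_rois = 12, n_timepoints = 90,
#'                           n_modules = 2, seed = 2)
#' subject_metrics(ts)
#' @export
subject_metrics <- function(ts, density = NULL, keep_nodes = FALSE) {
  if (inherits(ts, "roi_timeseries")) {
    ts <- list(subjects = list(subject = ts))
  }
  subs <- ts$subjects
  ge <- numeric(length(subs))
  lem <- numeric(length(subs))
  nodes <- NULL
  for (i in seq_along(subs)) {
    g <- correlation_graph(preprocess_subject(subs[[i]]), density = density)
    ge[i] <- global_efficiency(g)
    le <- local_efficiency(g)
    lem[i] <- le$le_mean
    if (keep_nodes) {
      if (is.null(nodes)) {
        nodes <- matrix(NA_real_, length(subs), length(le$le_per_node),
                        dimnames = list(names(subs), names(le$le_per_node)))
      }
      nodes[i, ] <- le$le_per_node
    }
  }
  out <- data.frame(subject_id = names(subs), ge = ge, le_mean = lem,
                    stringsAsFactors = FALSE)
  if (keep_nodes) attr(out, "le_per_node") <- nodes
  out
}
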