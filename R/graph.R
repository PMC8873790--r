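# Feature-correlation graph: Pearson matrix over the extracted features,
# absolute-value adjacency, degree matrix, symmetric normalized Laplacian
# and the [-1, 1]-rescaled Laplacian consumed by the Chebyshev filters.

#' Pearson correlation matrix over feature columns
#'
#' Sample correlation across rows of the feature table. Zero-variance
#' features get zero off-diagonal correlations (the node becomes isolated)
#' rather than propagating NaN; the diagonal is exactly 1.
#'
#' @param features n_samples x n_features numeric matrix, or a
#'   `feature_table`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(features) {
  if (inherits(features, "feature_table")) features <- features$features
  stopifnot(is.matrix(features), nrow(features) >= 2)
  sds <- apply(features, 2L, stats::sd)
  P <- suppressWarnings(stats::cor(features))
  if (any(sds < 1e-300)) {
    warning(sum(sds < 1e-300), " zero-variance feature(s); their correlations set to 0")
    P[!is.finite(P)] <- 0
  }
  diag(P) <- 1
  (P + t(P)) / 2
}

#' Adjacency matrix from a Pearson matrix
#'
#' A = |P| - I: a complete weighted graph on the feature nodes whose edge
#' weights are absolute correlations; zero diagonal, entries in [0, 1].
#'
#' @param P correlation matrix with unit diagonal.
#' @return adjacency matrix A.
#' @export
adjacency_from_pearson <- function(P) {
  if (any(abs(diag(P) - 1) > 1e-9)) {
    stop("P must have a unit diagonal")
  }
  A <- abs(P)
  diag(A) <- 0
  A
}

#' Degree matrix, normalized Laplacian and its rescaling
#'
#' D_ii = sum_j A_ij; L = I - D^{-1/2} A D^{-1/2} (isolated nodes get
#' L_ii = 1 and zero off-diagonals); lambda_max from a dense symmetric
#' eigensolve (or the common shortcut lambda_max = 2 in fast mode);
#' L_scaled = 2 L / lambda_max - I, with spectrum in [-1, 1].
#'
#' @param A symmetric nonnegative adjacency with zero diagonal.
#' @param fast_lambda if TRUE, skip the eigensolve and use lambda_max = 2.
#' @return list with `D` (degree vector), `L`, `lambda_max`, `L_scaled`.
#' @export
normalized_laplacian <- function(A, fast_lambda = FALSE) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (any(A < 0)) stop("adjacency entries must be nonnegative")
  if (max(abs(A - t(A))) > 1e-9) stop("adjacency must be symmetric")
  d <- rowSums(A)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- diag(nrow(A)) - outer(inv_sqrt, inv_sqrt) * A
  L <- (L + t(L)) / 2
  lambda_max <- if (fast_lambda) 2 else {
    max(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  }
  L_scaled <- 2 * L / lambda_max - diag(nrow(A))
  list(D = d, L = L, lambda_max = lambda_max, L_scaled = L_scaled)
}

#' Build the full feature graph
#'
#' @param features feature matrix or `feature_table` (rows restricted to
#'   the chosen partition by the caller).
#' @param fast_lambda see [normalized_laplacian()].
#' @return object of class `feature_graph` with `P`, `A`, `D`, `L`,
#'   `lambda_max`, `L_scaled` and `n`.
#' @export
build_feature_graph <- function(features, fast_lambda = FALSE) {
  P <- pearson_matrix(features)
  A <- adjacency_from_pearson(P)
  lap <- normalized_laplacian(A, fast_lambda)
  structure(list(P = P, A = A, D = lap$D, L = lap$L,
                 lambda_max = lap$lambda_max, L_scaled = lap$L_scaled,
                 n = nrow(P)),
            class = "feature_graph")
}

#' @export
print.feature_graph <- function(x, ...) {
  cat(sprintf("feature_graph: %d nodes, mean |P| off-diag %.3f, lambda_max %.4f\n",
              x$n, mean(x$A[upper.tri(x$A)]), x$lambda_max))
  invisible(x)
}

#' Export graph matrices to CSV for inspection
#'
#' Writes P, A and L (the four matrices usually visualized for a trained
#' run, with |P| recoverable as A + I).
#'
#' @param graph a [build_feature_graph()] result.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
export_graph_csv <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(graph$P, file.path(dir, "pearson.csv"), row.names = FALSE)
  utils::write.csv(graph$A, file.path(dir, "adjacency.csv"), row.names = FALSE)
  utils::write.csv(graph$L, file.path(dir, "laplacian.csv"), row.names = FALSE)
  invisible(dir)
}
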