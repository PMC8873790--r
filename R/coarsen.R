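# Multilevel graph coarsening (Graclus-style greedy normalized-cut
# matching), balanced-binary-tree fake-node indexing, and 1-D max pooling.
#
# At each level unmarked nodes are visited in seeded random order and merged
# with the unmarked neighbor maximizing the local normalized-cut weight
# w_ij (1/d_i + 1/d_j); unmatched nodes stay singletons. After n_levels of
# coarsening, fake (zero-degree) nodes pad every cluster chain so the
# level-0 node count is coarsest_size * 2^n_levels and a permutation places
# each parent's two children at adjacent positions — max pooling then
# reduces to taking maxima over consecutive pairs.

# One level of greedy matching. Returns 1-based parent ids (assigned in
# visit order) for every node. Ties broken by lowest node index.
graclus_match <- function(W) {
  n <- nrow(W)
  d <- rowSums(W)
  order <- sample.int(n)
  parent <- rep(NA_integer_, n)
  next_id <- 0L
  for (i in order) {
    if (!is.na(parent[i])) next
    next_id <- next_id + 1L
    parent[i] <- next_id
    nb <- which(W[i, ] > 0 & is.na(parent))
    if (length(nb)) {
      score <- W[i, nb] * (1 / d[i] + 1 / d[nb])
      best <- nb[score == max(score)]
      parent[min(best)] <- next_id
    }
  }
  parent
}

# Collapse a graph given parent assignments; returns the coarse adjacency
# (zero diagonal) and the total weight collapsed inside clusters.
coarsen_one <- function(W, parent) {
  n_c <- max(parent)
  M <- matrix(0, nrow(W), n_c)
  M[cbind(seq_len(nrow(W)), parent)] <- 1
  Wc <- t(M) %*% W %*% M
  collapsed <- sum(diag(Wc)) / 2
  diag(Wc) <- 0
  list(W = Wc, collapsed = collapsed)
}

#' Multilevel Graclus coarsening with fake-node padding
#'
#' @param A symmetric nonnegative adjacency (zero diagonal).
#' @param n_levels number of coarsening levels (each halves the padded node
#'   count).
#' @param seed seed for the random visit order.
#' @return object of class `coarsening_hierarchy`: per-level `graphs`
#'   (level 0 = input), `parents` (1-based cluster assignment per level),
#'   `collapsed` (intra-cluster weight per level), per-level padded index
#'   maps `perms` (entries > level size denote fake nodes), `perm` (the
#'   level-0 map of length coarsest * 2^n_levels), `n_fake`, padded
#'   adjacencies `padded` and their scaled normalized Laplacians
#'   `laplacians`.
#' @export
graclus_coarsen <- function(A, n_levels, seed = 1) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (max(abs(A - t(A))) > 1e-9) stop("adjacency must be symmetric")
  if (any(A < 0)) stop("adjacency weights must be nonnegative")
  if (n_levels < 1) stop("n_levels must be >= 1")
  if (nrow(A) / 2^n_levels < 1) {
    stop("n_levels too large for a graph with ", nrow(A), " nodes")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  graphs <- list(A)
  diag(graphs[[1]]) <- 0
  parents <- list()
  collapsed <- numeric(0)
  for (l in seq_len(n_levels)) {
    p <- graclus_match(graphs[[l]])
    co <- coarsen_one(graphs[[l]], p)
    parents[[l]] <- p
    collapsed[l] <- co$collapsed
    graphs[[l + 1L]] <- co$W
  }

  # top-down balanced-binary-tree index maps; fake indices exceed the
  # level's real node count
  n_coarsest <- nrow(graphs[[n_levels + 1L]])
  perms <- vector("list", n_levels + 1L)
  perms[[n_levels + 1L]] <- seq_len(n_coarsest)
  for (l in n_levels:1) {
    n_real <- nrow(graphs[[l]])
    n_coarse <- max(parents[[l]])
    fake_next <- n_real
    idx <- integer(0)
    for (p in perms[[l + 1L]]) {
      ch <- if (p <= n_coarse) which(parents[[l]] == p) else integer(0)
      if (length(ch) == 0L) {
        ch <- fake_next + 1:2
        fake_next <- fake_next + 2L
      } else if (length(ch) == 1L) {
        ch <- c(ch, fake_next + 1L)
        fake_next <- fake_next + 1L
      } else {
        ch <- sort(ch)
      }
      idx <- c(idx, ch)
    }
    perms[[l]] <- idx
  }

  padded <- vector("list", n_levels + 1L)
  laplacians <- vector("list", n_levels + 1L)
  for (l in seq_len(n_levels + 1L)) {
    idx <- perms[[l]]
    n_real <- nrow(graphs[[l]])
    M <- length(idx)
    Ap <- matrix(0, M, M)
    real <- which(idx <= n_real)
    Ap[real, real] <- graphs[[l]][idx[real], idx[real], drop = FALSE]
    padded[[l]] <- Ap
    laplacians[[l]] <- normalized_laplacian(Ap)$L_scaled
  }

  structure(list(graphs = graphs, parents = parents, collapsed = collapsed,
                 perms = perms, perm = perms[[1L]],
                 n_fake = length(perms[[1L]]) - nrow(graphs[[1L]]),
                 padded = padded, laplacians = laplacians,
                 n_levels = n_levels),
            class = "coarsening_hierarchy")
}

#' @export
print.coarsening_hierarchy <- function(x, ...) {
  sizes <- vapply(x$perms, length, integer(1))
  cat(sprintf("coarsening_hierarchy: %d levels, padded sizes %s, %d fake nodes\n",
              x$n_levels, paste(sizes, collapse = " -> "), x$n_fake))
  invisible(x)
}

#' Pad and permute a node signal for binary-tree pooling
#'
#' Real node values are placed at their permuted positions; fake-node
#' positions are filled with 0 (safe under max pooling against strictly
#' positive softplus activations).
#'
#' @param x signal over the original nodes: vector, or nodes x channels
#'   matrix.
#' @param hierarchy a [graclus_coarsen()] result.
#' @return padded, permuted signal (same kind as `x`).
#' @export
permute_signal <- function(x, hierarchy) {
  perm <- hierarchy$perm
  n_real <- nrow(hierarchy$graphs[[1L]])
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1L) else x
  if (nrow(xm) != n_real) stop("signal length does not match the graph")
  out <- matrix(0, length(perm), ncol(xm))
  real <- which(perm <= n_real)
  out[real, ] <- xm[perm[real], , drop = FALSE]
  if (vec) drop(out) else out
}

#' Invert [permute_signal()]
#'
#' @param x padded, permuted signal.
#' @param hierarchy a [graclus_coarsen()] result.
#' @return signal over the original nodes.
#' @export
unpermute_signal <- function(x, hierarchy) {
  perm <- hierarchy$perm
  n_real <- nrow(hierarchy$graphs[[1L]])
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1L) else x
  out <- matrix(0, n_real, ncol(xm))
  real <- which(perm <= n_real)
  out[perm[real], ] <- xm[real, , drop = FALSE]
  if (vec) drop(out) else out
}

#' 1-D max pooling over consecutive node blocks
#'
#' @param x vector or nodes x channels matrix; the node count must be
#'   divisible by `pool_size`.
#' @param pool_size block length (2 for binary-tree pooling).
#' @return pooled signal with nodes/pool_size rows.
#' @export
graph_maxpool <- function(x, pool_size = 2L) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1L) else x
  n <- nrow(xm)
  if (n %% pool_size != 0L) stop("signal length not divisible by pool_size")
  groups <- rep(seq_len(n %/% pool_size), each = pool_size)
  out <- apply(xm, 2L, function(col) tapply(col, groups, max))
  out <- matrix(out, ncol = ncol(xm))
  if (vec) drop(out) else out
}
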