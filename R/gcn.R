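# Chebyshev spectral graph convolution and the graph-convolutional
# classifier head.
#
# A spectral filter g_theta on graph signal x is U g_theta(Lambda) U' x for
# the Laplacian eigensystem L = U Lambda U'. The K-term Chebyshev
# approximation y = sum_{k=0}^{K-1} T_k(L_scaled) x theta_k (three-term
# recurrence T_k = 2 x T_{k-1} - T_{k-2}) needs matrix products only, is
# K-1-localized on the graph, and is the filter used in every layer.

#' Chebyshev spectral filter on a node signal
#'
#' @param x n_nodes x f_in signal matrix (a vector is treated as one input
#'   channel).
#' @param L_scaled rescaled Laplacian with spectrum in [-1, 1].
#' @param theta K x f_in x f_out coefficient array (or K-vector for scalar
#'   in/out channels).
#' @return n_nodes x f_out filtered signal.
#' @export
chebyshev_filter <- function(x, L_scaled, theta) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  if (is.null(dim(theta))) theta <- array(theta, c(length(theta), 1L, 1L))
  K <- dim(theta)[1]
  stopifnot(K >= 1, dim(theta)[2] == ncol(x), nrow(L_scaled) == nrow(x))
  f_out <- dim(theta)[3]
  y <- matrix(0, nrow(x), f_out)
  Tk_prev <- NULL
  Tk <- x
  for (k in seq_len(K)) {
    if (k == 2L) {
      Tk_new <- L_scaled %*% x
    } else if (k > 2L) {
      Tk_new <- 2 * (L_scaled %*% Tk) - Tk_prev
    } else {
      Tk_new <- Tk
    }
    if (k > 1L) { Tk_prev <- Tk; Tk <- Tk_new }
    y <- y + Tk %*% matrix(theta[k, , ], ncol(x), f_out)
  }
  y
}

#' Brute-force spectral filter via eigendecomposition (test oracle)
#'
#' Diagonalizes the (unscaled) normalized Laplacian, evaluates the
#' Chebyshev polynomial filter on the rescaled eigenvalues and
#' reconstructs — the reference the fast recurrence is checked against.
#'
#' @param x n_nodes x f_in signal.
#' @param L symmetric normalized Laplacian (unscaled).
#' @param theta K x f_in x f_out coefficients.
#' @param lambda_max optional; defaults to the largest eigenvalue of `L`.
#' @return n_nodes x f_out filtered signal.
#' @export
spectral_filter_oracle <- function(x, L, theta, lambda_max = NULL) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  if (is.null(dim(theta))) theta <- array(theta, c(length(theta), 1L, 1L))
  eig <- eigen(L, symmetric = TRUE)
  if (is.null(lambda_max)) lambda_max <- max(eig$values)
  lt <- 2 * eig$values / lambda_max - 1
  K <- dim(theta)[1]
  # T_k on the scaled eigenvalues, by the same scalar recurrence
  Tk <- matrix(0, K, length(lt))
  Tk[1, ] <- 1
  if (K >= 2) Tk[2, ] <- lt
  if (K >= 3) for (k in 3:K) Tk[k, ] <- 2 * lt * Tk[k - 1, ] - Tk[k - 2, ]
  f_in <- ncol(x); f_out <- dim(theta)[3]
  y <- matrix(0, nrow(x), f_out)
  for (i in seq_len(f_in)) {
    xi_hat <- crossprod(eig$vectors, x[, i])
    for (j in seq_len(f_out)) {
      g <- drop(theta[, i, j] %*% Tk)        # filter response per eigenvalue
      y[, j] <- y[, j] + eig$vectors %*% (g * xi_hat)
    }
  }
  y
}

# ---- batched Chebyshev layer ---------------------------------------------

# X: B x M x f_in. Returns Y: B x M x f_out plus the T_k(L) X caches
# (each (M*B) x f_in) needed for the backward pass.
cheb_forward_batch <- function(X, L, theta) {
  B <- dim(X)[1]; M <- dim(X)[2]; f_in <- dim(X)[3]
  K <- dim(theta)[1]; f_out <- dim(theta)[3]
  Xm <- aperm(X, c(2L, 1L, 3L)); dim(Xm) <- c(M, B * f_in)
  Tks <- vector("list", K)
  Tk_prev <- NULL; Tk <- Xm
  Yf <- matrix(0, M * B, f_out)
  for (k in seq_len(K)) {
    if (k == 2L) {
      Tn <- L %*% Xm
      Tk_prev <- Tk; Tk <- Tn
    } else if (k > 2L) {
      Tn <- 2 * (L %*% Tk) - Tk_prev
      Tk_prev <- Tk; Tk <- Tn
    }
    Tf <- Tk; dim(Tf) <- c(M * B, f_in)
    Tks[[k]] <- Tf
    Yf <- Yf + Tf %*% matrix(theta[k, , ], f_in, f_out)
  }
  dim(Yf) <- c(M, B, f_out)
  list(Y = aperm(Yf, c(2L, 1L, 3L)), Tks = Tks)
}

# T_k(L) applied to a single matrix by the recurrence.
apply_cheb_k <- function(L, G, k) {
  if (k == 1L) return(G)
  t_prev <- G
  t_cur <- L %*% G
  if (k == 2L) return(t_cur)
  for (j in 3:k) {
    t_new <- 2 * (L %*% t_cur) - t_prev
    t_prev <- t_cur; t_cur <- t_new
  }
  t_cur
}

# Backward of the batched Chebyshev layer. dY: B x M x f_out.
cheb_backward_batch <- function(dY, L, theta, Tks, B, M, f_in) {
  K <- dim(theta)[1]; f_out <- dim(theta)[3]
  dYm <- aperm(dY, c(2L, 1L, 3L)); dim(dYm) <- c(M * B, f_out)
  dtheta <- array(0, dim(theta))
  dXm <- matrix(0, M, B * f_in)
  for (k in seq_len(K)) {
    dtheta[k, , ] <- crossprod(Tks[[k]], dYm)
    G <- dYm %*% t(matrix(theta[k, , ], f_in, f_out))
    dim(G) <- c(M, B * f_in)
    dXm <- dXm + apply_cheb_k(L, G, k)      # T_k(L) is symmetric
  }
  dim(dXm) <- c(M, B, f_in)
  list(dX = aperm(dXm, c(2L, 1L, 3L)), dtheta = dtheta)
}

#' GCN hyperparameters
#'
#' The published architecture: six Chebyshev convolution layers of 16, 32,
#' 64, 128, 256 and 512 filters, each followed by batch norm, softplus and
#' a size-2 graph max pool; degree-2 Chebyshev polynomials (K = 3 terms);
#' cross-entropy loss with L2 1e-7; Adam with batch 16 at the published
#' 1e-7 learning rate (a practical desk-scale rate is ~1e-3).
#'
#' @param filters_per_layer filters per convolution layer.
#' @param pool_per_layer pooling factor per layer (2 each).
#' @param K number of Chebyshev terms (polynomial degree K - 1).
#' @param l2_coeff,batch_size,learning_rate,epochs,seed training knobs.
#' @return list of class `gcn_config`.
#' @export
gcn_config <- function(filters_per_layer = c(16, 32, 64, 128, 256, 512),
                       pool_per_layer = rep(2L, length(filters_per_layer)),
                       K = 3, l2_coeff = 1e-7, batch_size = 16,
                       learning_rate = 1e-7, epochs = 100, seed = 1) {
  stopifnot(length(filters_per_layer) == length(pool_per_layer), K >= 1)
  structure(list(filters_per_layer = as.integer(filters_per_layer),
                 pool_per_layer = as.integer(pool_per_layer),
                 K = as.integer(K), l2_coeff = l2_coeff,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = epochs,
                 seed = seed, n_classes = 4L),
            class = "gcn_config")
}

#' Initialize the GCN classifier for a coarsening hierarchy
#'
#' @param config a [gcn_config()].
#' @param hierarchy a [graclus_coarsen()] result with at least as many
#'   levels as there are layers.
#' @return model list: `params` (per-layer `theta`, batch-norm
#'   scale/shift, output head), `bn` running statistics, `config`,
#'   `hierarchy`.
#' @export
gcn_init <- function(config, hierarchy) {
  n_layers <- length(config$filters_per_layer)
  if (hierarchy$n_levels < n_layers) {
    stop("hierarchy has ", hierarchy$n_levels, " levels but the model needs ",
         n_layers)
  }
  sizes <- vapply(hierarchy$perms, length, integer(1))
  for (l in seq_len(n_layers)) {
    if (sizes[l] %% config$pool_per_layer[l] != 0L ||
        sizes[l] %/% config$pool_per_layer[l] != sizes[l + 1L]) {
      stop("padded size ", sizes[l], " at layer ", l,
           " incompatible with pool ", config$pool_per_layer[l])
    }
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(config$seed))
  params <- list(layers = list())
  bn <- list()
  f_in <- 1L
  for (l in seq_len(n_layers)) {
    f_out <- config$filters_per_layer[l]
    lim <- sqrt(6 / (config$K * f_in + f_out))
    params$layers[[l]] <- list(
      theta = array(stats::runif(config$K * f_in * f_out, -lim, lim),
                    c(config$K, f_in, f_out)),
      bn_gamma = rep(1, f_out), bn_beta = numeric(f_out))
    bn[[l]] <- list(mean = numeric(f_out), var = rep(1, f_out),
                    momentum = 0.9, eps = 1e-5)
    f_in <- f_out
  }
  flat_size <- sizes[n_layers + 1L] * f_in
  params$W_out <- glorot(flat_size, config$n_classes)
  params$b_out <- numeric(config$n_classes)
  list(params = params, bn = bn, config = config, hierarchy = hierarchy)
}

# Batched forward. X: B x M0 x 1 (already padded/permuted). Returns class
# probabilities, cache, and updated running stats.
gcn_forward_full <- function(params, bn, X, config, hierarchy,
                             mode = "eval") {
  n_layers <- length(config$filters_per_layer)
  B <- dim(X)[1]
  caches <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    L <- hierarchy$laplacians[[l]]
    cf <- cheb_forward_batch(X, L, params$layers[[l]]$theta)
    Z <- cf$Y
    M <- dim(Z)[2]; f <- dim(Z)[3]
    Zf <- Z; dim(Zf) <- c(B * M, f)
    if (mode == "train") {
      mu <- colMeans(Zf)
      v <- colMeans((Zf - rep(mu, each = B * M))^2)
      bn[[l]]$mean <- bn[[l]]$momentum * bn[[l]]$mean + (1 - bn[[l]]$momentum) * mu
      bn[[l]]$var <- bn[[l]]$momentum * bn[[l]]$var + (1 - bn[[l]]$momentum) * v
    } else {
      mu <- bn[[l]]$mean; v <- bn[[l]]$var
    }
    inv_std <- 1 / sqrt(v + bn[[l]]$eps)
    Zhat <- (Zf - rep(mu, each = B * M)) * rep(inv_std, each = B * M)
    BNZ <- Zhat * rep(params$layers[[l]]$bn_gamma, each = B * M) +
           rep(params$layers[[l]]$bn_beta, each = B * M)
    Act <- softplus(BNZ)
    A3 <- Act; dim(A3) <- c(B, M, f)
    # max pool over consecutive sibling pairs (general pool size p)
    p <- config$pool_per_layer[l]
    Mp <- M %/% p
    pooled <- array(-Inf, c(B, Mp, f))
    argmax <- array(1L, c(B, Mp, f))
    for (o in seq_len(p)) {
      cand <- A3[, seq(o, M, by = p), , drop = FALSE]
      upd <- cand > pooled
      pooled[upd] <- cand[upd]
      argmax[upd] <- o
    }
    caches[[l]] <- list(X = X, Tks = cf$Tks, Zhat = Zhat, inv_std = inv_std,
                        BNZ = BNZ, argmax = argmax, M = M, f = f, p = p)
    X <- pooled
  }
  Mf <- dim(X)[2]; ff <- dim(X)[3]
  Flat <- aperm(X, c(2L, 3L, 1L)); dim(Flat) <- c(Mf * ff, B)
  Flat <- t(Flat)
  O <- add_bias(Flat %*% params$W_out, params$b_out)
  P <- softmax_rows(O)
  list(probs = P, bn = bn,
       cache = list(layers = caches, Flat = Flat, O = O, B = B,
                    Mf = Mf, ff = ff))
}

# Cross-entropy loss + full gradients (training mode).
gcn_loss_grads <- function(params, bn, X, y, config, hierarchy) {
  B <- dim(X)[1]
  fwd <- gcn_forward_full(params, bn, X, config, hierarchy, mode = "train")
  P <- fwd$probs
  ch <- fwd$cache
  n_layers <- length(config$filters_per_layer)
  l2 <- config$l2_coeff *
    (sum(vapply(params$layers, function(pl) sum(pl$theta^2), numeric(1))) +
     sum(params$W_out^2))
  data_loss <- -mean(log(pmax(P[cbind(seq_len(B), y + 1L)], 1e-12)))
  loss <- data_loss + l2
  Yoh <- matrix(0, B, config$n_classes)
  Yoh[cbind(seq_len(B), y + 1L)] <- 1
  dO <- (P - Yoh) / B

  g <- param_map(params, function(x) x * 0)
  g$W_out <- crossprod(ch$Flat, dO) + 2 * config$l2_coeff * params$W_out
  g$b_out <- colSums(dO)
  dFlat <- dO %*% t(params$W_out)                  # B x (Mf*ff)
  dX <- t(dFlat); dim(dX) <- c(ch$Mf, ch$ff, B)
  dX <- aperm(dX, c(3L, 1L, 2L))                   # B x Mf x ff
  for (l in rev(seq_len(n_layers))) {
    cc <- ch$layers[[l]]
    M <- cc$M; f <- cc$f; p <- cc$p
    # un-pool: send gradient to the argmax sibling
    dA3 <- array(0, c(B, M, f))
    for (o in seq_len(p)) {
      sel <- cc$argmax == o
      tmp <- array(0, dim(dX))
      tmp[sel] <- dX[sel]
      dA3[, seq(o, M, by = p), ] <- tmp
    }
    dAct <- dA3; dim(dAct) <- c(B * M, f)
    dBNZ <- dAct * sigmoid(cc$BNZ)
    g$layers[[l]]$bn_gamma <- colSums(dBNZ * cc$Zhat)
    g$layers[[l]]$bn_beta <- colSums(dBNZ)
    dZhat <- dBNZ * rep(params$layers[[l]]$bn_gamma, each = B * M)
    N <- B * M
    s1 <- colSums(dZhat); s2 <- colSums(dZhat * cc$Zhat)
    dZf <- (dZhat - rep(s1 / N, each = N) - cc$Zhat * rep(s2 / N, each = N)) *
           rep(cc$inv_std, each = N)
    dZ <- dZf; dim(dZ) <- c(B, M, f)
    cb <- cheb_backward_batch(dZ, hierarchy$laplacians[[l]],
                              params$layers[[l]]$theta, cc$Tks,
                              B, M, dim(params$layers[[l]]$theta)[2])
    g$layers[[l]]$theta <- cb$dtheta +
      2 * config$l2_coeff * params$layers[[l]]$theta
    dX <- cb$dX
  }
  list(loss = loss, data_loss = data_loss, grads = g, probs = P,
       bn = fwd$bn)
}

# Pad/permute a feature matrix (n_samples x n_nodes) into the B x M0 x 1
# input array.
features_to_gcn_input <- function(features, hierarchy) {
  Xp <- apply(features, 1L, function(row) permute_signal(row, hierarchy))
  # Xp: M0 x n; rearrange to n x M0 x 1
  array(t(Xp), c(ncol(Xp), nrow(Xp), 1L))
}

#' GCN forward pass on feature rows
#'
#' @param model a [gcn_init()] or [train_gcn()] result.
#' @param features n x 64 feature matrix (or `feature_table`).
#' @param mode "eval" or "train".
#' @return n x 4 matrix of class probabilities (rows sum to 1).
#' @export
gcn_forward <- function(model, features, mode = "eval") {
  if (inherits(features, "feature_table")) features <- features$features
  if (is.null(dim(features))) features <- matrix(features, 1L)
  X <- features_to_gcn_input(features, model$hierarchy)
  gcn_forward_full(model$params, model$bn, X, model$config,
                   model$hierarchy, mode = mode)$probs
}

#' Train the graph convolutional classifier
#'
#' Cross-entropy plus L2, Adam over shuffled minibatches.
#'
#' @param ft a `feature_table` (from [extract_features()]) or a plain
#'   feature matrix.
#' @param labels class indices 0..3 (taken from `ft` when omitted).
#' @param graph a [build_feature_graph()] result.
#' @param config a [gcn_config()].
#' @param train_idx rows to train on (default all).
#' @param verbose print per-epoch progress.
#' @return trained model (`params`, `bn`, `config`, `hierarchy`, `log`).
#' @export
train_gcn <- function(ft, graph, config, labels = NULL,
                      train_idx = NULL, verbose = FALSE) {
  features <- if (inherits(ft, "feature_table")) ft$features else ft
  if (is.null(labels)) labels <- ft$labels
  if (is.null(train_idx)) train_idx <- seq_len(nrow(features))
  hierarchy <- graclus_coarsen(graph$A,
                               n_levels = length(config$filters_per_layer),
                               seed = stage_seed(config$seed, "coarsen"))
  model <- gcn_init(config, hierarchy)
  opt <- adam_init(model$params)
  n <- length(train_idx)
  Xall <- features_to_gcn_input(features[train_idx, , drop = FALSE],
                                hierarchy)
  yall <- labels[train_idx]
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    accuracy = numeric(0))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(config$seed) + 1L)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      take <- ord[start:min(start + config$batch_size - 1L, n)]
      X <- Xall[take, , , drop = FALSE]
      res <- gcn_loss_grads(model$params, model$bn, X, yall[take],
                            config, hierarchy)
      if (!is.finite(res$loss)) {
        stop("GCN training diverged (non-finite loss) at epoch ", ep)
      }
      model$bn <- res$bn
      if (config$learning_rate > 0) {
        st <- adam_step(model$params, res$grads, opt, config$learning_rate)
        model$params <- st$params
        opt <- st$state
      }
      ep_loss <- ep_loss + res$loss * length(take)
      ep_correct <- ep_correct + sum(max.col(res$probs) - 1L == yall[take])
    }
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / n,
                                 accuracy = ep_correct / n))
    if (verbose) {
      message(sprintf("gcn epoch %3d  loss %.5f  acc %.3f",
                      ep, ep_loss / n, ep_correct / n))
    }
  }
  model$log <- log
  model
}
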