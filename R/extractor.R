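# Attention-based bidirectional LSTM feature extractor.
#
# Forward and backward passes are written directly in dense matrix algebra.
# The per-timestep cell follows the standard gated recurrence:
#   i = sigmoid(x W_xi + h W_hi + b_i)      input gate
#   f = sigmoid(x W_xf + h W_hf + b_f)      forget gate
#   o = sigmoid(x W_xo + h W_ho + b_o)      output gate
#   g = tanh  (x W_xg + h W_hg + b_g)       candidate
#   c = f*c_prev + i*g ;  y = h = o*tanh(c)
# A 64x64 segment is consumed time-major (64 steps of 64-channel vectors);
# forward and time-reversed passes are concatenated per step, pooled by a
# softmax attention over timesteps, then FC -> batch norm -> softplus gives
# the 64 features that feed the graph classifier; a final linear+softmax
# head trains the whole stack against one-hot task targets.

#' Extractor hyperparameters
#'
#' Defaults are the published operating point of the method: 256 LSTM cells,
#' attention size 8, 64 FC features, 25% dropout, L2 1e-7, Adam at 1e-4,
#' batch 1024. `loss` selects mean squared Euclidean distance between the
#' softmax output and the one-hot target (default) or cross-entropy.
#'
#' @param input_size channels per timestep.
#' @param max_time timesteps per segment.
#' @param cell_size LSTM cell width (per direction).
#' @param attention_size width of the attention projection.
#' @param fc_size number of extracted features.
#' @param dropout_rate dropout on the attention context vector in training.
#' @param l2_coeff L2 penalty on all weight matrices.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param loss "mse" or "ce".
#' @param seed initialization/shuffling seed.
#' @return list of class `extractor_config`.
#' @export
extractor_config <- function(input_size = 64, max_time = 64, cell_size = 256,
                             attention_size = 8, fc_size = 64,
                             dropout_rate = 0.25, l2_coeff = 1e-7,
                             learning_rate = 1e-4, batch_size = 1024,
                             epochs = 300, loss = c("mse", "ce"), seed = 1) {
  loss <- match.arg(loss)
  cfg <- list(input_size = input_size, max_time = max_time,
              cell_size = cell_size, attention_size = attention_size,
              fc_size = fc_size, dropout_rate = dropout_rate,
              l2_coeff = l2_coeff, learning_rate = learning_rate,
              batch_size = batch_size, epochs = epochs, loss = loss,
              seed = seed, n_classes = 4L)
  stopifnot(all(unlist(cfg[c("input_size", "max_time", "cell_size",
                             "attention_size", "fc_size", "batch_size")]) > 0),
            dropout_rate >= 0, dropout_rate < 1)
  structure(cfg, class = "extractor_config")
}

#' Initialize one LSTM cell's parameters
#'
#' Glorot-uniform weights; forget-gate bias 1, other biases 0.
#'
#' @param input_size,cell_size dimensions.
#' @return named list of the 8 weight matrices and 4 bias vectors.
#' @export
lstm_params <- function(input_size, cell_size) {
  g <- function() glorot(input_size, cell_size)
  h <- function() glorot(cell_size, cell_size)
  list(W_xi = g(), W_xf = g(), W_xo = g(), W_xg = g(),
       W_hi = h(), W_hf = h(), W_ho = h(), W_hg = h(),
       b_i = numeric(cell_size), b_f = rep(1, cell_size),
       b_o = numeric(cell_size), b_g = numeric(cell_size))
}

add_bias <- function(M, b) M + rep(b, each = nrow(M))

#' One LSTM cell step
#'
#' @param x_t input at time t: a vector (one sample) or a batch x input
#'   matrix.
#' @param prev list with long-term state `c` and short-term state `h`
#'   (vectors, or batch x cell matrices).
#' @param p an [lstm_params()] list.
#' @return list with the new state (`c`, `h`) and the output `y` (= `h`).
#' @export
lstm_step <- function(x_t, prev, p) {
  vec <- is.null(dim(x_t))
  x <- if (vec) matrix(x_t, 1L) else x_t
  stopifnot_finite(x, "lstm input")
  H <- ncol(p$W_hi)
  cp <- if (is.null(dim(prev$c))) matrix(prev$c, nrow(x), H, byrow = TRUE) else prev$c
  hp <- if (is.null(dim(prev$h))) matrix(prev$h, nrow(x), H, byrow = TRUE) else prev$h
  i <- sigmoid(add_bias(x %*% p$W_xi + hp %*% p$W_hi, p$b_i))
  f <- sigmoid(add_bias(x %*% p$W_xf + hp %*% p$W_hf, p$b_f))
  o <- sigmoid(add_bias(x %*% p$W_xo + hp %*% p$W_ho, p$b_o))
  g <- tanh(add_bias(x %*% p$W_xg + hp %*% p$W_hg, p$b_g))
  c_new <- f * cp + i * g
  h_new <- o * tanh(c_new)
  if (vec) {
    list(c = drop(c_new), h = drop(h_new), y = drop(h_new))
  } else {
    list(c = c_new, h = h_new, y = h_new)
  }
}

# Unrolled forward pass of one direction over X (T x B x C); returns per-step
# output matrices and the caches needed for backpropagation through time.
# The four gate projections are fused into single matrix products, all input
# projections are computed in one BLAS call up front, and per-timestep values
# are kept as lists of contiguous B x H matrices (strided slicing of
# time-major arrays dominates runtime otherwise).
lstm_forward_dir <- function(X, p) {
  Tn <- dim(X)[1]; B <- dim(X)[2]; C <- dim(X)[3]; H <- ncol(p$W_hi)
  Wx <- cbind(p$W_xi, p$W_xf, p$W_xo, p$W_xg)        # C x 4H
  Wh <- cbind(p$W_hi, p$W_hf, p$W_ho, p$W_hg)        # H x 4H
  b <- c(p$b_i, p$b_f, p$b_o, p$b_g)
  Xb <- aperm(X, c(2L, 1L, 3L)); dim(Xb) <- c(B * Tn, C)  # rows: b fastest
  XW <- add_bias(Xb %*% Wx, b)                       # (B*T) x 4H
  i_ix <- seq_len(H); f_ix <- H + i_ix; o_ix <- 2L * H + i_ix
  g_ix <- 3L * H + i_ix
  lst <- function() vector("list", Tn)
  I <- lst(); F_ <- lst(); O <- lst(); G <- lst()
  C_ <- lst(); TC <- lst(); Hs <- lst()
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  for (t in seq_len(Tn)) {
    pre <- XW[((t - 1L) * B + 1L):(t * B), , drop = FALSE] + h %*% Wh
    i <- sigmoid(pre[, i_ix, drop = FALSE])
    f <- sigmoid(pre[, f_ix, drop = FALSE])
    o <- sigmoid(pre[, o_ix, drop = FALSE])
    g <- tanh(pre[, g_ix, drop = FALSE])
    cc <- f * cc + i * g
    tc <- tanh(cc)
    h <- o * tc
    I[[t]] <- i; F_[[t]] <- f; O[[t]] <- o; G[[t]] <- g
    C_[[t]] <- cc; TC[[t]] <- tc; Hs[[t]] <- h
  }
  list(H = Hs, cache = list(I = I, F = F_, O = O, G = G, C = C_, TC = TC,
                            Xb = Xb, B = B, Tn = Tn))
}

# BPTT for one direction. dH: list over t of B x H gradients on the
# per-step outputs.
lstm_backward_dir <- function(dH, fwd, p) {
  cc <- fwd$cache
  Tn <- cc$Tn; B <- cc$B; H <- ncol(p$W_hi)
  Wh <- cbind(p$W_hi, p$W_hf, p$W_ho, p$W_hg)
  WhT <- t(Wh)
  i_ix <- seq_len(H); f_ix <- H + i_ix; o_ix <- 2L * H + i_ix
  g_ix <- 3L * H + i_ix
  dPf <- matrix(0, B * Tn, 4L * H)
  dWh <- matrix(0, H, 4L * H)
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  zero <- matrix(0, B, H)
  for (t in rev(seq_len(Tn))) {
    i <- cc$I[[t]]; f <- cc$F[[t]]; o <- cc$O[[t]]; g <- cc$G[[t]]
    tc <- cc$TC[[t]]
    c_prev <- if (t > 1) cc$C[[t - 1L]] else zero
    dh <- dH[[t]] + dh_next
    do <- dh * tc
    dc <- dh * o * (1 - tc^2) + dc_next
    dc_next <- dc * f
    dpre <- cbind(dc * g * i * (1 - i),        # input gate
                  dc * c_prev * f * (1 - f),   # forget gate
                  do * o * (1 - o),            # output gate
                  dc * i * (1 - g^2))          # candidate
    dPf[((t - 1L) * B + 1L):(t * B), ] <- dpre
    if (t > 1) dWh <- dWh + crossprod(fwd$H[[t - 1L]], dpre)
    dh_next <- dpre %*% WhT
  }
  dWx <- crossprod(cc$Xb, dPf)
  db <- colSums(dPf)
  list(W_xi = dWx[, i_ix, drop = FALSE], W_xf = dWx[, f_ix, drop = FALSE],
       W_xo = dWx[, o_ix, drop = FALSE], W_xg = dWx[, g_ix, drop = FALSE],
       W_hi = dWh[, i_ix, drop = FALSE], W_hf = dWh[, f_ix, drop = FALSE],
       W_ho = dWh[, o_ix, drop = FALSE], W_hg = dWh[, g_ix, drop = FALSE],
       b_i = db[i_ix], b_f = db[f_ix], b_o = db[o_ix], b_g = db[g_ix])
}

#' Bidirectional LSTM forward pass over one segment
#'
#' The forward cell consumes timesteps left to right; the backward cell
#' consumes the time-reversed sequence and its outputs are re-reversed; per
#' timestep the two outputs are concatenated.
#'
#' @param x time-major matrix (max_time x input_size).
#' @param p_fwd,p_bwd [lstm_params()] for the two directions (same cell
#'   size).
#' @return max_time x (2 * cell_size) output matrix.
#' @export
bilstm_forward <- function(x, p_fwd, p_bwd) {
  stopifnot(is.matrix(x), ncol(p_fwd$W_hi) == ncol(p_bwd$W_hi))
  Tn <- nrow(x)
  X <- array(x, c(Tn, 1L, ncol(x)))
  fw <- lstm_forward_dir(X, p_fwd)
  Xr <- X[rev(seq_len(Tn)), , , drop = FALSE]
  bw <- lstm_forward_dir(Xr, p_bwd)
  H <- ncol(p_fwd$W_hi)
  out <- matrix(0, Tn, 2L * H)
  for (t in seq_len(Tn)) {
    out[t, ] <- c(fw$H[[t]], bw$H[[Tn - t + 1L]])
  }
  out
}

#' Initialize attention parameters
#' @param in_size input width (2 * cell_size).
#' @param attention_size projection width.
#' @return list with `W_w`, `b_w`, `u_w`.
#' @export
attention_params <- function(in_size, attention_size) {
  list(W_w = glorot(in_size, attention_size),
       b_w = numeric(attention_size),
       u_w = stats::runif(attention_size, -0.1, 0.1))
}

#' Attention pooling over timestep outputs
#'
#' u_t = tanh(W_w y_t + b_w); alpha = softmax over t of u_t' u_w;
#' s = sum_t alpha_t y_t.
#'
#' @param y max_time x width matrix of per-timestep outputs.
#' @param a an [attention_params()] list.
#' @return list with the context vector `s` (width) and weights `alpha`
#'   (max_time, summing to 1).
#' @export
attention_pool <- function(y, a) {
  stopifnot(is.matrix(y), nrow(y) >= 1)
  U <- tanh(add_bias(y %*% a$W_w, a$b_w))        # T x att
  e <- drop(U %*% a$u_w)                          # T
  e <- e - max(e)
  alpha <- exp(e) / sum(exp(e))
  list(s = drop(crossprod(y, alpha)), alpha = alpha)
}

# Batched attention over Y (list over t of B x W matrices). Returns
# S (B x W), alpha (B x T) and the cache for backprop.
attention_forward_batch <- function(Y, a) {
  Tn <- length(Y); B <- nrow(Y[[1]]); W <- ncol(Y[[1]])
  U <- vector("list", Tn)
  E <- matrix(0, B, Tn)
  for (t in seq_len(Tn)) {
    u <- tanh(add_bias(Y[[t]] %*% a$W_w, a$b_w))
    U[[t]] <- u
    E[, t] <- u %*% a$u_w
  }
  alpha <- softmax_rows(E)
  S <- matrix(0, B, W)
  for (t in seq_len(Tn)) S <- S + alpha[, t] * Y[[t]]
  list(S = S, alpha = alpha, U = U)
}

attention_backward_batch <- function(dS, Y, fwd, a) {
  Tn <- length(Y); B <- nrow(Y[[1]]); W <- ncol(Y[[1]])
  alpha <- fwd$alpha
  dalpha <- matrix(0, B, Tn)
  for (t in seq_len(Tn)) dalpha[, t] <- rowSums(dS * Y[[t]])
  dE <- alpha * (dalpha - rowSums(dalpha * alpha))   # softmax backward
  ga <- list(W_w = a$W_w * 0, b_w = a$b_w * 0, u_w = a$u_w * 0)
  WwT <- t(a$W_w)
  dY <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    u <- fwd$U[[t]]
    ga$u_w <- ga$u_w + drop(crossprod(u, dE[, t]))
    dpre <- outer(dE[, t], a$u_w) * (1 - u^2)
    ga$W_w <- ga$W_w + crossprod(Y[[t]], dpre)
    ga$b_w <- ga$b_w + colSums(dpre)
    dY[[t]] <- alpha[, t] * dS + dpre %*% WwT
  }
  list(dY = dY, grads = ga)
}

#' Initialize the full extractor model
#'
#' @param config an [extractor_config()].
#' @return list with trainable `params` (two LSTM cells, attention, FC,
#'   batch-norm scale/shift, output head), batch-norm running statistics
#'   `bn`, and the config.
#' @export
extractor_init <- function(config) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(config$seed))
  H2 <- 2L * config$cell_size
  params <- list(
    fwd = lstm_params(config$input_size, config$cell_size),
    bwd = lstm_params(config$input_size, config$cell_size),
    att = attention_params(H2, config$attention_size),
    W_fc = glorot(H2, config$fc_size), b_fc = numeric(config$fc_size),
    bn_gamma = rep(1, config$fc_size), bn_beta = numeric(config$fc_size),
    W_out = glorot(config$fc_size, config$n_classes),
    b_out = numeric(config$n_classes))
  list(params = params,
       bn = list(mean = numeric(config$fc_size),
                 var = rep(1, config$fc_size), momentum = 0.9, eps = 1e-5),
       config = config)
}

# Full forward pass. X: T x B x C. mode "train" uses batch statistics for
# BN and applies dropout (unless a fixed mask is supplied); "eval" uses
# running statistics and no dropout. Returns probabilities, post-softplus
# FC features, updated running stats and the cache for backprop.
extractor_forward_full <- function(params, bn, X, config, mode = "eval",
                                   dropout_mask = NULL) {
  Tn <- dim(X)[1]; B <- dim(X)[2]
  fw <- lstm_forward_dir(X, params$fwd)
  Xr <- X[rev(seq_len(Tn)), , , drop = FALSE]
  bwp <- lstm_forward_dir(Xr, params$bwd)
  Y <- lapply(seq_len(Tn), function(t) cbind(fw$H[[t]],
                                             bwp$H[[Tn - t + 1L]]))
  attf <- attention_forward_batch(Y, params$att)
  S <- attf$S
  if (mode == "train" && is.null(dropout_mask) && config$dropout_rate > 0) {
    keep <- 1 - config$dropout_rate
    dropout_mask <- matrix(stats::rbinom(length(S), 1L, keep) / keep,
                           nrow(S), ncol(S))
  }
  Sd <- if (!is.null(dropout_mask)) S * dropout_mask else S
  Z <- add_bias(Sd %*% params$W_fc, params$b_fc)
  if (mode == "train") {
    mu <- colMeans(Z)
    v <- colMeans((Z - rep(mu, each = B))^2)
    bn$mean <- bn$momentum * bn$mean + (1 - bn$momentum) * mu
    bn$var <- bn$momentum * bn$var + (1 - bn$momentum) * v
  } else {
    mu <- bn$mean; v <- bn$var
  }
  inv_std <- 1 / sqrt(v + bn$eps)
  Zhat <- (Z - rep(mu, each = B)) * rep(inv_std, each = B)
  BNZ <- add_bias(Zhat * rep(params$bn_gamma, each = B), params$bn_beta)
  F_ <- softplus(BNZ)
  O <- add_bias(F_ %*% params$W_out, params$b_out)
  P <- softmax_rows(O)
  list(probs = P, features = F_, bn = bn,
       cache = list(fw = fw, bw = bwp, Y = Y, att = attf, S = S,
                    mask = dropout_mask, Sd = Sd, Z = Z, Zhat = Zhat,
                    inv_std = inv_std, BNZ = BNZ, F = F_, O = O, Tn = Tn,
                    B = B))
}

# Loss + full gradient. Training-mode forward (batch-norm batch statistics)
# so the computation is differentiable end to end; dropout uses the supplied
# mask (or none).
extractor_loss_grads <- function(params, bn, X, y, config,
                                 dropout_mask = NULL) {
  B <- dim(X)[2]
  Yoh <- matrix(0, B, config$n_classes)
  Yoh[cbind(seq_len(B), y + 1L)] <- 1
  fwd <- extractor_forward_full(params, bn, X, config, mode = "train",
                                dropout_mask = dropout_mask)
  ch <- fwd$cache
  P <- fwd$probs
  w_l2 <- list(params$fwd[c("W_xi","W_xf","W_xo","W_xg",
                            "W_hi","W_hf","W_ho","W_hg")],
               params$bwd[c("W_xi","W_xf","W_xo","W_xg",
                            "W_hi","W_hf","W_ho","W_hg")],
               params$att["W_w"], params["W_fc"], params["W_out"])
  l2 <- config$l2_coeff * sum(vapply(w_l2, params_l2, numeric(1)))
  if (config$loss == "mse") {
    data_loss <- mean(rowSums((P - Yoh)^2))
    dP <- 2 * (P - Yoh) / B
    dO <- P * (dP - rowSums(dP * P))
  } else {
    data_loss <- -mean(log(pmax(P[cbind(seq_len(B), y + 1L)], 1e-12)))
    dO <- (P - Yoh) / B
  }
  loss <- data_loss + l2

  g <- param_map(params, function(x) x * 0)
  g$W_out <- crossprod(ch$F, dO)
  g$b_out <- colSums(dO)
  dF <- dO %*% t(params$W_out)
  dBNZ <- dF * sigmoid(ch$BNZ)
  g$bn_gamma <- colSums(dBNZ * ch$Zhat)
  g$bn_beta <- colSums(dBNZ)
  dZhat <- dBNZ * rep(params$bn_gamma, each = B)
  # batch-norm backward (batch statistics)
  s1 <- colSums(dZhat); s2 <- colSums(dZhat * ch$Zhat)
  dZ <- (dZhat - rep(s1 / B, each = B) - ch$Zhat * rep(s2 / B, each = B)) *
        rep(ch$inv_std, each = B)
  g$W_fc <- crossprod(ch$Sd, dZ)
  g$b_fc <- colSums(dZ)
  dSd <- dZ %*% t(params$W_fc)
  dS <- if (!is.null(ch$mask)) dSd * ch$mask else dSd
  attb <- attention_backward_batch(dS, ch$Y, ch$att, params$att)
  g$att <- attb$grads
  H <- config$cell_size
  Tn <- ch$Tn
  dH_f <- lapply(attb$dY, function(m) m[, seq_len(H), drop = FALSE])
  dH_b <- lapply(rev(seq_len(Tn)),
                 function(t) attb$dY[[t]][, H + seq_len(H), drop = FALSE])
  g$fwd <- lstm_backward_dir(dH_f, ch$fw, params$fwd)
  g$bwd <- lstm_backward_dir(dH_b, ch$bw, params$bwd)
  # L2 gradient on weight matrices
  for (nm in c("W_xi","W_xf","W_xo","W_xg","W_hi","W_hf","W_ho","W_hg")) {
    g$fwd[[nm]] <- g$fwd[[nm]] + 2 * config$l2_coeff * params$fwd[[nm]]
    g$bwd[[nm]] <- g$bwd[[nm]] + 2 * config$l2_coeff * params$bwd[[nm]]
  }
  g$att$W_w <- g$att$W_w + 2 * config$l2_coeff * params$att$W_w
  g$W_fc <- g$W_fc + 2 * config$l2_coeff * params$W_fc
  g$W_out <- g$W_out + 2 * config$l2_coeff * params$W_out
  list(loss = loss, data_loss = data_loss, grads = g, probs = P,
       bn = fwd$bn)
}

#' Forward pass of the extractor on segments
#'
#' @param model an initialized or trained extractor (from
#'   [extractor_init()] / [train_extractor()]).
#' @param ds a [segment_dataset()].
#' @param idx segment indices to evaluate (default all).
#' @param mode "eval" (running batch-norm statistics, no dropout) or
#'   "train".
#' @return list with `probs` (n x 4, rows sum to 1) and `features`
#'   (n x fc_size, strictly positive softplus activations).
#' @export
extractor_forward <- function(model, ds, idx = seq_along(ds$segments),
                              mode = "eval") {
  X <- segments_to_array(ds, idx)
  out <- extractor_forward_full(model$params, model$bn, X, model$config,
                                mode = mode)
  list(probs = out$probs, features = out$features)
}

#' Train the feature extractor
#'
#' Minimizes the configured loss (mean squared Euclidean distance between
#' the softmax output and the one-hot target by default, plus the L2
#' penalty) with Adam over shuffled minibatches.
#'
#' @param ds a [segment_dataset()].
#' @param config an [extractor_config()].
#' @param train_idx segment indices to train on (default all).
#' @param verbose print per-epoch loss/accuracy.
#' @return trained model list (`params`, `bn`, `config`, `log` with
#'   per-epoch loss and training accuracy).
#' @export
train_extractor <- function(ds, config, train_idx = seq_along(ds$segments),
                            verbose = FALSE) {
  model <- extractor_init(config)
  labels <- label_index(ds$meta$label[train_idx])
  n <- length(train_idx)
  if (n < 1) stop("need at least one training segment")
  opt <- adam_init(model$params)
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
      X <- segments_to_array(ds, train_idx[take])
      res <- extractor_loss_grads(model$params, model$bn, X, labels[take],
                                  config)
      if (!is.finite(res$loss)) {
        stop("extractor training diverged (non-finite loss) at epoch ", ep)
      }
      model$bn <- res$bn
      if (config$learning_rate > 0) {
        st <- adam_step(model$params, res$grads, opt, config$learning_rate)
        model$params <- st$params
        opt <- st$state
      }
      ep_loss <- ep_loss + res$loss * length(take)
      ep_correct <- ep_correct +
        sum(max.col(res$probs) - 1L == labels[take])
    }
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / n,
                                 accuracy = ep_correct / n))
    if (verbose) {
      message(sprintf("extractor epoch %3d  loss %.5f  acc %.3f",
                      ep, ep_loss / n, ep_correct / n))
    }
  }
  model$log <- log
  model
}

#' Extract FC-layer features for every segment
#'
#' Deterministic evaluation pass (no dropout, running batch-norm
#' statistics); row order and labels follow the dataset.
#'
#' @param ds a [segment_dataset()].
#' @param model a trained extractor.
#' @param batch_size evaluation batch size (memory control only).
#' @return object of class `feature_table`: `features` (n x fc_size),
#'   `labels` (0..3), and the dataset's `meta`/`splits`.
#' @export
extract_features <- function(ds, model, batch_size = 512) {
  n <- length(ds$segments)
  feats <- matrix(0, n, model$config$fc_size)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    feats[idx, ] <- extractor_forward(model, ds, idx)$features
  }
  structure(list(features = feats, labels = label_index(ds$meta$label),
                 meta = ds$meta, splits = ds$splits),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features, %d classes\n",
              nrow(x$features), ncol(x$features),
              length(unique(x$labels))))
  invisible(x)
}
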