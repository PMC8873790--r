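# Independent straight-line oracles for the recurrent cell, attention,
# correlation and metric formulas. These are deliberately naive (scalar
# loops, explicit sums) and share no code with the package internals.

oracle_sigmoid <- function(z) 1 / (1 + exp(-z))

# One LSTM cell step, scalar loops over units.
oracle_lstm_step <- function(x, c_prev, h_prev, p) {
  H <- length(p$b_i)
  i <- f <- o <- g <- c_new <- h_new <- numeric(H)
  for (j in seq_len(H)) {
    zi <- sum(x * p$W_xi[, j]) + sum(h_prev * p$W_hi[, j]) + p$b_i[j]
    zf <- sum(x * p$W_xf[, j]) + sum(h_prev * p$W_hf[, j]) + p$b_f[j]
    zo <- sum(x * p$W_xo[, j]) + sum(h_prev * p$W_ho[, j]) + p$b_o[j]
    zg <- sum(x * p$W_xg[, j]) + sum(h_prev * p$W_hg[, j]) + p$b_g[j]
    i[j] <- oracle_sigmoid(zi); f[j] <- oracle_sigmoid(zf)
    o[j] <- oracle_sigmoid(zo); g[j] <- tanh(zg)
    c_new[j] <- f[j] * c_prev[j] + i[j] * g[j]
    h_new[j] <- o[j] * tanh(c_new[j])
  }
  list(c = c_new, h = h_new)
}

# Materialized bidirectional unrolling: forward pass left to right, backward
# pass on the reversed sequence re-reversed, concatenated per step.
oracle_bilstm <- function(x, p_fwd, p_bwd) {
  Tn <- nrow(x); H <- length(p_fwd$b_i)
  hf <- matrix(0, Tn, H)
  st <- list(c = numeric(H), h = numeric(H))
  for (t in seq_len(Tn)) {
    st <- oracle_lstm_step(x[t, ], st$c, st$h, p_fwd)
    hf[t, ] <- st$h
  }
  hb_rev <- matrix(0, Tn, H)
  st <- list(c = numeric(H), h = numeric(H))
  for (t in seq_len(Tn)) {
    st <- oracle_lstm_step(x[Tn - t + 1, ], st$c, st$h, p_bwd)
    hb_rev[t, ] <- st$h
  }
  cbind(hf, hb_rev[Tn:1, , drop = FALSE])
}

# Attention pooling with explicit log-sum-exp stabilization.
oracle_attention <- function(y, a) {
  Tn <- nrow(y)
  e <- numeric(Tn)
  for (t in seq_len(Tn)) {
    u <- tanh(drop(y[t, ] %*% a$W_w) + a$b_w)
    e[t] <- sum(u * a$u_w)
  }
  m <- max(e)
  alpha <- exp(e - m) / sum(exp(e - m))
  s <- numeric(ncol(y))
  for (t in seq_len(Tn)) s <- s + alpha[t] * y[t, ]
  list(s = s, alpha = alpha, scores = e)
}

# Two-pass Pearson correlation.
oracle_pearson <- function(X) {
  n <- ncol(X)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      xi <- X[, i] - mean(X[, i]); xj <- X[, j] - mean(X[, j])
      P[i, j] <- mean(xi * xj) /
        (sqrt(mean(xi^2)) * sqrt(mean(xj^2)))
    }
  }
  P
}

oracle_kappa <- function(cm) {
  n <- sum(cm)
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  (p_o - p_e) / (1 - p_e)
}

oracle_prf1 <- function(cm) {
  k <- nrow(cm)
  prec <- rec <- f1 <- numeric(k)
  for (c in seq_len(k)) {
    tp <- cm[c, c]; fp <- sum(cm[, c]) - tp; fn <- sum(cm[c, ]) - tp
    prec[c] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[c] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[c] <- if (prec[c] + rec[c] > 0) 2 * prec[c] * rec[c] / (prec[c] + rec[c]) else 0
  }
  list(precision = mean(prec), recall = mean(rec), f1 = mean(f1))
}

# Exhaustive threshold-sweep micro AUC on the flattened one-vs-rest problem.
oracle_micro_auc <- function(y_true, probs) {
  k <- ncol(probs)
  truth <- c(sapply(seq_len(k) - 1L, function(c) as.numeric(y_true == c)))
  score <- c(probs)
  thr <- sort(unique(score), decreasing = TRUE)
  pts <- data.frame(fpr = 0, tpr = 0)
  for (th in thr) {
    pred <- score >= th
    tpr <- sum(pred & truth == 1) / sum(truth == 1)
    fpr <- sum(pred & truth == 0) / sum(truth == 0)
    pts <- rbind(pts, data.frame(fpr = fpr, tpr = tpr))
  }
  auc <- 0
  for (i in 2:nrow(pts)) {
    auc <- auc + (pts$fpr[i] - pts$fpr[i - 1]) *
      (pts$tpr[i] + pts$tpr[i - 1]) / 2
  }
  auc
}

# Central finite-difference gradient of `lossfun` at selected coordinates.
numeric_gradient <- function(lossfun, pflat, idx, h = 1e-5) {
  vapply(idx, function(i) {
    pp <- pflat; pp[i] <- pp[i] + h
    pm <- pflat; pm[i] <- pm[i] - h
    (lossfun(pp) - lossfun(pm)) / (2 * h)
  }, numeric(1))
}

relative_error <- function(a, b) {
  abs(a - b) / pmax(abs(a) + abs(b), 1e-8)
}

# Small shared fixtures -----------------------------------------------------

tiny_synth_spec <- function(...) {
  args <- utils::modifyList(list(n_channels = 8, n_trials_per_class = 4,
                                 snr = 4, seed = 5), list(...))
  do.call(synth_spec, args)
}

tiny_extractor_config <- function(...) {
  args <- utils::modifyList(list(input_size = 8, max_time = 64,
                                 cell_size = 8, attention_size = 4,
                                 fc_size = 8, batch_size = 64,
                                 learning_rate = 2e-3, epochs = 2, seed = 3),
                            list(...))
  do.call(extractor_config, args)
}

random_lstm_params <- function(input_size, cell_size) {
  p <- lstm_params(input_size, cell_size)
  lapply(p, function(x) {
    v <- stats::rnorm(length(x), sd = 0.5)
    if (!is.null(dim(x))) dim(v) <- dim(x)
    v
  })
}
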