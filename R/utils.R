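# Numerically safe activations used across the extractor and the GCN.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Softplus activation
#'
#' `log(1 + exp(x))` evaluated in an overflow-safe form. Used after batch
#' normalization in both networks; its strictly positive range is what makes
#' zero-padded fake nodes safe under max pooling.
#'
#' @param x numeric vector, matrix or array.
#' @return object of the same shape with softplus applied elementwise.
#' @export
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# Row-wise softmax with the usual max-shift stabilization.
softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

stopifnot_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop("non-finite values in ", what, call. = FALSE)
  invisible(x)
}

# ---- nested parameter lists ----------------------------------------------
# Model parameters are nested named lists of numeric arrays. These helpers
# map elementwise over two same-shaped trees, flatten to a vector (for
# finite-difference gradient checks) and restore the structure.

param_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(param_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else {
    r <- f(a, b)
    if (!is.null(dim(a))) dim(r) <- dim(a)
    r
  }
}

param_map <- function(a, f) {
  if (is.list(a)) {
    out <- lapply(a, param_map, f = f)
    names(out) <- names(a)
    out
  } else {
    r <- f(a)
    if (!is.null(dim(a))) dim(r) <- dim(a)
    r
  }
}

params_flatten <- function(p) {
  unlist(p, use.names = FALSE)
}

params_unflatten <- function(template, v) {
  idx <- 0L
  rebuild <- function(x) {
    if (is.list(x)) {
      out <- lapply(x, rebuild)
      names(out) <- names(x)
      out
    } else {
      n <- length(x)
      r <- v[(idx + 1L):(idx + n)]
      idx <<- idx + n
      if (!is.null(dim(x))) dim(r) <- dim(x)
      r
    }
  }
  out <- rebuild(template)
  stopifnot(idx == length(v))
  out
}

params_l2 <- function(p) sum(params_flatten(p)^2)

# Glorot-uniform initialization.
glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# ---- Adam optimizer -------------------------------------------------------
# One state object per parameter tree; update returns both new params and
# new state. Plain textbook Adam with bias correction.

adam_init <- function(params) {
  list(m = param_map(params, function(x) x * 0),
       v = param_map(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- param_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- param_map(state$m, function(m) m / bc1)
  vhat <- param_map(state$v, function(v) v / bc2)
  upd <- param_map2(mhat, vhat, function(m, v) lr * m / (sqrt(v) + eps))
  params <- param_map2(params, upd, `-`)
  list(params = params, state = state)
}

# ---- seeding --------------------------------------------------------------
# A single user-facing seed fans out to per-stage seeds by fixed offsets so
# that stages can be re-run in isolation. Kept within 32-bit integer range.

stage_seed <- function(seed, stage) {
  offsets <- c(prepare = 11L, synth = 23L, split = 37L, extractor = 53L,
               graph = 71L, gcn = 89L, eval = 101L, coarsen = 113L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}

# FNV-1a hash of a serialized object; used only to fingerprint run configs
# for cache invalidation (no cryptographic intent).
config_fingerprint <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
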