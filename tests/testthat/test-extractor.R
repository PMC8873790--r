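test_that("lstm_step matches hand-evaluated closed forms", {
  p <- lstm_params(3, 1)
  for (nm in names(p)) p[[nm]] <- p[[nm]] * 0
  # all-zero parameters: gates sigmoid(0)=0.5, candidate tanh(0)=0
  st <- lstm_step(c(0.5, -1, 2), list(c = 0, h = 0), p)
  expect_equal(st$c, 0)
  expect_equal(st$h, 0)
  # zero weights, c_prev = 1: c = f*1 = 0.5, h = o*tanh(c)
  st2 <- lstm_step(c(0.5, -1, 2), list(c = 1, h = 0), p)
  expect_equal(st2$c, 0.5)
  expect_equal(st2$h, 0.5 * tanh(0.5))
  expect_error(lstm_step(c(NA, 1, 2), list(c = 0, h = 0), p), "non-finite")
})

test_that("lstm_step and bilstm_forward match the straight-line oracle", {
  set.seed(21)
  for (rep in 1:5) {
    p_fwd <- random_lstm_params(4, 3)
    p_bwd <- random_lstm_params(4, 3)
    x <- matrix(rnorm(5 * 4), 5, 4)
    # single step
    c0 <- rnorm(3); h0 <- rnorm(3)
    got <- lstm_step(x[1, ], list(c = c0, h = h0), p_fwd)
    want <- oracle_lstm_step(x[1, ], c0, h0, p_fwd)
    expect_equal(got$c, want$c, tolerance = 1e-12)
    expect_equal(got$h, want$h, tolerance = 1e-12)
    # full bidirectional unroll
    expect_equal(bilstm_forward(x, p_fwd, p_bwd),
                 oracle_bilstm(x, p_fwd, p_bwd), tolerance = 1e-10)
  }
})

test_that("short-term state is bounded by the sigmoid-tanh product", {
  set.seed(8)
  p <- random_lstm_params(2, 4)
  st <- list(c = rnorm(4, sd = 3), h = rnorm(4))
  for (k in 1:10) {
    st <- lstm_step(rnorm(2, sd = 5), list(c = st$c, h = st$h), p)
    expect_true(all(abs(st$h) < 1))
  }
})

test_that("bilstm output is reversal-symmetric for constant input and shared params", {
  set.seed(13)
  p <- random_lstm_params(3, 4)
  x <- matrix(rep(rnorm(3), each = 6), 6, 3)   # time-constant input
  y <- bilstm_forward(x, p, p)
  # the backward half retraces the forward trajectory in reversed time:
  # position t of the backward half is the state after 6 - t + 1 steps
  expect_equal(y[, 5:8], y[6:1, 1:4], tolerance = 1e-12)
  # consequence: at the midpoint-symmetric positions the halves cross
  expect_equal(y[3, 5:8], y[4, 1:4], tolerance = 1e-12)
})

test_that("single-timestep bilstm is the concatenation of two cell steps", {
  set.seed(14)
  p_fwd <- random_lstm_params(3, 2); p_bwd <- random_lstm_params(3, 2)
  x <- matrix(rnorm(3), 1, 3)
  y <- bilstm_forward(x, p_fwd, p_bwd)
  sf <- lstm_step(x[1, ], list(c = numeric(2), h = numeric(2)), p_fwd)
  sb <- lstm_step(x[1, ], list(c = numeric(2), h = numeric(2)), p_bwd)
  expect_equal(drop(y), c(sf$h, sb$h), tolerance = 1e-12)
})

test_that("attention pooling matches the oracle and normalizes", {
  set.seed(31)
  a <- attention_params(6, 4)
  # singleton: alpha = 1, s = y_1
  y1 <- matrix(rnorm(6), 1, 6)
  ap <- attention_pool(y1, a)
  expect_equal(ap$alpha, 1)
  expect_equal(ap$s, drop(y1))
  # identical timesteps: uniform weights
  yc <- matrix(rep(rnorm(6), each = 5), 5, 6)
  apc <- attention_pool(yc, a)
  expect_equal(apc$alpha, rep(0.2, 5))
  expect_equal(apc$s, yc[1, ], tolerance = 1e-12)
  # random inputs vs log-sum-exp oracle; weights sum to 1
  for (rep in 1:10) {
    y <- matrix(rnorm(4 * 6, sd = 2), 4, 6)
    got <- attention_pool(y, a)
    want <- oracle_attention(y, a)
    expect_equal(got$alpha, want$alpha, tolerance = 1e-10)
    expect_equal(got$s, want$s, tolerance = 1e-10)
    expect_equal(sum(got$alpha), 1, tolerance = 1e-6)
    # softmax shift invariance of the scores
    shifted <- exp(want$scores + 100 - max(want$scores + 100))
    expect_equal(shifted / sum(shifted), got$alpha, tolerance = 1e-10)
  }
})

test_that("extractor forward satisfies its output contracts", {
  spec <- tiny_synth_spec(n_trials_per_class = 2)
  ds <- generate_dataset(spec)
  cfg <- tiny_extractor_config()
  m <- extractor_init(cfg)
  out1 <- extractor_forward(m, ds, 1:10)
  out2 <- extractor_forward(m, ds, 1:10)
  expect_identical(out1$probs, out2$probs)       # eval determinism
  expect_equal(rowSums(out1$probs), rep(1, 10), tolerance = 1e-12)
  expect_true(all(out1$probs > 0))
  expect_true(all(out1$features > 0))            # softplus range
  # duplicated segments give identical feature rows
  ds2 <- ds; ds2$segments[[2]] <- ds2$segments[[1]]
  f <- extractor_forward(m, ds2, 1:2)$features
  expect_identical(f[1, ], f[2, ])
})

test_that("zero learning rate leaves parameters untouched", {
  spec <- tiny_synth_spec(n_trials_per_class = 2)
  ds <- generate_dataset(spec)
  # full-batch, no dropout: every epoch sees the identical computation
  cfg <- tiny_extractor_config(learning_rate = 0, epochs = 2,
                               batch_size = 200, dropout_rate = 0)
  m0 <- extractor_init(cfg)
  m <- train_extractor(ds, cfg)
  expect_equal(migcn:::params_flatten(m$params),
               migcn:::params_flatten(m0$params))
  expect_equal(diff(m$log$loss), 0, tolerance = 1e-9)
})

test_that("training loss decreases on a separable toy problem", {
  spec <- synth_spec(n_channels = 8, n_trials_per_class = 4, snr = 10,
                     seed = 19)
  ds <- generate_dataset(spec)
  cfg <- tiny_extractor_config(epochs = 8, learning_rate = 3e-3)
  m <- train_extractor(ds, cfg)
  expect_lt(tail(m$log$loss, 1), m$log$loss[1])
  expect_gt(tail(m$log$accuracy, 1), 0.5)
})

test_that("extracted features preserve order, labels and determinism", {
  spec <- tiny_synth_spec(n_trials_per_class = 2)
  ds <- generate_dataset(spec)
  cfg <- tiny_extractor_config(epochs = 1)
  m <- train_extractor(ds, cfg)
  ft1 <- extract_features(ds, m)
  ft2 <- extract_features(ds, m)
  expect_identical(ft1$features, ft2$features)
  expect_equal(nrow(ft1$features), length(ds$segments))
  expect_identical(ft1$labels, label_index(ds$meta$label))
})

test_that("extractor backprop matches finite differences", {
  set.seed(77)
  cfg <- extractor_config(input_size = 5, max_time = 6, cell_size = 4,
                          attention_size = 3, fc_size = 4, dropout_rate = 0,
                          batch_size = 8, epochs = 1, seed = 3)
  m <- extractor_init(cfg)
  X <- array(rnorm(6 * 7 * 5), c(6, 7, 5))
  y <- sample(0:3, 7, replace = TRUE)
  res <- migcn:::extractor_loss_grads(m$params, m$bn, X, y, cfg)
  gflat <- migcn:::params_flatten(res$grads)
  pflat <- migcn:::params_flatten(m$params)
  idx <- sample(length(pflat), 25)
  num <- numeric_gradient(function(v) {
    migcn:::extractor_loss_grads(migcn:::params_unflatten(m$params, v),
                                 m$bn, X, y, cfg)$loss
  }, pflat, idx)
  expect_lt(max(relative_error(num, gflat[idx])), 1e-4)
})

test_that("larger cells do at least as well as tiny cells when noiseless", {
  accs <- sapply(c(4, 32), function(cs) {
    accs_seed <- sapply(1:3, function(s) {
      spec <- synth_spec(n_channels = 8, n_trials_per_class = 3, snr = Inf,
                         seed = 20 + s)
      ds <- generate_dataset(spec)
      cfg <- extractor_config(input_size = 8, max_time = 64, cell_size = cs,
                              attention_size = 4, fc_size = 8,
                              batch_size = 64, learning_rate = 3e-3,
                              epochs = 6, seed = s)
      tail(train_extractor(ds, cfg)$log$accuracy, 1)
    })
    mean(accs_seed)
  })
  expect_gte(accs[2], accs[1])
})
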