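test_that("Chebyshev filter reproduces its first two basis terms", {
  A <- generate_random_graph(8, seed = 1)
  lap <- normalized_laplacian(A)
  x <- matrix(rnorm(8), 8, 1)
  # K = 1, theta_0 = 1: y = T_0 x = x
  expect_equal(chebyshev_filter(x, lap$L_scaled, c(1)), x)
  # K = 2, theta = (0, 1): y = T_1 x = L_scaled x
  expect_equal(chebyshev_filter(x, lap$L_scaled, c(0, 1)),
               lap$L_scaled %*% x)
})

test_that("spectral oracle fixed points: identity and Laplacian filters", {
  A <- generate_random_graph(6, seed = 2)
  lap <- normalized_laplacian(A)
  x <- matrix(rnorm(6), 6, 1)
  # constant filter g == 1 reconstructs x (U U' = I)
  expect_equal(spectral_filter_oracle(x, lap$L, c(1)), x, tolerance = 1e-10)
  # g(lambda) = lambda on the scaled Laplacian: theta = (0, 1)
  expect_equal(spectral_filter_oracle(x, lap$L, c(0, 1)),
               lap$L_scaled %*% x, tolerance = 1e-10)
})

test_that("recurrence and spectral evaluations agree on random instances", {
  set.seed(55)
  for (rep in 1:25) {
    n <- sample(4:16, 1)
    K <- sample(1:4, 1)
    f_in <- sample(1:3, 1); f_out <- sample(1:3, 1)
    A <- generate_random_graph(n, seed = rep)
    lap <- normalized_laplacian(A)
    theta <- array(rnorm(K * f_in * f_out), c(K, f_in, f_out))
    x <- matrix(rnorm(n * f_in), n, f_in)
    y_fast <- chebyshev_filter(x, lap$L_scaled, theta)
    y_ref <- spectral_filter_oracle(x, lap$L, theta)
    expect_lt(max(abs(y_fast - y_ref)), 1e-8)
  }
})

test_that("a K-term filter is (K-1)-localized on a path graph", {
  n <- 12
  A <- matrix(0, n, n)
  for (i in 1:(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  lap <- normalized_laplacian(A)
  K <- 3
  theta <- array(rnorm(K), c(K, 1, 1))
  x <- matrix(rnorm(n), n, 1)
  y1 <- chebyshev_filter(x, lap$L_scaled, theta)
  # zero an input more than K-1 = 2 hops from node 1: output at node 1
  # must be bit-identical
  x2 <- x; x2[7, 1] <- 0
  y2 <- chebyshev_filter(x2, lap$L_scaled, theta)
  expect_identical(y1[1, 1], y2[1, 1])
  # but zeroing a node within reach changes it
  x3 <- x; x3[2, 1] <- 0
  y3 <- chebyshev_filter(x3, lap$L_scaled, theta)
  expect_false(isTRUE(all.equal(y1[1, 1], y3[1, 1])))
})

test_that("batched layer agrees with the per-sample public filter", {
  set.seed(56)
  A <- generate_random_graph(10, seed = 3)
  lap <- normalized_laplacian(A)
  theta <- array(rnorm(3 * 2 * 4), c(3, 2, 4))
  X <- array(rnorm(5 * 10 * 2), c(5, 10, 2))
  Y <- migcn:::cheb_forward_batch(X, lap$L_scaled, theta)$Y
  for (b in 1:5) {
    xb <- matrix(X[b, , ], 10, 2)
    expect_equal(matrix(Y[b, , ], 10, 4),
                 chebyshev_filter(xb, lap$L_scaled, theta),
                 tolerance = 1e-12)
  }
})

test_that("gcn forward obeys the probability and shape contracts", {
  set.seed(57)
  A <- generate_random_graph(64, seed = 9, p_edge = 1)
  h <- graclus_coarsen(A, 6, seed = 10)
  # dense 64-node graph coarsens along the full binary tree to one node
  expect_equal(vapply(h$perms, length, integer(1)) , 64 / 2^(0:6) * 1L)
  cfg <- gcn_config(seed = 2)                     # 6 layers, 16..512 filters
  m <- gcn_init(cfg, h)
  f <- matrix(abs(rnorm(3 * 64)) + 0.1, 3, 64)
  p1 <- gcn_forward(m, f)
  p2 <- gcn_forward(m, f)
  expect_identical(p1, p2)                        # eval determinism
  expect_equal(dim(p1), c(3L, 4L))
  expect_equal(rowSums(p1), rep(1, 3), tolerance = 1e-12)
  expect_true(all(p1 > 0 & p1 < 1))
  # depth mismatch is rejected
  h2 <- graclus_coarsen(A, 2, seed = 10)
  expect_error(gcn_init(cfg, h2), "levels")
})

test_that("zero learning rate freezes GCN parameters", {
  set.seed(58)
  ftr <- matrix(abs(rnorm(40 * 16)) + 0.1, 40, 16)
  y <- rep(0:3, 10)
  g <- build_feature_graph(ftr)
  cfg <- gcn_config(filters_per_layer = c(4, 8), pool_per_layer = c(2, 2),
                    batch_size = 20, learning_rate = 0, epochs = 2, seed = 4)
  m <- train_gcn(ftr, g, cfg, labels = y)
  m0 <- gcn_init(cfg, m$hierarchy)
  expect_equal(migcn:::params_flatten(m$params),
               migcn:::params_flatten(m0$params))
})

test_that("GCN training descends on separable features", {
  set.seed(59)
  y <- rep(0:3, each = 15)
  centers <- matrix(runif(4 * 16, 0.5, 3), 4, 16)
  ftr <- centers[y + 1, ] + matrix(rnorm(60 * 16, sd = 0.15), 60, 16)
  ftr <- abs(ftr) + 0.05
  g <- build_feature_graph(ftr)
  cfg <- gcn_config(filters_per_layer = c(4, 8), pool_per_layer = c(2, 2),
                    batch_size = 16, learning_rate = 1e-3, epochs = 30,
                    seed = 6)
  m <- train_gcn(ftr, g, cfg, labels = y)
  expect_lt(tail(m$log$loss, 1), m$log$loss[1])
  expect_gt(tail(m$log$accuracy, 1), 0.8)
})

test_that("GCN backprop matches finite differences", {
  set.seed(60)
  A <- generate_random_graph(16, seed = 5)
  cfg <- gcn_config(filters_per_layer = c(3, 5), pool_per_layer = c(2, 2),
                    K = 3, batch_size = 12, learning_rate = 1e-3,
                    epochs = 1, seed = 2)
  h <- graclus_coarsen(A, 2, seed = 9)
  m <- gcn_init(cfg, h)
  feats <- matrix(abs(rnorm(12 * 16)) + 0.1, 12, 16)
  y <- sample(0:3, 12, replace = TRUE)
  X <- migcn:::features_to_gcn_input(feats, h)
  res <- migcn:::gcn_loss_grads(m$params, m$bn, X, y, cfg, h)
  gflat <- migcn:::params_flatten(res$grads)
  pflat <- migcn:::params_flatten(m$params)
  idx <- sample(length(pflat), 30)
  num <- numeric_gradient(function(v) {
    migcn:::gcn_loss_grads(migcn:::params_unflatten(m$params, v),
                           m$bn, X, y, cfg, h)$loss
  }, pflat, idx)
  expect_lt(max(relative_error(num, gflat[idx])), 1e-4)
})
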