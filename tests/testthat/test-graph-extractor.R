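test_that("adjacency init draws symmetric Xavier-bounded weights", {
  a <- init_adjacency(62L, seed = 1L)
  expect_identical(dim(a$raw_weights), c(62L, 62L))
  expect_equal(a$raw_weights, t(a$raw_weights))
  expect_true(all(abs(a$raw_weights) < 1 / sqrt(62)))
  expect_identical(a$raw_weights, init_adjacency(62L, seed = 1L)$raw_weights)
  expect_false(identical(a$raw_weights, init_adjacency(62L, seed = 2L)$raw_weights))
  expect_error(init_adjacency(1L), "n_channels")
})

test_that("pooled adjacency draws have mean zero under the uniform law", {
  draws <- unlist(lapply(1:40, function(s) init_adjacency(50L, seed = s)$raw_weights))
  # uniform(-b, b) has sd b/sqrt(3); symmetrized entries keep mean 0
  b <- 1 / sqrt(50)
  se <- (b / sqrt(3)) / sqrt(length(draws))
  expect_lt(abs(mean(draws)), 3 * se)
})

test_that("symmetric normalization matches hand computations", {
  # all-ones 2x2: degrees 2, L = J/2
  st <- normalize_adjacency(matrix(1, 2, 2))
  expect_equal(st$normalized, matrix(0.5, 2, 2))
  # an all-negative row is rectified away: zero row/column, no blow-up
  a <- matrix(c(1, -2, -2, -3), 2, 2)
  st2 <- normalize_adjacency(a)
  expect_equal(st2$normalized[2, ], c(0, 0))
  expect_equal(st2$normalized[, 2], c(0, 0))
  expect_true(all(is.finite(st2$normalized)))
  # positive diagonal: D = A', so L has unit diagonal
  st3 <- normalize_adjacency(diag(c(2, 3, 4)))
  expect_equal(st3$normalized, diag(3))
  expect_error(normalize_adjacency(structure(list(raw_weights = matrix(1, 2, 3),
                                                  n_channels = 2L),
                                             class = "adjacency_state")),
               "square")
})

test_that("normalized adjacency is symmetric with spectral radius at most 1", {
  for (s in 1:200) {
    set.seed(s)
    n <- sample(3:10, 1)
    st <- normalize_adjacency(matrix(rnorm(n * n), n, n))
    expect_equal(st$normalized, t(st$normalized), tolerance = 1e-12)
    ev <- eigen(st$normalized, symmetric = TRUE, only.values = TRUE)$values
    expect_lt(max(abs(ev)), 1 + 1e-6)
  }
})

test_that("chebyshev_stack follows the recursion and the spectral oracle", {
  expect_length(chebyshev_stack(diag(3), 1L), 1L)
  expect_equal(chebyshev_stack(diag(3), 1L)[[1]], diag(3))
  # diagonal L: T_2 = diag(2 lambda^2 - 1)
  lam <- c(0.3, -0.5, 0.9)
  bank <- chebyshev_stack(diag(lam), 3L)
  expect_equal(bank[[3]], diag(2 * lam^2 - 1))
  # eigendecomposition oracle on random symmetric matrices
  cheb_scalar <- function(x, k) {
    if (k == 0) return(rep(1, length(x)))
    if (k == 1) return(x)
    tm2 <- rep(1, length(x)); tm1 <- x
    for (j in 2:k) { t <- 2 * x * tm1 - tm2; tm2 <- tm1; tm1 <- t }
    tm1
  }
  for (s in 1:10) {
    set.seed(s)
    n <- sample(5:10, 1)
    l <- normalize_adjacency(matrix(rnorm(n * n), n, n))$normalized
    bank <- chebyshev_stack(l, 8L)
    eg <- eigen(l, symmetric = TRUE)
    for (k in 0:7) {
      oracle <- eg$vectors %*% diag(cheb_scalar(eg$values, k)) %*% t(eg$vectors)
      expect_equal(bank[[k + 1]], oracle, tolerance = 1e-6)
    }
  }
  expect_error(chebyshev_stack(diag(3), 0L), "order")
})

test_that("graph convolution matches a hand-computed tiny case", {
  # identity filter: K = 1, W_0 = I, nonnegative input
  x <- array(abs(rnorm(2 * 3 * 2)), c(2, 3, 2))
  bank <- list(diag(3))
  layer <- list(weights = list(diag(2)), negative_slope = 0.01)
  expect_equal(graph_conv_forward(x, bank, layer), x)
  # K = 2, 3 channels, 2 features, single sample: T0 X W0 + T1 X W1
  set.seed(5)
  xm <- matrix(rnorm(6), 3, 2)
  l <- normalize_adjacency(matrix(runif(9), 3, 3))$normalized
  w0 <- matrix(rnorm(4), 2, 2); w1 <- matrix(rnorm(4), 2, 2)
  pre <- xm %*% w0 + l %*% xm %*% w1
  expected <- ifelse(pre > 0, pre, 0.01 * pre)
  x1 <- array(xm, c(1, 3, 2))
  got <- graph_conv_forward(x1, list(diag(3), l),
                            list(weights = list(w0, w1), negative_slope = 0.01))
  expect_equal(got[1, , ], expected, tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences", {
  tdn <- asNamespace("tddann")
  set.seed(42)
  st <- init_extractor(4L, 3L, cheb_order = 3L, n_layers = 2L, out_dim = 4L,
                       seed = 7L)
  x <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  set.seed(9)
  wloss <- matrix(rnorm(5 * st$d_feat), 5, st$d_feat)
  loss_fn <- function(params) {
    st2 <- st; st2$params <- params
    sum(wloss * tdn$extractor_forward(st2, x))
  }
  fwd <- tdn$extractor_forward(st, x, cache = TRUE)
  g <- tdn$extractor_backward(st, fwd, wloss)
  h <- 1e-6
  check_block <- function(get, set, gmat, n_checks = 8L) {
    for (i in seq_len(n_checks)) {
      p <- st$params
      m <- get(p)
      ii <- sample(length(m), 1)
      m[ii] <- m[ii] + h; lp <- loss_fn(set(p, m))
      m[ii] <- m[ii] - 2 * h; lm <- loss_fn(set(p, m))
      fd <- (lp - lm) / (2 * h)
      expect_equal(gmat[ii], fd, tolerance = 1e-4)
    }
  }
  check_block(function(p) p$adjacency,
              function(p, m) { p$adjacency <- m; p }, g$adjacency)
  for (l in 1:2) for (k in 1:3) {
    check_block(function(p) p$layers[[l]]$weights[[k]],
                function(p, m) { p$layers[[l]]$weights[[k]] <- m; p },
                g$layers[[l]]$weights[[k]], n_checks = 4L)
  }
})

test_that("extractor is a pure per-row map with the contracted output shape", {
  st <- init_extractor(16L, 5L, seed = 3L)
  x <- array(rnorm(48 * 16 * 5), c(48, 16, 5))
  f <- extract_features(x, st)
  expect_identical(dim(f), c(48L, 16L * 32L))
  x2 <- x; x2[2, , ] <- x[1, , ]
  f2 <- extract_features(x2, st)
  expect_equal(f2[1, ], f2[2, ])
  expect_error(extract_features(x, list()), "not initialized")
})

test_that("channel permutation equivariance holds before flattening", {
  n <- 6L
  st <- init_extractor(n, 3L, out_dim = 4L, seed = 2L)
  x <- array(rnorm(4 * n * 3), c(4, n, 3))
  perm <- sample(n)
  st_p <- st
  st_p$params$adjacency <- st$params$adjacency[perm, perm]
  x_p <- x[, perm, , drop = FALSE]
  f <- extract_features(x, st)       # rows flatten as (channel, feature)
  f_p <- extract_features(x_p, st_p)
  arr <- array(f, c(4, n, st$out_dim))
  arr_p <- array(f_p, c(4, n, st$out_dim))
  expect_equal(arr_p, arr[, perm, , drop = FALSE], tolerance = 1e-10)
})

test_that("the perceptron ablation matches the graph extractor's output width", {
  st_g <- init_extractor(16L, 5L, seed = 1L)
  st_m <- init_extractor(16L, 5L, use_mlp = TRUE, seed = 1L)
  x <- array(rnorm(3 * 16 * 5), c(3, 16, 5))
  expect_identical(dim(extract_features(x, st_m)), dim(extract_features(x, st_g)))
})
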