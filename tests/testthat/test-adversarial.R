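test_that("reversal strength has the closed-form endpoints and is monotone", {
  # iter 0 forces coeff = lo regardless of alpha
  for (alpha in c(0.1, 1, 10, 100)) {
    s <- grl_schedule(hi = 0.9, lo = 0.5, alpha = alpha, iter_num = 0L,
                      max_iters = 1000L)
    expect_identical(grl_coefficient(s), 0.5)
  }
  # degenerate constant schedule
  s <- grl_schedule(hi = 0.7, lo = 0.7, alpha = 5, iter_num = 123L,
                    max_iters = 500L)
  expect_equal(grl_coefficient(s), 0.7)
  # grid: bounded by hi, nondecreasing, and hits the closed-form terminal value
  vals <- vapply(seq(0L, 1000L, length.out = 1000L), function(it) {
    s <- grl_schedule(0.9, 0.5, 10, as.integer(it), 1000L)
    grl_coefficient(s)
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_lt(max(vals), 0.9)
  terminal <- 2 * 0.4 / (1 + exp(-10)) - 0.4 + 0.5
  expect_equal(vals[length(vals)], terminal, tolerance = 1e-12)
  expect_error(grl_schedule(max_iters = 0L), "max_iters")
})

test_that("gradient reversal is identity forward and scales gradients by -coeff", {
  x <- matrix(rnorm(12), 3, 4)
  expect_identical(reverse_gradient(x, 0.7), x)
  # coeff 0 annihilates, coeff 1 negates
  g <- matrix(1, 3, 4)
  expect_equal(reverse_gradient_backward(g, 0), matrix(0, 3, 4))
  expect_equal(reverse_gradient_backward(g, 1), -g)
  # composition: two reversals with coefficients a and b scale by ab
  a <- 0.6; b <- 0.3
  expect_equal(reverse_gradient_backward(reverse_gradient_backward(g, a), b),
               a * b * g)
  # finite-difference contract on a quadratic loss through a discriminator
  set.seed(4)
  dd <- init_domain_discriminator(4L, hidden = 6L, seed = 2L)
  f <- matrix(rnorm(12), 3, 4)
  tdn <- asNamespace("tddann")
  loss_nogrl <- function(fm) {
    p <- domain_discriminator_forward(fm, dd)
    sum(p^2)
  }
  for (coeff in c(0, 0.5, 1)) {
    fw <- tdn$mlp2_forward(dd, f)
    p <- as.vector(tdn$sigmoid(fw$out))
    g_u <- matrix(2 * p * p * (1 - p), ncol = 1L)   # d sum(p^2) / d logit
    bk <- tdn$mlp2_backward(dd, fw, g_u)
    g_feat <- reverse_gradient_backward(bk$g_x, coeff)
    h <- 1e-5
    for (t in 1:6) {
      i <- sample(3, 1); j <- sample(4, 1)
      fp <- f; fp[i, j] <- fp[i, j] + h
      fm <- f; fm[i, j] <- fm[i, j] - h
      fd <- (loss_nogrl(fp) - loss_nogrl(fm)) / (2 * h)
      expect_equal(g_feat[i, j], -coeff * fd, tolerance = 1e-4)
    }
  }
})

test_that("discriminator outputs are proper probabilities and deterministic", {
  dd <- init_domain_discriminator(10L, seed = 5L)
  x <- matrix(rnorm(40 * 10), 40, 10)
  p <- domain_discriminator_forward(x, dd)
  expect_true(all(p > 0 & p < 1))
  expect_identical(p, domain_discriminator_forward(x, dd))
  # zero final layer gives exactly 0.5 / uniform softmax
  dd0 <- dd; dd0$l2$w[] <- 0; dd0$l2$b[] <- 0
  expect_equal(domain_discriminator_forward(x, dd0), rep(0.5, 40))
  di <- init_individual_discriminator(10L, 15L, seed = 5L)
  di0 <- di; di0$l2$w[] <- 0; di0$l2$b[] <- 0
  out <- individual_discriminator_forward(x, di0)
  expect_equal(out$prob, matrix(1 / 15, 40, 15))
  expect_equal(rowSums(individual_discriminator_forward(x, di)$prob),
               rep(1, 40), tolerance = 1e-6)
  # duplicated rows give identical probability rows
  x2 <- rbind(x[1, ], x[1, ])
  o2 <- individual_discriminator_forward(x2, di)
  expect_equal(o2$prob[1, ], o2$prob[2, ])
  expect_error(init_individual_discriminator(10L, 1L), "at least 2")
})

test_that("discriminators fit linearly separable groups without reversal", {
  tdn <- asNamespace("tddann")
  cl <- separable_clusters(n_per = 60L, d = 8L, k = 3L, seed = 11L)
  di <- init_individual_discriminator(8L, 3L, hidden = 16L, seed = 3L)
  opt <- tdn$rmsprop_state(di)
  for (step in 1:400) {
    fw <- tdn$mlp2_forward(di, cl$x)
    prob <- tdn$softmax_rows(fw$out)
    g <- tdn$individual_loss_grad(prob, cl$y)
    bk <- tdn$mlp2_backward(di, fw, g)
    up <- tdn$rmsprop_update(di, bk$grads, opt, lr = 5e-3)
    di <- up$p; opt <- up$v
  }
  pred <- max.col(individual_discriminator_forward(cl$x, di)$logits) - 1L
  expect_gt(mean(pred == cl$y), 0.95)

  cl2 <- separable_clusters(n_per = 80L, d = 8L, k = 2L, seed = 12L)
  dd <- init_domain_discriminator(8L, hidden = 16L, seed = 3L)
  opt <- tdn$rmsprop_state(dd)
  y <- cl2$y  # 0/1 domain labels
  for (step in 1:400) {
    fw <- tdn$mlp2_forward(dd, cl2$x)
    p <- as.vector(tdn$sigmoid(fw$out))
    g_u <- matrix((p - y) / length(y), ncol = 1L)
    bk <- tdn$mlp2_backward(dd, fw, g_u)
    up <- tdn$rmsprop_update(dd, bk$grads, opt, lr = 5e-3)
    dd <- up$p; opt <- up$v
  }
  p <- domain_discriminator_forward(cl2$x, dd)
  expect_gt(mean((p > 0.5) == (y == 1)), 0.95)
})
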