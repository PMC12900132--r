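test_that("bce matches closed forms and the elementwise oracle", {
  expect_equal(bce(c(1, 0, 1), c(1, 0, 1)), 0, tolerance = 1e-5)
  expect_equal(bce(1, 0.5), log(2), tolerance = 1e-12)
  set.seed(21)
  for (rep in 1:5) {
    y <- rbinom(17, 1, 0.5)
    p <- runif(17)
    expect_equal(bce(y, p), loop_bce(y, p), tolerance = 1e-10)
  }
  expect_error(bce(c(1, 0), c(0.5, 0.5, 0.5)), "length")
})

test_that("domain loss has its closed forms and swap symmetry", {
  expect_lt(domain_loss(rep(1 - 1e-9, 5), rep(1e-9, 5)), 1e-5)
  expect_equal(domain_loss(rep(0.5, 4), rep(0.5, 6)), log(2), tolerance = 1e-12)
  set.seed(8)
  d_s <- runif(9); d_t <- runif(13)
  expect_equal(domain_loss(d_s, d_t),
               0.5 * (loop_bce(1, d_s) + loop_bce(0, d_t)),
               tolerance = 1e-10)
  # complementing probabilities and swapping roles leaves the loss unchanged
  expect_equal(domain_loss(d_s, d_t), domain_loss(1 - d_t, 1 - d_s),
               tolerance = 1e-12)
  # permutation invariance within each side
  expect_equal(domain_loss(sample(d_s), sample(d_t)), domain_loss(d_s, d_t))
  expect_error(domain_loss(numeric(0), d_t), "non-empty")
})

test_that("individual loss matches uniform closed form and a row loop", {
  p_uni <- matrix(1 / 15, 8, 15)
  expect_equal(individual_loss(p_uni, rep(3L, 8), 15L), log(15),
               tolerance = 1e-12)
  onehot <- diag(4)[c(1, 3, 2, 4), ]
  expect_lt(individual_loss(pmin(pmax(onehot, 1e-9), 1 - 1e-9),
                            c(0L, 2L, 1L, 3L), 4L), 1e-5)
  set.seed(13)
  p <- matrix(runif(6 * 5), 6, 5); p <- p / rowSums(p)
  id <- sample(0:4, 6, TRUE)
  loop <- -mean(sapply(1:6, function(i) log(p[i, id[i] + 1])))
  expect_equal(individual_loss(p, id, 5L), loop, tolerance = 1e-10)
  expect_error(individual_loss(p, c(id[-6], 5L), 5L), "label")
})

test_that("classification loss covers both heads with loop oracles", {
  sc05 <- matrix(0, 4, 3)  # sigmoid(0) = 0.5 everywhere
  expect_equal(classification_loss(sc05, c(0L, 1L, 2L, 0L)), log(2),
               tolerance = 1e-12)
  set.seed(31)
  scores <- matrix(rnorm(5 * 3), 5, 3)
  labels <- sample(0:2, 5, TRUE)
  onehot <- matrix(0, 5, 3); onehot[cbind(1:5, labels + 1)] <- 1
  p <- 1 / (1 + exp(-scores))
  loop_ova <- -mean(onehot * log(p) + (1 - onehot) * log(1 - p))
  expect_equal(classification_loss(scores, labels), loop_ova, tolerance = 1e-10)
  sm <- exp(scores) / rowSums(exp(scores))
  loop_ce <- -mean(log(sm[cbind(1:5, labels + 1)]))
  expect_equal(classification_loss(scores, labels, head = "softmax_ce"),
               loop_ce, tolerance = 1e-10)
  expect_error(classification_loss(scores, c(0L, 1L, 3L, 0L, 1L)), "label")
})

test_that("confident-target selection implements both rules", {
  # logits giving confidences ~0.95 (sigmoid(3) = 0.953)
  hi_conf <- matrix(c(3, -3, -3), 6, 3, byrow = TRUE)
  sel <- select_confident_targets(hi_conf, threshold = 0.9)
  expect_equal(sel$n_selected, 6L)
  lo_conf <- matrix(0, 6, 3)
  sel0 <- select_confident_targets(lo_conf, threshold = 0.9)
  expect_equal(sel0$n_selected, 0L)
  expect_equal(cluster_loss(numeric(0)), 0)
  # top-50% of 10 rows with distinct confidences: exactly the 5 largest
  set.seed(2)
  logits <- matrix(0, 10, 3)
  logits[, 1] <- seq(-2, 2.5, length.out = 10)
  sel5 <- select_confident_targets(logits, rule = "top_fraction", fraction = 0.5)
  expect_identical(sel5$idx, 6:10)
  expect_equal(sel5$n_selected, 5L)
})

test_that("cluster loss closed forms and monotonicity", {
  expect_lt(cluster_loss(rep(1 - 1e-9, 4)), 1e-5)
  expect_equal(cluster_loss(0.5), log(2), tolerance = 1e-12)
  set.seed(17)
  d <- runif(7)
  expect_equal(cluster_loss(d), loop_bce(1, d), tolerance = 1e-10)
  # monotone decreasing as outputs move toward 1
  grid <- seq(0.05, 0.95, by = 0.1)
  vals <- vapply(grid, function(v) cluster_loss(rep(v, 5)), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("total loss is the exact weighted sum", {
  b <- total_loss(1, 2, 3, 4, lambda_cluster = 0.5, n_selected = 7L)
  expect_identical(b$total, 1 + 2 + 3 + 0.5 * 4)
  b0 <- total_loss(1, 2, 3, 99, lambda_cluster = 0)
  expect_identical(b0$total, 6)
  set.seed(23)
  for (rep in 1:10) {
    v <- runif(4); lam <- runif(1)
    bb <- total_loss(v[1], v[2], v[3], v[4], lam)
    expect_equal(bb$total, v[1] + v[2] + v[3] + lam * v[4], tolerance = 0)
  }
})
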