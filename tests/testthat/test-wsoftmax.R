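test_that("negative-weight biasing follows the closed-form and its limits", {
  # gamma = 0 leaves the weights untouched (softmax special case)
  set.seed(21)
  W <- random_unit_columns(5, 4)
  expect_identical(bias_negative_weights(W, 2, 0), W)

  # hand-checkable 2-d case: w_c = e1, w_i = e2, gamma = 1
  W2 <- cbind(c(1, 0), c(0, 1))
  out <- bias_negative_weights(W2, 1, 1)
  expect_equal(out[, 1], c(1, 0))
  expect_equal(out[, 2], c(1, 1) / sqrt(2), tolerance = 1e-12)

  # gamma -> inf drives every negative weight onto w_c
  big <- bias_negative_weights(W, 3, 1e6)
  for (i in c(1, 2, 4)) {
    expect_gt(sum(big[, i] * W[, 3]), 1 - 1e-6)
  }

  # all biased columns are unit norm across random draws
  set.seed(22)
  for (r in 1:50) {
    Wr <- random_unit_columns(sample(2:8, 1), sample(2:6, 1))
    g <- stats::runif(1, 0, 3)
    Wb <- bias_negative_weights(Wr, 1, g)
    expect_equal(sqrt(colSums(Wb^2)), rep(1, ncol(Wb)), tolerance = 1e-12)
  }

  # exactly antipodal weights at gamma = 1 are degenerate
  Wd <- cbind(c(1, 0), c(-1, 0))
  expect_error(bias_negative_weights(Wd, 1, 1), "degenerate")
})

test_that("w-softmax probabilities normalize and agree with a direct oracle", {
  set.seed(23)
  # zero feature vector: all logits zero -> uniform
  W <- random_unit_columns(4, 5)
  expect_equal(wsoftmax_probabilities(rep(0, 4), W, 2, 1), rep(0.2, 5),
               tolerance = 1e-12)

  # gamma = 0 equals plain softmax of W^T x
  x <- stats::rnorm(4)
  p0 <- wsoftmax_probabilities(x, W, 3, 0)
  z <- drop(crossprod(W, x))
  expect_equal(p0, exp(z) / sum(exp(z)), tolerance = 1e-12)

  # C = 3, d = 2 random instance against brute-force exponentiation of the
  # biased logits built independently here
  for (r in 1:20) {
    W3 <- random_unit_columns(2, 3)
    x3 <- stats::rnorm(2)
    g <- stats::runif(1, 0, 2)
    cidx <- sample(3, 1)
    p <- wsoftmax_probabilities(x3, W3, cidx, g)
    z3 <- numeric(3)
    for (j in 1:3) {
      wj <- if (j == cidx) W3[, j] else {
        v <- g * W3[, cidx] + W3[, j]
        v / sqrt(sum(v^2))
      }
      z3[j] <- sum(wj * x3)
    }
    expect_equal(p, exp(z3) / sum(exp(z3)), tolerance = 1e-10)
  }

  # probabilities sum to one over many random draws
  set.seed(24)
  worst <- 0
  for (r in 1:1000) {
    d <- sample(2:6, 1); C <- sample(2:6, 1)
    p <- wsoftmax_probabilities(stats::rnorm(d) * stats::runif(1, 0.1, 10),
                                random_unit_columns(d, C),
                                sample(C, 1), stats::runif(1, 0, 3))
    worst <- max(worst, abs(sum(p) - 1))
    expect_true(all(p > 0 & p < 1))
  }
  expect_lt(worst, 1e-12)
  expect_error(wsoftmax_probabilities(c(NaN, 1), random_unit_columns(2, 2), 1, 1),
               "non-finite")
})

test_that("the loss reduces to cross-entropy at gamma 0, in value and gradients", {
  set.seed(25)
  N <- 8; d <- 6; C <- 5
  X <- matrix(stats::rnorm(N * d), N, d)
  W <- random_unit_columns(d, C)
  labels <- sample(C, N, replace = TRUE)
  res <- wsoftmax_loss(X, labels, W, gamma = 0)
  # independent cross-entropy implementation
  Z <- X %*% W
  P <- exp(Z - apply(Z, 1, max))
  P <- P / rowSums(P)
  ce <- -mean(log(P[cbind(seq_len(N), labels)]))
  G <- P; G[cbind(seq_len(N), labels)] <- G[cbind(seq_len(N), labels)] - 1
  expect_equal(res$loss, ce, tolerance = 1e-10)
  expect_equal(res$dX, (G / N) %*% t(W), tolerance = 1e-8)
  expect_equal(res$dW, t(X) %*% (G / N), tolerance = 1e-8)
})

test_that("single-sample closed form and the margin-widening property hold", {
  # C = 2, d = 2, orthonormal weights, x = w_1, gamma = 0:
  # loss = ln(1 + exp(-1))
  W <- cbind(c(1, 0), c(0, 1))
  res <- wsoftmax_loss(matrix(c(1, 0), 1), 1L, W, gamma = 0)
  expect_equal(res$loss, log(1 + exp(-1)), tolerance = 1e-12)

  # the bias widens the margin a correctly-classified sample must clear:
  # for features aligned with their class weight the biased-negative
  # logit cos(theta/2) always dominates cos(theta), so the loss at
  # gamma = 1 is at least the loss at gamma = 0. (For arbitrary feature
  # positions this monotonicity can fail when weight pairs are obtuse
  # and all logits negative, which is the degenerate regime discussed in
  # the vignette, so the sweep samples the aligned family.)
  set.seed(26)
  for (r in 1:1000) {
    d <- sample(2:5, 1); C <- sample(2:5, 1)
    W <- random_unit_columns(d, C)
    cidx <- sample(C, 1)
    x <- stats::runif(1, 0.1, 5) * W[, cidx]
    l0 <- wsoftmax_loss(matrix(x, 1), cidx, W, 0, grads = FALSE)$loss
    l1 <- wsoftmax_loss(matrix(x, 1), cidx, W, 1, grads = FALSE)$loss
    expect_gte(l1, l0 - 1e-12)
  }
})

test_that("analytic gradients match finite differences at several gamma values", {
  set.seed(27)
  N <- 4; d <- 5; C <- 4
  X <- matrix(stats::rnorm(N * d), N, d)
  W <- random_unit_columns(d, C)
  labels <- sample(C, N, replace = TRUE)
  eps <- 1e-6
  for (gamma in c(0, 0.5, 1)) {
    res <- wsoftmax_loss(X, labels, W, gamma)
    for (k in 1:6) {
      i <- sample(N * d, 1)
      Xp <- X; Xp[i] <- Xp[i] + eps
      Xm <- X; Xm[i] <- Xm[i] - eps
      fd <- (wsoftmax_loss(Xp, labels, W, gamma, grads = FALSE)$loss -
             wsoftmax_loss(Xm, labels, W, gamma, grads = FALSE)$loss) / (2 * eps)
      expect_equal(res$dX[i], fd, tolerance = 1e-4)
    }
    for (k in 1:6) {
      i <- sample(d * C, 1)
      Wp <- W; Wp[i] <- Wp[i] + eps
      Wm <- W; Wm[i] <- Wm[i] - eps
      fd <- (wsoftmax_loss(X, labels, Wp, gamma, grads = FALSE)$loss -
             wsoftmax_loss(X, labels, Wm, gamma, grads = FALSE)$loss) / (2 * eps)
      expect_equal(res$dW[i], fd, tolerance = 1e-4)
    }
  }
  expect_error(wsoftmax_loss(X, c(1, 2, 9, 1), W, 1), "label out of range")
})
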