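test_that("the Gaussian Gram matrix matches elementwise evaluation", {
  set.seed(1)
  X <- matrix(rnorm(5 * 3), 5)
  K <- gaussian_gram(X, r = 2)
  for (i in 1:5) for (j in 1:5)
    expect_equal(K[i, j], exp(-2 * sum((X[i, ] - X[j, ])^2)), tolerance = 1e-12)
  expect_equal(diag(K), rep(1, 5))
  expect_identical(K, t(K))
  expect_true(all(K > 0 & K <= 1))
  expect_error(gaussian_gram(X, r = 0), "r")
  expect_error(gaussian_gram(X, matrix(0, 2, 4)), "dimensions")
})

test_that("Gram centering equals H K H, is idempotent and zeroes the margins", {
  set.seed(2)
  X <- matrix(rnorm(20), 10)
  K <- gaussian_gram(X, r = 1)
  Kc <- center_gram(K)
  H <- diag(10) - matrix(1 / 10, 10, 10)
  expect_equal(Kc, H %*% K %*% H, tolerance = 1e-12)
  expect_lt(max(abs(rowSums(Kc))), 1e-10)
  expect_lt(max(abs(colSums(Kc))), 1e-10)
  expect_equal(center_gram(Kc), Kc, tolerance = 1e-12)
  expect_error(center_gram(matrix(0, 2, 3)), "square")
})

test_that("kernel PCA reconstructs the centered Gram and centers the training cloud", {
  set.seed(3)
  X <- matrix(rnorm(30 * 4), 30)
  Kc <- center_gram(gaussian_gram(X, r = 0.5))
  kp <- kpca_fit(Kc)
  expect_true(all(diff(kp$eigenvalues) <= 1e-10))
  P <- Kc %*% kp$W
  expect_equal(P %*% t(P), Kc, tolerance = 1e-8)
  # the projected training set has feature-space mean zero
  expect_lt(max(abs(colSums(P))), 1e-8)
  expect_error(kpca_fit(matrix(0, 4, 4)), "floor|component")
})

test_that("the within-class graph matches a brute-force neighbor search and never crosses classes", {
  set.seed(4)
  X <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 3), 10))
  y <- rep(c(1, 2), each = 10)
  K <- gaussian_gram(X, r = 0.3)
  g <- within_class_adjacency(K, y, t = 3)
  # cross-class entries are exactly zero, in raw and symmetrized forms
  expect_true(all(g$A_raw[1:10, 11:20] == 0))
  expect_true(all(g$A[11:20, 1:10] == 0))
  # brute-force recomputation
  d2 <- outer(diag(K), diag(K), "+") - 2 * K
  for (i in 1:20) {
    same <- setdiff(which(y == y[i]), i)
    ord <- same[order(d2[i, same], same)][1:3]
    sig_i <- sqrt(d2[i, ord[3]])
    for (j in ord) {
      sig_j <- sqrt(d2[j, setdiff(which(y == y[j]), j)[
        order(d2[j, setdiff(which(y == y[j]), j)],
              setdiff(which(y == y[j]), j))][3]])
      expect_equal(g$A_raw[i, j], exp(-d2[i, j] / (sig_i * sig_j)),
                   tolerance = 1e-10)
    }
  }
  # duplicate points carry pre-normalization weight 1
  Xd <- rbind(X, X[1, , drop = FALSE])
  yd <- c(y, 1)
  gd <- within_class_adjacency(gaussian_gram(Xd, r = 0.3), yd, t = 3)
  expect_equal(gd$A_raw[1, 21], 1)
  expect_error(within_class_adjacency(K, y, t = 10), "class size")
})

test_that("the scatter matrix is PSD and matches its definitional sum over samples", {
  set.seed(5)
  X <- rbind(matrix(rnorm(24, 0), 12), matrix(rnorm(24, 2.5), 12))
  y <- rep(c(1, 2), each = 12)
  K <- gaussian_gram(X, r = 0.5)
  Kc <- center_gram(K)
  kp <- kpca_fit(Kc)
  g <- within_class_adjacency(K, y, t = 4)
  Sw <- wcnp_scatter(Kc, kp, g)
  expect_equal(Sw, t(Sw), tolerance = 1e-10)
  expect_gte(min(eigen(Sw, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  # definitional route: sum_i (p_i - sum_j A_ij p_j)(p_i - sum_j A_ij p_j)'
  P <- Kc %*% kp$W
  R <- P - g$A %*% P
  Sw2 <- t(R) %*% R
  expect_equal(Sw, Sw2, tolerance = 1e-8)
  # disabled graph reduces to W' K K' W
  Sw0 <- wcnp_scatter(Kc, kp, matrix(0, 24, 24))
  expect_equal(Sw0, t(kp$W) %*% Kc %*% t(Kc) %*% kp$W, tolerance = 1e-8)
})

test_that("the geometry transform is exact at eta = 0 and its powers invert each other", {
  set.seed(6)
  A <- matrix(rnorm(36), 6); Sw <- crossprod(A)
  g0 <- geometry_transform(Sw, eta = 0, N = 10)
  expect_equal(g0$S_half, diag(6), tolerance = 1e-12)
  expect_equal(g0$S_invhalf, diag(6), tolerance = 1e-12)
  g <- geometry_transform(Sw, eta = 2, N = 10)
  expect_equal(g$S_half %*% g$S_half, g$S, tolerance = 1e-8)
  expect_equal(g$S_invhalf %*% g$S %*% g$S_invhalf, diag(6), tolerance = 1e-8)
  expect_equal(g$S_inv %*% g$S, diag(6), tolerance = 1e-8)
  # condition number grows with eta
  cond <- vapply(c(0.5, 2, 8, 32), function(e) {
    kappa(geometry_transform(Sw, e, 10)$S, exact = TRUE)
  }, 0)
  expect_true(all(diff(cond) > 0))
  expect_error(geometry_transform(Sw, -1, 10), "eta")
})

test_that("the classifier satisfies its dual constraints and separates a separable set", {
  set.seed(7)
  X <- rbind(matrix(rnorm(60, 0, 0.3), 30), matrix(rnorm(60, 3, 0.3), 30))
  y <- rep(c(-1, 1), each = 30)
  m <- csvc_fit(X, y, C = 10, r = 2, eta = 2, t = 5)
  expect_lt(abs(sum(m$alpha_y)), 1e-6)
  expect_lte(max(abs(m$alpha_y)), 10 + 1e-8)
  pred <- csvc_decision(m, X)
  expect_equal(pred$class, y)
  # margin constraints on non-support points
  non_sv <- setdiff(seq_len(60), m$sv_index)
  expect_true(all(y[non_sv] * pred$score[non_sv] >= 1 - 1e-6))
  expect_true(all(pred$prob >= 0 & pred$prob <= 1))
  # continuity of the decision score
  x0 <- X[1, , drop = FALSE]
  expect_lt(abs(csvc_decision(m, x0 + 1e-6)$score - pred$score[1]), 1e-3)
  expect_error(csvc_fit(X, rep(1, 60)), "both classes")
})

test_that("kernel-form and transformed-linear decisions coincide", {
  set.seed(8)
  X <- two_moons(40, noise = 0.15, seed = 3)
  y <- rep(c(-1, 1), each = 40)
  for (eta in c(0, 2)) {
    m <- csvc_fit(X, y, C = 0.5, r = 2, eta = eta, t = 7)
    Xt <- two_moons(15, noise = 0.15, seed = 4)
    lin <- csvc_decision(m, Xt, route = "linear")
    ker <- csvc_decision(m, Xt, route = "kernel")
    expect_lt(max(abs(lin$score - ker$score)), 1e-8)
  }
})

test_that("the box codec matches its closed form and round-trips exactly", {
  expect_equal(bbox_encode(c(10, 10, 4, 4), c(10, 10, 4, 4)), c(z1 = 0, z2 = 0, z3 = 1, z4 = 1))
  expect_equal(bbox_encode(c(10, 10, 4, 4), c(12, 10, 8, 4)),
               c(z1 = 0.5, z2 = 0, z3 = 2, z4 = 1))
  expect_equal(unname(bbox_decode(c(5, 6, 2, 3), c(0, 0, 1, 1))), c(5, 6, 2, 3))
  set.seed(9)
  for (i in 1:25) {
    a <- c(runif(2, 5, 50), runif(2, 2, 20))
    p <- c(runif(2, 5, 50), runif(2, 2, 20))
    expect_equal(unname(bbox_decode(a, bbox_encode(a, p))), p,
                 tolerance = 1e-12)
  }
  # clipping keeps the box inside the frame
  out <- bbox_decode(c(30, 30, 20, 20), c(2, 2, 3, 3), bounds = c(64, 64))
  expect_lte(out["x_center"] + out["width"] / 2, 64)
  expect_lte(out["y_center"] + out["height"] / 2, 64)
  expect_error(bbox_encode(c(1, 1, 0, 2), c(1, 1, 1, 1)), "positive")
  expect_error(bbox_decode(c(1, 1, 2, 2), c(0, 0, -1, 1)), "positive")
})

test_that("the regressor honors its dead zone, descends its objective and recovers low-rank maps", {
  set.seed(10)
  n <- 40
  X <- matrix(runif(n * 5), n)
  K <- gaussian_gram(X, r = 2); Kc <- center_gram(K)
  Phi <- Kc %*% kpca_fit(Kc)$W
  A0 <- matrix(0, ncol(Phi), 4)
  A0[1, ] <- c(0.6, -0.4, 0.5, 0.3); A0[2, ] <- c(-0.3, 0.5, 0.2, -0.6)
  Z <- Phi %*% A0 + matrix(c(1, -1, 2, 0), n, 4, byrow = TRUE)
  # dead zone: a zone wider than the target spread leaves B = 0
  m0 <- msvr_fit(X, Z, C = 2, epsilon = 50, r = 2, eta = 0, t = 5)
  expect_equal(max(abs(m0$B)), 0)
  expect_equal(msvr_predict(m0, X[1:3, ]),
               matrix(m0$b, 3, 4, byrow = TRUE), tolerance = 1e-12)
  # recovery: with the loss dominating, residual norms fall inside the zone
  m <- suppressWarnings(msvr_fit(X, Z, C = 1e5, epsilon = 0.5, r = 2,
                                 eta = 0, t = 5, tol = 1e-10,
                                 max_iter = 1000))
  u <- sqrt(rowSums((Z - msvr_predict(m, X))^2))
  expect_gte(mean(u <= 0.5 + 1e-6), 0.95)
  expect_true(all(diff(m$trace) <= 1e-12))
  expect_error(msvr_fit(X[1:3, ], Z[1:3, ]), "5 samples")
  expect_error(msvr_fit(X, Z * Inf), "finite")
})

test_that("regressor kernel-form and transformed-linear predictions coincide", {
  set.seed(11)
  n <- 30
  X <- matrix(runif(n * 4), n)
  Z <- cbind(X %*% rnorm(4), X %*% rnorm(4), rnorm(n), rnorm(n))
  for (eta in c(0, 2)) {
    m <- suppressWarnings(msvr_fit(X, Z, C = 1, epsilon = 0.1, r = 2,
                                   eta = eta, t = 5))
    Xt <- matrix(runif(10 * 4), 10)
    expect_lt(max(abs(msvr_predict(m, Xt) -
                        msvr_predict(m, Xt, route = "kernel"))), 1e-8)
  }
})
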