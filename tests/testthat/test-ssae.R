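test_that("the KL sparsity penalty evaluates to its closed form and is non-negative", {
  expect_equal(kl_sparsity(0.2, rep(0.2, 8)), 0)
  expect_equal(kl_sparsity(0.2, 0.5), 0.2 * log(0.4) + 0.8 * log(1.6),
               tolerance = 1e-12)
  set.seed(1)
  for (i in 1:20) expect_gte(kl_sparsity(runif(1, .05, .95), runif(6, .05, .95)), 0)
  expect_error(kl_sparsity(0, 0.5), "strictly")
  expect_error(kl_sparsity(0.2, c(0.3, 1)), "strictly")
})

test_that("analytic gradients match central finite differences to 1e-6 relative", {
  set.seed(2)
  v <- 6L; h <- 4L
  layer <- list(W1 = matrix(rnorm(h * v, 0, 0.5), h), b1 = rnorm(h, 0, 0.1),
                W2 = matrix(rnorm(v * h, 0, 0.5), v), b2 = rnorm(v, 0, 0.1))
  X <- matrix(runif(v * 10), v)
  cg <- sae_cost_grad(layer, X, lambda = 1e-2, beta = 0.3, rho = 0.2)
  theta <- c(layer$W1, layer$b1, layer$W2, layer$b2)
  fn <- function(th) {
    l <- myodetect:::sae_unpack(th, v, h)
    sae_cost_grad(l, X, 1e-2, 0.3, 0.2)$cost
  }
  eps <- 1e-6
  num <- vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (fn(tp) - fn(tm)) / (2 * eps)
  }, 0)
  ana <- c(cg$grad$W1, cg$grad$b1, cg$grad$W2, cg$grad$b2)
  expect_lt(max(abs(ana - num) / pmax(abs(num), 1e-8)), 1e-6)
})

test_that("the cost decomposes exactly and is linear in lambda", {
  set.seed(3)
  layer <- list(W1 = matrix(rnorm(12, 0, .3), 3), b1 = rnorm(3),
                W2 = matrix(rnorm(12, 0, .3), 4), b2 = rnorm(4))
  X <- matrix(runif(4 * 6), 4)
  cg <- sae_cost_grad(layer, X, 0.02, 0.3, 0.2)
  expect_equal(cg$cost, cg$recon + cg$weight + cg$sparse, tolerance = 1e-12)
  cg2 <- sae_cost_grad(layer, X, 0.04, 0.3, 0.2)
  expect_equal(cg2$weight, 2 * cg$weight, tolerance = 1e-12)
  expect_equal(cg2$recon, cg$recon)
  cg0 <- sae_cost_grad(layer, X, 0, 0, 0.2)
  expect_equal(cg0$cost, cg0$recon)
  expect_error(sae_cost_grad(layer, X * NA, 0.02, 0.3, 0.2), "NaN")
})

test_that("layer training descends from its initialization, hits the sparsity target and is seeded", {
  set.seed(5)
  X <- sapply(1:500, function(i) {
    f <- matrix(0, 8, 8)
    f[sample(1:8, 1), ] <- 1; f[, sample(1:8, 1)] <- 1
    as.vector(f) * runif(1, 0.5, 1)
  })
  l <- sae_train(X, 16, lambda = 1e-2, beta = 0.3, rho = 0.2, maxit = 150,
                 seed = 1)
  expect_lte(l$cost, l$init_cost)
  expect_gte(mean(l$rho_hat), 0.1)
  expect_lte(mean(l$rho_hat), 0.4)
  l2 <- sae_train(X, 16, lambda = 1e-2, beta = 0.3, rho = 0.2, maxit = 150,
                  seed = 1)
  expect_identical(l$W1, l2$W1)
})

test_that("greedy pretraining stacks layers on the previous activations", {
  set.seed(6)
  X <- matrix(runif(64 * 120), 64)
  m <- ssae_pretrain(X, c(64L, 32L, 16L), maxit = 40, seed = 2)
  expect_length(m$layers, 2L)
  expect_equal(dim(m$layers[[1]]$W1), c(32L, 64L))
  expect_equal(dim(m$layers[[2]]$W1), c(16L, 32L))
  # layer-2 training inputs are the layer-1 activations
  A1 <- 1 / (1 + exp(-(m$layers[[1]]$W1 %*% X + m$layers[[1]]$b1)))
  l2 <- sae_train(A1, 16L, m$lambda, m$beta, m$rho, maxit = 40, seed = 2 + 2)
  expect_identical(m$layers[[2]]$W1, l2$W1)
  # a single layer reduces to sae_train
  m1 <- ssae_pretrain(X, c(64L, 32L), maxit = 40, seed = 2)
  l1 <- sae_train(X, 32L, m1$lambda, m1$beta, m1$rho, maxit = 40, seed = 3)
  expect_identical(m1$layers[[1]]$W1, l1$W1)
  expect_equal(ncol(ssae_encode(m, t(X))), 16L)
  expect_error(ssae_pretrain(X, c(64L, 16L, 32L)), "decreasing")
  expect_error(ssae_pretrain(X, c(32L, 16L)), "mismatch")
})

test_that("fine-tuning separates a separable two-class set and normalizes the head", {
  set.seed(7)
  n <- 40
  X <- cbind(matrix(runif(64 * n, 0.7, 1), 64), matrix(runif(64 * n, 0, 0.3), 64))
  y <- rep(c(1, 0), each = n)
  m <- ssae_pretrain(X, c(64L, 32L, 16L), maxit = 80, seed = 2)
  m <- ssae_finetune(m, X, y, epochs = 30, batch = 16, seed = 3)
  P <- ssae_predict_prob(m, t(X))
  expect_equal(unname(rowSums(P)), rep(1, 2 * n), tolerance = 1e-12)
  expect_equal(mean((P[, "positive"] > 0.5) == (y == 1)), 1)
  expect_error(ssae_finetune(m, X, rep(1, 2 * n)), "both classes")
  # frozen encoder: only the head moves
  m2 <- ssae_finetune(m, X, y, epochs = 2, batch = 16, seed = 4,
                      freeze_encoder = TRUE)
  expect_identical(m2$layers[[1]]$W1, m$layers[[1]]$W1)
  expect_false(identical(m2$head$W, m$head$W))
})

test_that("encoding is deterministic, bounded and batch-order invariant", {
  set.seed(8)
  X <- matrix(runif(64 * 30), 64)
  m <- ssae_pretrain(X, c(64L, 32L, 16L), maxit = 30, seed = 1)
  F1 <- ssae_encode(m, t(X))
  expect_true(all(F1 > 0 & F1 < 1))
  expect_identical(F1, ssae_encode(m, t(X)))
  ord <- sample(30)
  expect_equal(ssae_encode(m, t(X)[ord, ]), F1[ord, ], tolerance = 1e-14)
  expect_identical(F1[3, ], ssae_encode(m, t(X)[c(3, 3), ])[2, ])
  expect_error(ssae_encode(m, matrix(0.1, 2, 10)), "crop size")
})

test_that("crop preparation resizes to tau x tau in [0, 1]", {
  sl <- make_slice(phantom_params(seed = 4))
  cr <- prepare_crop(sl$image, as.numeric(sl$gt), 24)
  expect_equal(dim(cr), c(24L, 24L))
  expect_gte(min(cr), 0); expect_lte(max(cr), 1)
  # pool-centered crops differ from background crops after encoding
  set.seed(9)
  m <- ssae_pretrain(matrix(runif(576 * 80), 576), c(576L, 60L, 20L),
                     maxit = 25, seed = 1, tau = 24)
  bg <- prepare_crop(sl$image, c(20, 20, 20, 20), 24)
  f <- ssae_encode(m, list(cr, bg))
  expect_gt(sqrt(sum((f[1, ] - f[2, ])^2)), 0)
  expect_error(ssae_layer_sizes(17), "preset")
  expect_equal(ssae_layer_sizes(60), c(3600L, 1600L, 750L, 350L))
})
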