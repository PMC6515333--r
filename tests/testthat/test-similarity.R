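test_that("log-Gabor filters peak at their center frequency and have no DC response", {
  bank <- build_log_gabor_bank(c(64, 64), n_scales = 3, n_orientations = 4)
  for (j in seq_len(4)) for (n in seq_len(3)) {
    f <- bank$filters[[j]][[n]]
    expect_identical(f[1, 1], 0)
    expect_true(all(f >= 0))
    expect_lte(max(f), 1 + 1e-12)
  }
  # the radial profile reaches 1 at omega = omega0 along the filter orientation
  wl <- bank$min_wavelength
  expect_gt(max(bank$filters[[1]][[1]]), 0.99)
  expect_error(build_log_gabor_bank(c(64, 64), min_wavelength = 0), "positive")
  expect_error(build_log_gabor_bank(c(4, 4)), "8")
})

test_that("two-sided orientation coverage of the bank is rotation-invariant up to the grid", {
  bank <- build_log_gabor_bank(c(64, 64), n_scales = 1, n_orientations = 6)
  total <- Reduce(`+`, lapply(bank$filters, `[[`, 1))
  # the filters are one-sided quadrature pairs: a real image excites a
  # frequency and its conjugate together, so coverage is assessed on
  # antipodal frequency pairs around a mid-frequency ring
  H <- 64
  idx <- function(a, r) {
    fx <- round(r * cos(a)); fy <- round(r * sin(a))
    c((fy %% H) + 1, (fx %% H) + 1)
  }
  angs <- seq(0, pi, length.out = 19)[-19]
  vals <- vapply(angs, function(a) {
    ij <- idx(a, 10); ji <- idx(a + pi, 10)
    total[ij[1], ij[2]] + total[ji[1], ji[2]]
  }, 0)
  expect_lt(stats::sd(vals) / mean(vals), 0.15)
})

test_that("phase congruency is zero on flat images, peaks on edges, and is contrast invariant", {
  bank <- build_log_gabor_bank(c(128, 128))
  flat <- matrix(0.5, 128, 128)
  expect_lt(max(phase_congruency(flat, bank)), 1e-6)
  step <- cbind(matrix(0, 128, 64), matrix(1, 128, 64))
  pc <- phase_congruency(step, bank)
  expect_true(all(pc >= 0) && all(pc <= 1 + 1e-9))
  # the edge column carries the maximal congruency (interior columns away
  # from the image-wrap seam)
  cm <- colMeans(pc)[10:119]
  expect_equal(sort(which.max(cm) + 9), 64)
  expect_gt(mean(pc[, 64:65]), mean(pc[, 54]))
  # with noise-energy compensation the edge dominates sharply
  pcn <- phase_congruency(step, bank, noise_comp = TRUE)
  expect_gt(mean(pcn[, 64:65]), 2 * mean(pcn[, 54]))
  # contrast invariance of the ratio, away from the amplitude floor
  pc0 <- phase_congruency(step, bank, eps_amp = 1e-9)
  pc2 <- phase_congruency(2 * step, bank, eps_amp = 1e-9)
  mask <- pc0 > 0.1
  expect_lt(max(abs(pc2[mask] - pc0[mask]) / pc0[mask]), 1e-6)
  expect_error(phase_congruency(matrix(0, 32, 32), bank), "shape")
})

test_that("the ratio-form measures evaluate to their closed-form values", {
  expect_equal(s_pm(0.3, 0.3, 0.01), 1)
  expect_equal(s_pm(0, 0, 0.01), 1)
  expect_equal(s_pm(1, 0, 0.01), 0.01 / 1.01, tolerance = 1e-12)
  expect_equal(s_im(0.7, 0.7, 1e-4), 1)
  expect_equal(s_im(3, 1, 1e-12), 0.6, tolerance = 1e-8)
  expect_equal(s_cm(2, 2, 1e-4), 1)
  expect_equal(s_cm(2, 0, 0.01), 0.01 / 4.01, tolerance = 1e-12)
  # contrast measure is less sensitive at high base contrast
  expect_gt(s_cm(10, 11, 0.01), s_cm(1, 2, 0.01))
  expect_equal(s_dm(c(1, 2), c(1, 2), 3), 1)
  expect_equal(s_dm(c(0, 0), c(5, 5), 0), 1)
  expect_equal(s_dm(c(0, 0), c(1, 0), log(2)), 0.5, tolerance = 1e-12)
  # intensity measure decreases with |mu_u - mu_v| at fixed sum
  sums <- vapply(seq(0, 0.9, by = 0.1),
                 function(d) s_im(1 + d, 1 - d, 1e-4), 0)
  expect_true(all(diff(sums) < 0))
})

test_that("the structure measure folds anti-correlation and kills orthogonal patterns", {
  u <- c(1, 2, 3, 4, 2, 1, 0, 5, 3)
  expect_equal(s_sm(u, u, 1e-4), 1)
  expect_equal(s_sm(u, -u + 10, 1e-12), 1)
  a <- c(1, -1, 1, -1); b <- c(1, 1, -1, -1) # orthogonal, zero-mean
  expect_lt(s_sm(a, b, 1e-12), 1e-10)
  expect_error(s_sm(1:4, 1:5), "mismatch")
})

test_that("patch statistics use the d-1 denominator and mirror the borders", {
  img <- matrix(runif(400), 20)
  img[5:7, 5:7] <- matrix(1:9, 3)
  st <- patch_stats(img, c(6, 6), 3)
  expect_equal(st$mean, 5)
  expect_equal(st$sd^2, 7.5)
  flat <- matrix(0.5, 9, 9)
  expect_equal(patch_stats(flat, c(5, 5), 3)$sd, 0)
  # corner patch mirrors into the interior: same mean as its reflection
  c1 <- patch_stats(img, c(1, 1), 5)
  expect_equal(c1$mean, mean(img[c(2:3, 1, 2:3), c(2:3, 1, 2:3)]))
  expect_error(patch_stats(img, c(5, 5), 4), "odd")
})

test_that("hybrid similarity is the product of its five factors and is symmetric", {
  set.seed(3)
  img <- matrix(runif(64 * 64), 64)
  bank <- build_log_gabor_bank(c(64, 64))
  pc <- phase_congruency(img, bank)
  cfg <- similarity_config(alpha = 0.01)
  u <- c(20, 30); v <- c(35, 22)
  S <- hybrid_similarity(u, v, cfg, "patch", img, pc)
  su <- patch_stats(img, u, cfg$p); sv <- patch_stats(img, v, cfg$p)
  manual <- s_pm(pc[u[1], u[2]], pc[v[1], v[2]], cfg$c1) *
    s_im(su$mean, sv$mean, cfg$c2) * s_cm(su$sd, sv$sd, cfg$c3) *
    s_sm(su$patch, sv$patch, cfg$c4) *
    s_dm(rev(u) - 0.5, rev(v) - 0.5, 0.01)
  expect_equal(S, manual, tolerance = 1e-12)
  expect_equal(S, hybrid_similarity(v, u, cfg, "patch", img, pc),
               tolerance = 1e-12)
  expect_equal(hybrid_similarity(u, u, cfg, "patch", img, pc), 1)
  cfg0 <- similarity_config(alpha = 0.01, beta = rep(0, 5))
  expect_equal(hybrid_similarity(u, v, cfg0, "patch", img, pc), 1)
})

test_that("every measure stays in (0, 1] and is symmetric on random inputs", {
  set.seed(7)
  for (i in 1:50) {
    p1 <- runif(1); p2 <- runif(1); m1 <- runif(1, 0, 3); m2 <- runif(1, 0, 3)
    s1 <- runif(1, 0, 2); s2 <- runif(1, 0, 2)
    u <- runif(2, 0, 50); v <- runif(2, 0, 50)
    vals <- c(s_pm(p1, p2, 1e-4), s_im(m1, m2, 1e-4), s_cm(s1, s2, 1e-4),
              s_dm(u, v, 0.01))
    expect_true(all(vals > 0 & vals <= 1 + 1e-12))
    expect_equal(s_pm(p1, p2, 1e-4), s_pm(p2, p1, 1e-4))
    expect_equal(s_im(m1, m2, 1e-4), s_im(m2, m1, 1e-4))
    expect_equal(s_cm(s1, s2, 1e-4), s_cm(s2, s1, 1e-4))
    expect_equal(s_dm(u, v, 0.01), s_dm(v, u, 0.01))
    a <- runif(16); b <- runif(16)
    expect_equal(s_sm(a, b, 1e-4), s_sm(b, a, 1e-4))
  }
})

test_that("region-mode similarity uses region summaries and centroid coordinates", {
  img <- rbind(cbind(matrix(0.2, 16, 16), matrix(0.8, 16, 16)),
               cbind(matrix(0.8, 16, 16), matrix(0.2, 16, 16)))
  labels <- rbind(cbind(matrix(1L, 16, 16), matrix(2L, 16, 16)),
                  cbind(matrix(3L, 16, 16), matrix(4L, 16, 16)))
  st <- region_stats(img, labels, n_bins = 32)
  cfg <- similarity_config(alpha = 0)
  # identical-content diagonal regions are more similar than contrasting ones
  s_same <- hybrid_similarity(st[[1]], st[[4]], cfg, "region")
  s_diff <- hybrid_similarity(st[[1]], st[[2]], cfg, "region")
  expect_gt(s_same, s_diff)
  expect_equal(hybrid_similarity(st[[2]], st[[3]], cfg, "region"),
               hybrid_similarity(st[[3]], st[[2]], cfg, "region"))
  expect_error(hybrid_similarity(list(n = 0), st[[1]], cfg, "region"), "empty")
})
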