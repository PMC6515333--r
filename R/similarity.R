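#' Similarity configuration
#'
#' Collects the tunable constants of the hybrid patch/region similarity: the
#' patch side \code{p}, the stabilizing constants \code{c1..c4} of the
#' ratio-form measures, the coordinate decay \code{alpha} (defaulting to
#' \code{2K/N} when the superpixel count is known), the five exponents
#' \code{beta}, and the log-Gabor filter-bank settings used for phase
#' congruency.
#'
#' Images are min-max normalized to \code{[0, 1]} per slice before similarity
#' computation, so the SSIM-style default \code{c = (0.01 * L)^2} with
#' \code{L = 1} applies to every constant.
#'
#' @param p odd patch side (7 or 9 work well on cardiac slices).
#' @param c1,c2,c3,c4 positive stabilizing constants for the phase-congruency,
#'   intensity, contrast and structure measures.
#' @param alpha coordinate-measure decay in 1/pixels^2; \code{NULL} means
#'   "derive as 2K/N from the superpixel count at use time".
#' @param beta numeric length-5 exponents of the five similarity factors.
#' @param n_scales,n_orientations log-Gabor bank size.
#' @param min_wavelength smallest filter wavelength in pixels.
#' @param mult wavelength multiplier between successive scales.
#' @param sigma_ratio ratio defining the radial log-Gaussian bandwidth
#'   (sigma/omega0 of the log-frequency Gaussian).
#' @param sigma_theta_frac angular bandwidth as a fraction of the orientation
#'   spacing \code{pi/n_orientations}.
#' @param eps_amp amplitude floor added to the phase-congruency denominator
#'   (the ratio is 0/0 on flat regions).
#' @param pc_patch_center if \code{TRUE} (default) patch-mode phase congruency
#'   uses the value at the patch center; otherwise the patch mean.
#' @param n_bins histogram bins for the region-mode structure term.
#' @return Object of class \code{similarity_config}.
#' @export
similarity_config <- function(p = 9L, c1 = 1e-4, c2 = 1e-4, c3 = 1e-4,
                              c4 = 1e-4, alpha = NULL, beta = rep(1, 5),
                              n_scales = 4L, n_orientations = 6L,
                              min_wavelength = 3, mult = 2.1,
                              sigma_ratio = 0.55, sigma_theta_frac = 0.6,
                              eps_amp = 1e-4, pc_patch_center = TRUE,
                              n_bins = 32L) {
  if (p %% 2 == 0) stop("patch side p must be odd")
  if (any(c(c1, c2, c3, c4) <= 0)) stop("c1..c4 must be positive")
  if (length(beta) != 5L) stop("beta must have length 5")
  structure(list(p = as.integer(p), c1 = c1, c2 = c2, c3 = c3, c4 = c4,
                 alpha = alpha, beta = beta, n_scales = as.integer(n_scales),
                 n_orientations = as.integer(n_orientations),
                 min_wavelength = min_wavelength, mult = mult,
                 sigma_ratio = sigma_ratio, sigma_theta_frac = sigma_theta_frac,
                 eps_amp = eps_amp, pc_patch_center = isTRUE(pc_patch_center),
                 n_bins = as.integer(n_bins)),
            class = "similarity_config")
}

#' Build a 2-D log-Gabor quadrature filter bank
#'
#' Frequency-domain filters
#' \deqn{G(\omega, \theta) = \exp(-\log(\omega/\omega_0)^2 / (2\sigma_r^2))
#'       \exp(-(\theta - \theta_j)^2 / (2\sigma_\theta^2))}
#' on the discrete frequency grid of an \code{H x W} image, with the DC bin
#' forced to zero. The angular term is one-sided (centered on \eqn{\theta_j}
#' only), so inverse-transforming a filtered image yields the even (real) and
#' odd (imaginary) quadrature responses.
#'
#' @param shape integer \code{c(H, W)}, both at least 8.
#' @param n_scales,n_orientations bank size.
#' @param min_wavelength smallest wavelength in pixels (center frequency
#'   \code{omega0 = 1/wavelength} must be positive).
#' @param mult scale multiplier.
#' @param sigma_ratio radial bandwidth ratio (log-Gaussian).
#' @param sigma_theta angular standard deviation in radians; default
#'   \code{0.6 * pi / n_orientations}.
#' @return Object of class \code{log_gabor_bank} with
#'   \code{filters[[orientation]][[scale]]} frequency-domain matrices.
#' @export
build_log_gabor_bank <- function(shape, n_scales = 4L, n_orientations = 6L,
                                 min_wavelength = 3, mult = 2.1,
                                 sigma_ratio = 0.55, sigma_theta = NULL) {
  H <- shape[1L]; W <- shape[2L]
  if (H < 8 || W < 8) stop("image must be at least 8 x 8")
  if (min_wavelength <= 0) stop("center frequency must be positive")
  if (is.null(sigma_theta)) sigma_theta <- 0.6 * pi / n_orientations
  fx <- ifftshift_vec(((seq_len(W) - 1) - floor(W / 2)) / W)
  fy <- ifftshift_vec(((seq_len(H) - 1) - floor(H / 2)) / H)
  FX <- matrix(rep(fx, each = H), H)
  FY <- matrix(rep(fy, W), H)
  radius <- sqrt(FX^2 + FY^2)
  radius[1L, 1L] <- 1 # avoid log(0); DC is zeroed below
  theta <- atan2(-FY, FX)
  sig_log <- abs(log(sigma_ratio))
  orients <- (seq_len(n_orientations) - 1) * pi / n_orientations
  filters <- vector("list", n_orientations)
  for (j in seq_len(n_orientations)) {
    dtheta <- theta - orients[j]
    dtheta <- atan2(sin(dtheta), cos(dtheta)) # wrap to (-pi, pi]
    spread <- exp(-dtheta^2 / (2 * sigma_theta^2))
    filters[[j]] <- vector("list", n_scales)
    for (n in seq_len(n_scales)) {
      wl <- min_wavelength * mult^(n - 1)
      omega0 <- 1 / wl
      radial <- exp(-(log(radius / omega0))^2 / (2 * sig_log^2))
      f <- radial * spread
      f[1L, 1L] <- 0
      filters[[j]][[n]] <- f
    }
  }
  structure(list(filters = filters, shape = c(H, W), n_scales = n_scales,
                 n_orientations = n_orientations, orientations = orients,
                 min_wavelength = min_wavelength, mult = mult,
                 sigma_ratio = sigma_ratio, sigma_theta = sigma_theta),
            class = "log_gabor_bank")
}

ifftshift_vec <- function(v) {
  n <- length(v)
  c(v[(floor(n / 2) + 1):n], v[seq_len(floor(n / 2))])
}

#' Per-pixel phase congruency
#'
#' Filters the image with the quadrature log-Gabor bank and forms, per pixel,
#' the ratio of summed orientation energies to the total amplitude:
#' \deqn{PC(u) = \sum_j E_{\theta_j}(u) /
#'       (\sum_n \sum_j A_{n,\theta_j}(u) + \epsilon_A)}
#' where \eqn{A_{n,\theta_j} = \sqrt{e^2 + o^2}} is the local amplitude and
#' \eqn{E_{\theta_j} = \sqrt{(\sum_n e)^2 + (\sum_n o)^2}} the local energy
#' along orientation \eqn{\theta_j}. The ratio lies in \code{[0, 1]} and is
#' invariant to a positive rescaling of the image.
#'
#' @param image numeric matrix, finite-valued.
#' @param bank a [build_log_gabor_bank()] object matching the image shape.
#' @param eps_amp amplitude floor for the denominator.
#' @param noise_comp if \code{TRUE}, subtract a per-orientation noise-energy
#'   threshold (the classical extension, estimated as \code{noise_k} times the
#'   mean smallest-scale amplitude) from each orientation energy before
#'   summing. Off by default: the plain energy-over-amplitude ratio is used.
#'   Without compensation the ratio saturates wherever the responses of the
#'   few active scales are mutually in phase, however weak — sharp edges are
#'   still the per-image maxima, but weak-structure pixels do not score near
#'   zero.
#' @param noise_k noise-threshold multiplier when \code{noise_comp} is on.
#' @return Matrix of phase-congruency values in \code{[0, 1]}.
#' @export
phase_congruency <- function(image, bank, eps_amp = 1e-4, noise_comp = FALSE,
                             noise_k = 2) {
  if (!all(is.finite(image))) stop("image must be finite-valued")
  if (!identical(dim(image), as.integer(bank$shape)))
    stop("image shape does not match the filter bank")
  Fimg <- stats::fft(image)
  HW <- length(image)
  sumE <- matrix(0, nrow(image), ncol(image))
  sumA <- matrix(0, nrow(image), ncol(image))
  for (j in seq_len(bank$n_orientations)) {
    se <- matrix(0, nrow(image), ncol(image))
    so <- matrix(0, nrow(image), ncol(image))
    A1 <- NULL
    for (n in seq_len(bank$n_scales)) {
      resp <- stats::fft(Fimg * bank$filters[[j]][[n]], inverse = TRUE) / HW
      e <- Re(resp); o <- Im(resp)
      A <- sqrt(e^2 + o^2)
      if (n == 1L) A1 <- A
      sumA <- sumA + A
      se <- se + e; so <- so + o
    }
    Ej <- sqrt(se^2 + so^2)
    if (noise_comp) Ej <- pmax(Ej - noise_k * mean(A1) * bank$n_scales, 0)
    sumE <- sumE + Ej
  }
  sumE / (sumA + eps_amp)
}

#' Pairwise similarity measures
#'
#' The five ratio-form measures combined by [hybrid_similarity()]: phase
#' congruency \code{s_pm}, intensity \code{s_im}, contrast \code{s_cm},
#' structure \code{s_sm} and coordinate \code{s_dm}. Each is symmetric, lies
#' in \code{(0, 1]} and equals 1 for identical arguments.
#'
#' @param pc_u,pc_v phase-congruency values in \code{[0, 1]}.
#' @param c1,c2,c3,c4 positive stabilizing constants.
#' @name similarity_measures
NULL

#' @rdname similarity_measures
#' @export
s_pm <- function(pc_u, pc_v, c1 = 1e-4) {
  (2 * pc_u * pc_v + c1) / (pc_u^2 + pc_v^2 + c1)
}

#' @rdname similarity_measures
#' @param mu_u,mu_v patch or region mean intensities.
#' @export
s_im <- function(mu_u, mu_v, c2 = 1e-4) {
  (2 * mu_u * mu_v + c2) / (mu_u^2 + mu_v^2 + c2)
}

#' @rdname similarity_measures
#' @param sigma_u,sigma_v patch or region standard deviations (\code{>= 0}).
#' @export
s_cm <- function(sigma_u, sigma_v, c3 = 1e-4) {
  (2 * sigma_u * sigma_v + c3) / (sigma_u^2 + sigma_v^2 + c3)
}

#' @rdname similarity_measures
#' @param patch_u,patch_v equal-length numeric vectors (patch intensities, or
#'   histogram densities in region mode).
#' @details The structure measure is
#'   \code{|2 * cov(u, v) + c4| / (sd(u) * sd(v) + c4)} with \code{d - 1}
#'   denominators, clipped to \code{[0, 1]}; the absolute value folds perfect
#'   anti-correlation onto 1.
#' @export
s_sm <- function(patch_u, patch_v, c4 = 1e-4) {
  if (length(patch_u) != length(patch_v)) stop("patch size mismatch")
  d <- length(patch_u)
  mu <- mean(patch_u); mv <- mean(patch_v)
  suv <- sum((patch_u - mu) * (patch_v - mv)) / (d - 1)
  su <- sqrt(sum((patch_u - mu)^2) / (d - 1))
  sv <- sqrt(sum((patch_v - mv)^2) / (d - 1))
  min(1, max(0, abs(2 * suv + c4) / (su * sv + c4)))
}

#' @rdname similarity_measures
#' @param u,v numeric \code{c(x, y)} pixel coordinates (or region centroids).
#' @param alpha coordinate decay in 1/pixels^2 (\code{>= 0}).
#' @export
s_dm <- function(u, v, alpha) {
  if (alpha < 0) stop("alpha must be >= 0")
  exp(-alpha * sum((u - v)^2))
}

#' Patch statistics at a pixel
#'
#' Extracts the \code{p x p} patch centered on pixel \code{center} (mirror
#' padding at the borders) and returns its mean, standard deviation
#' (\code{d - 1} denominator) and intensity vector.
#'
#' @param image numeric matrix.
#' @param center integer \code{c(row, col)}, 1-based.
#' @param p odd patch side.
#' @return List with \code{mean}, \code{sd}, \code{patch} (length \code{p^2})
#'   and \code{center}.
#' @export
patch_stats <- function(image, center, p = 9L) {
  if (p %% 2 == 0) stop("patch side p must be odd")
  half <- p %/% 2
  H <- nrow(image); W <- ncol(image)
  mirror <- function(q, n) {
    while (any(bad <- q < 1 | q > n)) {
      q[q < 1] <- 2 - q[q < 1]
      q[q > n] <- 2 * n - q[q > n]
    }
    q
  }
  rows <- mirror(center[1L] + (-half:half), H)
  cols <- mirror(center[2L] + (-half:half), W)
  patch <- as.vector(image[rows, cols])
  list(mean = mean(patch), sd = stats::sd(patch), patch = patch,
       center = center)
}

#' Hybrid similarity of two locations or regions
#'
#' Combines the five measures as
#' \deqn{S = S_{pm}^{\beta_1} S_{im}^{\beta_2} S_{cm}^{\beta_3}
#'           S_{sm}^{\beta_4} S_{dm}^{\beta_5}.}
#' In patch mode \code{u} and \code{v} are pixel positions \code{c(row, col)}
#' and the statistics come from \code{p x p} patches (phase congruency at the
#' patch center by default). In region mode \code{u} and \code{v} are region
#' summaries as produced by [region_stats()] — mean/sd over all region pixels,
#' mean phase congruency, centroid, and a histogram whose correlation supplies
#' the structure term (regions differ in size, so per-pixel correlation is
#' undefined).
#'
#' @param u,v pixel positions (patch mode) or region summary lists (region
#'   mode).
#' @param cfg a [similarity_config()].
#' @param mode \code{"patch"} or \code{"region"}.
#' @param image,pc image and phase-congruency matrices (patch mode only; the
#'   image should be min-max normalized to \code{[0, 1]}).
#' @param alpha coordinate decay; defaults to \code{cfg$alpha}.
#' @return Similarity in \code{(0, 1]}.
#' @export
hybrid_similarity <- function(u, v, cfg = similarity_config(),
                              mode = c("patch", "region"),
                              image = NULL, pc = NULL, alpha = NULL) {
  mode <- match.arg(mode)
  if (is.null(alpha)) alpha <- if (is.null(cfg$alpha)) 0 else cfg$alpha
  b <- cfg$beta
  if (mode == "patch") {
    if (is.null(image) || is.null(pc)) stop("patch mode needs image and pc")
    su <- patch_stats(image, u, cfg$p); sv <- patch_stats(image, v, cfg$p)
    pcu <- if (cfg$pc_patch_center) pc[u[1L], u[2L]] else
      patch_stats(pc, u, cfg$p)$mean
    pcv <- if (cfg$pc_patch_center) pc[v[1L], v[2L]] else
      patch_stats(pc, v, cfg$p)$mean
    terms <- c(s_pm(pcu, pcv, cfg$c1), s_im(su$mean, sv$mean, cfg$c2),
               s_cm(su$sd, sv$sd, cfg$c3), s_sm(su$patch, sv$patch, cfg$c4),
               # coordinates as (x, y) = (col - .5, row - .5)
               s_dm(rev(u) - 0.5, rev(v) - 0.5, alpha))
  } else {
    if (is.null(u$n) || is.null(v$n) || u$n < 1 || v$n < 1)
      stop("empty region")
    terms <- c(s_pm(u$pc_mean, v$pc_mean, cfg$c1),
               s_im(u$mean, v$mean, cfg$c2),
               s_cm(u$sd, v$sd, cfg$c3),
               s_sm(u$hist / u$n, v$hist / v$n, cfg$c4),
               s_dm(u$centroid, v$centroid, alpha))
  }
  prod(terms^b)
}

# min-max normalize a slice to [0, 1] (constant slices map to 0)
normalize01 <- function(image) {
  rng <- range(image)
  if (rng[2L] > rng[1L]) (image - rng[1L]) / (rng[2L] - rng[1L])
  else image * 0
}

#' Export a phase-congruency (or any intensity) map as PNG
#'
#' @param map numeric matrix; rescaled to \code{[0, 1]}.
#' @param path output file.
#' @export
write_map_png <- function(map, path) {
  png::writePNG(normalize01(map), path)
  invisible(path)
}
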