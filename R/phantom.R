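#' Parameters for a synthetic short-axis cardiac slice
#'
#' Describes one synthetic short-axis cardiac MR slice: a bright left-ventricle
#' blood pool inside a mid-intensity myocardial annulus, optional papillary
#' muscles inside the pool, an adjacent right-ventricle crescent, a low-signal
#' lung region, a smooth multiplicative bias field and Rician noise.
#'
#' Coordinates are continuous, 0-based; pixel \code{(r, c)} (1-based matrix
#' indices) has its center at \code{(x, y) = (c - 0.5, r - 0.5)}. All bounding
#' boxes in the package use the half-open convention: a box
#' \code{(x_center, y_center, width, height)} covers
#' \code{[x - w/2, x + w/2) x [y - h/2, y + h/2)}.
#'
#' @param image_size integer vector \code{c(H, W)} in pixels.
#' @param lv_center numeric \code{c(x, y)} center of the left ventricle.
#' @param r_endo,r_epi endocardial / epicardial radii in pixels
#'   (\code{0 < r_endo < r_epi < min(H, W)/2}).
#' @param intensity_pool,intensity_myo,intensity_bg,intensity_lung tissue
#'   intensities in \code{[0, 1]}; the pool must be brighter than the
#'   myocardium.
#' @param papillary_count number of dark papillary-muscle spots in the pool.
#' @param rv_present logical, draw a right-ventricle crescent.
#' @param bias_amplitude amplitude of the smooth multiplicative bias field as a
#'   fraction of the dynamic range.
#' @param noise_sigma Rician noise level (intensity units).
#' @param seed integer seed controlling papillary placement, bias-field
#'   coefficients and noise.
#' @return An object of class \code{phantom_params}.
#' @seealso [make_slice()], [make_dataset()]
#' @export
phantom_params <- function(image_size = c(160L, 160L),
                           lv_center = NULL,
                           r_endo = 12, r_epi = 20,
                           intensity_pool = 0.9, intensity_myo = 0.45,
                           intensity_bg = 0.3, intensity_lung = 0.05,
                           papillary_count = 2L, rv_present = TRUE,
                           bias_amplitude = 0.1, noise_sigma = 0.03,
                           seed = 1L) {
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size < 16L))
    stop("image_size must be c(H, W) with H, W >= 16")
  if (is.null(lv_center))
    lv_center <- c(image_size[2L] * 0.55, image_size[1L] * 0.5)
  p <- structure(list(
    image_size = image_size, lv_center = as.numeric(lv_center),
    r_endo = r_endo, r_epi = r_epi,
    intensity_pool = intensity_pool, intensity_myo = intensity_myo,
    intensity_bg = intensity_bg, intensity_lung = intensity_lung,
    papillary_count = as.integer(papillary_count),
    rv_present = isTRUE(rv_present),
    bias_amplitude = bias_amplitude, noise_sigma = noise_sigma,
    seed = as.integer(seed)), class = "phantom_params")
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  H <- p$image_size[1L]; W <- p$image_size[2L]
  if (!(p$r_endo > 0 && p$r_endo < p$r_epi && p$r_epi < min(H, W) / 2))
    stop("radii must satisfy 0 < r_endo < r_epi < min(H, W)/2")
  ints <- c(p$intensity_pool, p$intensity_myo, p$intensity_bg, p$intensity_lung)
  if (any(ints < 0 | ints > 1)) stop("intensities must lie in [0, 1]")
  if (p$intensity_pool <= p$intensity_myo)
    stop("intensity_pool must exceed intensity_myo (bright pool in darker annulus)")
  if (p$noise_sigma < 0) stop("noise_sigma must be >= 0")
  # the LV ROI (epicardial disk) must fit strictly inside the image
  cx <- p$lv_center[1L]; cy <- p$lv_center[2L]
  if (cx - p$r_epi < 0 || cx + p$r_epi > W || cy - p$r_epi < 0 || cy + p$r_epi > H)
    stop("left-ventricle geometry extends outside the image")
  invisible(p)
}

# evaluate expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Axis-aligned bounding box
#'
#' @param x_center,y_center box center in continuous 0-based pixel coordinates.
#' @param width,height box extents in pixels (must be positive).
#' @return Named numeric vector of class \code{bbox}.
#' @export
bbox <- function(x_center, y_center, width, height) {
  if (width <= 0 || height <= 0) stop("box width and height must be positive")
  structure(c(x_center = x_center, y_center = y_center,
              width = width, height = height), class = "bbox")
}

#' Corrupt an intensity image with Rician noise
#'
#' The magnitude-image noise model of MR: each output pixel is
#' \code{sqrt((x + n1)^2 + n2^2)} with \code{n1, n2} i.i.d. zero-mean Gaussian
#' of standard deviation \code{sigma}. At \code{sigma = 0} the output is
#' \code{|x|}.
#'
#' @param image numeric matrix of intensities.
#' @param sigma noise standard deviation (\code{>= 0}).
#' @param seed integer seed.
#' @return Matrix of the same shape.
#' @export
rician_noise <- function(image, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(abs(image))
  with_seed(seed, {
    n1 <- matrix(stats::rnorm(length(image), 0, sigma), nrow(image))
    n2 <- matrix(stats::rnorm(length(image), 0, sigma), nrow(image))
    sqrt((image + n1)^2 + n2^2)
  })
}

#' Render one synthetic cardiac slice
#'
#' Draws background tissue, a low-signal lung region, an optional
#' right-ventricle crescent, the left-ventricle myocardial annulus enclosing a
#' bright blood pool with dark papillary spots, applies a low-order polynomial
#' bias field scaled to \code{bias_amplitude} and Rician noise. The ground
#' truth is the tight axis-aligned box of the epicardial disk (myocardium plus
#' pool), i.e. the left-ventricle region of interest.
#'
#' @param params a [phantom_params()] object.
#' @return An object of class \code{myo_slice}: a list with \code{image}
#'   (H x W matrix), \code{gt} (a [bbox()]) and \code{params}.
#' @examples
#' sl <- make_slice(phantom_params(noise_sigma = 0, bias_amplitude = 0))
#' sl$gt
#' @export
make_slice <- function(params) {
  validate_phantom_params(params)
  H <- params$image_size[1L]; W <- params$image_size[2L]
  cx <- params$lv_center[1L]; cy <- params$lv_center[2L]
  xs <- matrix(rep(seq_len(W) - 0.5, each = H), H)
  ys <- matrix(rep(seq_len(H) - 0.5, W), H)
  d_lv <- sqrt((xs - cx)^2 + (ys - cy)^2)

  img <- matrix(params$intensity_bg, H, W)
  # lung: low-signal ellipse on the far side of the LV
  lx <- cx + params$r_epi * 2.6; ly <- cy - params$r_epi * 0.8
  ax <- W * 0.22; ay <- H * 0.3
  lung <- ((xs - lx) / ax)^2 + ((ys - ly) / ay)^2 <= 1
  img[lung] <- params$intensity_lung
  # right-ventricle crescent: pool-bright region hugging the LV
  if (params$rv_present) {
    rvx <- cx - params$r_epi * 1.45; rvy <- cy
    d_rv <- sqrt((xs - rvx)^2 + (ys - rvy)^2)
    rv <- d_rv <= params$r_epi * 0.95 & d_lv > params$r_epi * 1.02
    img[rv] <- min(1, params$intensity_pool * 0.88)
    rim <- d_rv <= params$r_epi * 1.1 & d_rv > params$r_epi * 0.95 &
      d_lv > params$r_epi * 1.02
    img[rim] <- params$intensity_myo
  }
  # LV: myocardial annulus around the blood pool
  img[d_lv <= params$r_epi] <- params$intensity_myo
  img[d_lv <= params$r_endo] <- params$intensity_pool

  with_seed(params$seed, {
    if (params$papillary_count > 0L) {
      ang <- stats::runif(params$papillary_count, 0, 2 * pi)
      rad <- stats::runif(params$papillary_count, 0.2, 0.55) * params$r_endo
      pr <- max(1, 0.22 * params$r_endo)
      for (i in seq_len(params$papillary_count)) {
        px <- cx + rad[i] * cos(ang[i]); py <- cy + rad[i] * sin(ang[i])
        sp <- (xs - px)^2 + (ys - py)^2 <= pr^2 & d_lv <= params$r_endo
        img[sp] <- params$intensity_myo
      }
    }
    if (params$bias_amplitude > 0) {
      u <- (xs / W) * 2 - 1; v <- (ys / H) * 2 - 1
      cf <- stats::runif(5, -1, 1)
      bias <- cf[1] * u + cf[2] * v + cf[3] * u * v + cf[4] * u^2 + cf[5] * v^2
      rng <- max(abs(bias))
      if (rng > 0) bias <- bias / rng
      img <- img * (1 + params$bias_amplitude * bias)
    }
  })
  img <- rician_noise(img, params$noise_sigma, seed = params$seed + 1L)

  # tight box of the rasterized epicardial disk
  inside <- d_lv <= params$r_epi
  rr <- range(which(rowSums(inside) > 0)); rc <- range(which(colSums(inside) > 0))
  gt <- bbox(x_center = (rc[1L] - 1 + rc[2L]) / 2, y_center = (rr[1L] - 1 + rr[2L]) / 2,
             width = rc[2L] - rc[1L] + 1, height = rr[2L] - rr[1L] + 1)
  structure(list(image = img, gt = gt, params = params), class = "myo_slice")
}

#' @export
print.myo_slice <- function(x, ...) {
  cat(sprintf("<myo_slice> %d x %d, gt box (x=%.1f, y=%.1f, w=%.0f, h=%.0f)\n",
              nrow(x$image), ncol(x$image), x$gt["x_center"], x$gt["y_center"],
              x$gt["width"], x$gt["height"]))
  invisible(x)
}

#' @export
plot.myo_slice <- function(x, box = NULL, ...) {
  H <- nrow(x$image); W <- ncol(x$image)
  graphics::image(x = seq_len(W) - 0.5, y = seq_len(H) - 0.5,
                  z = t(x$image)[, H:1], col = grDevices::gray.colors(256, 0, 1),
                  xlab = "x", ylab = "y", asp = 1, ...)
  draw <- function(b, col) {
    graphics::rect(b["x_center"] - b["width"] / 2, H - (b["y_center"] + b["height"] / 2),
                   b["x_center"] + b["width"] / 2, H - (b["y_center"] - b["height"] / 2),
                   border = col, lwd = 2)
  }
  draw(x$gt, "red")
  if (!is.null(box)) draw(box, "yellow")
  invisible(x)
}

#' Generate a synthetic multi-subject cardiac phantom dataset
#'
#' Each subject is a short-axis stack of slices whose left-ventricle radii
#' shrink monotonically from base to apex, with per-subject geometry,
#' intensities and noise drawn from the supplied ranges. Every slice carries
#' one ground-truth box fully inside the image. Generation is deterministic:
#' the same seed reproduces the dataset bit for bit, and every subject has its
#' own substream derived from the master seed.
#'
#' @param n_subjects number of subjects (\code{>= 1}).
#' @param slices_per_subject slices in each stack, base to apex.
#' @param seed master integer seed.
#' @param variability named list of 2-vectors \code{c(min, max)} overriding the
#'   default per-subject sampling ranges: \code{image_size} (square side),
#'   \code{rel_radius} (basal epicardial radius as a fraction of the image
#'   side — the heart occupies a roughly constant fraction of the short-axis
#'   field of view), \code{endo_ratio}, \code{noise_sigma},
#'   \code{bias_amplitude}, \code{intensity_pool}, \code{intensity_myo},
#'   \code{intensity_bg}.
#' @param split optional named fractions, e.g. \code{c(train = .6, test = .4)};
#'   subjects are tagged in proportion (deterministically, from the seed).
#' @return Object of class \code{phantom_dataset}: list of subjects, each with
#'   a list of \code{myo_slice} objects, a \code{tag} and its drawn parameters.
#' @export
make_dataset <- function(n_subjects, slices_per_subject = 5L, seed = 1L,
                         variability = list(), split = NULL) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  def <- list(image_size = c(128, 192), rel_radius = c(0.095, 0.155),
              endo_ratio = c(0.55, 0.7), noise_sigma = c(0.01, 0.05),
              bias_amplitude = c(0.05, 0.15), intensity_pool = c(0.82, 0.95),
              intensity_myo = c(0.38, 0.5), intensity_bg = c(0.24, 0.34))
  for (nm in names(variability)) {
    v <- variability[[nm]]
    if (!nm %in% names(def)) stop("unknown variability field: ", nm)
    if (length(v) != 2L || v[2L] < v[1L]) stop("variability ranges must be c(min, max)")
    def[[nm]] <- v
  }
  tags <- rep("train", n_subjects)
  if (!is.null(split)) {
    split <- split / sum(split)
    k <- diff(round(cumsum(c(0, split)) * n_subjects))
    tags <- rep(names(split), k)
    length(tags) <- n_subjects
    tags[is.na(tags)] <- names(split)[length(split)]
  }
  subjects <- vector("list", n_subjects)
  S <- as.integer(slices_per_subject)
  for (i in seq_len(n_subjects)) {
    sub_seed <- (as.numeric(seed) * 104729 + i * 7919) %% 2147483647
    draws <- with_seed(sub_seed, {
      d <- lapply(def, function(rg) stats::runif(1, rg[1L], rg[2L]))
      d$rv_present <- stats::runif(1) < 0.8
      d$papillary_count <- sample(0:3, 1)
      d$center_jitter <- stats::runif(2, -0.06, 0.06)
      d
    })
    side <- as.integer(round(draws$image_size))
    shrink <- if (S > 1) seq(1, 0.5, length.out = S) else 1
    slices <- vector("list", S)
    for (s in seq_len(S)) {
      r_epi <- max(6, draws$rel_radius * side * shrink[s])
      r_endo <- max(2.5, r_epi * draws$endo_ratio)
      ctr <- c(side * (0.55 + draws$center_jitter[1L]),
               side * (0.5 + draws$center_jitter[2L]))
      pp <- phantom_params(
        image_size = c(side, side), lv_center = ctr,
        r_endo = r_endo, r_epi = r_epi,
        intensity_pool = draws$intensity_pool, intensity_myo = draws$intensity_myo,
        intensity_bg = draws$intensity_bg,
        papillary_count = if (s <= ceiling(S / 2)) draws$papillary_count else 0L,
        rv_present = draws$rv_present,
        bias_amplitude = draws$bias_amplitude, noise_sigma = draws$noise_sigma,
        seed = as.integer((sub_seed + s * 131) %% 2147483647))
      sl <- make_slice(pp)
      sl$subject <- i; sl$slice <- s
      sl$mid_stack <- s <= ceiling(S * 0.6)
      slices[[s]] <- sl
    }
    subjects[[i]] <- list(slices = slices, tag = tags[i], draws = draws)
  }
  structure(list(subjects = subjects, seed = seed,
                 slices_per_subject = S), class = "phantom_dataset")
}

#' Flatten a phantom dataset into a list of slices
#'
#' @param dataset a \code{phantom_dataset}.
#' @param tag optional split tag filter (e.g. \code{"train"}).
#' @param mid_stack if \code{TRUE}, keep only mid-stack slices (the basal-to-mid
#'   portion of each stack, where the target is well formed).
#' @return List of \code{myo_slice} objects.
#' @export
dataset_slices <- function(dataset, tag = NULL, mid_stack = FALSE) {
  out <- list()
  for (sub in dataset$subjects) {
    if (!is.null(tag) && !identical(sub$tag, tag)) next
    for (sl in sub$slices) {
      if (mid_stack && !isTRUE(sl$mid_stack)) next
      out[[length(out) + 1L]] <- sl
    }
  }
  out
}

#' @export
print.phantom_dataset <- function(x, ...) {
  n <- length(x$subjects)
  tags <- table(vapply(x$subjects, `[[`, "", "tag"))
  cat(sprintf("<phantom_dataset> %d subjects x %d slices (seed %s)\n",
              n, x$slices_per_subject, format(x$seed)))
  cat("  split:", paste(names(tags), as.integer(tags), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a phantom dataset to disk
#'
#' Slices are written as 8-bit PNG (one file per slice) or as one float32
#' NIfTI stack per subject; ground-truth boxes go to a CSV table with columns
#' \code{subject, slice, x_center, y_center, width, height} (0-based, half-open
#' pixel coordinates).
#'
#' @param dataset a \code{phantom_dataset}.
#' @param dir output directory (created if missing).
#' @param format \code{"png"} or \code{"nifti"}.
#' @return Invisibly, the path of the box table.
#' @export
write_dataset <- function(dataset, dir, format = c("png", "nifti")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (sub in dataset$subjects) {
    i <- sub$slices[[1L]]$subject
    if (format == "nifti") {
      arr <- simplify2array(lapply(sub$slices, `[[`, "image"))
      RNifti::writeNifti(RNifti::asNifti(arr),
                         file.path(dir, sprintf("subject%03d.nii.gz", i)))
    }
    for (sl in sub$slices) {
      if (format == "png") {
        img <- pmin(pmax(sl$image, 0), 1)
        png::writePNG(img, file.path(dir, sprintf("subject%03d_slice%02d.png",
                                                  i, sl$slice)))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject = i, slice = sl$slice, x_center = sl$gt["x_center"],
        y_center = sl$gt["y_center"], width = sl$gt["width"],
        height = sl$gt["height"], tag = sub$tag, row.names = NULL)
    }
  }
  tab <- do.call(rbind, rows)
  path <- file.path(dir, "boxes.csv")
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a slice image from disk
#'
#' Reads a single PNG slice or one slice of a NIfTI volume (sliced along the
#' third axis) as a plain intensity matrix.
#'
#' @param path file path (.png, .nii or .nii.gz).
#' @param slice slice index for NIfTI volumes.
#' @return Numeric matrix.
#' @export
read_slice <- function(path, slice = 1L) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    return(img)
  }
  arr <- RNifti::readNifti(path)
  if (length(dim(arr)) == 2L) return(arr[, ])
  arr[, , slice]
}
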