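#' Per-region summary statistics of a labeling
#'
#' For each region of a label map: pixel count, intensity mean and standard
#' deviation (d-1 denominator), mean phase congruency, centroid (x, y) and an
#' intensity histogram (counts over \code{n_bins} bins of \code{[0, 1]}).
#'
#' @param image numeric matrix, normalized to \code{[0, 1]}.
#' @param labels integer label matrix (ids 1..L).
#' @param pc phase-congruency matrix (optional; zeros if missing).
#' @param n_bins histogram bins.
#' @return List of per-region summary lists (fields \code{n, mean, sd,
#'   pc_mean, centroid, hist, sum, sumsq, pc_sum, xsum, ysum}).
#' @export
region_stats <- function(image, labels, pc = NULL, n_bins = 32L) {
  if (is.null(pc)) pc <- matrix(0, nrow(image), ncol(image))
  L <- max(labels)
  lab <- as.vector(labels)
  v <- as.vector(image)
  n <- tabulate(lab, L)
  s <- as.vector(rowsum(v, lab, reorder = TRUE))
  s2 <- as.vector(rowsum(v^2, lab, reorder = TRUE))
  ps <- as.vector(rowsum(as.vector(pc), lab, reorder = TRUE))
  H <- nrow(image); W <- ncol(image)
  ys <- as.vector(rowsum(as.vector(row(image)) - 0.5, lab, reorder = TRUE))
  xs <- as.vector(rowsum(as.vector(col(image)) - 0.5, lab, reorder = TRUE))
  bins <- pmin(pmax(floor(v * n_bins) + 1L, 1L), n_bins)
  hist <- matrix(tabulate((bins - 1L) * L + lab, nbins = L * n_bins), L, n_bins)
  lapply(seq_len(L), function(k) {
    var <- if (n[k] > 1) max(0, (s2[k] - s[k]^2 / n[k]) / (n[k] - 1)) else 0
    list(id = k, n = n[k], mean = s[k] / n[k], sd = sqrt(var),
         pc_mean = ps[k] / n[k], centroid = c(xs[k] / n[k], ys[k] / n[k]),
         hist = hist[k, ], sum = s[k], sumsq = s2[k], pc_sum = ps[k],
         xsum = xs[k], ysum = ys[k])
  })
}

#' Structural-similarity-driven superpixel over-segmentation
#'
#' SLIC-style clustering in which the color/space distance is replaced by
#' \code{1 - S}, with \code{S} the hybrid similarity between a pixel (described
#' by its \code{p x p} patch statistics and phase congruency) and a seed region
#' (described by its running mean, standard deviation, mean phase congruency,
#' intensity histogram and centroid). Seeds start on a regular grid, perturbed
#' to the lowest-gradient position in a 3 x 3 neighborhood; pixels are
#' reassigned within a \code{2g x 2g} window around each region centroid
#' (\code{g} the grid step); iteration stops when fewer than \code{tol} of the
#' pixels change label or after \code{max_iter} sweeps. Stranded fragments are
#' relabeled to the dominant adjacent region so every region is 4-connected.
#'
#' @param image numeric matrix (any range; min-max normalized internally).
#' @param M initial superpixel count (\code{2 <= M <=} pixel count).
#' @param cfg a [similarity_config()]; \code{cfg$alpha = NULL} uses
#'   \code{2M/N}.
#' @param max_iter maximum assignment sweeps.
#' @param tol convergence threshold (fraction of pixels changing label).
#' @return Object of class \code{supervoxels}: list with \code{labels}
#'   (integer matrix, ids 1..L), \code{stats} (see [region_stats()]),
#'   \code{adjacency} (2-column matrix of region-id edges), \code{pc},
#'   \code{image} (normalized) and \code{cfg}.
#' @export
supervoxel_segment <- function(image, M = 500L, cfg = similarity_config(),
                               max_iter = 10L, tol = 0.001) {
  N <- length(image)
  if (M < 2 || M > N) stop("M must be in [2, pixel count]")
  img <- normalize01(image)
  H <- nrow(img); W <- ncol(img)
  bank <- build_log_gabor_bank(c(H, W), cfg$n_scales, cfg$n_orientations,
                               cfg$min_wavelength, cfg$mult, cfg$sigma_ratio,
                               cfg$sigma_theta_frac * pi / cfg$n_orientations)
  pc <- phase_congruency(img, bank, cfg$eps_amp)
  maps <- .cpp_patch_maps(img, cfg$p, cfg$n_bins)
  alpha <- if (is.null(cfg$alpha)) 2 * M / N else cfg$alpha

  # regular-grid seeds, perturbed to the lowest-gradient 3x3 position
  g <- sqrt(N / M)
  ny <- max(1L, round(H / g)); nx <- max(1L, ceiling(M / ny))
  sy <- (seq_len(ny) - 0.5) * H / ny
  sx <- (seq_len(nx) - 0.5) * W / nx
  seeds <- as.matrix(expand.grid(y = sy, x = sx))[seq_len(min(M, ny * nx)), , drop = FALSE]
  gx <- img[, c(2:W, W)] - img[, c(1, 1:(W - 1))]
  gy <- img[c(2:H, H), ] - img[c(1, 1:(H - 1)), ]
  grad <- abs(gx) + abs(gy)
  for (k in seq_len(nrow(seeds))) {
    r <- min(max(round(seeds[k, 1L] + 0.5), 2L), H - 1L)
    c <- min(max(round(seeds[k, 2L] + 0.5), 2L), W - 1L)
    win <- grad[(r - 1):(r + 1), (c - 1):(c + 1)]
    pos <- which(win == min(win), arr.ind = TRUE)[1L, ]
    seeds[k, ] <- c(r + pos[1L] - 2L - 0.5, c + pos[2L] - 2L - 0.5)
  }

  res <- .cpp_slic_iterate(img, pc, maps$mean, maps$sd, maps$hist,
                           as.integer(cfg$p)^2, seeds, g, alpha,
                           c(cfg$c1, cfg$c2, cfg$c3, cfg$c4), cfg$beta,
                           as.integer(max_iter), tol)
  labels <- .cpp_enforce_connectivity(res$labels)
  labels <- compact_labels(labels)
  structure(list(labels = labels,
                 stats = region_stats(img, labels, pc, cfg$n_bins),
                 adjacency = region_adjacency(labels),
                 pc = pc, image = img, cfg = cfg, alpha = alpha,
                 iterations = res$iterations),
            class = "supervoxels")
}

# renumber labels to 1..L preserving order of first appearance by id
compact_labels <- function(labels) {
  ids <- sort(unique(as.vector(labels)))
  matrix(match(as.vector(labels), ids), nrow(labels), ncol(labels))
}

#' Region adjacency of a label map
#'
#' Regions \code{a} and \code{b} are adjacent iff some pixel of \code{a} is a
#' 4-neighbor of some pixel of \code{b} (no diagonals).
#'
#' @param labels integer label matrix.
#' @return 2-column integer matrix of undirected edges (a < b), sorted.
#' @export
region_adjacency <- function(labels) {
  H <- nrow(labels); W <- ncol(labels)
  pairs <- rbind(
    if (H > 1) cbind(as.vector(labels[-H, ]), as.vector(labels[-1, ])),
    if (W > 1) cbind(as.vector(labels[, -W]), as.vector(labels[, -1])))
  pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  if (nrow(pairs) == 0L)
    return(matrix(integer(), 0L, 2L, dimnames = list(NULL, c("a", "b"))))
  pairs <- cbind(pmin(pairs[, 1L], pairs[, 2L]), pmax(pairs[, 1L], pairs[, 2L]))
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  colnames(pairs) <- c("a", "b")
  pairs
}

# region-mode hybrid similarity from two summary lists
region_similarity <- function(ru, rv, cfg, alpha) {
  hybrid_similarity(ru, rv, cfg, mode = "region", alpha = alpha)
}

#' Bottom-up hierarchical merging of superpixels
#'
#' Repeatedly merges the adjacent region pair with the highest region-mode
#' hybrid similarity (coordinate term on region centroids), recomputing the
#' merged region's statistics exactly from its pooled pixel sums and refreshing
#' its edge similarities, until \code{K} regions remain. Ties are broken by the
#' lexicographically smallest region-id pair, making the merge sequence
#' deterministic.
#'
#' @param sv a \code{supervoxels} object.
#' @param K target region count (\code{1 <= K <=} current count).
#' @param alpha coordinate decay for the merge stage; default \code{2K/N}.
#' @return A new \code{supervoxels} object with \code{K} regions.
#' @export
hierarchical_merge <- function(sv, K, alpha = NULL) {
  if (K < 1) stop("K must be >= 1")
  L <- length(sv$stats)
  if (K > L) stop("K exceeds the current region count")
  cfg <- sv$cfg
  if (is.null(alpha)) alpha <- 2 * K / length(sv$image)
  if (K == L) return(sv)

  n_bins <- cfg$n_bins
  parent <- seq_len(L)
  # mergeable per-region sums (matrix form for vectorized similarity updates)
  n <- vapply(sv$stats, `[[`, 0, "n")
  s1 <- vapply(sv$stats, `[[`, 0, "sum")
  s2 <- vapply(sv$stats, `[[`, 0, "sumsq")
  ps <- vapply(sv$stats, `[[`, 0, "pc_sum")
  xs <- vapply(sv$stats, `[[`, 0, "xsum")
  ys <- vapply(sv$stats, `[[`, 0, "ysum")
  hs <- t(vapply(sv$stats, `[[`, numeric(n_bins), "hist"))
  # region-mode hybrid similarity between region sets i and j (vectorized)
  pair_sim <- function(i, j) {
    mi <- s1[i] / n[i]; mj <- s1[j] / n[j]
    vi <- pmax(0, (s2[i] - s1[i]^2 / n[i]) / pmax(n[i] - 1, 1))
    vj <- pmax(0, (s2[j] - s1[j]^2 / n[j]) / pmax(n[j] - 1, 1))
    sdi <- sqrt(vi); sdj <- sqrt(vj)
    pci <- ps[i] / n[i]; pcj <- ps[j] / n[j]
    spm <- (2 * pci * pcj + cfg$c1) / (pci^2 + pcj^2 + cfg$c1)
    sim <- (2 * mi * mj + cfg$c2) / (mi^2 + mj^2 + cfg$c2)
    scm <- (2 * sdi * sdj + cfg$c3) / (sdi^2 + sdj^2 + cfg$c3)
    hi <- hs[i, , drop = FALSE] / n[i]; hj <- hs[j, , drop = FALSE] / n[j]
    hi <- hi - rowMeans(hi); hj <- hj - rowMeans(hj)
    cov <- rowSums(hi * hj) / (n_bins - 1)
    sdu <- sqrt(rowSums(hi^2) / (n_bins - 1))
    sdv <- sqrt(rowSums(hj^2) / (n_bins - 1))
    ssm <- pmin(1, pmax(0, abs(2 * cov + cfg$c4) / (sdu * sdv + cfg$c4)))
    d2 <- (xs[i] / n[i] - xs[j] / n[j])^2 + (ys[i] / n[i] - ys[j] / n[j])^2
    sdm <- exp(-alpha * d2)
    b <- cfg$beta
    if (all(b == 1)) spm * sim * scm * ssm * sdm
    else spm^b[1] * sim^b[2] * scm^b[3] * ssm^b[4] * sdm^b[5]
  }
  ea <- sv$adjacency[, 1L]; eb <- sv$adjacency[, 2L]
  esim <- pair_sim(ea, eb)
  n_alive <- L
  while (n_alive > K && length(ea) > 0L) {
    best <- max(esim)
    cand <- which(esim >= best - 1e-15)
    # deterministic tie-break: smallest (a, b)
    e <- cand[order(ea[cand], eb[cand])][1L]
    a <- ea[e]; b <- eb[e]
    # merge b into a: pooled sums give exact merged statistics
    n[a] <- n[a] + n[b]; s1[a] <- s1[a] + s1[b]; s2[a] <- s2[a] + s2[b]
    ps[a] <- ps[a] + ps[b]; xs[a] <- xs[a] + xs[b]; ys[a] <- ys[a] + ys[b]
    hs[a, ] <- hs[a, ] + hs[b, ]
    parent[parent == b] <- a
    # rewire edges of b to a, drop the merged edge, dedupe parallels
    ea[ea == b] <- a; eb[eb == b] <- a
    swap <- ea > eb
    tmp <- ea[swap]; ea[swap] <- eb[swap]; eb[swap] <- tmp
    drop <- ea == eb | duplicated(ea * (L + 1) + eb)
    ea <- ea[!drop]; eb <- eb[!drop]; esim <- esim[!drop]
    # refresh similarities on a's surviving edges
    touch <- which(ea == a | eb == a)
    if (length(touch) > 0L)
      esim[touch] <- pair_sim(ea[touch], eb[touch])
    n_alive <- n_alive - 1L
  }
  labels <- matrix(parent[as.vector(sv$labels)], nrow(sv$labels), ncol(sv$labels))
  labels <- compact_labels(labels)
  structure(list(labels = labels,
                 stats = region_stats(sv$image, labels, sv$pc, n_bins),
                 adjacency = region_adjacency(labels),
                 pc = sv$pc, image = sv$image, cfg = cfg, alpha = alpha,
                 iterations = sv$iterations),
            class = "supervoxels")
}

#' @export
print.supervoxels <- function(x, ...) {
  cat(sprintf("<supervoxels> %d regions on a %d x %d image\n",
              length(x$stats), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Proposal filter settings
#'
#' @param aspect_ratio_range allowed \code{height/width} range.
#' @param area_range allowed box area as a fraction of the image area.
#' @param border_margin boxes closer than this many pixels to the image border
#'   are dropped (0 keeps boxes touching the border).
#' @return Object of class \code{proposal_filter}.
#' @export
proposal_filter <- function(aspect_ratio_range = c(1 / 3, 3),
                            area_range = c(0.002, 0.40),
                            border_margin = 2) {
  stopifnot(aspect_ratio_range[1L] <= aspect_ratio_range[2L],
            area_range[1L] <= area_range[2L])
  structure(list(aspect_ratio_range = aspect_ratio_range,
                 area_range = area_range, border_margin = border_margin),
            class = "proposal_filter")
}

# tight half-open bounding boxes of every region: data.frame rows keyed by id
region_boxes <- function(labels) {
  L <- max(labels)
  rows <- as.vector(row(labels)); cols <- as.vector(col(labels))
  lab <- as.vector(labels)
  rmin <- tapply(rows, lab, min); rmax <- tapply(rows, lab, max)
  cmin <- tapply(cols, lab, min); cmax <- tapply(cols, lab, max)
  data.frame(id = as.integer(names(rmin)),
             x_center = (cmin - 1 + cmax) / 2, y_center = (rmin - 1 + rmax) / 2,
             width = cmax - cmin + 1, height = rmax - rmin + 1,
             row.names = NULL)
}

#' Bounding-box proposals from merged regions
#'
#' Emits the tight axis-aligned box of every region passing the aspect-ratio,
#' area and border-margin filters, plus the boxes of unions of each region with
#' each adjacent region (recovering targets split across two regions), plus
#' the box of each region's closed neighborhood (the region united with all
#' its adjacent regions at once — a ring-shaped target fragments into several
#' arcs around its enclosed pool, and the pool's closed neighborhood is
#' exactly the full target), deduplicated.
#'
#' @param sv a \code{supervoxels} object.
#' @param filt a [proposal_filter()].
#' @return data.frame with columns \code{x_center, y_center, width, height,
#'   region_a, region_b} (\code{region_b} is \code{NA} for single-region
#'   boxes). Coordinates are 0-based, half-open.
#' @export
proposals_from_regions <- function(sv, filt = proposal_filter()) {
  labels <- sv$labels
  H <- nrow(labels); W <- ncol(labels)
  rb <- region_boxes(labels)
  singles <- cbind(rb[, c("x_center", "y_center", "width", "height")],
                   region_a = rb$id, region_b = NA_integer_)
  adj <- sv$adjacency
  if (nrow(adj) > 0L) {
    ia <- match(adj[, 1L], rb$id); ib <- match(adj[, 2L], rb$id)
    x0 <- pmin(rb$x_center[ia] - rb$width[ia] / 2, rb$x_center[ib] - rb$width[ib] / 2)
    x1 <- pmax(rb$x_center[ia] + rb$width[ia] / 2, rb$x_center[ib] + rb$width[ib] / 2)
    y0 <- pmin(rb$y_center[ia] - rb$height[ia] / 2, rb$y_center[ib] - rb$height[ib] / 2)
    y1 <- pmax(rb$y_center[ia] + rb$height[ia] / 2, rb$y_center[ib] + rb$height[ib] / 2)
    unions <- data.frame(x_center = (x0 + x1) / 2, y_center = (y0 + y1) / 2,
                         width = x1 - x0, height = y1 - y0,
                         region_a = adj[, 1L], region_b = adj[, 2L])
    # closed-neighborhood (star) unions: region plus all its neighbors
    bx0 <- rb$x_center - rb$width / 2; bx1 <- rb$x_center + rb$width / 2
    by0 <- rb$y_center - rb$height / 2; by1 <- rb$y_center + rb$height / 2
    stars <- do.call(rbind, lapply(rb$id, function(k) {
      grp <- match(c(k, adj[adj[, 1L] == k, 2L], adj[adj[, 2L] == k, 1L]), rb$id)
      sx0 <- min(bx0[grp]); sx1 <- max(bx1[grp])
      sy0 <- min(by0[grp]); sy1 <- max(by1[grp])
      data.frame(x_center = (sx0 + sx1) / 2, y_center = (sy0 + sy1) / 2,
                 width = sx1 - sx0, height = sy1 - sy0,
                 region_a = k, region_b = NA_integer_)
    }))
    out <- rbind(singles, unions, stars)
  } else out <- singles
  # filters
  ar <- out$height / out$width
  area <- out$width * out$height / (H * W)
  x0 <- out$x_center - out$width / 2; x1 <- out$x_center + out$width / 2
  y0 <- out$y_center - out$height / 2; y1 <- out$y_center + out$height / 2
  keep <- ar >= filt$aspect_ratio_range[1L] & ar <= filt$aspect_ratio_range[2L] &
    area >= filt$area_range[1L] & area <= filt$area_range[2L] &
    x0 >= filt$border_margin & y0 >= filt$border_margin &
    x1 <= W - filt$border_margin & y1 <= H - filt$border_margin
  out <- out[keep, , drop = FALSE]
  out <- out[!duplicated(out[, c("x_center", "y_center", "width", "height")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a label map as an id-coded PNG
#'
#' @param labels integer label matrix.
#' @param path output file.
#' @export
write_labels_png <- function(labels, path) {
  png::writePNG(labels / max(labels), path)
  invisible(path)
}
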