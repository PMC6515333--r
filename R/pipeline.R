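#' Intersection over union of axis-aligned boxes
#'
#' Boxes are \code{(x_center, y_center, width, height)} under the 0-based,
#' half-open convention, so areas are exact pixel counts for integer-aligned
#' boxes. Vectorized over rows; with one box per argument a scalar is
#' returned.
#'
#' @param a,b boxes as vectors or matrices/data.frames with rows
#'   \code{(x, y, w, h)}; one of them may have a single row.
#' @return IoU values in \code{[0, 1]}.
#' @export
iou <- function(a, b) {
  as_box_matrix <- function(x)
    if (is.null(dim(x))) matrix(as.numeric(x), 1L) else as.matrix(x)
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  ix <- pmax(0, pmin(a[, 1L] + a[, 3L] / 2, b[, 1L] + b[, 3L] / 2) -
               pmax(a[, 1L] - a[, 3L] / 2, b[, 1L] - b[, 3L] / 2))
  iy <- pmax(0, pmin(a[, 2L] + a[, 4L] / 2, b[, 2L] + b[, 4L] / 2) -
               pmax(a[, 2L] - a[, 4L] / 2, b[, 2L] - b[, 4L] / 2))
  inter <- ix * iy
  uni <- a[, 3L] * a[, 4L] + b[, 3L] * b[, 4L] - inter
  unname(inter / uni)
}

#' Non-maximum suppression
#'
#' Greedy descending-score selection: the highest-scoring box is kept and
#' every box overlapping it with IoU above \code{threshold} is suppressed;
#' repeat on the remainder.
#'
#' @param boxes matrix/data.frame of boxes (rows).
#' @param scores numeric scores, same length.
#' @param threshold suppression IoU threshold.
#' @return Integer indices of the surviving boxes, in descending score order.
#' @export
nms <- function(boxes, scores, threshold = 0.3) {
  boxes <- rbind(as.matrix(boxes))
  if (nrow(boxes) != length(scores)) stop("boxes and scores lengths differ")
  ord <- order(scores, decreasing = TRUE)
  keep <- integer()
  while (length(ord) > 0L) {
    i <- ord[1L]
    keep <- c(keep, i)
    ord <- ord[-1L]
    if (length(ord) > 0L) {
      ov <- iou(boxes[i, , drop = FALSE], boxes[ord, , drop = FALSE])
      ord <- ord[ov <= threshold]
    }
  }
  keep
}

#' Label proposals against the ground truth by IoU
#'
#' IoU above \code{iou_pos} makes a positive sample, below \code{iou_neg} a
#' negative; the band in between is ignored for training.
#'
#' @param proposals data.frame of boxes.
#' @param gt ground-truth box.
#' @param iou_pos,iou_neg labeling thresholds.
#' @return The proposals with added columns \code{iou} and \code{label}
#'   (\code{"positive"}, \code{"negative"} or \code{"ignored"}).
#' @export
label_proposals <- function(proposals, gt, iou_pos = 0.5, iou_neg = 0.3) {
  ious <- iou(proposals[, c("x_center", "y_center", "width", "height")], gt)
  proposals$iou <- ious
  proposals$label <- ifelse(ious > iou_pos, "positive",
                            ifelse(ious < iou_neg, "negative", "ignored"))
  proposals
}

#' Rasterize a half-open box to a pixel mask
#'
#' A pixel belongs to the mask iff its center lies inside the box.
#'
#' @param box a box vector \code{(x, y, w, h)}.
#' @param H,W image dimensions.
#' @return Logical H x W matrix.
#' @export
box_mask <- function(box, H, W) {
  x0 <- box[1L] - box[3L] / 2; x1 <- box[1L] + box[3L] / 2
  y0 <- box[2L] - box[4L] / 2; y1 <- box[2L] + box[4L] / 2
  cols <- (seq_len(W) - 0.5) >= x0 & (seq_len(W) - 0.5) < x1
  rows <- (seq_len(H) - 0.5) >= y0 & (seq_len(H) - 0.5) < y1
  outer(rows, cols, "&")
}

#' Overlap (Dice-style) ratio of two masks
#'
#' The detection literature this package follows scores overlap as
#' \code{DR = 2|A n B| / |A u B|} — twice the IoU, which reaches 2 for
#' identical masks; values are clipped at 1 when reported. The classical Dice
#' coefficient \code{2|A n B| / (|A| + |B|)} is available as a variant.
#'
#' @param a,b logical masks of the same shape.
#' @param variant \code{"printed"} (2 IoU, clipped at 1) or
#'   \code{"classical"}.
#' @return Ratio in \code{[0, 1]}.
#' @export
dice_ratio <- function(a, b, variant = c("printed", "classical")) {
  variant <- match.arg(variant)
  if (!identical(dim(a), dim(b))) stop("masks must share a shape")
  inter <- sum(a & b)
  if (variant == "printed") {
    uni <- sum(a | b)
    if (uni == 0) return(0)
    min(1, 2 * inter / uni)
  } else {
    tot <- sum(a) + sum(b)
    if (tot == 0) return(0)
    2 * inter / tot
  }
}

#' Detector configuration
#'
#' Bundles every tunable of the detection pipeline. The similarity/proposal
#' defaults are \code{M = 500} initial superpixels merged down to
#' \code{K = 100} regions; crops are resized to \code{tau x tau} and encoded
#' by a stacked sparse autoencoder with the preset layer stack for that
#' \code{tau} (see [ssae_layer_sizes()]), trained with weight penalty
#' \code{lambda = 1e-2}, sparsity weight \code{beta = 0.3} and target rate
#' \code{rho = 0.2}. The classifier/regressor use a Gaussian kernel with
#' \code{r = 2}, slack \code{C = 0.5}, geometry trade-off \code{eta = 2} and
#' neighbor rank \code{t = 7}. The regression insensitivity \code{epsilon} is
#' dimensionful (units of the box-offset target norm); \code{epsilon = NULL}
#' (default) selects it from the candidate grid
#' \code{{0.01, 0.5, 1, 1.5, 2}} on a held-out anchor split during training,
#' by the refined-box IoU. IoU thresholds: positives above 0.5, negatives below
#' 0.3, hard negatives below 0.1, regressor eligibility above 0.6, NMS
#' suppression above 0.3.
#'
#' The \code{max_*} arguments cap how many crops feed each training stage
#' (sampled, balanced, deterministic under the training seed) so that training
#' scales to a workstation.
#'
#' @param M,K initial and merged superpixel counts.
#' @param tau crop side in pixels.
#' @param layer_sizes autoencoder stack (input first); default: preset for
#'   \code{tau}.
#' @param lambda,beta,rho autoencoder penalties.
#' @param C,r,eta,epsilon,t kernel-machine hyperparameters.
#' @param iou_pos,iou_neg,iou_hard,iou_regress,nms_threshold IoU thresholds.
#' @param mining_rounds hard-negative mining rounds.
#' @param pretrain_maxit per-layer L-BFGS cap for pretraining.
#' @param finetune_epochs,finetune_batch,finetune_lr fine-tuning schedule.
#' @param max_pretrain,neg_pos_ratio,max_classifier,max_regress training-set
#'   caps.
#' @param crop_pad multiplicative context enlargement of each crop window (a
#'   slightly larger window than the candidate box, so background corners are
#'   visible to the encoder).
#' @param filter a [proposal_filter()].
#' @param sim a [similarity_config()].
#' @return Object of class \code{myo_config}.
#' @export
myo_config <- function(M = 500L, K = 100L, tau = 60L, layer_sizes = NULL,
                       lambda = 1e-2, beta = 0.3, rho = 0.2,
                       C = 0.5, r = 2, eta = 2, epsilon = NULL, t = 7L,
                       iou_pos = 0.5, iou_neg = 0.3, iou_hard = 0.1,
                       iou_regress = 0.6, nms_threshold = 0.3,
                       mining_rounds = 1L, pretrain_maxit = 100L,
                       finetune_epochs = 40L, finetune_batch = 128L,
                       finetune_lr = 0.1, max_pretrain = 2000L,
                       neg_pos_ratio = 3, max_classifier = 1000L,
                       max_regress = 400L, crop_pad = 1.5, filter = proposal_filter(),
                       sim = similarity_config()) {
  if (is.null(layer_sizes)) layer_sizes <- ssae_layer_sizes(tau)
  if (layer_sizes[1L] != tau^2) stop("layer_sizes[1] must equal tau^2")
  stopifnot(iou_hard < iou_neg, iou_neg < iou_pos,
            all(c(iou_pos, iou_neg, iou_hard, iou_regress, nms_threshold) >= 0),
            all(c(iou_pos, iou_neg, iou_hard, iou_regress, nms_threshold) <= 1))
  structure(list(M = as.integer(M), K = as.integer(K), tau = as.integer(tau),
                 layer_sizes = as.integer(layer_sizes), lambda = lambda,
                 beta = beta, rho = rho, C = C, r = r, eta = eta,
                 epsilon = epsilon, t = as.integer(t), iou_pos = iou_pos,
                 iou_neg = iou_neg, iou_hard = iou_hard,
                 iou_regress = iou_regress, nms_threshold = nms_threshold,
                 mining_rounds = as.integer(mining_rounds),
                 pretrain_maxit = as.integer(pretrain_maxit),
                 finetune_epochs = as.integer(finetune_epochs),
                 finetune_batch = as.integer(finetune_batch),
                 finetune_lr = finetune_lr,
                 max_pretrain = as.integer(max_pretrain),
                 neg_pos_ratio = neg_pos_ratio,
                 max_classifier = as.integer(max_classifier),
                 max_regress = as.integer(max_regress), crop_pad = crop_pad,
                 filter = filter, sim = sim),
            class = "myo_config")
}

#' Region proposals for one slice
#'
#' Runs the proposal stage (superpixel over-segmentation, hierarchical
#' merging, box filtering) on a single slice.
#'
#' @param image numeric matrix (a raw slice; normalized internally).
#' @param config a [myo_config()].
#' @return data.frame of proposal boxes.
#' @export
propose_regions <- function(image, config = myo_config()) {
  sv <- supervoxel_segment(image, config$M, config$sim)
  svm <- hierarchical_merge(sv, config$K)
  proposals_from_regions(svm, config$filter)
}

# L2-normalize feature rows: deep features feeding a Gaussian kernel are
# conventionally projected to the unit sphere so kernel distances sit in a
# scale-free, informative range
unit_rows <- function(X) {
  n <- sqrt(rowSums(X^2))
  X / pmax(n, 1e-12)
}

# proposals + prepared crops + labels for one slice
slice_training_rows <- function(sl, config) {
  props <- propose_regions(sl$image, config)
  if (nrow(props) == 0L) return(NULL)
  props <- label_proposals(props, sl$gt, config$iou_pos, config$iou_neg)
  crops <- t(vapply(seq_len(nrow(props)), function(i) {
    as.vector(prepare_crop(sl$image, as.numeric(props[i, 1:4]), config$tau,
                           config$crop_pad))
  }, numeric(config$tau^2)))
  list(props = props, crops = crops, gt = sl$gt,
       dims = dim(sl$image))
}

#' Identify hard negatives under a fitted classifier
#'
#' Hard negatives are training proposals that the classifier marks positive
#' although their IoU with the ground truth is below \code{iou_hard}. They are
#' re-injected into the training pool to rebalance the classifier.
#'
#' @param svc a fitted \code{wcnp_svc}.
#' @param features encoded feature matrix of candidate proposals (rows).
#' @param label character labels from [label_proposals()].
#' @param iou_with_gt numeric IoU of each proposal with its ground truth.
#' @param iou_hard mining IoU ceiling.
#' @return Logical vector marking the mined proposals (never intersects the
#'   positives).
#' @export
hard_negative_mine <- function(svc, features, label, iou_with_gt,
                               iou_hard = 0.1) {
  pred <- csvc_decision(svc, features)
  pred$class == 1 & label == "negative" & iou_with_gt < iou_hard
}

#' Fit the myocardium detector
#'
#' End-to-end training on a phantom dataset (or any list of slices with
#' ground-truth boxes): per slice, candidate regions are proposed and labeled
#' by IoU; crops are resized to \code{tau x tau}; the stacked sparse
#' autoencoder is pretrained layerwise and fine-tuned with balanced batches;
#' encoded features train the within-class neighborhood preserved C-SVC; one
#' (configurable) round of hard-negative mining re-injects confidently
#' misclassified background regions, briefly re-fine-tunes the autoencoder and
#' refits the classifier; finally the multi-output epsilon-SVR is fitted on
#' proposals overlapping the ground truth with IoU above
#' \code{config$iou_regress}, with targets encoding the ground truth relative
#' to each proposal box. Training is deterministic given \code{seed}.
#'
#' @param dataset a \code{phantom_dataset}, or a list of \code{myo_slice}
#'   objects.
#' @param config a [myo_config()].
#' @param seed integer seed for every training-stage random draw.
#' @param verbose print per-stage progress.
#' @return Object of class \code{myo_detector}: the fitted \code{ssae},
#'   \code{svc}, \code{svr}, the \code{config} and a training \code{log}.
#' @export
myo_detector <- function(dataset, config = myo_config(), seed = 1L,
                         verbose = FALSE) {
  slices <- if (inherits(dataset, "phantom_dataset")) {
    tr <- dataset_slices(dataset, tag = "train")
    if (length(tr) == 0L) dataset_slices(dataset) else tr
  } else dataset
  if (length(slices) < 2L) stop("need at least 2 training slices")
  say <- function(...) if (verbose) message(sprintf(...))

  say("proposing regions on %d slices", length(slices))
  rows <- lapply(slices, slice_training_rows, config = config)
  rows <- Filter(Negate(is.null), rows)
  props <- do.call(rbind, lapply(rows, `[[`, "props"))
  crops <- do.call(rbind, lapply(rows, `[[`, "crops"))
  n_pos <- sum(props$label == "positive")
  n_neg <- sum(props$label == "negative")
  if (n_pos == 0L)
    stop("no positive training samples: best proposal IoU was ",
         signif(max(props$iou), 3),
         " over ", nrow(props), " proposals — increase K or loosen filters")
  say("%d proposals: %d positive, %d negative", nrow(props), n_pos, n_neg)

  with_seed(seed, {
    pos_idx <- which(props$label == "positive")
    neg_idx <- which(props$label == "negative")
    # pretraining set: balanced up to the cap; negatives stratified so that
    # bright near-miss crops (overlapping the target) are represented
    take_pos <- sample(pos_idx, min(length(pos_idx), config$max_pretrain %/% 2L))
    neg_budget <- min(length(neg_idx), config$max_pretrain - length(take_pos))
    near0 <- neg_idx[props$iou[neg_idx] >= 0.05]
    far0 <- setdiff(neg_idx, near0)
    take_neg <- c(sample(near0, min(length(near0), ceiling(neg_budget / 2))))
    take_neg <- c(take_neg, sample(far0, min(length(far0),
                                             neg_budget - length(take_neg))))
    pre_idx <- c(take_pos, take_neg)
    say("pretraining SSAE on %d crops", length(pre_idx))
    ssae <- ssae_pretrain(t(crops[pre_idx, , drop = FALSE]),
                          config$layer_sizes, config$lambda, config$beta,
                          config$rho, maxit = config$pretrain_maxit,
                          seed = seed, tau = config$tau)
    say("fine-tuning SSAE (%d epochs)", config$finetune_epochs)
    ssae <- ssae_finetune(ssae, t(crops[pre_idx, , drop = FALSE]),
                          props$label[pre_idx] == "positive",
                          epochs = config$finetune_epochs,
                          batch = config$finetune_batch,
                          lr = config$finetune_lr, seed = seed + 1L)

    # classifier training set: positives plus a sampled multiple of negatives,
    # stratified so that near-miss negatives (overlapping the target, e.g. the
    # right-ventricle lookalikes) are well represented alongside easy background
    cls_pos <- sample(pos_idx, min(length(pos_idx), config$max_classifier %/% 2L))
    n_neg_budget <- min(length(neg_idx),
                        min(config$max_classifier - length(cls_pos),
                            round(config$neg_pos_ratio * length(cls_pos))))
    near <- neg_idx[props$iou[neg_idx] >= 0.05]
    far <- setdiff(neg_idx, near)
    take_near <- sample(near, min(length(near), ceiling(n_neg_budget / 2)))
    take_far <- sample(far, min(length(far), n_neg_budget - length(take_near)))
    cls_idx <- c(cls_pos, take_near, take_far)
    feats_cls <- unit_rows(ssae_encode(ssae, crops[cls_idx, , drop = FALSE]))
    y_cls <- ifelse(props$label[cls_idx] == "positive", 1, -1)
    say("fitting classifier on %d samples", length(cls_idx))
    svc <- csvc_fit(feats_cls, y_cls, config$C, config$r, config$eta, config$t)

    mined_total <- 0L
    for (round in seq_len(config$mining_rounds)) {
      cand <- setdiff(neg_idx, cls_idx)
      if (length(cand) == 0L) break
      feats_cand <- unit_rows(ssae_encode(ssae, crops[cand, , drop = FALSE]))
      hard <- hard_negative_mine(svc, feats_cand, props$label[cand],
                                 props$iou[cand], config$iou_hard)
      say("mining round %d: %d hard negatives", round, sum(hard))
      if (!any(hard)) break
      mined_total <- mined_total + sum(hard)
      cls_idx <- c(cls_idx, cand[hard])
      ft_idx <- unique(c(pre_idx, cand[hard]))
      ssae <- ssae_finetune(ssae, t(crops[ft_idx, , drop = FALSE]),
                            props$label[ft_idx] == "positive",
                            epochs = max(1L, ceiling(config$finetune_epochs / 4)),
                            batch = config$finetune_batch,
                            lr = config$finetune_lr * 0.5,
                            seed = seed + 1L + round)
      feats_cls <- unit_rows(ssae_encode(ssae, crops[cls_idx, , drop = FALSE]))
      y_cls <- ifelse(props$label[cls_idx] == "positive", 1, -1)
      svc <- csvc_fit(feats_cls, y_cls, config$C, config$r, config$eta,
                      config$t)
    }

    reg_idx <- which(props$iou > config$iou_regress)
    if (length(reg_idx) > config$max_regress)
      reg_idx <- sample(reg_idx, config$max_regress)
    svr <- NULL
    if (length(reg_idx) >= max(10L, config$t + 3L)) {
      say("fitting box regressor on %d samples", length(reg_idx))
      feats_reg <- unit_rows(ssae_encode(ssae, crops[reg_idx, , drop = FALSE]))
      gts <- do.call(rbind, lapply(rows, function(rr)
        matrix(rep(as.numeric(rr$gt), nrow(rr$props)), ncol = 4L, byrow = TRUE)))
      anchors <- as.matrix(props[reg_idx, 1:4])
      Zt <- bbox_encode(anchors, gts[reg_idx, , drop = FALSE])
      epsilon <- config$epsilon
      if (is.null(epsilon)) {
        # the insensitivity zone is selected on a held-out anchor split from
        # the candidate grid, by the refined-box IoU it yields
        grid <- c(0.01, 0.5, 1.0, 1.5, 2.0)
        nv <- max(3L, round(length(reg_idx) / 5))
        val <- sample(seq_along(reg_idx), nv)
        fit_i <- setdiff(seq_along(reg_idx), val)
        tt <- min(config$t, length(fit_i) - 1L)
        val_iou <- vapply(grid, function(eps) {
          mm <- msvr_fit(feats_reg[fit_i, , drop = FALSE],
                         Zt[fit_i, , drop = FALSE], config$C, eps,
                         config$r, config$eta, tt)
          z <- msvr_predict(mm, feats_reg[val, , drop = FALSE])
          z[, 3:4] <- pmax(z[, 3:4], 1e-3)
          rb <- bbox_decode(anchors[val, , drop = FALSE], z)
          mean(iou(rb, gts[reg_idx[val], , drop = FALSE]))
        }, 0)
        epsilon <- grid[which.max(val_iou)]
        say("selected epsilon = %g (validation IoU %s)", epsilon,
            paste(round(val_iou, 3), collapse = "/"))
      }
      svr <- msvr_fit(feats_reg, Zt, config$C, epsilon, config$r,
                      config$eta, min(config$t, length(reg_idx) - 1L))
      svr$epsilon_selected <- epsilon
    } else {
      warning("too few high-IoU proposals (", length(reg_idx),
              ") to fit the box regressor; detections will not be refined")
    }
  })

  structure(list(ssae = ssae, svc = svc, svr = svr, config = config,
                 seed = seed,
                 log = list(n_slices = length(slices),
                            n_proposals = nrow(props),
                            n_pos = n_pos, n_neg = n_neg,
                            n_classifier = length(cls_idx),
                            n_mined = mined_total,
                            n_regress = length(reg_idx))),
            class = "myo_detector")
}

#' Detect the myocardium region in one slice
#'
#' Runs the fitted pipeline on a slice: propose, encode, classify, keep
#' positives, non-maximum suppression, then refine each survivor with the box
#' regressor. The single top-probability box is reported as the myocardium
#' (\code{top_k} exposes more).
#'
#' @param object a fitted \code{myo_detector}.
#' @param slice a \code{myo_slice} or a plain image matrix.
#' @param top_k maximum number of reported boxes.
#' @param prob_threshold positive-class probability cutoff before NMS.
#' @return Object of class \code{myo_detection}: \code{boxes} (refined, with
#'   probabilities, sorted descending), \code{unrefined}, \code{n_proposals},
#'   \code{n_survivors} and an \code{empty} flag set when nothing is
#'   classified positive.
#' @export
detect_myocardium <- function(object, slice, top_k = 1L,
                              prob_threshold = 0.5) {
  if (!inherits(object, "myo_detector")) stop("not a fitted myo_detector")
  image <- if (inherits(slice, "myo_slice")) slice$image else slice
  config <- object$config
  props <- propose_regions(image, config)
  empty_result <- function(n) structure(
    list(boxes = data.frame(), unrefined = data.frame(),
         n_proposals = n, n_survivors = 0L, empty = TRUE),
    class = "myo_detection")
  if (nrow(props) == 0L) return(empty_result(0L))
  crops <- t(vapply(seq_len(nrow(props)), function(i) {
    as.vector(prepare_crop(image, as.numeric(props[i, 1:4]), config$tau,
                           config$crop_pad))
  }, numeric(config$tau^2)))
  feats <- unit_rows(ssae_encode(object$ssae, crops))
  pred <- csvc_decision(object$svc, feats)
  keep <- which(pred$prob > prob_threshold)
  if (length(keep) == 0L) return(empty_result(nrow(props)))
  boxes <- as.matrix(props[keep, 1:4])
  probs <- pred$prob[keep]
  kept <- nms(boxes, probs, config$nms_threshold)
  kept <- kept[seq_len(min(top_k, length(kept)))]
  unrefined <- data.frame(boxes[kept, , drop = FALSE], prob = probs[kept])
  refined <- unrefined
  if (!is.null(object$svr)) {
    z <- msvr_predict(object$svr, feats[keep[kept], , drop = FALSE])
    z[, 3:4] <- pmax(z[, 3:4], 1e-3) # guard degenerate size factors
    rb <- bbox_decode(boxes[kept, , drop = FALSE], z, bounds = dim(image))
    refined <- data.frame(rb, prob = probs[kept])
  }
  structure(list(boxes = refined, unrefined = unrefined,
                 n_proposals = nrow(props), n_survivors = length(kept),
                 empty = FALSE),
            class = "myo_detection")
}

#' @export
predict.myo_detector <- function(object, newdata, ...) {
  if (inherits(newdata, "myo_slice") || is.matrix(newdata))
    return(detect_myocardium(object, newdata, ...))
  lapply(newdata, function(sl) detect_myocardium(object, sl, ...))
}

#' @export
print.myo_detector <- function(x, ...) {
  cat("<myo_detector>\n")
  cat(sprintf("  trained on %d slices, %d proposals (%d pos / %d neg)\n",
              x$log$n_slices, x$log$n_proposals, x$log$n_pos, x$log$n_neg))
  cat(sprintf("  SSAE %s; classifier N=%d (+%d mined); regressor N=%s\n",
              paste(x$config$layer_sizes, collapse = "-"),
              x$log$n_classifier, x$log$n_mined,
              if (is.null(x$svr)) "none" else x$log$n_regress))
  invisible(x)
}

#' @export
summary.myo_detector <- function(object, ...) {
  print(object)
  eps <- if (!is.null(object$svr)) object$svr$epsilon_selected
         else object$config$epsilon
  cat(sprintf("  config: M=%d K=%d tau=%d C=%g r=%g eta=%g eps=%s t=%d\n",
              object$config$M, object$config$K, object$config$tau,
              object$config$C, object$config$r, object$config$eta,
              if (is.null(eps)) "auto" else format(eps), object$config$t))
  invisible(object)
}

#' @export
print.myo_detection <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("<myo_detection> empty (%d proposals, none positive)\n",
                x$n_proposals))
  } else {
    cat(sprintf("<myo_detection> %d box(es) from %d proposals\n",
                nrow(x$boxes), x$n_proposals))
    print(x$boxes, digits = 4)
  }
  invisible(x)
}

#' Evaluate detections against ground truth
#'
#' Pixelwise confusion counts between each detected box region and its
#' ground-truth box region (all pixels weighted equally towards their box),
#' pooled over slices: \code{Tpr = tp/(tp+fn)}, \code{Ppv = tp/(tp+fp)},
#' \code{F1 = 2 Tpr Ppv/(Tpr+Ppv)}. The overlap ratio DR (see [dice_ratio()])
#' is averaged per slice in both its printed and classical variants. Detection
#' success is the fraction of slices whose top box reaches IoU above
#' \code{iou_success}; the slice-level AUC sweeps the top-box probability
#' against that hit/miss outcome (undefined when all slices agree).
#'
#' @param detections list of \code{myo_detection} results.
#' @param slices matching list of \code{myo_slice} objects (ground truth).
#' @param iou_success IoU threshold defining a successful detection.
#' @return Object of class \code{myo_eval}: pooled counts and metrics plus a
#'   per-slice table.
#' @export
evaluate_detections <- function(detections, slices, iou_success = 0.5) {
  if (length(detections) != length(slices))
    stop("detections and slices differ in length")
  tp <- fp <- fn <- tn <- 0
  per <- vector("list", length(slices))
  for (i in seq_along(slices)) {
    sl <- slices[[i]]; det <- detections[[i]]
    H <- nrow(sl$image); W <- ncol(sl$image)
    gt_mask <- box_mask(as.numeric(sl$gt), H, W)
    if (det$empty || nrow(det$boxes) == 0L) {
      det_mask <- matrix(FALSE, H, W)
      bx <- NULL; prob <- NA_real_
    } else {
      bx <- as.numeric(det$boxes[1L, 1:4])
      prob <- det$boxes$prob[1L]
      det_mask <- box_mask(bx, H, W)
    }
    tp_i <- sum(det_mask & gt_mask); fp_i <- sum(det_mask & !gt_mask)
    fn_i <- sum(!det_mask & gt_mask); tn_i <- sum(!det_mask & !gt_mask)
    tp <- tp + tp_i; fp <- fp + fp_i; fn <- fn + fn_i; tn <- tn + tn_i
    box_iou <- if (is.null(bx)) 0 else iou(bx, as.numeric(sl$gt))
    per[[i]] <- data.frame(
      slice = i, iou = box_iou, hit = box_iou > iou_success, prob = prob,
      tp = tp_i, fp = fp_i, fn = fn_i, tn = tn_i,
      dr_printed = dice_ratio(gt_mask, det_mask, "printed"),
      dr_classical = dice_ratio(gt_mask, det_mask, "classical"))
  }
  per <- do.call(rbind, per)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (isTRUE(tpr + ppv > 0)) 2 * tpr * ppv / (tpr + ppv) else 0
  auc <- NA_real_
  probs <- ifelse(is.na(per$prob), 0, per$prob)
  if (length(unique(per$hit)) == 2L)
    auc <- as.numeric(pROC::auc(pROC::roc(per$hit, probs, quiet = TRUE,
                                          direction = "<")))
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 Tpr = tpr, Ppv = ppv, F1 = f1,
                 AUC = auc,
                 DR_printed = mean(per$dr_printed),
                 DR_classical = mean(per$dr_classical),
                 detection_rate = mean(per$hit),
                 mean_iou = mean(per$iou),
                 per_slice = per),
            class = "myo_eval")
}

#' Proposal-level AUC
#'
#' Area under the ROC of per-proposal positive-class probabilities against
#' the proposal labels (threshold swept from 0 to 1).
#'
#' @param prob positive-class probabilities.
#' @param is_positive logical proposal labels.
#' @return AUC in \code{[0, 1]} (NA when only one class is present).
#' @export
proposal_auc <- function(prob, is_positive) {
  if (length(unique(is_positive)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(is_positive, prob, quiet = TRUE,
                                 direction = "<")))
}

#' @export
print.myo_eval <- function(x, ...) {
  cat("<myo_eval>\n")
  cat(sprintf("  pixels: tp=%d fp=%d fn=%d tn=%d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  Tpr=%.4f Ppv=%.4f F1=%.4f AUC=%s\n", x$Tpr, x$Ppv, x$F1,
              ifelse(is.na(x$AUC), "NA", sprintf("%.4f", x$AUC))))
  cat(sprintf("  DR(printed)=%.4f DR(classical)=%.4f\n",
              x$DR_printed, x$DR_classical))
  cat(sprintf("  detection rate (IoU>0.5)=%.3f, mean IoU=%.3f over %d slices\n",
              x$detection_rate, x$mean_iou, nrow(x$per_slice)))
  invisible(x)
}
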