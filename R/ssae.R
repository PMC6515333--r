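sigmoid <- function(z) 1 / (1 + exp(-z))

#' Kullback-Leibler sparsity penalty
#'
#' \eqn{\sum_j [\rho \log(\rho/\hat\rho_j) +
#'      (1-\rho)\log((1-\rho)/(1-\hat\rho_j))]} — the divergence between the
#' target activation rate \code{rho} and each hidden unit's mean activation.
#' Boundary values (0 or 1) are rejected: the divergence is infinite there.
#'
#' @param rho target sparsity in (0, 1).
#' @param rho_hat per-unit mean activations, each in (0, 1).
#' @return Non-negative penalty value.
#' @export
kl_sparsity <- function(rho, rho_hat) {
  if (rho <= 0 || rho >= 1 || any(rho_hat <= 0) || any(rho_hat >= 1))
    stop("rho and rho_hat must lie strictly inside (0, 1)")
  sum(rho * log(rho / rho_hat) + (1 - rho) * log((1 - rho) / (1 - rho_hat)))
}

# pack/unpack one autoencoder layer
sae_pack <- function(layer) c(layer$W1, layer$b1, layer$W2, layer$b2)
sae_unpack <- function(theta, v, h) {
  i <- 0L
  W1 <- matrix(theta[i + seq_len(h * v)], h, v); i <- i + h * v
  b1 <- theta[i + seq_len(h)]; i <- i + h
  W2 <- matrix(theta[i + seq_len(v * h)], v, h); i <- i + v * h
  b2 <- theta[i + seq_len(v)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

#' Cost and gradient of a sparse autoencoder
#'
#' Total cost of one sigmoid autoencoder layer on a batch:
#' mean squared reconstruction error
#' \eqn{(1/n)\sum \frac12 \lVert y - x\rVert^2}, plus the quadratic weight
#' penalty \eqn{(\lambda/2)\sum W^2} over encode and decode weights, plus
#' \eqn{\beta} times the KL sparsity penalty on the batch-mean hidden
#' activations. Gradients are computed by back-propagation, including the
#' sparsity term's contribution through \eqn{\hat\rho}.
#'
#' @param layer list with \code{W1} (h x v), \code{b1}, \code{W2} (v x h),
#'   \code{b2}.
#' @param X input batch, one sample per column (v x n), values in \code{[0, 1]}.
#' @param lambda weight-penalty factor.
#' @param beta sparsity-penalty weight.
#' @param rho target sparsity.
#' @return List with \code{cost}, its three components (\code{recon},
#'   \code{weight}, \code{sparse}), \code{rho_hat}, and gradient list
#'   \code{grad} mirroring the layer fields.
#' @export
sae_cost_grad <- function(layer, X, lambda = 1e-2, beta = 0.3, rho = 0.2) {
  if (any(is.na(X))) stop("NaN in input batch")
  n <- ncol(X)
  if (n < 1) stop("empty batch")
  Hh <- sigmoid(layer$W1 %*% X + layer$b1)
  rho_hat <- rowMeans(Hh)
  Y <- sigmoid(layer$W2 %*% Hh + layer$b2)
  recon <- sum((Y - X)^2) / (2 * n)
  weight <- lambda / 2 * (sum(layer$W1^2) + sum(layer$W2^2))
  sparse <- if (beta > 0) beta * kl_sparsity(rho, rho_hat) else 0
  d2 <- (Y - X) * Y * (1 - Y) / n
  gW2 <- d2 %*% t(Hh) + lambda * layer$W2
  gb2 <- rowSums(d2)
  sp <- if (beta > 0)
    beta * (-rho / rho_hat + (1 - rho) / (1 - rho_hat)) / n else 0
  d1 <- (t(layer$W2) %*% d2 + sp) * Hh * (1 - Hh)
  gW1 <- d1 %*% t(X) + lambda * layer$W1
  gb1 <- rowSums(d1)
  list(cost = recon + weight + sparse, recon = recon, weight = weight,
       sparse = sparse, rho_hat = rho_hat,
       grad = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

sae_init <- function(v, h, seed) {
  with_seed(seed, {
    r <- sqrt(6 / (v + h))
    list(W1 = matrix(stats::runif(h * v, -r, r), h, v), b1 = rep(0, h),
         W2 = matrix(stats::runif(v * h, -r, r), v, h), b2 = rep(0, v))
  })
}

#' Train one sparse autoencoder layer
#'
#' Full-batch L-BFGS minimization of the [sae_cost_grad()] objective from a
#' seeded uniform \eqn{\pm\sqrt{6/(fan_{in}+fan_{out})}} initialization. The
#' returned parameters never cost more than the initialization.
#'
#' @param X input batch, one sample per column, scaled to \code{[0, 1]}.
#' @param n_hidden hidden-unit count.
#' @param lambda,beta,rho penalty hyperparameters.
#' @param maxit L-BFGS iteration cap.
#' @param seed integer seed for the initialization.
#' @return Object of class \code{sae_layer} (fields \code{W1, b1, W2, b2},
#'   plus \code{cost}, \code{init_cost}, \code{rho_hat}).
#' @export
sae_train <- function(X, n_hidden, lambda = 1e-2, beta = 0.3, rho = 0.2,
                      maxit = 400L, seed = 1L) {
  v <- nrow(X)
  layer0 <- sae_init(v, n_hidden, seed)
  fn <- function(theta) {
    l <- sae_unpack(theta, v, n_hidden)
    cg <- sae_cost_grad(l, X, lambda, beta, rho)
    if (!is.finite(cg$cost)) stop("training diverged (non-finite cost)")
    cg$cost
  }
  gr <- function(theta) {
    l <- sae_unpack(theta, v, n_hidden)
    g <- sae_cost_grad(l, X, lambda, beta, rho)$grad
    c(g$W1, g$b1, g$W2, g$b2)
  }
  init_cost <- fn(sae_pack(layer0))
  opt <- stats::optim(sae_pack(layer0), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  layer <- sae_unpack(opt$par, v, n_hidden)
  final <- sae_cost_grad(layer, X, lambda, beta, rho)
  out <- if (final$cost <= init_cost) layer else layer0
  structure(c(out, list(cost = min(final$cost, init_cost),
                        init_cost = init_cost,
                        rho_hat = if (final$cost <= init_cost) final$rho_hat
                        else sae_cost_grad(layer0, X, lambda, beta, rho)$rho_hat)),
            class = "sae_layer")
}

#' Greedy layerwise pretraining of a stacked sparse autoencoder
#'
#' Trains the first autoencoder on the raw inputs, the second on the first
#' layer's hidden activations, and so on down the (strictly decreasing) layer
#' sizes — the sparse bottleneck design. Decoders are retained inside each
#' layer but only encoders are used after pretraining.
#'
#' @param X input batch, one sample per column (\code{nrow(X)} must equal
#'   \code{layer_sizes[1]}).
#' @param layer_sizes integer vector, input size first, strictly decreasing.
#' @param lambda,beta,rho hyperparameters passed to each [sae_train()].
#' @param maxit per-layer L-BFGS cap.
#' @param seed integer seed.
#' @param tau crop side stored with the model (\code{tau^2} must equal the
#'   input size when crops are used).
#' @return Object of class \code{ssae} (no classification head yet).
#' @export
ssae_pretrain <- function(X, layer_sizes, lambda = 1e-2, beta = 0.3,
                          rho = 0.2, maxit = 400L, seed = 1L, tau = NULL) {
  if (nrow(X) != layer_sizes[1L]) stop("input size mismatch with layer_sizes")
  if (length(layer_sizes) < 2L || any(diff(layer_sizes) >= 0))
    stop("layer_sizes must be strictly decreasing (input first)")
  layers <- vector("list", length(layer_sizes) - 1L)
  A <- X
  for (l in seq_along(layers)) {
    layers[[l]] <- sae_train(A, layer_sizes[l + 1L], lambda, beta, rho,
                             maxit = maxit, seed = seed + l)
    A <- sigmoid(layers[[l]]$W1 %*% A + layers[[l]]$b1)
  }
  structure(list(layers = layers, layer_sizes = layer_sizes, head = NULL,
                 lambda = lambda, beta = beta, rho = rho,
                 tau = if (is.null(tau)) as.integer(round(sqrt(layer_sizes[1L])))
                 else as.integer(tau)),
            class = "ssae")
}

ssae_forward <- function(model, X) {
  A <- X
  for (l in model$layers) A <- sigmoid(l$W1 %*% A + l$b1)
  A
}

softmax_cols <- function(Z) {
  Z <- Z - matrix(apply(Z, 2L, max), nrow(Z), ncol(Z), byrow = TRUE)
  E <- exp(Z)
  E / matrix(colSums(E), nrow(Z), ncol(Z), byrow = TRUE)
}

#' Softmax-coupled fine-tuning of a stacked sparse autoencoder
#'
#' Attaches a two-class softmax head to the last encoding layer and jointly
#' updates encoders and head by mini-batch gradient descent on cross-entropy
#' plus the quadratic weight penalty \eqn{(\lambda/2)\sum W^2}. Mini-batches
#' are drawn with equal class proportions (the positive class is heavily
#' outnumbered in detection training sets). The KL sparsity term applies
#' during pretraining only.
#'
#' @param model a pretrained \code{ssae}.
#' @param X input batch, one sample per column.
#' @param y labels, coercible to 0/1 (positive = 1); both classes required.
#' @param epochs passes over the data.
#' @param batch mini-batch size.
#' @param lr initial learning rate, decayed as \code{lr * 0.95^epoch}.
#' @param lambda weight-penalty factor (default: the model's).
#' @param freeze_encoder if \code{TRUE} only the head is updated.
#' @param seed integer seed for batch sampling and head initialization.
#' @return The fine-tuned \code{ssae} with a fitted \code{head}.
#' @export
ssae_finetune <- function(model, X, y, epochs = 30L, batch = 128L, lr = 0.1,
                          lambda = model$lambda, freeze_encoder = FALSE,
                          seed = 1L) {
  y <- as.integer(y > 0)
  if (length(unique(y)) < 2L)
    stop("fine-tuning needs both classes (balanced batching impossible)")
  h_last <- model$layer_sizes[length(model$layer_sizes)]
  with_seed(seed, {
    if (is.null(model$head)) {
      model$head <- list(W = matrix(stats::rnorm(2 * h_last, 0, 0.01), 2L),
                         b = rep(0, 2L))
    }
    pos <- which(y == 1L); neg <- which(y == 0L)
    nl <- length(model$layers)
    half <- max(1L, batch %/% 2L)
    steps <- max(1L, ceiling(length(y) / batch))
    for (ep in seq_len(epochs)) {
      rate <- lr * 0.95^(ep - 1)
      for (st in seq_len(steps)) {
        idx <- c(sample(pos, half, replace = length(pos) < half),
                 sample(neg, half, replace = length(neg) < half))
        Xb <- X[, idx, drop = FALSE]
        yb <- y[idx]
        acts <- vector("list", nl + 1L)
        acts[[1L]] <- Xb
        for (l in seq_len(nl))
          acts[[l + 1L]] <- sigmoid(model$layers[[l]]$W1 %*% acts[[l]] +
                                      model$layers[[l]]$b1)
        P <- softmax_cols(model$head$W %*% acts[[nl + 1L]] + model$head$b)
        Tm <- rbind(1 - yb, yb)
        nb <- length(idx)
        dZ <- (P - Tm) / nb
        gWh <- dZ %*% t(acts[[nl + 1L]]) + lambda * model$head$W
        gbh <- rowSums(dZ)
        if (!freeze_encoder) {
          dA <- t(model$head$W) %*% dZ
          for (l in rev(seq_len(nl))) {
            dZl <- dA * acts[[l + 1L]] * (1 - acts[[l + 1L]])
            gW <- dZl %*% t(acts[[l]]) + lambda * model$layers[[l]]$W1
            gb <- rowSums(dZl)
            dA <- t(model$layers[[l]]$W1) %*% dZl
            model$layers[[l]]$W1 <- model$layers[[l]]$W1 - rate * gW
            model$layers[[l]]$b1 <- model$layers[[l]]$b1 - rate * gb
          }
        }
        model$head$W <- model$head$W - rate * gWh
        model$head$b <- model$head$b - rate * gbh
      }
    }
  })
  model
}

#' Encode crops (or prepared vectors) to deep features
#'
#' Deterministic forward pass through all encoding layers.
#'
#' @param model an \code{ssae}.
#' @param crops either a numeric matrix with one \code{tau^2}-vector per row,
#'   or a list of \code{tau x tau} matrices scaled to \code{[0, 1]}.
#' @return Feature matrix, one row per crop, \code{layer_sizes[last]} columns,
#'   values in (0, 1).
#' @export
ssae_encode <- function(model, crops) {
  X <- crops_to_matrix(model, crops)
  t(ssae_forward(model, X))
}

#' Class probabilities from the softmax head
#'
#' @param model a fine-tuned \code{ssae}.
#' @param crops as in [ssae_encode()].
#' @return Matrix with columns \code{negative}, \code{positive}; rows sum to 1.
#' @export
ssae_predict_prob <- function(model, crops) {
  if (is.null(model$head)) stop("model has no fitted softmax head")
  X <- crops_to_matrix(model, crops)
  P <- t(softmax_cols(model$head$W %*% ssae_forward(model, X) + model$head$b))
  colnames(P) <- c("negative", "positive")
  P
}

crops_to_matrix <- function(model, crops) {
  if (is.list(crops))
    crops <- do.call(rbind, lapply(crops, as.vector))
  X <- t(crops)
  if (nrow(X) != model$layer_sizes[1L])
    stop("crop size does not match the model input layer (tau^2 = ",
         model$layer_sizes[1L], ")")
  X
}

#' Cut a box from a slice and prepare it for the autoencoder
#'
#' Crops the (clamped) box region enlarged by the context factor \code{pad}
#' (a slightly larger window than the region itself, so surrounding tissue in
#' the corners is visible to the encoder), resizes it to \code{tau x tau}
#' with bilinear interpolation and min-max scales it per crop.
#'
#' @param image numeric matrix.
#' @param box a [bbox()] or numeric \code{(x, y, w, h)} vector.
#' @param tau output side in pixels.
#' @param pad multiplicative context enlargement of the box sides.
#' @return \code{tau x tau} matrix in \code{[0, 1]}.
#' @export
prepare_crop <- function(image, box, tau, pad = 1.5) {
  H <- nrow(image); W <- ncol(image)
  bw <- box[3L] * pad; bh <- box[4L] * pad
  x0 <- max(1L, floor(box[1L] - bw / 2) + 1L)
  x1 <- min(W, ceiling(box[1L] + bw / 2))
  y0 <- max(1L, floor(box[2L] - bh / 2) + 1L)
  y1 <- min(H, ceiling(box[2L] + bh / 2))
  if (x1 < x0 || y1 < y0) stop("box lies outside the image")
  crop <- image[y0:y1, x0:x1, drop = FALSE]
  rs <- EBImage::resize(EBImage::Image(crop), w = tau, h = tau,
                        filter = "bilinear")
  normalize01(EBImage::imageData(rs))
}

#' Layer sizes matching a crop side
#'
#' The sparse-bottleneck stacks used for feature learning, one per supported
#' crop side: \code{{576,400,300,200}} for \code{tau=24},
#' \code{{1296,750,450,250}} for 36, \code{{2304,1150,600,300}} for 48 and
#' \code{{3600,1600,750,350}} for 60.
#'
#' @param tau crop side (24, 36, 48 or 60).
#' @return Integer vector of layer sizes, input first.
#' @export
ssae_layer_sizes <- function(tau) {
  switch(as.character(tau),
         "24" = c(576L, 400L, 300L, 200L),
         "36" = c(1296L, 750L, 450L, 250L),
         "48" = c(2304L, 1150L, 600L, 300L),
         "60" = c(3600L, 1600L, 750L, 350L),
         stop("no preset layer sizes for tau = ", tau))
}

#' @export
print.ssae <- function(x, ...) {
  cat(sprintf("<ssae> layers %s, tau=%d%s\n",
              paste(x$layer_sizes, collapse = "-"), x$tau,
              if (is.null(x$head)) " (pretrained, no head)" else " (fine-tuned)"))
  invisible(x)
}
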