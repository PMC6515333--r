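#' Gaussian kernel Gram matrix
#'
#' \eqn{K_{ij} = \exp(-r \lVert x_i - x_j \rVert^2)} between the rows of
#' \code{Xa} and \code{Xb}.
#'
#' @param Xa,Xb sample matrices (rows = samples); \code{Xb = NULL} means
#'   \code{Xa} vs itself.
#' @param r kernel width parameter (\code{> 0}).
#' @return \code{nrow(Xa) x nrow(Xb)} kernel matrix with entries in (0, 1].
#' @export
gaussian_gram <- function(Xa, Xb = NULL, r = 2) {
  if (r <= 0) stop("kernel parameter r must be > 0")
  Xa <- as.matrix(Xa)
  sym <- is.null(Xb)
  Xb <- if (sym) Xa else as.matrix(Xb)
  if (ncol(Xa) != ncol(Xb)) stop("feature dimensions do not match")
  d2 <- outer(rowSums(Xa^2), rowSums(Xb^2), "+") - 2 * tcrossprod(Xa, Xb)
  d2[d2 < 0] <- 0
  K <- exp(-r * d2)
  if (sym) K <- (K + t(K)) / 2
  K
}

#' Double-center a Gram matrix
#'
#' \eqn{K_c = HKH} with \eqn{H = I - \mathbf{1}\mathbf{1}^T/N}; rows and
#' columns of the result sum to zero. Centering an already-centered matrix is
#' a no-op.
#'
#' @param K square symmetric kernel matrix.
#' @return Centered kernel matrix.
#' @export
center_gram <- function(K) {
  if (nrow(K) != ncol(K)) stop("K must be square")
  rm <- rowMeans(K); cm <- colMeans(K); gm <- mean(K)
  K - outer(rm, rep(1, ncol(K))) - outer(rep(1, nrow(K)), cm) + gm
}

# center a cross-kernel block k(new, train) consistently with the training Gram
center_cross <- function(Knew, col_means, grand_mean) {
  sweep(Knew - rowMeans(Knew), 2L, col_means) + grand_mean
}

#' Kernel PCA from a centered Gram matrix
#'
#' Eigendecomposition of the centered Gram matrix; coefficient vectors are
#' scaled so each retained component has unit norm in feature space
#' (\eqn{\mu_i \leftarrow \mu_i / \sqrt{\lambda_i}} with \eqn{\lambda_i} the
#' Gram eigenvalue). Components with eigenvalue at or below
#' \code{floor_frac * max(eigenvalue)} are dropped as numerical null space.
#' The projection of a sample is \eqn{W^T k_c(x, \cdot)}.
#'
#' @param K_centered centered symmetric kernel matrix.
#' @param floor_frac relative eigenvalue floor.
#' @return Object of class \code{kpca_proj}: \code{W} (N x m coefficients,
#'   descending eigenvalue order) and \code{eigenvalues} (length m).
#' @export
kpca_fit <- function(K_centered, floor_frac = 1e-10) {
  eg <- eigen(K_centered, symmetric = TRUE)
  keep <- eg$values > floor_frac * max(eg$values)
  if (!any(keep)) stop("no kernel PCA component above the eigenvalue floor")
  W <- sweep(eg$vectors[, keep, drop = FALSE], 2L, sqrt(eg$values[keep]), "/")
  structure(list(W = W, eigenvalues = eg$values[keep]), class = "kpca_proj")
}

#' Within-class neighborhood adjacency in kernel space
#'
#' Kernel-space squared distances \eqn{d^2_{ij} = K_{ii} + K_{jj} - 2K_{ij}};
#' for pairs where one sample is among the other's \code{t} nearest
#' within-class neighbors, the weight is
#' \eqn{\exp(-d^2_{ij} / (\sigma_i(t)\sigma_j(t)))} with \eqn{\sigma_i(t)} the
#' distance from sample i to its t-th within-class neighbor. Weights are zero
#' across classes and for non-neighbors. Rows are normalized to sum to one and
#' the matrix is then symmetrized as \eqn{(A + A^T)/2} (row normalization
#' breaks the symmetry the scatter construction expects).
#'
#' @param K kernel matrix of the training samples.
#' @param labels class labels (any type; compared with \code{==}).
#' @param t neighbor rank (\code{t <} every class size).
#' @return Object of class \code{wc_graph}: \code{A} (symmetrized, normalized),
#'   \code{A_raw}, \code{sigma}, \code{t}.
#' @export
within_class_adjacency <- function(K, labels, t = 7L) {
  N <- nrow(K)
  d2 <- outer(diag(K), diag(K), "+") - 2 * K
  d2[d2 < 0] <- 0
  for (cl in unique(labels)) if (sum(labels == cl) <= t)
    stop("t must be smaller than every class size")
  sigma <- numeric(N)
  nn <- vector("list", N)
  for (i in seq_len(N)) {
    same <- which(labels == labels[i] & seq_len(N) != i)
    ord <- same[order(d2[i, same], same)]
    nn[[i]] <- ord[seq_len(t)]
    sigma[i] <- sqrt(d2[i, nn[[i]][t]])
  }
  A <- matrix(0, N, N)
  eps <- 1e-12
  for (i in seq_len(N)) {
    for (j in nn[[i]]) {
      w <- exp(-d2[i, j] / max(sigma[i] * sigma[j], eps))
      A[i, j] <- w
      A[j, i] <- max(A[j, i], w) # mutual neighbor condition (i in NN(j) or j in NN(i))
    }
  }
  A_raw <- A
  rs <- rowSums(A)
  rs[rs == 0] <- 1
  A <- A / rs
  A <- (A + t(A)) / 2
  structure(list(A = A, A_raw = A_raw, sigma = sigma, t = t,
                 labels = labels), class = "wc_graph")
}

#' Within-class neighborhood preserving scatter matrix
#'
#' \eqn{S_w^\phi = W^T K (I - A)^T (I - A) K W} in the kernel-PCA coordinate
#' system — a positive semidefinite quadratic form penalizing embeddings that
#' break local same-class geometry.
#'
#' @param K_centered centered kernel matrix.
#' @param kpca a [kpca_fit()] object.
#' @param graph a [within_class_adjacency()] object (or a plain matrix
#'   \code{A}).
#' @return Symmetric PSD matrix (m x m).
#' @export
wcnp_scatter <- function(K_centered, kpca, graph) {
  A <- if (inherits(graph, "wc_graph")) graph$A else graph
  IA <- diag(nrow(K_centered)) - A
  M <- IA %*% K_centered %*% kpca$W
  S <- crossprod(M)
  (S + t(S)) / 2
}

#' Geometry transform S and its matrix powers
#'
#' \eqn{S = I + \frac{\eta}{2N} S_w^\phi}, symmetric positive definite by
#' construction; \eqn{S^{1/2}}, \eqn{S^{-1/2}} and \eqn{S^{-1}} come from its
#' symmetric eigendecomposition. \code{eta = 0} gives the identity.
#'
#' @param Sw scatter matrix from [wcnp_scatter()].
#' @param eta trade-off parameter (\code{>= 0}).
#' @param N training-sample count.
#' @return Object of class \code{geom_transform} with \code{S, S_half,
#'   S_invhalf, S_inv, eta}.
#' @export
geometry_transform <- function(Sw, eta = 2, N) {
  if (eta < 0) stop("eta must be >= 0")
  m <- nrow(Sw)
  S <- diag(m) + eta / (2 * N) * Sw
  eg <- eigen(S, symmetric = TRUE)
  vals <- pmax(eg$values, 1e-12)
  V <- eg$vectors
  pow <- function(p) V %*% (vals^p * t(V))
  structure(list(S = S, S_half = pow(0.5), S_invhalf = pow(-0.5),
                 S_inv = pow(-1), eta = eta, N = N),
            class = "geom_transform")
}

# shared machinery: KPCA + graph + transform; returns transformed features
wcnp_space <- function(X, labels, r, eta, t, floor_frac = 1e-10) {
  X <- as.matrix(X)
  K <- gaussian_gram(X, r = r)
  Kc <- center_gram(K)
  kp <- kpca_fit(Kc, floor_frac)
  if (eta > 0) {
    gr <- within_class_adjacency(K, labels, t)
    Sw <- wcnp_scatter(Kc, kp, gr)
  } else {
    gr <- NULL
    Sw <- matrix(0, ncol(kp$W), ncol(kp$W))
  }
  gt <- geometry_transform(Sw, eta, nrow(X))
  P <- Kc %*% kp$W               # KPCA projections, rows = samples
  Xbar <- P %*% gt$S_invhalf     # geometry-transformed features
  list(X = X, r = r, K = K, Kc = Kc, kpca = kp, graph = gr, transform = gt,
       Xbar = Xbar, col_means = colMeans(K), grand_mean = mean(K))
}

# transformed features for new samples; also returns the centered cross kernel
wcnp_transform_new <- function(space, Xnew) {
  Knew <- gaussian_gram(as.matrix(Xnew), space$X, r = space$r)
  Kc_new <- center_cross(Knew, space$col_means, space$grand_mean)
  list(Kc = Kc_new,
       Xbar = Kc_new %*% space$kpca$W %*% space$transform$S_invhalf)
}

#' Within-class neighborhood preserved C-SVC
#'
#' Builds the kernel-PCA projection of the training samples, the within-class
#' neighborhood graph and the geometry transform \eqn{S^{-1/2}}, maps every
#' sample to \eqn{\bar x_i = S^{-1/2} W^T k_c(x_i, \cdot)}, and solves the
#' standard soft-margin C-SVM with a linear kernel in the transformed space
#' (the nonlinearity already lives in the kernel-PCA map). With
#' \code{eta = 0} the model degrades to a plain Gaussian-kernel C-SVM.
#' A logistic (Platt-style) map fitted on the training decision values supplies
#' class probabilities.
#'
#' @param X feature matrix, rows = samples.
#' @param y labels in \code{{-1, +1}} (coerced; both classes required).
#' @param C slack penalty.
#' @param r Gaussian kernel width.
#' @param eta geometry trade-off.
#' @param t within-class neighbor rank.
#' @return Object of class \code{wcnp_svc} with support coefficients
#'   \code{alpha_y} (\eqn{\alpha_i^* y_i}), \code{sv_index}, bias \code{b},
#'   primal weight \code{w_bar} and the embedded space.
#' @export
csvc_fit <- function(X, y, C = 0.5, r = 2, eta = 2, t = 7L) {
  y <- ifelse(as.numeric(y) > 0, 1, -1)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  space <- wcnp_space(X, y, r, eta, t)
  fit <- e1071::svm(x = space$Xbar, y = factor(y, levels = c(-1, 1)),
                    scale = FALSE, kernel = "linear", cost = C)
  dvm <- attr(stats::predict(fit, space$Xbar, decision.values = TRUE),
              "decision.values")
  # e1071 orients the decision value toward the first class of its column
  # label "A/B"; flip so that a positive score means class +1
  flip <- if (startsWith(colnames(dvm)[1L], "-1")) -1 else 1
  score <- flip * dvm[, 1L]
  alpha_y <- flip * fit$coefs[, 1L]
  b <- flip * (-fit$rho)
  w_bar <- drop(crossprod(space$Xbar[fit$index, , drop = FALSE], alpha_y))
  platt <- suppressWarnings(stats::glm.fit(cbind(1, score),
                                           (y + 1) / 2,
                                           family = stats::binomial()))$coefficients
  if (any(!is.finite(platt))) platt <- c(0, 1)
  platt <- pmin(pmax(platt, -500), 500) # separable data blows the MLE up
  structure(list(space = space, C = C, eta = eta, t = t, r = r,
                 alpha_y = alpha_y, sv_index = fit$index, b = b,
                 w_bar = w_bar, platt = platt, y = y,
                 train_score = score),
            class = "wcnp_svc")
}

#' Decision values, classes and probabilities of a WCNP classifier
#'
#' The transformed-linear route evaluates \eqn{\langle \bar w, \bar x\rangle +
#' b^*}; the kernel route evaluates the representer form
#' \eqn{\sum_i \alpha_i^* y_i\, k_c(x_i,\cdot)^T W S^{-1} W^T k_c(x,\cdot) +
#' b^*}. The two agree to machine precision — exercising the identity between
#' the transformed primal and the kernel-form decision rule.
#'
#' @param model a fitted \code{wcnp_svc}.
#' @param Xnew matrix of new samples (rows).
#' @param route \code{"linear"} or \code{"kernel"}.
#' @return data.frame with \code{score}, \code{class} (\eqn{\pm 1}) and
#'   \code{prob} (positive-class probability).
#' @export
csvc_decision <- function(model, Xnew, route = c("linear", "kernel")) {
  route <- match.arg(route)
  if (!inherits(model, "wcnp_svc")) stop("not a fitted wcnp_svc model")
  tr <- wcnp_transform_new(model$space, Xnew)
  if (route == "linear") {
    score <- drop(tr$Xbar %*% model$w_bar) + model$b
  } else {
    sp <- model$space
    # k_c(x,.)' W S^{-1} W' k_c(x_i,.), evaluated projection-first to keep the
    # representer form well conditioned
    proj_new <- tr$Kc %*% sp$kpca$W
    proj_sv <- crossprod(sp$kpca$W, sp$Kc[, model$sv_index, drop = FALSE])
    score <- drop(proj_new %*% sp$transform$S_inv %*% proj_sv %*%
                    model$alpha_y) + model$b
  }
  prob <- 1 / (1 + exp(-(model$platt[1L] + model$platt[2L] * score)))
  data.frame(score = score, class = ifelse(score >= 0, 1, -1), prob = prob)
}

#' @export
predict.wcnp_svc <- function(object, newdata, ...) {
  csvc_decision(object, newdata, ...)
}

#' @export
print.wcnp_svc <- function(x, ...) {
  cat(sprintf("<wcnp_svc> N=%d, SVs=%d, C=%g, r=%g, eta=%g, t=%d\n",
              nrow(x$space$X), length(x$sv_index), x$C, x$r, x$eta, x$t))
  invisible(x)
}

#' Anchor/box regression codec
#'
#' Parameterizes the transformation from an anchor box to a target box as
#' \eqn{z = ((x_p - x_a)/w_a, (y_p - y_a)/h_a, w_p/w_a, h_p/h_a)} (ratios, not
#' logs). [bbox_decode()] inverts it exactly:
#' \eqn{(x_a + w_a z_1, y_a + h_a z_2, w_a z_3, h_a z_4)}, optionally clipped
#' to image bounds.
#'
#' @param anchor,proposal boxes as \code{(x_center, y_center, width, height)}
#'   vectors or matrices (rows = boxes).
#' @return [bbox_encode()]: z vectors (same shape as input);
#'   [bbox_decode()]: boxes.
#' @export
bbox_encode <- function(anchor, proposal) {
  a <- rbind(anchor); p <- rbind(proposal)
  if (any(a[, 3L] <= 0) || any(a[, 4L] <= 0)) stop("anchor size must be positive")
  z <- cbind((p[, 1L] - a[, 1L]) / a[, 3L], (p[, 2L] - a[, 2L]) / a[, 4L],
             p[, 3L] / a[, 3L], p[, 4L] / a[, 4L])
  colnames(z) <- c("z1", "z2", "z3", "z4")
  if (nrow(z) == 1L && is.null(dim(anchor))) drop(z) else z
}

#' @rdname bbox_encode
#' @param z regression 4-vector(s); \code{z3, z4} must be positive.
#' @param bounds optional \code{c(H, W)} image bounds for clipping.
#' @export
bbox_decode <- function(anchor, z, bounds = NULL) {
  a <- rbind(anchor); zz <- rbind(z)
  if (any(zz[, 3L] <= 0) || any(zz[, 4L] <= 0))
    stop("size factors z3, z4 must be positive")
  out <- cbind(x_center = a[, 1L] + a[, 3L] * zz[, 1L],
               y_center = a[, 2L] + a[, 4L] * zz[, 2L],
               width = a[, 3L] * zz[, 3L], height = a[, 4L] * zz[, 4L])
  if (!is.null(bounds)) {
    H <- bounds[1L]; W <- bounds[2L]
    x0 <- pmax(0, out[, 1L] - out[, 3L] / 2); x1 <- pmin(W, out[, 1L] + out[, 3L] / 2)
    y0 <- pmax(0, out[, 2L] - out[, 4L] / 2); y1 <- pmin(H, out[, 2L] + out[, 4L] / 2)
    x1 <- pmax(x1, x0 + 1); y1 <- pmax(y1, y0 + 1)
    out <- cbind(x_center = (x0 + x1) / 2, y_center = (y0 + y1) / 2,
                 width = x1 - x0, height = y1 - y0)
  }
  if (nrow(out) == 1L && is.null(dim(anchor))) drop(out) else out
}

# true multi-output epsilon-insensitive objective
msvr_objective <- function(B, b, Phi, Z, C, epsilon) {
  E <- Z - Phi %*% B - matrix(b, nrow(Z), length(b), byrow = TRUE)
  u <- sqrt(rowSums(E^2))
  0.5 * sum(B^2) + C * sum(pmax(u - epsilon, 0)^2)
}

#' Within-class neighborhood preserved MIMO epsilon-SVR
#'
#' Multi-output support vector regression with the epsilon-insensitive loss
#' \eqn{L(u) = (u - \epsilon)^2} on the joint residual norm
#' \eqn{u_i = \lVert z_i - B^T \bar x_i - b \rVert}, fitted in the same
#' geometry-transformed kernel-PCA space as the classifier. Solved by
#' iteratively reweighted least squares: weights
#' \eqn{a_i = 2C(u_i - \epsilon)/u_i} for \eqn{u_i \ge \epsilon} (else 0), a
#' regularized weighted least-squares subproblem for \code{B, b}, and a
#' step-halving line search whenever the full step would increase the true
#' objective; convergence at relative objective change below \code{tol}.
#'
#' @param X feature matrix (rows = samples, \code{N >= 5}).
#' @param Z target matrix (N x q, q = 4 for box regression).
#' @param C slack penalty.
#' @param epsilon insensitivity-zone radius on the residual norm.
#' @param r Gaussian kernel width.
#' @param eta geometry trade-off.
#' @param t within-class neighbor rank.
#' @param labels class labels for the neighborhood graph (default: one class).
#' @param tol relative objective-change tolerance.
#' @param max_iter IRWLS iteration cap.
#' @return Object of class \code{wcnp_svr} with primal coefficients \code{B},
#'   representer coefficients \code{beta}, biases \code{b}, the objective
#'   \code{trace} and \code{converged} flag.
#' @export
msvr_fit <- function(X, Z, C = 0.5, epsilon = 1.5, r = 2, eta = 2, t = 7L,
                     labels = NULL, tol = 1e-6, max_iter = 200L) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  if (nrow(X) < 5L) stop("need at least 5 samples")
  if (any(!is.finite(Z))) stop("targets must be finite")
  if (is.null(labels)) labels <- rep(1L, nrow(X))
  space <- wcnp_space(X, labels, r, eta, t)
  Phi <- space$Xbar
  N <- nrow(Phi); m <- ncol(Phi); q <- ncol(Z)
  B <- matrix(0, m, q)
  b <- colMeans(Z)
  obj <- msvr_objective(B, b, Phi, Z, C, epsilon)
  trace <- obj
  converged <- FALSE
  backtrack <- function(dB, db, obj) {
    s <- 1
    repeat {
      Bt <- B + s * dB; bt <- b + s * db
      ot <- msvr_objective(Bt, bt, Phi, Z, C, epsilon)
      if (ot <= obj || s < 1e-12) break
      s <- s / 2
    }
    list(B = Bt, b = bt, obj = ot, ok = ot <= obj)
  }
  for (it in seq_len(max_iter)) {
    E <- Z - Phi %*% B - matrix(b, N, q, byrow = TRUE)
    u <- sqrt(rowSums(E^2))
    a <- ifelse(u >= epsilon, 2 * C * (u - epsilon) / pmax(u, 1e-300), 0)
    step <- NULL
    if (any(a > 0)) {
      # quasi-Newton IRWLS direction from the weighted least-squares subproblem
      Pa <- Phi * a
      M <- rbind(cbind(crossprod(Phi, Pa) + diag(m), colSums(Pa)),
                 c(colSums(Pa), sum(a)))
      rhs <- rbind(crossprod(Pa, Z), colSums(Z * a))
      sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
      if (!is.null(sol)) {
        cand <- backtrack(sol[seq_len(m), , drop = FALSE] - B,
                          sol[m + 1L, ] - b, obj)
        if (cand$ok) step <- cand
      }
    }
    if (is.null(step)) {
      # fall back to a backtracking gradient step on the true objective
      gB <- B - crossprod(Phi, E * a)
      gb <- -colSums(E * a)
      gnorm <- sqrt(sum(gB^2) + sum(gb^2))
      if (gnorm < 1e-12) { converged <- TRUE; break } # stationary
      cand <- backtrack(-gB / max(1, gnorm), -gb / max(1, gnorm), obj)
      if (!cand$ok) { converged <- TRUE; break } # numerically stationary
      step <- cand
    }
    delta <- obj - step$obj
    B <- step$B; b <- step$b; obj <- step$obj
    trace <- c(trace, obj)
    if (delta <= tol * max(obj, 1e-12)) { converged <- TRUE; break }
  }
  if (!converged)
    warning("IRWLS did not converge in ", max_iter,
            " iterations; final objective ", signif(obj, 6))
  # representer coefficients beta with Phi' beta = B, via the closed form
  # (Phi'Phi)^{-1} = S^{1/2} D^{-1} S^{1/2} (D = Gram eigenvalues), which keeps
  # the kernel-form predictions exactly equal to the primal ones
  Sh <- space$transform$S_half
  beta <- Phi %*% (Sh %*% ((Sh %*% B) / space$kpca$eigenvalues))
  structure(list(space = space, B = B, b = b, beta = beta, C = C,
                 epsilon = epsilon, r = r, eta = eta, t = t,
                 trace = trace, converged = converged),
            class = "wcnp_svr")
}

#' Predict multi-output regression targets
#'
#' The linear route evaluates \eqn{B^T \bar x + b}; the kernel route uses the
#' representer form \eqn{\hat z_j = \sum_i [k_c(x_i,\cdot)^T W S^{-1} W^T
#' k_c(x,\cdot)]_i \beta_{ji} + b_j}. Both agree to machine precision.
#'
#' @param model a fitted \code{wcnp_svr}.
#' @param Xnew new samples (rows).
#' @param route \code{"linear"} or \code{"kernel"}.
#' @return Matrix of predicted target vectors (rows).
#' @export
msvr_predict <- function(model, Xnew, route = c("linear", "kernel")) {
  route <- match.arg(route)
  if (!inherits(model, "wcnp_svr")) stop("not a fitted wcnp_svr model")
  tr <- wcnp_transform_new(model$space, Xnew)
  if (route == "linear") {
    out <- tr$Xbar %*% model$B
  } else {
    sp <- model$space
    proj_new <- tr$Kc %*% sp$kpca$W
    proj_tr <- crossprod(sp$kpca$W, sp$Kc)
    out <- proj_new %*% sp$transform$S_inv %*% (proj_tr %*% model$beta)
  }
  sweep(out, 2L, model$b, "+")
}

#' @export
predict.wcnp_svr <- function(object, newdata, ...) {
  msvr_predict(object, newdata, ...)
}

#' @export
print.wcnp_svr <- function(x, ...) {
  cat(sprintf(
    "<wcnp_svr> N=%d, q=%d, C=%g, eps=%g, eta=%g; %d IRWLS steps%s\n",
    nrow(x$space$X), ncol(x$B), x$C, x$epsilon, x$eta, length(x$trace) - 1L,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}
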