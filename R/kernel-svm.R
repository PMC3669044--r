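#' Kernel width heuristic
#'
#' sigma is the median, over positive training points, of the Euclidean
#' distance to the nearest negative training point (median of an even count
#' = mean of the two central values, the usual `median()`). If that median is
#' zero because some positive coincides with a negative, the smallest
#' positive nearest-negative distance is used instead; if every positive
#' coincides with a negative the heuristic is undefined and an error is
#' raised. Distances are computed on imputed (complete) feature vectors.
#'
#' @param x numeric feature matrix, one row per training point.
#' @param labels numeric vector in \{-1, +1\}.
#' @return Positive scalar sigma, in feature-distance units.
#' @export
sigma_heuristic <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.numeric(labels)
  stopifnot(nrow(x) == length(labels), all(labels %in% c(-1, 1)))
  pos <- x[labels == 1, , drop = FALSE]
  neg <- x[labels == -1, , drop = FALSE]
  if (nrow(pos) == 0L || nrow(neg) == 0L) {
    stop("sigma heuristic needs at least one point of each class")
  }
  d2 <- cross_sqdist(pos, neg)
  nearest <- sqrt(pmax(apply(d2, 1L, min), 0))
  s <- stats::median(nearest)
  if (s == 0) {
    # a positive coincides with a negative: fall back to the smallest
    # strictly positive positive-negative distance
    nonzero <- d2[d2 > 0]
    if (length(nonzero) == 0L) {
      stop("all positive points coincide with negatives; sigma undefined")
    }
    s <- sqrt(min(nonzero))
  }
  s
}

# squared Euclidean distances between rows of a and rows of b
cross_sqdist <- function(a, b) {
  an <- rowSums(a * a)
  bn <- rowSums(b * b)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Radial-basis kernel block
#'
#' `K(x, y) = exp(-||x - y||^2 / sigma^2)`, so `K(x, x) = 1` and off-diagonal
#' entries lie in (0, 1].
#'
#' @param x_a,x_b numeric feature matrices (rows = points). `x_b` defaults to
#'   `x_a`, giving the symmetric kernel over one set.
#' @param sigma positive kernel width.
#' @return Numeric matrix `nrow(x_a)` by `nrow(x_b)`.
#' @export
rbf_kernel <- function(x_a, x_b = x_a, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be a positive scalar")
  }
  d2 <- cross_sqdist(as.matrix(x_a), as.matrix(x_b))
  if (missing(x_b)) diag(d2) <- 0   # kill roundoff so K(x, x) is exactly 1
  exp(-d2 / sigma^2)
}

#' Build the training kernel with class-imbalance diagonal augmentation
#'
#' The self-similarity of each training point is raised by
#' `lambda * |C| / N`, where `|C|` is the size of the point's class, `N` the
#' training size, and `lambda = m / 2` with `m` the median of the
#' pre-augmentation kernel diagonal (for an RBF kernel `m = 1`, so
#' `lambda = 1/2`). Off-diagonal entries are untouched. The augmentation
#' realizes a 2-norm soft margin whose regularization is proportional to
#' class size, penalizing the majority class more: with a 1:4
#' positive:negative split the negative-class augmentation is exactly 4 times
#' the positive-class one. It also makes the dual problem strictly convex.
#'
#' @param k symmetric numeric kernel matrix over the training set
#'   (un-augmented).
#' @param labels numeric vector in \{-1, +1\}, one per row of `k`.
#' @param sigma optional kernel width to record.
#' @return A `kernel_matrix`: list with `values` (augmented), `base`
#'   (un-augmented), `aug` (per-point diagonal addition), `sigma`, `lam`,
#'   `m`, `class_sizes` (named `n_pos`, `n_neg`), `labels`.
#' @export
augment_diagonal <- function(k, labels, sigma = NA_real_) {
  k <- as.matrix(k)
  labels <- as.numeric(labels)
  if (nrow(k) != ncol(k)) stop("kernel must be square")
  if (length(labels) != nrow(k)) stop("labels length must match kernel size")
  if (!all(labels %in% c(-1, 1))) stop("labels must be -1/+1")
  n <- length(labels)
  n_pos <- sum(labels == 1)
  n_neg <- n - n_pos
  m <- stats::median(diag(k))
  lam <- m / 2
  class_size <- ifelse(labels == 1, n_pos, n_neg)
  aug <- lam * class_size / n
  values <- k
  diag(values) <- diag(k) + aug
  structure(
    list(values = values, base = k, aug = aug, sigma = sigma, lam = lam,
         m = m, class_sizes = c(n_pos = n_pos, n_neg = n_neg),
         labels = labels),
    class = "kernel_matrix"
  )
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf(
    "kernel_matrix: %d x %d, sigma = %.4g, lambda = %.4g (m = %.4g), N+ = %d, N- = %d\n",
    nrow(x$values), ncol(x$values), x$sigma, x$lam, x$m,
    x$class_sizes[["n_pos"]], x$class_sizes[["n_neg"]]))
  invisible(x)
}

#' Train a two-class SVM on a precomputed augmented kernel
#'
#' Solves the hard-margin dual on the augmented kernel,
#' \deqn{\min_\alpha \tfrac12 \alpha^T Q \alpha - \sum_i \alpha_i,
#'       \quad Q_{ij} = y_i y_j K_{ij}, \quad
#'       \sum_i \alpha_i y_i = 0, \ \alpha_i \ge 0,}
#' with no upper box constraint: the diagonal augmentation already implements
#' the (2-norm) soft margin, and it makes Q positive definite, so the
#' optimum is unique. The solver is sequential minimal optimization with
#' maximal-violating-pair working-set selection; the bias is the average of
#' the per-support-vector estimates, which places `y_i f(x_i) = 1` on the
#' support vectors (in the augmented geometry).
#'
#' @param kernel a `kernel_matrix` from [augment_diagonal()].
#' @param tol KKT violation tolerance for convergence.
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   residual.
#' @return An `svm_model`: list with `alpha`, `bias`, `support` (indices
#'   with `alpha > 1e-8 * max(alpha)`), `labels`, `objective` (dual value
#'   `sum(alpha) - 0.5 * alpha' Q alpha`), `kkt_residual`, `iterations`.
#' @export
train_svm <- function(kernel, tol = 1e-8, max_iter = 200000L) {
  stopifnot(inherits(kernel, "kernel_matrix"))
  y <- kernel$labels
  n <- length(y)
  if (all(y == 1) || all(y == -1)) stop("both classes required")
  q <- kernel$values * tcrossprod(y)
  alpha <- numeric(n)
  grad <- rep(-1, n)                 # gradient of 0.5 a'Qa - sum(a) at a = 0
  it <- 0L
  residual <- Inf
  repeat {
    it <- it + 1L
    gy <- -y * grad
    up <- y == 1 | alpha > 0         # pairs along which alpha may move
    low <- y == -1 | alpha > 0
    i <- which(up)[which.max(gy[up])]
    j <- which(low)[which.min(gy[low])]
    m_up <- gy[i]
    m_low <- gy[j]
    residual <- m_up - m_low
    if (residual <= tol) break
    if (it > max_iter) {
      stop(sprintf("SVM solver did not converge: KKT residual %.3g after %d iterations",
                   m_up - m_low, max_iter))
    }
    a2 <- q[i, i] + q[j, j] - 2 * y[i] * y[j] * q[i, j]
    t_step <- (m_up - m_low) / a2
    if (y[i] == -1) t_step <- min(t_step, alpha[i])
    if (y[j] == 1) t_step <- min(t_step, alpha[j])
    d_i <- y[i] * t_step
    d_j <- -y[j] * t_step
    alpha[i] <- alpha[i] + d_i
    alpha[j] <- alpha[j] + d_j
    # clamp tiny negatives from roundoff
    if (alpha[i] < 0) alpha[i] <- 0
    if (alpha[j] < 0) alpha[j] <- 0
    grad <- grad + q[, i] * d_i + q[, j] * d_j
  }
  sv <- if (max(alpha) > 0) which(alpha > 1e-8 * max(alpha)) else integer(0)
  bias <- if (length(sv)) mean((-y * grad)[sv]) else 0
  structure(
    list(alpha = alpha, bias = bias, support = sv, labels = y,
         objective = sum(alpha) - 0.5 * drop(crossprod(alpha, q %*% alpha)),
         kkt_residual = residual, iterations = it),
    class = "svm_model"
  )
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("svm_model: %d support vectors of %d points, bias %.4g, dual objective %.6g\n",
              length(x$support), length(x$alpha), x$bias, x$objective))
  invisible(x)
}

#' Discriminant values for new points
#'
#' `f(x) = sum_i alpha_i y_i K(x, x_i) + b` over the support vectors. The
#' cross-kernel must be the plain (un-augmented) kernel: the diagonal
#' augmentation applies to training self-similarities only, so evaluating a
#' training point through its un-augmented kernel row reproduces the
#' training-time discriminant.
#'
#' @param model an `svm_model`.
#' @param k_cross numeric matrix, rows = evaluation points, columns indexed
#'   identically to the model's training set.
#' @return Numeric vector of discriminant values, one per row of `k_cross`.
#' @export
discriminants <- function(model, k_cross) {
  stopifnot(inherits(model, "svm_model"))
  k_cross <- as.matrix(k_cross)
  if (ncol(k_cross) != length(model$alpha)) {
    stop("cross-kernel columns must match the training set size")
  }
  unname(drop(k_cross %*% (model$alpha * model$labels))) + model$bias
}
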