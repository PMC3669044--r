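# Independent oracles used by the unit and acceptance tests. These share no
# code with the implementation paths they check.

# Exhaustive active-set QP oracle for the hard-margin dual on a (strictly
# convex, augmented) kernel: minimize 0.5 a'Qa - sum(a) s.t. y'a = 0, a >= 0,
# with Q = (y y') * K. Enumerates every support subset, solves the KKT
# system, and returns the first (hence, by convexity, the) feasible solution.
oracle_svm <- function(k_aug, y) {
  n <- length(y)
  q <- k_aug * tcrossprod(y)
  bits <- 2^(0:(n - 1))
  for (mask in seq_len(2^n - 1)) {
    s <- which(bitwAnd(mask, bits) > 0)
    if (length(unique(y[s])) < 2L) next
    ns <- length(s)
    kkt <- rbind(cbind(q[s, s, drop = FALSE], -y[s]), c(y[s], 0))
    rhs <- c(rep(1, ns), 0)
    sol <- tryCatch(solve(kkt, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    a_s <- sol[seq_len(ns)]
    beta <- sol[ns + 1L]
    if (any(a_s < -1e-9)) next
    alpha <- numeric(n)
    alpha[s] <- pmax(a_s, 0)
    # dual feasibility of the zero coordinates
    slack <- drop(q %*% alpha) - 1 - beta * y
    if (any(slack[-s] < -1e-7)) next
    return(list(alpha = alpha, bias = -beta,
                objective = sum(alpha) - 0.5 * drop(crossprod(alpha, q %*% alpha))))
  }
  stop("oracle found no KKT point")
}

# Exhaustive precision-recall enumeration: one point per distinct score,
# predicted positive iff score >= threshold.
oracle_pr <- function(probs, labels) {
  pos <- labels == 1
  thr <- sort(unique(probs), decreasing = TRUE)
  do.call(rbind, lapply(thr, function(t) {
    pred <- probs >= t
    data.frame(threshold = t, tp = sum(pred & pos), pp = sum(pred),
               precision = sum(pred & pos) / sum(pred),
               recall = sum(pred & pos) / sum(pos))
  }))
}

oracle_precision_at_recall <- function(probs, labels, r) {
  cv <- oracle_pr(probs, labels)
  max(cv$precision[cv$recall >= r])
}

oracle_gene_precision <- function(p_gene, probs, labels) {
  cv <- oracle_pr(probs, labels)
  ok <- cv$threshold <= p_gene
  if (!any(ok)) 0 else max(cv$precision[ok])
}

# Random small SVM task over an RBF kernel with the package's augmentation
# recomputed independently (so only train_svm itself is under test).
random_svm_task <- function(n, p = 3L) {
  y <- c(1, -1, sample(c(-1, 1), n - 2L, replace = TRUE))
  x <- matrix(rnorm(n * p), n, p) + 0.5 * y  # mild class separation
  d2 <- unname(as.matrix(dist(x)))^2
  sigma <- sqrt(median(d2[d2 > 0]))
  k <- exp(-d2 / sigma^2)
  n_pos <- sum(y == 1)
  lam <- median(diag(k)) / 2
  k_aug <- k
  diag(k_aug) <- diag(k) + lam * ifelse(y == 1, n_pos, n - n_pos) / n
  list(x = x, y = y, k = k, k_aug = k_aug, sigma = sigma)
}
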