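#' Smoothed calibration targets
#'
#' Instead of 0/1 labels, the sigmoid is fitted to smoothed targets
#' `t = (N+ + 1) / (N+ + 2)` for every positive and `t = 1 / (N- + 2)` for
#' every negative of the calibration fold, where `N+`, `N-` are the fold's
#' class sizes. The targets stay strictly inside (0, 1), which keeps the
#' maximum-likelihood problem well posed even when the discriminant values
#' separate the classes perfectly.
#'
#' @param labels numeric vector in \{-1, +1\} for the calibration fold.
#' @return A `calibration_targets` list: `t` (per-point target), `n_pos`,
#'   `n_neg`.
#' @export
platt_targets <- function(labels) {
  labels <- as.numeric(labels)
  stopifnot(all(labels %in% c(-1, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == -1)
  if (n_pos == 0L || n_neg == 0L) {
    stop("calibration fold must contain both classes")
  }
  t <- ifelse(labels == 1, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  structure(list(t = t, n_pos = n_pos, n_neg = n_neg),
            class = "calibration_targets")
}

# log(1 + exp(z)) without overflow
log1pexp <- function(z) ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))

sigmoid_nll <- function(par, f, t) {
  z <- par[1L] * f + par[2L]
  # nll contribution: log(1 + e^z) - (1 - t) * z
  sum(log1pexp(z) - (1 - t) * z)
}

#' Fit the probability-calibration sigmoid
#'
#' Model: `p(y = 1 | x) = 1 / (1 + exp(a * f(x) + b))`, fitted to the
#' smoothed targets of [platt_targets()] by minimizing the cross-entropy
#' (the negative of the log-likelihood), via Newton iterations with
#' backtracking line search on numerically stable `log1p`/`exp`
#' formulations. Note the sign convention: when positives have larger
#' discriminants than negatives the fitted slope `a` is negative.
#'
#' Initialization: `a = 0`, `b = log((N- + 1) / (N+ + 1))`, which starts the
#' fit at the smoothed class prior.
#'
#' @param f numeric vector of discriminant values for the calibration fold.
#' @param targets a `calibration_targets` object.
#' @param grad_tol stop when the gradient norm falls below this.
#' @param max_iter Newton iteration cap; if reached, the best iterate is
#'   returned with `converged = FALSE` and a warning.
#' @return A `sigmoid_fit` list: `a`, `b`, `converged`, `final_nll`,
#'   `iterations`.
#' @export
fit_sigmoid <- function(f, targets, grad_tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(targets, "calibration_targets"))
  f <- as.numeric(f)
  t <- targets$t
  if (length(f) != length(t)) stop("f and targets length mismatch")
  if (length(unique(f)) < 2L) {
    stop("all discriminant values identical; sigmoid slope unidentifiable")
  }
  par <- c(a = 0, b = log((targets$n_neg + 1) / (targets$n_pos + 1)))
  nll <- sigmoid_nll(par, f, t)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    z <- par[1L] * f + par[2L]
    p <- 1 / (1 + exp(z))
    gz <- t - p                      # d nll / d z, with p = 1/(1+e^z)
    grad <- c(sum(gz * f), sum(gz))
    if (sqrt(sum(grad^2)) <= grad_tol) {
      converged <- TRUE
      break
    }
    w <- p * (1 - p)
    h <- matrix(c(sum(w * f * f), sum(w * f), sum(w * f), sum(w)), 2L, 2L)
    step <- tryCatch(-solve(h + diag(1e-12, 2L), grad),
                     error = function(e) -grad)
    # backtracking line search on the cross-entropy
    eta <- 1
    repeat {
      cand <- par + eta * step
      cand_nll <- sigmoid_nll(cand, f, t)
      if (is.finite(cand_nll) && cand_nll <= nll + 1e-12) break
      eta <- eta / 2
      if (eta < 1e-12) break
    }
    if (eta < 1e-12) break           # no descent possible; treat as stalled
    par <- par + eta * step
    nll <- cand_nll
  }
  if (!converged) {
    z <- par[1L] * f + par[2L]
    p <- 1 / (1 + exp(z))
    grad <- c(sum((t - p) * f), sum(t - p))
    if (sqrt(sum(grad^2)) <= grad_tol) converged <- TRUE
    else warning("sigmoid fit did not converge; best iterate returned")
  }
  structure(list(a = unname(par[1L]), b = unname(par[2L]),
                 converged = converged, final_nll = nll, iterations = it),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("sigmoid_fit: a = %.6g, b = %.6g, nll = %.6g, converged = %s\n",
              x$a, x$b, x$final_nll, x$converged))
  invisible(x)
}

#' Map discriminant values to posterior probabilities
#'
#' Elementwise `p = 1 / (1 + exp(a * f + b))`; output strictly inside (0, 1)
#' for finite `f`.
#'
#' @param fit a `sigmoid_fit`.
#' @param f numeric vector of discriminant values.
#' @return Numeric vector of class-membership probabilities.
#' @export
apply_sigmoid <- function(fit, f) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  z <- fit$a * as.numeric(f) + fit$b
  p <- 1 / (1 + exp(z))
  # keep strictly inside (0,1) against floating underflow at extreme f
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps)
}
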