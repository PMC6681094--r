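## Phylogenetic signal: GLS mean and evolutionary rate, Blomberg's K with a
## contrast-variance randomization test, Pagel's lambda by profile maximum
## likelihood with a likelihood-ratio test, and phylogenetic standardization
## of predictors.

## Align a named vector (or the rows of a matrix) to the tip order of V.
align_to_tips <- function(x, tip_order) {
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.matrix(x)
    if (is.null(rownames(x))) {
      if (nrow(x) != length(tip_order)) stop("row count != tip count", call. = FALSE)
      rownames(x) <- tip_order
    }
    missing <- setdiff(tip_order, rownames(x))
    if (length(missing)) stop("values missing for tips: ",
                              paste(missing, collapse = ", "), call. = FALSE)
    x[tip_order, , drop = FALSE]
  } else {
    if (is.null(names(x))) {
      if (length(x) != length(tip_order)) stop("length != tip count", call. = FALSE)
      names(x) <- tip_order
    }
    missing <- setdiff(tip_order, names(x))
    if (length(missing)) stop("values missing for tips: ",
                              paste(missing, collapse = ", "), call. = FALSE)
    x[tip_order]
  }
}

#' Phylogenetic (GLS) mean and evolutionary rate
#'
#' For tip values `X` (one or more variables) and tip covariance `V`, the
#' phylogenetic mean per variable is the generalized-least-squares estimate
#' `a = (1' V^-1 1)^-1 1' V^-1 x`, and the evolutionary rate (or
#' cross-variable rate matrix) is
#' `R = (X - 1 a')' V^-1 (X - 1 a') / (n - 1)`. The `n - 1` divisor makes
#' star-tree standardization coincide with the ordinary sample z-score; pass
#' `divisor = "n"` for the maximum-likelihood convention.
#'
#' @param x Named numeric vector or matrix of per-tip values (rows = tips).
#' @param V A `phylo_cov` (or plain covariance matrix with tip rownames).
#' @param divisor `"n-1"` (default) or `"n"`.
#' @return List with `a_hat` (per-variable GLS mean) and `rate` (rate matrix
#'   `R`; a 1x1 matrix for a single variable).
#' @export
phylo_mean_rate <- function(x, V, divisor = c("n-1", "n")) {
  divisor <- match.arg(divisor)
  tip_order <- rownames(V)
  X <- align_to_tips(x, tip_order)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1, dimnames = list(tip_order, "x"))
  n <- nrow(X)
  sv <- solve_vcv(V, b = cbind(1, X))      # V^-1 [1, X]
  Vinv_one <- sv$x[, 1L]
  denom <- sum(Vinv_one)                   # 1' V^-1 1
  if (!is.finite(denom) || denom <= 0) stop("singular V after jitter", call. = FALSE)
  a_hat <- as.vector(crossprod(Vinv_one, X)) / denom
  names(a_hat) <- colnames(X)
  centered <- sweep(X, 2, a_hat)
  Vinv_centered <- sv$x[, -1L, drop = FALSE] - outer(Vinv_one, a_hat)
  R <- crossprod(centered, Vinv_centered) /
    (if (divisor == "n-1") n - 1 else n)
  list(a_hat = a_hat, rate = R)
}

#' Blomberg's K for a continuous trait
#'
#' `K = (MSE0/MSE) / E[MSE0/MSE]` where `MSE0` is the mean squared deviation
#' of tip values from the phylogenetic mean, `MSE` the GLS analogue under the
#' Brownian-motion covariance `V`, and the expectation under BM is
#' `(tr(V) - n / (1'V^-1 1)) / (n - 1)`. `K = 1` is the BM expectation;
#' `K < 1` means relatives resemble each other less than BM predicts.
#'
#' @param x Named per-tip values.
#' @param tree A `phylo` object (BM covariance is built internally), or pass
#'   a precomputed `V`.
#' @param V Optional precomputed BM covariance.
#' @return The scalar K.
#' @export
blomberg_k <- function(x, tree = NULL, V = NULL) {
  if (is.null(V)) V <- vcv_from_tree(tree, "BM")
  tip_order <- rownames(V)
  x <- align_to_tips(x, tip_order)
  n <- length(x)
  if (n < 3L) stop("need at least 3 tips", call. = FALSE)
  sv <- solve_vcv(V, b = cbind(1, x))
  denom <- sum(sv$x[, 1L])
  a_hat <- sum(sv$x[, 1L] * x) / denom
  dev <- x - a_hat
  mse0 <- sum(dev^2) / (n - 1)
  mse <- as.numeric(sum(dev * (sv$x[, 2L] - a_hat * sv$x[, 1L]))) / (n - 1)
  if (mse0 <= .Machine$double.eps) stop("trait constant", call. = FALSE)
  expected <- (sum(diag(unclass(V))) - n / denom) / (n - 1)
  (mse0 / mse) / expected
}

#' Randomization test for phylogenetic signal (Blomberg's K)
#'
#' Reports K from the observed data and a permutation P-value for signal.
#' The test statistic is the variance (mean square) of the standardized
#' independent contrasts; tip values are shuffled across tips `n_reps`
#' times, and signal corresponds to the observed contrast variance being
#' *small*, so `p = (1 + #\{null <= observed\}) / (n_reps + 1)`.
#' Contrasts are linear in the tip values, so the permutation null is
#' computed with one matrix product over all permutations.
#'
#' @param x Named per-tip values.
#' @param tree A `phylo` object.
#' @param n_reps Number of randomizations (default 999).
#' @param seed Integer seed (required; no silent nondeterminism).
#' @return Object of class `k_result`: list `K`, `p_value`, `obs_statistic`,
#'   `n_reps`, `seed`, `n`.
#' @export
k_randomization_test <- function(x, tree, n_reps = 999, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  set.seed(seed)
  x <- align_to_tips(x, tree$tip.label)
  n <- length(x)
  K <- blomberg_k(x, tree)
  L <- pic_operator(tree)                  # (n-1) x n, rows standardized contrasts
  obs <- mean((L %*% x)^2)
  perm_idx <- replicate(n_reps, sample.int(n))
  Xp <- matrix(x[perm_idx], nrow = n)
  null_stat <- colMeans((L %*% Xp)^2)
  p <- (1 + sum(null_stat <= obs)) / (n_reps + 1)
  structure(list(K = K, p_value = p, obs_statistic = obs,
                 n_reps = n_reps, seed = seed, n = n),
            class = "k_result")
}

#' @export
print.k_result <- function(x, ...) {
  cat(sprintf("Blomberg's K = %.4g, randomization P = %.4g (%d reps, n = %d)\n",
              x$K, x$p_value, x$n_reps, x$n))
  invisible(x)
}

## Build a fast profile log-likelihood function for the lambda model.
## On an ultrametric tree diag(V) = T * I, so V(lambda) = lambda*V +
## (1-lambda)*T*I shares V's eigenvectors: one eigendecomposition makes
## every profile evaluation O(n). Falls back to per-evaluation Cholesky on
## non-ultrametric trees.
lambda_profile <- function(x, V_bm) {
  V <- unclass(V_bm)
  d <- diag(V)
  n <- length(x)
  if (max(d) - min(d) < 1e-8 * max(d)) {
    Tm <- mean(d)
    eg <- eigen(V, symmetric = TRUE)
    q1 <- crossprod(eg$vectors, rep(1, n))
    qx <- crossprod(eg$vectors, x)
    function(lambda) {
      ev <- lambda * eg$values + (1 - lambda) * Tm
      if (any(ev <= 0)) return(-Inf)
      w <- 1 / ev
      denom <- sum(w * q1^2)               # 1' V(l)^-1 1
      a_hat <- sum(w * q1 * qx) / denom
      dev <- qx - a_hat * q1               # rotated residuals
      sigma2 <- sum(w * dev^2) / n
      if (sigma2 <= 0) return(-Inf)
      -0.5 * (n * log(2 * pi * sigma2) + sum(log(ev)) + n)
    }
  } else {
    function(lambda) lambda_loglik(lambda, x, V_bm)
  }
}

## Profile log-likelihood of the lambda model at a given lambda.
lambda_loglik <- function(lambda, x, V_bm) {
  V <- unclass(V_bm) * lambda
  diag(V) <- diag(unclass(V_bm))
  n <- length(x)
  sv <- solve_vcv(V, b = cbind(1, x))
  denom <- sum(sv$x[, 1L])
  a_hat <- sum(sv$x[, 1L] * x) / denom
  dev <- x - a_hat
  sigma2 <- as.numeric(sum(dev * (sv$x[, 2L] - a_hat * sv$x[, 1L]))) / n
  if (sigma2 <= 0) return(-Inf)
  -0.5 * (n * log(2 * pi * sigma2) + sv$logdet + n)
}

#' Pagel's lambda by profile maximum likelihood with a likelihood-ratio test
#'
#' The branch-scaling parameter `lambda` multiplies the off-diagonal entries
#' of the Brownian covariance: `lambda = 0` removes all phylogenetic
#' structure, `lambda = 1` is Brownian motion. The profile log-likelihood
#' (phylogenetic mean and rate maximized out analytically) is optimized over
#' `[0, lambda_max]` by bounded scalar search with equally spaced restarts.
#' The test of `lambda > 0` compares the fitted log-likelihood with that at
#' `lambda = 0` via a chi-squared likelihood-ratio test on 1 df (a
#' conservative choice at the boundary). Binary 0/1 states may be passed and
#' are treated as continuous values; a warning notes the model mismatch.
#'
#' @param x Named per-tip values (continuous, or 0/1 coded).
#' @param tree A `phylo` object.
#' @param lambda_max Upper bound for lambda (1 for ultrametric trees).
#' @param n_restarts Number of equally spaced optimizer restarts.
#' @return Object of class `lambda_result`: list `lambda_hat`, `logL_hat`,
#'   `logL_at_zero`, `lr_stat`, `p_value`, `n`.
#' @export
pagel_lambda_ml <- function(x, tree, lambda_max = 1, n_restarts = 10) {
  x <- align_to_tips(x, tree$tip.label)
  n <- length(x)
  if (n < 4L) stop("need at least 4 tips", call. = FALSE)
  if (all(x %in% c(0, 1))) {
    warning("binary 0/1 trait treated as continuous for the lambda model",
            call. = FALSE)
  }
  V_bm <- vcv_from_tree(tree, "BM")
  off <- unclass(V_bm); diag(off) <- 0
  if (max(abs(off)) < 1e-12 * max(diag(unclass(V_bm)))) {
    warning("lambda unidentifiable on a star tree; returning lambda = 0",
            call. = FALSE)
    l0 <- lambda_loglik(0, x, V_bm)
    return(structure(list(lambda_hat = 0, logL_hat = l0, logL_at_zero = l0,
                          lr_stat = 0, p_value = 1, n = n),
                     class = "lambda_result"))
  }
  f <- lambda_profile(x, V_bm)
  grid <- seq(0, lambda_max, length.out = n_restarts + 1L)
  best <- list(maximum = 0, objective = f(0))
  for (i in seq_len(n_restarts)) {
    opt <- stats::optimize(f, lower = grid[i], upper = grid[i + 1L],
                           maximum = TRUE, tol = 1e-8)
    if (opt$objective > best$objective) best <- opt
  }
  # the bounds themselves are candidate optima
  for (l in c(0, lambda_max)) {
    v <- f(l)
    if (v > best$objective) best <- list(maximum = l, objective = v)
  }
  if (!is.finite(best$objective)) stop("non-finite lambda likelihood", call. = FALSE)
  logL0 <- f(0)
  lr <- max(0, 2 * (best$objective - logL0))
  structure(list(lambda_hat = best$maximum,
                 logL_hat = best$objective,
                 logL_at_zero = logL0,
                 lr_stat = lr,
                 p_value = stats::pchisq(lr, df = 1, lower.tail = FALSE),
                 n = n),
            class = "lambda_result")
}

#' @export
print.lambda_result <- function(x, ...) {
  cat(sprintf("Pagel's lambda = %.4g (logL %.4g vs %.4g at 0; LR = %.4g, P = %.4g)\n",
              x$lambda_hat, x$logL_hat, x$logL_at_zero, x$lr_stat, x$p_value))
  invisible(x)
}

#' Phylogenetic standardization of predictor columns
#'
#' Centers each column on its phylogenetic (GLS) mean and divides by the
#' square root of its evolutionary rate, so that regression coefficients on
#' different predictors are comparable. On a star tree this reduces to the
#' ordinary z-score (with the `n - 1` divisor).
#'
#' @param X Matrix or data.frame of predictor columns (rows = tips).
#' @param V A `phylo_cov` or covariance matrix with tip rownames.
#' @param divisor Passed to [phylo_mean_rate()].
#' @return Matrix of standardized columns with attributes `a_hat` and `rate`.
#' @export
standardize_phylo <- function(X, V, divisor = c("n-1", "n")) {
  divisor <- match.arg(divisor)
  mr <- phylo_mean_rate(X, V, divisor = divisor)
  X <- align_to_tips(X, rownames(V))
  if (!is.matrix(X)) X <- matrix(X, ncol = 1, dimnames = list(rownames(V), "x"))
  sds <- sqrt(diag(as.matrix(mr$rate)))
  if (any(sds <= .Machine$double.eps)) {
    stop("constant predictor: ",
         paste(colnames(X)[sds <= .Machine$double.eps], collapse = ", "),
         call. = FALSE)
  }
  out <- sweep(sweep(X, 2, mr$a_hat), 2, sds, "/")
  attr(out, "a_hat") <- mr$a_hat
  attr(out, "rate") <- mr$rate
  out
}
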