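## Phylogenetic least squares under Brownian-motion and Ornstein-Uhlenbeck
## covariance, ML model comparison, and simulation-based phylogenetic ANOVA.

## GLS fit for a fixed covariance V (unit rate; sigma2 profiled out by ML).
gls_core <- function(y, X, V) {
  n <- length(y)
  k <- ncol(X)
  sv <- solve_vcv(V, b = cbind(X, y))
  Vinv_X <- sv$x[, seq_len(k), drop = FALSE]
  Vinv_y <- sv$x[, k + 1L]
  XtVX <- crossprod(X, Vinv_X)
  qrx <- qr(XtVX)
  if (qrx$rank < k) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):k]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- solve(qrx, crossprod(Vinv_X, y))
  e <- y - X %*% beta
  quad <- as.numeric(crossprod(e, Vinv_y - Vinv_X %*% beta))
  sigma2_ml <- quad / n
  logL <- -0.5 * (n * log(2 * pi * sigma2_ml) + sv$logdet + n)
  cov_beta <- (quad / (n - k)) * solve(qrx)   # small-sample n/(n-k) scale
  list(beta = as.vector(beta), cov_beta = cov_beta, sigma2 = sigma2_ml,
       logL = logL, n = n, k = k)
}

#' Phylogenetic least-squares regression
#'
#' Fits `y ~ X` by maximum likelihood with residual covariance proportional
#' to a phylogeny-derived matrix: Brownian motion (`model = "BM"`) or
#' Ornstein-Uhlenbeck with a fixed root on an ultrametric tree
#' (`model = "OU"`). Under OU the selection strength `alpha` is profiled over
#' a log-spaced grid on `[1e-8/T, 50/T]` (T = tree height) and refined by
#' bounded scalar search; the profile curve is returned because near-BM data
#' leave the likelihood flat in `alpha`. Coefficient standard errors use the
#' `n/(n-k)` small-sample scale and P-values a t reference with `n - k` df.
#' `AIC = 2*(k+1) - 2 logL` for BM (coefficients + rate) plus 1 for `alpha`
#' under OU.
#'
#' @param y Named per-tip response.
#' @param X Matrix/data.frame of predictors (rows = tips), or `NULL` for an
#'   intercept-only fit. An intercept column is added unless
#'   `intercept = FALSE`.
#' @param tree A `phylo` object.
#' @param model `"BM"` or `"OU"`.
#' @param intercept Include an intercept column.
#' @return Object of class `gls_fit`: coefficients, `se`, `t`, `p`,
#'   `sigma2`, `alpha` (OU), `alpha_profile` (OU), `logL`, `aic`, `model`,
#'   `n`, `k`, `alpha_at_bound` flag.
#' @export
pgls_fit <- function(y, X = NULL, tree, model = c("BM", "OU"), intercept = TRUE) {
  model <- match.arg(model)
  y <- align_to_tips(y, tree$tip.label)
  n <- length(y)
  if (!is.null(X)) {
    X <- align_to_tips(X, tree$tip.label)
    if (!is.matrix(X)) X <- matrix(X, ncol = 1, dimnames = list(tree$tip.label, "x"))
  }
  Xd <- if (intercept) {
    cbind(`(Intercept)` = rep(1, n), X)
  } else {
    if (is.null(X)) stop("no predictors and no intercept", call. = FALSE)
    X
  }
  k <- ncol(Xd)
  if (n <= k + 2L) stop("need n > k + 2", call. = FALSE)

  if (model == "BM") {
    V <- vcv_from_tree(tree, "BM")
    fit <- gls_core(y, Xd, V)
    alpha <- NULL; profile <- NULL; at_bound <- FALSE
    n_params <- k + 1L
  } else {
    um <- is_ultrametric(tree, rel_tol = 1e-4)
    if (!um$ultrametric) stop("OU fit requires an ultrametric tree", call. = FALSE)
    Th <- tree_height(tree)
    Tshared <- ape::vcv.phylo(tree)
    D <- ape::cophenetic.phylo(tree)[rownames(Tshared), colnames(Tshared)]
    ou_V <- function(a) exp(-a * D) * (1 - exp(-2 * a * Tshared)) / (2 * a)
    prof_fun <- function(log_a) gls_core(y, Xd, ou_V(exp(log_a)))$logL
    lo <- log(1e-8 / Th); hi <- log(50 / Th)
    grid <- seq(lo, hi, length.out = 30L)
    prof <- vapply(grid, prof_fun, numeric(1))
    i_best <- which.max(prof)
    bl <- grid[max(1L, i_best - 1L)]; bu <- grid[min(length(grid), i_best + 1L)]
    opt <- stats::optimize(prof_fun, lower = bl, upper = bu, maximum = TRUE,
                           tol = 1e-10)
    cand <- rbind(cbind(grid, prof), c(opt$maximum, opt$objective))
    j <- which.max(cand[, 2L])
    log_a_hat <- unname(cand[j, 1L])
    alpha <- exp(log_a_hat)
    at_bound <- log_a_hat <= lo + 1e-9 || log_a_hat >= hi - 1e-9
    fit <- gls_core(y, Xd, ou_V(alpha))
    profile <- data.frame(alpha = exp(grid), logL = prof)
    n_params <- k + 2L
  }
  se <- sqrt(diag(fit$cov_beta))
  tval <- fit$beta / se
  pval <- 2 * stats::pt(abs(tval), df = n - k, lower.tail = FALSE)
  names(fit$beta) <- names(se) <- names(tval) <- names(pval) <- colnames(Xd)
  structure(list(coefficients = fit$beta, se = se, t = tval, p = pval,
                 sigma2 = fit$sigma2, alpha = alpha, alpha_profile = profile,
                 alpha_at_bound = if (model == "OU") at_bound else NULL,
                 logL = fit$logL, aic = 2 * n_params - 2 * fit$logL,
                 model = model, n = n, k = k,
                 data_signature = c(n = n, k = k, sum_y = sum(y))),
            class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat(sprintf("PGLS (%s): n = %d, logL = %.4f, AIC = %.4f%s\n",
              x$model, x$n, x$logL, x$aic,
              if (!is.null(x$alpha)) sprintf(", alpha = %.4g%s", x$alpha,
                if (isTRUE(x$alpha_at_bound)) " [at bound]" else "") else ""))
  print(data.frame(estimate = x$coefficients, se = x$se, t = x$t, p = x$p))
  invisible(x)
}

#' Compare BM and OU phylogenetic regressions
#'
#' BM is nested in OU at `alpha -> 0`, so the comparison uses both the AIC
#' difference and a likelihood-ratio test on 1 df.
#'
#' @param fit_bm A BM `gls_fit`.
#' @param fit_ou An OU `gls_fit` on the same response, design and tree.
#' @return List `delta_aic` (`AIC_OU - AIC_BM`), `lr_stat`, `p`.
#' @export
compare_models <- function(fit_bm, fit_ou) {
  stopifnot(inherits(fit_bm, "gls_fit"), inherits(fit_ou, "gls_fit"))
  if (fit_bm$model != "BM" || fit_ou$model != "OU") {
    stop("pass the BM fit first and the OU fit second", call. = FALSE)
  }
  if (!isTRUE(all.equal(fit_bm$data_signature, fit_ou$data_signature))) {
    stop("fits are not on the same data", call. = FALSE)
  }
  lr <- 2 * (fit_ou$logL - fit_bm$logL)
  if (lr < -1e-6) stop("OU log-likelihood below BM: nesting violated", call. = FALSE)
  lr <- max(0, lr)
  list(delta_aic = fit_ou$aic - fit_bm$aic,
       lr_stat = lr,
       p = stats::pchisq(lr, df = 1, lower.tail = FALSE))
}

#' Simulation-based phylogenetic ANOVA
#'
#' One-way ANOVA of a continuous trait on a grouping factor, with the null
#' distribution of F generated by Brownian-motion simulation of the trait on
#' the tree (rate and mean estimated from the data by GLS), so that the test
#' accounts for phylogenetic non-independence.
#'
#' @param y Named continuous per-tip values.
#' @param group Named factor of group memberships per tip.
#' @param tree A `phylo` object.
#' @param n_sims Number of BM simulations for the null (default 1000).
#' @param seed Integer seed (required).
#' @return List `F`, `p_sim`, `df_among`, `df_within`, `n_sims`.
#' @export
phyl_anova <- function(y, group, tree, n_sims = 1000, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  y <- align_to_tips(y, tree$tip.label)
  group <- align_to_tips(group, tree$tip.label)
  group <- factor(group)
  tab <- table(group)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop("need >= 2 groups each with >= 2 tips", call. = FALSE)
  }
  n <- length(y)
  g <- length(tab)
  # column-wise one-way F over a matrix of traits (vectorized null)
  f_stat <- function(S) {
    sums <- rowsum(S, group)                       # g x m group sums
    grand <- colSums(S) / n
    ssb <- colSums(sums^2 / as.vector(tab)) - n * grand^2
    sst <- colSums(S^2) - n * grand^2
    (ssb / (g - 1)) / ((sst - ssb) / (n - g))
  }
  obs <- f_stat(matrix(y, ncol = 1))
  V <- vcv_from_tree(tree, "BM")
  mr <- phylo_mean_rate(y, V, divisor = "n")
  sigma2 <- as.numeric(mr$rate)
  ch <- chol(unclass(V) * sigma2 + diag(1e-12, n))
  Z <- matrix(stats::rnorm(n * n_sims), n, n_sims)
  f_null <- f_stat(mr$a_hat + crossprod(ch, Z))
  list(F = unname(obs),
       p_sim = (1 + sum(f_null >= obs)) / (n_sims + 1),
       df_among = g - 1L, df_within = n - g,
       n_sims = n_sims)
}
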