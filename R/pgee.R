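## Phylogenetic generalized estimating equations for a binary trait:
## binomial family, logit link, working correlation from the unit-branch
## phylogeny, phylogenetic degrees of freedom, and QIC.

#' Working correlation matrix for the phylogenetic GEE
#'
#' Brownian covariance of the tree with every branch length set to 1
#' (entries count shared edges), normalized to a correlation matrix.
#'
#' @param tree A `phylo` object.
#' @return Correlation matrix with tip rownames.
#' @export
gee_working_correlation <- function(tree) {
  unclass(vcv_from_tree(tree, "unit", correlation = TRUE))
}

#' Phylogenetic degrees of freedom
#'
#' `dfP = (sum of all branch lengths) / (mean root-to-tip distance)`,
#' computed on the unit-branch-length transform of the tree to match the
#' working-correlation convention (set `unit_branches = FALSE` to use the
#' original branch lengths). Equals the number of tips on a star tree and
#' decreases as shared history grows.
#'
#' @param tree A `phylo` object.
#' @param unit_branches Apply the unit-branch transform first (default TRUE).
#' @return The scalar dfP.
#' @export
phylo_df <- function(tree, unit_branches = TRUE) {
  validate_tree(tree)
  if (unit_branches) tree$edge.length <- rep(1, length(tree$edge.length))
  depth <- node_depths(tree)[seq_along(tree$tip.label)]
  if (mean(depth) <= 0) stop("zero tree height", call. = FALSE)
  sum(tree$edge.length) / mean(depth)
}

#' Phylogenetic GEE for a binary response
#'
#' Solves the estimating equations `U(beta) = D' Sigma^-1 (y - mu) = 0` for
#' a binomial response with logit link, where `mu = plogis(X beta)`,
#' `D = dmu/dbeta`, `Sigma = phi * A^(1/2) R A^(1/2)` with
#' `A = diag(mu(1-mu))` and `R` the unit-branch phylogenetic working
#' correlation. Fisher scoring starts from the ordinary GLM estimate and
#' iterates until `max |delta beta| < tol`. The dispersion `phi` is the
#' Pearson chi-squared over `n - k`. Standard errors come from the
#' model-based covariance `(D' Sigma^-1 D)^-1` — with a single cluster (one
#' phylogeny) the sandwich estimator is degenerate — and P-values use a
#' two-sided t reference with `dfP - k` degrees of freedom.
#'
#' Response coding: UV pattern present = 0, pattern absent (uniform
#' absorption) = 1, so positive coefficients mean "more likely uniformly
#' UV-absorbing".
#'
#' @param y Named 0/1 response per tip.
#' @param X Matrix/data.frame of predictors (rows = tips); an intercept is
#'   added.
#' @param tree A `phylo` object.
#' @param tol Convergence tolerance on `max |delta beta|`.
#' @param max_iter Maximum Fisher-scoring iterations.
#' @return Object of class `gee_fit`: `coefficients`, `se`, `t`, `p`,
#'   `phi`, `dfP`, `qic`, `n`, `k`, `iterations`, `residual_norm`
#'   (estimating-equation norm at the solution), `vcov` (model-based),
#'   `fitted`.
#' @export
gee_fit <- function(y, X, tree, tol = 1e-8, max_iter = 50L) {
  y <- align_to_tips(y, tree$tip.label)
  if (!all(y %in% c(0, 1))) stop("y must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) stop("response has no variation", call. = FALSE)
  X <- align_to_tips(X, tree$tip.label)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1, dimnames = list(tree$tip.label, "x"))
  n <- length(y)
  Xd <- cbind(`(Intercept)` = rep(1, n), X)
  k <- ncol(Xd)
  if (qr(Xd)$rank < k) stop("rank-deficient design matrix", call. = FALSE)

  R <- gee_working_correlation(tree)
  Rinv <- solve_vcv(R)$x

  beta <- stats::coef(stats::glm.fit(Xd, y, family = stats::binomial()))
  # U(beta) = D' Sigma^-1 (y - mu) = X' S R^-1 S^-1 (y - mu) up to 1/phi,
  # with S = A^(1/2); phi cancels in the root. Solved by Newton iteration
  # with the exact Jacobian (Fisher scoring drops the dS/dbeta terms and can
  # spiral when the working correlation is strong); Newton directions are
  # descent directions for |U|^2, so step-halving on |U|^2 is safe.
  state_at <- function(b) {
    mu <- stats::plogis(as.vector(Xd %*% b))
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)   # guard against separation
    v <- mu * (1 - mu)
    s <- sqrt(v)
    r <- (y - mu) / s
    U <- crossprod(Xd * s, Rinv %*% r)
    c1 <- (1 - 2 * mu) * s / 2                    # d s_i / d eta_i
    c2 <- -s - r * (1 - 2 * mu) / 2               # d r_j / d eta_j
    # J = X' [ diag(c1 * (R^-1 r)) + diag(s) R^-1 diag(c2) ] X
    J <- crossprod(Xd * (c1 * as.vector(Rinv %*% r)), Xd) +
      crossprod(Xd * s, Rinv %*% (c2 * Xd))
    list(U = U, J = J, mu = mu)
  }
  # global stage: minimize |U|^2 by BFGS (gradient 2 J'U) to reach the root
  # basin, then polish by Newton. The |U|^2 surface can hold non-root local
  # minima, so if the GLM start stalls above zero, retry from deterministic
  # perturbed starts (RNG state preserved).
  obj <- function(b) {
    v <- sum(state_at(b)$U^2)
    if (is.finite(v)) v else .Machine$double.xmax
  }
  grd <- function(b) {
    st <- state_at(b)
    g <- 2 * as.vector(crossprod(st$J, st$U))
    if (all(is.finite(g))) g else rep(0, length(b))
  }
  beta_glm <- beta
  best <- stats::optim(beta, obj, grd, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-14))
  if (best$value > 1e-8) {
    # restart from perturbed starts and collect candidate roots; the
    # estimating equations can admit several roots, in which case the one
    # nearest the GLM solution is taken (continuity in R: as the working
    # correlation tends to the identity the GEE root tends to the GLM fit)
    old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv(), inherits = FALSE) else NULL
    set.seed(1071L)
    roots <- list()
    for (j in 1:20) {
      o <- tryCatch(
        stats::optim(beta_glm + stats::rnorm(k, 0, 1.5), obj, grd,
                     method = "BFGS",
                     control = list(maxit = 1000, reltol = 1e-14)),
        error = function(e) NULL)
      if (is.null(o)) next
      if (o$value < best$value) best <- o
      if (o$value < 1e-8) roots[[length(roots) + 1L]] <- o$par
    }
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
    if (length(roots)) {
      d <- vapply(roots, function(r) sum((r - beta_glm)^2), numeric(1))
      best <- list(par = roots[[which.min(d)]], value = 0)
    }
  }
  if (is.finite(best$value) && best$value <= obj(beta)) beta <- best$par

  trace <- numeric(0)
  converged <- FALSE
  st <- state_at(beta)
  for (it in seq_len(max_iter)) {
    delta <- tryCatch(-as.vector(solve(st$J, st$U)), error = function(e) NULL)
    if (is.null(delta) || max(abs(beta)) > 30) {
      # a singular Jacobian at extreme coefficients means the fitted
      # probabilities are pinned at 0/1: separation, no finite root
      if (max(abs(beta)) > 15) {
        warning("separation detected: |coefficient| diverging; ",
                "estimates are unreliable", call. = FALSE)
        converged <- TRUE
        break
      }
      stop("GEE Jacobian singular", call. = FALSE)
    }
    norm0 <- sum(st$U^2)
    step <- 1
    repeat {
      st_new <- state_at(beta + step * delta)
      n_new <- sum(st_new$U^2)
      if ((is.finite(n_new) && n_new < norm0) || step < 1e-6) break
      step <- step / 2
    }
    beta <- beta + step * delta
    st <- st_new
    trace <- c(trace, max(abs(step * delta)))
    if (max(abs(step * delta)) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("GEE did not converge in ", max_iter, " iterations; |delta| trace: ",
         paste(signif(utils::tail(trace, 5), 3), collapse = ", "),
         call. = FALSE)
  }
  eta <- as.vector(Xd %*% beta)
  mu <- pmin(pmax(stats::plogis(eta), 1e-10), 1 - 1e-10)
  v <- mu * (1 - mu)
  sv <- sqrt(v)
  phi <- sum((y - mu)^2 / v) / (n - k)
  As_X <- Xd * sv
  info <- crossprod(As_X, Rinv) %*% As_X
  vcov_beta <- phi * tryCatch(solve(info), error = function(e)
    MASS::ginv(info))   # pseudo-inverse only reachable under separation
  dimnames(vcov_beta) <- list(colnames(Xd), colnames(Xd))
  resid_norm <- max(abs(crossprod(As_X, Rinv) %*% ((y - mu) / sv))) / phi

  dfP <- phylo_df(tree)
  se <- sqrt(diag(vcov_beta))
  tval <- beta / se
  df_t <- dfP - k
  if (df_t <= 0) warning("dfP - k <= 0; P-values undefined", call. = FALSE)
  pval <- if (df_t > 0) 2 * stats::pt(abs(tval), df = df_t, lower.tail = FALSE)
          else rep(NA_real_, k)
  names(beta) <- names(se) <- names(tval) <- names(pval) <- colnames(Xd)
  if (any(abs(beta[-1L]) > 15)) {
    warning("possible separation: |coefficient| > 15", call. = FALSE)
  }
  fit <- structure(list(coefficients = beta, se = se, t = tval, p = pval,
                        phi = phi, dfP = dfP, n = n, k = k,
                        iterations = it, residual_norm = resid_norm,
                        vcov = vcov_beta, fitted = mu, y = y, X = Xd),
                   class = "gee_fit")
  fit$qic <- qic(fit)
  fit
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("phylogenetic GEE: n = %d, dfP = %.3f, phi = %.3f, QIC = %.3f\n",
              x$n, x$dfP, x$phi, x$qic))
  print(data.frame(estimate = x$coefficients, se = x$se, t = x$t, p = x$p))
  invisible(x)
}

#' Quasi-likelihood information criterion (QIC) for a GEE fit
#'
#' `QIC = -2 QL(mu_hat) + 2 trace(Omega_I^-1 V_hat)` with `QL` the binomial
#' quasi-likelihood at the GEE estimate, `Omega_I` the information under an
#' independence working correlation (scaled by the fitted dispersion) and
#' `V_hat` the model-based covariance of the coefficients. With an identity
#' working correlation the trace term equals the number of coefficients and
#' QIC reduces to the GLM AIC.
#'
#' @param fit A converged `gee_fit`.
#' @return The scalar QIC.
#' @export
qic <- function(fit) {
  stopifnot(inherits(fit, "gee_fit"))
  mu <- fit$fitted
  y <- fit$y
  ql <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  v <- mu * (1 - mu)
  omega_i <- crossprod(fit$X * sqrt(v)) / fit$phi   # X' A X / phi
  if (qr(omega_i)$rank < ncol(omega_i)) stop("singular independence information",
                                             call. = FALSE)
  -2 * ql + 2 * sum(diag(omega_i %*% fit$vcov))
}
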