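## Felsenstein's phylogenetic independent contrasts (PICs) and
## through-origin contrast regression.

## Resolve multifurcations to zero-length branches (plus a tiny jitter so
## expected contrast variances stay positive) and validate branch lengths.
prepare_bifurcating <- function(tree, jitter = 1e-10) {
  validate_tree(tree)
  if (!ape::is.binary(tree)) {
    warning("multifurcations resolved to zero-length branches (jitter ",
            jitter, ")", call. = FALSE)
    tree <- ape::multi2di(tree, random = FALSE)
  }
  zero <- tree$edge.length <= 0
  if (any(zero)) tree$edge.length[zero] <- tree$edge.length[zero] + jitter
  tree
}

## Linear operator L ((n-1) x n) such that L %*% x gives the standardized
## contrasts: each internal node's working value is a linear combination of
## tip values, so the whole pruning pass can be stored as weight vectors.
## Shares the postorder pass with compute_pics.
pic_core <- function(tree) {
  tree <- prepare_bifurcating(tree)
  n <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  n_node <- max(tr$edge)
  W <- matrix(0, n_node, n)               # node value = W[node, ] %*% x
  W[cbind(seq_len(n), seq_len(n))] <- 1
  blen <- numeric(n_node)                 # working branch length above node
  blen[tr$edge[, 2L]] <- tr$edge.length
  contrasts <- matrix(0, n - 1L, n)
  exp_var <- numeric(n - 1L)
  node_ids <- integer(n - 1L)
  k <- 0L
  i <- 1L
  m <- nrow(tr$edge)
  while (i <= m) {
    parent <- tr$edge[i, 1L]
    # postorder groups all children of a node contiguously
    j <- i
    while (j <= m && tr$edge[j, 1L] == parent) j <- j + 1L
    children <- tr$edge[i:(j - 1L), 2L]
    if (length(children) != 2L) {
      stop("internal error: non-binary node after resolution", call. = FALSE)
    }
    c1 <- children[1L]; c2 <- children[2L]
    b1 <- blen[c1]; b2 <- blen[c2]
    k <- k + 1L
    exp_var[k] <- b1 + b2
    contrasts[k, ] <- (W[c1, ] - W[c2, ]) / sqrt(b1 + b2)
    node_ids[k] <- parent
    W[parent, ] <- (W[c1, ] / b1 + W[c2, ] / b2) / (1 / b1 + 1 / b2)
    blen[parent] <- blen[parent] + b1 * b2 / (b1 + b2)
    i <- j
  }
  list(L = contrasts, exp_var = exp_var, node_ids = node_ids,
       tip_order = tree$tip.label)
}

## Cached-free accessor used by the K randomization test.
pic_operator <- function(tree) pic_core(tree)$L

#' Phylogenetic independent contrasts
#'
#' Felsenstein's pruning algorithm: at each internal node the standardized
#' contrast is `(x_i - x_j) / sqrt(b_i + b_j)`, the ancestral working value
#' the `1/b`-weighted mean of the two daughters, and the ancestor's branch
#' is extended by `b_i b_j / (b_i + b_j)`. Multifurcations are resolved to
#' zero-length branches with a logged warning.
#'
#' @param x Named per-tip values.
#' @param tree A `phylo` object.
#' @return Object of class `contrast_set`: list with `contrasts` (length
#'   n-1), `expected_variances`, `node_ids`, `n_tips`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' compute_pics(c(A = 2, B = 0, C = 1), tr)$contrasts
#' @export
compute_pics <- function(x, tree) {
  core <- pic_core(tree)
  x <- align_to_tips(x, core$tip_order)
  structure(list(contrasts = as.vector(core$L %*% x),
                 expected_variances = core$exp_var,
                 node_ids = core$node_ids,
                 n_tips = length(x)),
            class = "contrast_set")
}

#' @export
print.contrast_set <- function(x, ...) {
  cat(sprintf("contrast_set: %d contrasts from %d tips\n",
              length(x$contrasts), x$n_tips))
  invisible(x)
}

#' Through-origin regression of independent contrasts
#'
#' Regresses the contrasts of `y` on the contrasts of `x` with the intercept
#' fixed at zero (the correct model for contrasts, whose expectation is
#' zero). Each contrast pair is oriented so that the predictor contrast is
#' non-negative; this fixes the reported slope's sign without affecting the
#' fit. Degrees of freedom are `n - 2` (n-1 contrasts minus the slope).
#'
#' @param y Named per-tip response values.
#' @param x Named per-tip predictor values.
#' @param tree A `phylo` object.
#' @return List `slope`, `se`, `t`, `p`, `n_contrasts`.
#' @export
pic_origin_regression <- function(y, x, tree) {
  core <- pic_core(tree)
  uy <- as.vector(core$L %*% align_to_tips(y, core$tip_order))
  ux <- as.vector(core$L %*% align_to_tips(x, core$tip_order))
  flip <- ux < 0
  ux[flip] <- -ux[flip]
  uy[flip] <- -uy[flip]
  sxx <- sum(ux^2)
  if (sxx <= .Machine$double.eps) stop("predictor contrasts all zero", call. = FALSE)
  slope <- sum(ux * uy) / sxx
  m <- length(ux)
  df <- m - 1L                             # = n_tips - 2
  rss <- sum((uy - slope * ux)^2)
  se <- sqrt(rss / df / sxx)
  tval <- if (se > 0) slope / se else sign(slope) * Inf
  list(slope = slope, se = se, t = tval,
       p = 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE),
       n_contrasts = m)
}
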