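#' Parse a Newick string into a validated phylogeny
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' downstream comparative machinery relies on: unique tip labels, a branch
#' length on every edge, and non-negative branch lengths. A length on the
#' root edge, if present, is ignored.
#'
#' @param text A single Newick string (terminating `;` optional but
#'   recommended).
#' @return An object of class `phylo`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("malformed Newick: ", conditionMessage(e), call. = FALSE),
    warning = function(w) stop("malformed Newick: ", conditionMessage(w), call. = FALSE)
  )
  if (is.null(tree)) {
    stop("malformed Newick: parser returned no tree for input starting at position 1",
         call. = FALSE)
  }
  validate_tree(tree)
}

#' Validate a phylogeny for comparative analysis
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths (no silent defaults are applied)", call. = FALSE)
  }
  if (length(tree$edge.length) != nrow(tree$edge) || anyNA(tree$edge.length)) {
    stop("every edge must carry a branch length", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) stop("negative branch length", call. = FALSE)
  tree
}

#' Write a tree as Newick with 9 significant digits
#'
#' @param tree A `phylo` object.
#' @param path Optional file path; if `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree, digits = 9)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Prune a phylogeny to a set of taxa
#'
#' Drops all tips not in `keep` and collapses the resulting degree-2 internal
#' nodes, summing branch lengths, so that pairwise patristic distances among
#' the kept tips are unchanged.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned `phylo` object.
#' @export
prune_to_taxa <- function(tree, keep) {
  keep <- as.character(keep)
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing)) {
    stop("taxa not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(keep) < 2L) stop("need at least 2 taxa to keep", call. = FALSE)
  if (setequal(keep, tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Test whether a tree is ultrametric
#'
#' All root-to-tip distances must agree within `rel_tol` times the tree
#' height.
#'
#' @param tree A `phylo` object.
#' @param rel_tol Relative tolerance on tip-height deviation.
#' @return A list with `ultrametric` (logical) and `max_deviation` (largest
#'   absolute difference between a tip height and the mean tip height).
#' @export
is_ultrametric <- function(tree, rel_tol = 1e-6) {
  h <- node_depths(tree)[seq_along(tree$tip.label)]
  dev <- max(abs(h - mean(h)))
  list(ultrametric = dev <= rel_tol * max(h), max_deviation = dev)
}

## Root-to-node distances for all nodes, preorder pass over the edge matrix.
node_depths <- function(tree) {
  n_node <- max(tree$edge)
  depth <- numeric(n_node)
  e <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(e$edge))) {
    depth[e$edge[i, 2L]] <- depth[e$edge[i, 1L]] + e$edge.length[i]
  }
  depth
}

#' Tree height (mean root-to-tip distance)
#' @param tree A `phylo` object.
#' @return Mean root-to-tip distance.
#' @export
tree_height <- function(tree) {
  mean(node_depths(tree)[seq_along(tree$tip.label)])
}

#' Tip variance-covariance matrix under a named evolutionary model
#'
#' Builds the expected among-tip covariance of a trait evolving on `tree`
#' under one of four models (unit rate; the rate parameter is estimated
#' downstream):
#' \describe{
#'   \item{BM}{Brownian motion: `V[i,j]` is the shared root-to-MRCA path
#'     length, `V[i,i]` the tip height.}
#'   \item{lambda}{Pagel's branch-scaling transform: BM off-diagonals
#'     multiplied by `lambda`, diagonal unchanged.}
#'   \item{unit}{All branch lengths set to 1 before the BM computation, so
#'     entries count shared edges (the working-correlation convention for the
#'     phylogenetic GEE).}
#'   \item{OU}{Ornstein-Uhlenbeck with a fixed root on an ultrametric tree:
#'     `V[i,j] = exp(-alpha*d_ij) * (1 - exp(-2*alpha*t_ij)) / (2*alpha)` with
#'     `d_ij` the patristic distance and `t_ij` the shared time from the
#'     root.}
#' }
#'
#' @param tree A `phylo` object.
#' @param model One of `"BM"`, `"lambda"`, `"unit"`, `"OU"`.
#' @param lambda Branch-scaling parameter in `[0, 1]` (model `"lambda"`).
#' @param alpha Selection strength `> 0` (model `"OU"`).
#' @param correlation If `TRUE`, return the correlation matrix
#'   (divide by the square roots of the diagonal products).
#' @return An object of class `phylo_cov`: the matrix with attributes
#'   `model`, `tip_order` and `height`.
#' @export
vcv_from_tree <- function(tree, model = c("BM", "lambda", "unit", "OU"),
                          lambda = 1, alpha = NULL, correlation = FALSE) {
  model <- match.arg(model)
  validate_tree(tree)
  V <- switch(model,
    BM = ape::vcv.phylo(tree),
    lambda = {
      if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]", call. = FALSE)
      V0 <- ape::vcv.phylo(tree)
      d <- diag(V0)
      V0 <- V0 * lambda
      diag(V0) <- d
      V0
    },
    unit = {
      tr1 <- tree
      tr1$edge.length <- rep(1, length(tree$edge.length))
      ape::vcv.phylo(tr1)
    },
    OU = {
      if (is.null(alpha) || alpha <= 0) stop("OU requires alpha > 0", call. = FALSE)
      um <- is_ultrametric(tree, rel_tol = 1e-4)
      if (!um$ultrametric) stop("OU covariance requires an ultrametric tree", call. = FALSE)
      Tshared <- ape::vcv.phylo(tree)        # shared time from root t_ij
      D <- ape::cophenetic.phylo(tree)       # patristic distances d_ij
      D <- D[rownames(Tshared), colnames(Tshared)]
      exp(-alpha * D) * (1 - exp(-2 * alpha * Tshared)) / (2 * alpha)
    }
  )
  if (correlation) V <- stats::cov2cor(V)
  structure(V,
            class = c("phylo_cov", "matrix", "array"),
            model = model,
            lambda = if (model == "lambda") lambda else NULL,
            alpha = if (model == "OU") alpha else NULL,
            tip_order = rownames(V),
            height = tree_height(tree))
}

#' @export
print.phylo_cov <- function(x, ...) {
  cat(sprintf("phylo_cov: %d x %d, model %s, height %.4g\n",
              nrow(x), ncol(x), attr(x, "model"), attr(x, "height")))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE])
  invisible(x)
}

## Cholesky factor of V with a ridge fallback for (numerically) singular V.
## Zero-length terminal branches make V singular; a 1e-10 jitter on the
## diagonal restores a usable factorization with a warning.
chol_vcv <- function(V, jitter = 1e-10) {
  V <- unclass(V)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    warning("covariance matrix singular; adding diagonal jitter ", jitter,
            call. = FALSE)
    ch <- chol(V + diag(jitter * mean(diag(V)), nrow(V)))
  }
  ch
}

## Solve V x = b (default b = I, i.e. the full inverse) via Cholesky, with
## the log-determinant as a by-product.
solve_vcv <- function(V, b = NULL, jitter = 1e-10) {
  ch <- chol_vcv(V, jitter)
  if (is.null(b)) b <- diag(nrow(ch))
  list(x = backsolve(ch, forwardsolve(t(ch), b)),
       logdet = 2 * sum(log(diag(ch))),
       chol = ch)
}

#' Read a set of trees sharing a common tip set
#'
#' Accepts newline-delimited Newick (`format = "newick-lines"`) or a NEXUS
#' trees block with an optional translate table (`format = "nexus-trees"`).
#' All trees must contain an identical tip set unless
#' `prune_to_intersection = TRUE`, in which case every tree is pruned to the
#' shared tips.
#'
#' @param path File path.
#' @param format `"newick-lines"`, `"nexus-trees"`, or `"auto"` (sniff for a
#'   `#NEXUS` header).
#' @param prune_to_intersection Prune all trees to the common tip set rather
#'   than erroring on inconsistent tip sets.
#' @return A `tree_set`: a `multiPhylo` list with a `source` attribute.
#' @export
read_tree_set <- function(path, format = c("auto", "newick-lines", "nexus-trees"),
                          prune_to_intersection = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
    format <- if (length(first) && startsWith(first, "#NEXUS")) "nexus-trees" else "newick-lines"
  }
  trees <- if (format == "nexus-trees") {
    ape::read.nexus(path)
  } else {
    txt <- readLines(path, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    if (!length(txt)) stop("empty tree file: ", path, call. = FALSE)
    ape::read.tree(text = paste(txt, collapse = "\n"))
  }
  if (is.null(trees)) stop("no trees parsed from ", path, call. = FALSE)
  if (inherits(trees, "phylo")) trees <- c(trees)  # multiPhylo of one
  as_tree_set(trees, prune_to_intersection = prune_to_intersection, source = path)
}

#' Coerce a list of trees to a validated tree set
#'
#' @param trees A `multiPhylo` object or list of `phylo` trees.
#' @param prune_to_intersection Prune to the shared tip set instead of
#'   erroring when tip sets differ.
#' @param source Provenance string stored on the result.
#' @return A `tree_set` object (`multiPhylo` with class and `source`).
#' @export
as_tree_set <- function(trees, prune_to_intersection = FALSE, source = "in-memory") {
  trees <- lapply(trees, validate_tree)
  if (!length(trees)) stop("tree set must contain at least one tree", call. = FALSE)
  tip_sets <- lapply(trees, `[[`, "tip.label")
  common <- Reduce(intersect, tip_sets)
  same <- all(vapply(tip_sets, function(s) setequal(s, common), logical(1)))
  if (!same) {
    if (!prune_to_intersection) {
      stop("trees have inconsistent tip sets; pass prune_to_intersection = TRUE ",
           "to prune all trees to the ", length(common), " shared tips", call. = FALSE)
    }
    trees <- lapply(trees, prune_to_taxa, keep = common)
  }
  class(trees) <- c("tree_set", "multiPhylo")
  attr(trees, "source") <- source
  trees
}

#' @export
print.tree_set <- function(x, ...) {
  cat(sprintf("tree_set: %d trees, %d shared tips (source: %s)\n",
              length(x), length(x[[1]]$tip.label), attr(x, "source")))
  invisible(x)
}

#' Write a tree set as newline-delimited Newick
#' @param trees A `tree_set` or `multiPhylo`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tree_set <- function(trees, path) {
  writeLines(vapply(trees, write_newick, character(1)), path)
  invisible(path)
}
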