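## Running an analysis over a posterior sample of trees and aggregating the
## per-tree estimates, SEs and P-values.

#' Run an analysis over every tree in a set
#'
#' Applies `analysis(tree, data, seed = per_tree_seed, ...)` to each tree.
#' Species in `data` must be present in every tree; each tree is pruned to
#' the data's species first, so posterior trees may carry extra taxa.
#' Failures on individual trees are recorded and excluded from aggregation
#' rather than aborting the run. Deterministic given `seed`: tree `i`
#' receives `seed + i`.
#'
#' @param trees A `tree_set` (or `multiPhylo`).
#' @param analysis Function of `(tree, data, seed, ...)` returning a named
#'   list/vector of numbers (typical elements: `estimate`s and `p`s).
#' @param data Passed through to `analysis` (e.g. a `trait_table`).
#' @param seed Integer base seed.
#' @param ... Further arguments for `analysis`.
#' @return Object of class `multi_tree_results`: list of per-tree results
#'   (`NULL` where failed) with attributes `failures` (character messages
#'   keyed by tree index) and `n_trees`.
#' @export
run_across_trees <- function(trees, analysis, data = NULL, seed = 1L, ...) {
  stopifnot(is.function(analysis))
  species <- if (!is.null(data) && !is.null(data$species)) data$species else NULL
  results <- vector("list", length(trees))
  failures <- character(0)
  for (i in seq_along(trees)) {
    tree <- trees[[i]]
    res <- tryCatch({
      if (!is.null(species)) {
        missing <- setdiff(species, tree$tip.label)
        if (length(missing)) {
          stop("species absent from tree: ", paste(missing, collapse = ", "))
        }
        tree <- prune_to_taxa(tree, species)
      }
      analysis(tree, data, seed = seed + i, ...)
    }, error = function(e) {
      failures[[as.character(i)]] <<- conditionMessage(e)
      NULL
    })
    results[i] <- list(res)   # keep NULL slots for failed trees
  }
  if (length(failures)) {
    warning(length(failures), " of ", length(trees), " per-tree fits failed",
            call. = FALSE)
  }
  structure(results, class = "multi_tree_results",
            failures = failures, n_trees = length(trees))
}

#' Aggregate per-tree results into mean, SE and mean P
#'
#' For each numeric element shared by the per-tree results, reports the
#' arithmetic mean across trees, the standard error of the estimates across
#' trees, and (for elements whose name contains `p`) the arithmetic mean of
#' P-values — the aggregation convention used when reporting comparative
#' results over a posterior tree sample. `se_mode` chooses between
#' `sd/sqrt(m)` (default) and plain `sd` across trees; the choice is
#' recorded in the output.
#'
#' @param results A `multi_tree_results` object (or list of named numeric
#'   vectors/lists).
#' @param se_mode `"sd/sqrt(m)"` or `"sd"`.
#' @return Object of class `multi_tree_summary`: data.frame with columns
#'   `parameter`, `mean`, `se`, `n_trees`, plus attributes `se_mode` and
#'   `n_failed`.
#' @export
summarize_across_trees <- function(results, se_mode = c("sd/sqrt(m)", "sd")) {
  se_mode <- match.arg(se_mode)
  ok <- Filter(Negate(is.null), results)
  if (!length(ok)) stop("no successful per-tree results", call. = FALSE)
  flat <- lapply(ok, function(r) unlist(r, use.names = TRUE))
  params <- names(flat[[1L]])
  mat <- do.call(rbind, lapply(flat, function(v) v[params]))
  m <- nrow(mat)
  means <- colMeans(mat)
  sds <- apply(mat, 2L, stats::sd)
  ses <- if (m == 1L) rep(0, ncol(mat)) else
    if (se_mode == "sd") sds else sds / sqrt(m)
  out <- data.frame(parameter = params, mean = means, se = ses,
                    n_trees = m, row.names = NULL)
  structure(out, class = c("multi_tree_summary", "data.frame"),
            se_mode = se_mode,
            n_failed = length(attr(results, "failures") %||% character(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
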