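## Two-stage comparative pipeline: stage 1 analyses the binary UV-pattern
## state across all species; stage 2 analyses quantitative UVP within the
## patterned subset. Every analysis runs across a tree set and is
## aggregated as mean / SE / mean P.

GEO_VARS <- c("latitude", "altitude")
BIOCLIM_VARS <- c("temperature", "precipitation", "uvb")
PREDICTOR_VARS <- c(GEO_VARS, BIOCLIM_VARS)

## ---- per-tree analysis functions (each: tree already pruned to the data) ----

analysis_signal <- function(tree, data, seed, vars, include_lambda_pattern = FALSE,
                            n_randomizations = 999) {
  out <- c()
  if (include_lambda_pattern) {
    lam <- suppressWarnings(
      pagel_lambda_ml(stats::setNames(data$pattern_bin, data$species), tree))
    out <- c(out, lambda_pattern.estimate = lam$lambda_hat,
             lambda_pattern.p = lam$p_value)
  }
  for (v in vars) {
    kr <- k_randomization_test(stats::setNames(data[[v]], data$species), tree,
                               n_reps = n_randomizations, seed = seed)
    out <- c(out, stats::setNames(c(kr$K, kr$p_value),
                                  paste0("K_", v, c(".estimate", ".p"))))
  }
  out
}

analysis_gee <- function(tree, data, seed, vars) {
  V <- vcv_from_tree(tree, "BM")
  X <- as.matrix(data[, vars, drop = FALSE])
  rownames(X) <- data$species
  Xs <- standardize_phylo(X, V)
  y <- stats::setNames(data$pattern_bin, data$species)
  fit <- gee_fit(y, Xs, tree)
  est <- fit$coefficients
  names(est)[1L] <- "intercept"
  c(stats::setNames(est, paste0(names(est), ".estimate")),
    stats::setNames(stats::setNames(fit$p, names(est)),
                    paste0(names(est), ".p")),
    qic = fit$qic, dfP = fit$dfP)
}

analysis_pgls <- function(tree, data, seed, vars) {
  V <- vcv_from_tree(tree, "BM")
  X <- as.matrix(data[, vars, drop = FALSE])
  rownames(X) <- data$species
  Xs <- standardize_phylo(X, V)
  y <- stats::setNames(data$uvp, data$species)
  fit_bm <- pgls_fit(y, Xs, tree, model = "BM")
  fit_ou <- pgls_fit(y, Xs, tree, model = "OU")
  cmp <- compare_models(fit_bm, fit_ou)
  grab <- function(fit, tag) {
    est <- fit$coefficients
    names(est)[1L] <- "intercept"
    c(stats::setNames(est, paste0(tag, ".", names(est), ".estimate")),
      stats::setNames(stats::setNames(fit$p, names(est)),
                      paste0(tag, ".", names(est), ".p")),
      stats::setNames(c(fit$aic, fit$logL), paste0(tag, c(".aic", ".logLik"))))
  }
  c(grab(fit_bm, "BM"), grab(fit_ou, "OU"),
    OU.alpha = fit_ou$alpha, lrt.p = cmp$p, delta_aic = cmp$delta_aic)
}

analysis_pic <- function(tree, data, seed, vars) {
  y <- stats::setNames(data$uvp, data$species)
  out <- c()
  for (v in vars) {
    r <- pic_origin_regression(y, stats::setNames(data[[v]], data$species), tree)
    out <- c(out, stats::setNames(c(r$slope, r$p),
                                  paste0("slope_", v, c(".estimate", ".p"))))
  }
  out
}

## Reshape a multi_tree_summary whose parameters are "<name>.estimate" /
## "<name>.p" pairs into an estimate/SE/P table.
summary_to_table <- function(summ) {
  est <- summ[grepl("\\.estimate$", summ$parameter), ]
  p <- summ[grepl("\\.p$", summ$parameter), ]
  name <- sub("\\.estimate$", "", est$parameter)
  pmap <- stats::setNames(p$mean, sub("\\.p$", "", p$parameter))
  data.frame(parameter = name,
             estimate = est$mean,
             se = est$se,
             p = unname(pmap[name]),
             n_trees = est$n_trees,
             row.names = NULL)
}

#' Run the full two-stage comparative pipeline
#'
#' Stage 1 (all species): UV-pattern classification; Pagel's lambda for the
#' binary pattern state and Blomberg's K (with randomization P) for each
#' continuous variable; phylogenetic GEEs of the pattern state on the
#' geographic (latitude + altitude) and bioclimatic (temperature +
#' precipitation + UV-B) predictor sets, phylogenetically standardized.
#' Stage 2 (patterned species only, UVP below the threshold): trees pruned
#' to the subset; K for UVP and the predictors; PGLS of UVP on the two
#' predictor sets under BM and OU with AIC/LRT comparison; per-predictor
#' through-origin PIC regressions. Every analysis runs across the tree set
#' and is aggregated as mean, SE and mean P across trees.
#'
#' @param traits A `trait_table` (see [load_trait_table()]).
#' @param trees A `tree_set` (a single tree is accepted and wrapped).
#' @param out_dir Output directory for the report bundle (created if
#'   needed); `NULL` skips writing.
#' @param seed Integer base seed.
#' @param n_randomizations Randomizations for the K test (default 999).
#' @param n_trees_cap Use at most this many trees (default 200).
#' @param se_mode Across-tree SE convention (see
#'   [summarize_across_trees()]).
#' @return Object of class `pipeline_result`: list of data.frames `table1`
#'   (signal, all species), `table2` (signal, patterned subset), `table3`
#'   (GEE), `table4` (PGLS), `pic_slopes`, plus `counts`, `crosstab`,
#'   `provenance`, `failures`.
#' @export
run_pipeline <- function(traits, trees, out_dir = NULL, seed = 1L,
                         n_randomizations = 999, n_trees_cap = 200L,
                         se_mode = c("sd/sqrt(m)", "sd")) {
  se_mode <- match.arg(se_mode)
  stopifnot(inherits(traits, "trait_table"))
  if (inherits(trees, "phylo")) trees <- as_tree_set(c(trees))
  if (length(trees) > n_trees_cap) trees <- as_tree_set(trees[seq_len(n_trees_cap)],
                                                        source = attr(trees, "source"))
  unmatched <- setdiff(traits$species, trees[[1L]]$tip.label)
  if (length(unmatched)) {
    stop("species absent from trees: ", paste(unmatched, collapse = ", "),
         call. = FALSE)
  }
  log_lines <- c(sprintf("[%s] pipeline start: %d species, %d trees, seed %d",
                         format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), nrow(traits),
                         length(trees), seed))
  threshold <- attr(traits, "threshold")
  patterned_sp <- traits$species[traits$pattern == "patterned"]
  stage2 <- traits[traits$pattern == "patterned", , drop = FALSE]

  failures <- list()
  collect <- function(tag, res) {
    f <- attr(res, "failures")
    if (length(f)) failures[[tag]] <<- f
    res
  }

  # ---- stage 1 ----
  r1 <- collect("signal_all", run_across_trees(
    trees, analysis_signal, data = traits, seed = seed,
    vars = PREDICTOR_VARS, include_lambda_pattern = TRUE,
    n_randomizations = n_randomizations))
  table1 <- summary_to_table(summarize_across_trees(r1, se_mode))

  r3geo <- collect("gee_geographic", run_across_trees(
    trees, analysis_gee, data = traits, seed = seed, vars = GEO_VARS))
  r3bio <- collect("gee_bioclimatic", run_across_trees(
    trees, analysis_gee, data = traits, seed = seed, vars = BIOCLIM_VARS))
  s3geo <- summarize_across_trees(r3geo, se_mode)
  s3bio <- summarize_across_trees(r3bio, se_mode)
  t3 <- function(s, model) {
    tab <- summary_to_table(s)
    tab$model <- model
    tab$qic <- s$mean[s$parameter == "qic"]
    tab$dfP <- s$mean[s$parameter == "dfP"]
    tab[, c("model", "parameter", "estimate", "se", "p", "qic", "dfP", "n_trees")]
  }
  table3 <- rbind(t3(s3geo, "geographic"), t3(s3bio, "bioclimatic"))

  # ---- stage 2 ----
  r2 <- collect("signal_patterned", run_across_trees(
    trees, analysis_signal, data = stage2, seed = seed,
    vars = c("uvp", PREDICTOR_VARS), include_lambda_pattern = FALSE,
    n_randomizations = n_randomizations))
  table2 <- summary_to_table(summarize_across_trees(r2, se_mode))

  r4geo <- collect("pgls_geographic", run_across_trees(
    trees, analysis_pgls, data = stage2, seed = seed, vars = GEO_VARS))
  r4bio <- collect("pgls_bioclimatic", run_across_trees(
    trees, analysis_pgls, data = stage2, seed = seed, vars = BIOCLIM_VARS))
  t4 <- function(res, model) {
    s <- summarize_across_trees(res, se_mode)
    tab <- summary_to_table(s)
    tab$structure <- sub("\\..*$", "", tab$parameter)
    tab$parameter <- sub("^[^.]*\\.", "", tab$parameter)
    pick <- function(nm) s$mean[s$parameter == nm]
    tab$aic <- ifelse(tab$structure == "BM", pick("BM.aic"), pick("OU.aic"))
    tab$logLik <- ifelse(tab$structure == "BM", pick("BM.logLik"), pick("OU.logLik"))
    tab$alpha <- ifelse(tab$structure == "OU", pick("OU.alpha"), NA_real_)
    tab$lrt_p <- pick("lrt.p")
    tab$model <- model
    tab[, c("model", "structure", "parameter", "estimate", "se", "p",
            "aic", "logLik", "alpha", "lrt_p", "n_trees")]
  }
  table4 <- rbind(t4(r4geo, "geographic"), t4(r4bio, "bioclimatic"))

  rpic <- collect("pic_slopes", run_across_trees(
    trees, analysis_pic, data = stage2, seed = seed, vars = PREDICTOR_VARS))
  pic_slopes <- summary_to_table(summarize_across_trees(rpic, se_mode))

  counts <- list(n_species = nrow(traits),
                 n_patterned = length(patterned_sp),
                 n_uniform = nrow(traits) - length(patterned_sp),
                 threshold = threshold)
  crosstab <- color_pattern_crosstab(traits)

  provenance <- list(
    seed = seed,
    n_trees = length(trees),
    n_randomizations = n_randomizations,
    threshold = threshold,
    se_mode = se_mode,
    tree_source = attr(trees, "source") %||% "in-memory",
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("floraluv"))
  )
  log_lines <- c(log_lines,
                 sprintf("[%s] pipeline done: %d patterned / %d uniform; %d per-tree failures",
                         format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                         counts$n_patterned, counts$n_uniform,
                         sum(lengths(failures))))

  result <- structure(list(table1 = table1, table2 = table2, table3 = table3,
                           table4 = table4, pic_slopes = pic_slopes,
                           counts = counts, crosstab = crosstab,
                           provenance = provenance, failures = failures),
                      class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("table1", "table2", "table3", "table4", "pic_slopes")) {
      utils::write.csv(result[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      list(provenance = provenance, counts = counts,
           crosstab = list(counts = as.data.frame.matrix(crosstab$counts)),
           failures = failures),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d species (%d patterned / %d uniform), %d trees\n",
              x$counts$n_species, x$counts$n_patterned, x$counts$n_uniform,
              x$provenance$n_trees))
  cat("tables: table1 (signal, all), table2 (signal, patterned), table3 (GEE),",
      "table4 (PGLS), pic_slopes\n")
  invisible(x)
}
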