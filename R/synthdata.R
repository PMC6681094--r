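## Synthetic-data generators: ultrametric trees, perturbed tree sets
## standing in for a posterior sample, traits under BM / lambda / OU,
## threshold binary states, and a full study-scale dataset with the joint
## structure the comparative analyses assume.

#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' @param n_tips Number of tips (>= 3).
#' @param height Tree height (time units); branch lengths are rescaled so
#'   every root-to-tip path equals `height`.
#' @param seed Integer seed (required; generators are pure functions of
#'   their arguments).
#' @return A `phylo` object with tips `t1 ... tn`.
#' @export
sim_yule_tree <- function(n_tips, height = 1, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (n_tips < 3L) stop("n_tips must be >= 3", call. = FALSE)
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$edge.length <- tree$edge.length * (height / tree_height(tree))
  tree$tip.label <- paste0("t", seq_len(n_tips))
  tree
}

## Rebuild edge lengths from node ages (root age = height, tips at 0),
## keeping the tree exactly ultrametric.
edges_from_ages <- function(tree, age) {
  tree$edge.length <- age[tree$edge[, 1L]] - age[tree$edge[, 2L]]
  tree
}

## Node ages (time before present) of an ultrametric tree.
node_ages <- function(tree) {
  d <- node_depths(tree)
  max(d[seq_along(tree$tip.label)]) - d
}

#' Simulate a perturbed tree set standing in for a posterior sample
#'
#' Each tree is the base tree with (a) `n_nni` random nearest-neighbour
#' interchange moves and (b) multiplicative lognormal jitter on internal
#' node ages, then restored to exact ultrametricity at the original height.
#' With `branch_jitter_sd = 0` and `n_nni = 0` the set contains identical
#' copies of the base tree.
#'
#' @param base_tree An ultrametric `phylo` object.
#' @param n_trees Number of trees.
#' @param branch_jitter_sd Lognormal sd of node-age jitter (0 = none).
#' @param n_nni Number of NNI moves per tree (0 = none).
#' @param seed Integer seed (required).
#' @return A `tree_set`.
#' @export
sim_tree_set <- function(base_tree, n_trees, branch_jitter_sd = 0.1,
                         n_nni = 2L, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (branch_jitter_sd < 0) stop("branch_jitter_sd must be >= 0", call. = FALSE)
  set.seed(seed)
  validate_tree(base_tree)
  n <- length(base_tree$tip.label)
  height <- tree_height(base_tree)
  trees <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    tr <- base_tree
    if (n_nni > 0L) {
      tr <- phangorn::rNNI(tr, moves = n_nni)
      # NNI keeps edge lengths but breaks ultrametricity; rebuild ages by
      # placing every internal node halfway between its deepest child and
      # its parent, processed root-to-tip after a postorder age init
      age <- node_ages(ape::compute.brlen(tr, method = "Grafen"))
      age <- age * (height / max(age))
      tr <- edges_from_ages(tr, age)
    }
    if (branch_jitter_sd > 0) {
      age <- node_ages(tr)
      internal <- (n + 1L):max(tr$edge)
      age[internal] <- age[internal] * exp(stats::rnorm(length(internal), 0,
                                                        branch_jitter_sd))
      # enforce parent older than child (postorder sweep), then rescale
      po <- ape::reorder.phylo(tr, "postorder")
      for (j in seq_len(nrow(po$edge))) {
        p <- po$edge[j, 1L]; ch <- po$edge[j, 2L]
        if (age[p] <= age[ch]) age[p] <- age[ch] + 1e-6 * height
      }
      root <- n + 1L
      age <- age * (height / age[root])
      tr <- edges_from_ages(tr, age)
    }
    trees[[i]] <- tr
  }
  as_tree_set(trees, source = sprintf("sim_tree_set(seed=%d)", seed))
}

#' Simulate a trait on a tree under BM, lambda, or OU
#'
#' Draws from the multivariate normal with mean `mean` and covariance
#' `sigma2 * V(model)` via Cholesky factorization.
#'
#' @param tree A `phylo` object.
#' @param model `"BM"`, `"lambda"`, or `"OU"`.
#' @param sigma2 Evolutionary rate (>= 0; 0 gives a constant trait).
#' @param lambda Branch-scaling parameter (model `"lambda"`).
#' @param alpha Selection strength (model `"OU"`).
#' @param mean Trait mean (the root state / optimum).
#' @param seed Integer seed (required).
#' @return Named per-tip numeric vector.
#' @export
sim_trait <- function(tree, model = c("BM", "lambda", "OU"), sigma2 = 1,
                      lambda = 1, alpha = 1, mean = 0, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  model <- match.arg(model)
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  set.seed(seed)
  n <- length(tree$tip.label)
  if (sigma2 == 0) {
    return(stats::setNames(rep(mean, n), tree$tip.label))
  }
  V <- switch(model,
    BM = vcv_from_tree(tree, "BM"),
    lambda = vcv_from_tree(tree, "lambda", lambda = lambda),
    OU = vcv_from_tree(tree, "OU", alpha = alpha))
  ch <- tryCatch(chol(unclass(V) * sigma2),
                 error = function(e) chol(unclass(V) * sigma2 + diag(1e-10, n)))
  x <- mean + as.vector(crossprod(ch, stats::rnorm(n)))
  stats::setNames(x, tree$tip.label)
}

#' Simulate a phylogenetically clustered binary state by thresholding
#'
#' A latent liability evolves on the tree (BM, optionally lambda-damped) and
#' is cut at its empirical quantile so that the "present" (0-coded) state
#' count is hit exactly, guaranteeing phylogenetic clustering of states.
#'
#' @param tree A `phylo` object.
#' @param prevalence Target proportion of 0-coded ("patterned") tips, in
#'   (0, 1).
#' @param lambda Branch-scaling of the liability (1 = BM).
#' @param seed Integer seed (required).
#' @param liability Optional externally supplied latent values (overrides
#'   simulation; used when the liability includes fixed effects).
#' @return Named integer vector, 0 = state present (below threshold
#'   liability), 1 = absent.
#' @export
sim_binary_threshold <- function(tree, prevalence, lambda = 1, seed,
                                 liability = NULL) {
  n <- length(tree$tip.label)
  n0 <- round(prevalence * n)
  if (n0 < 1L || n0 > n - 1L) {
    stop("prevalence too extreme: would give ", n0, " of ", n,
         " tips in the 0 state", call. = FALSE)
  }
  if (is.null(liability)) {
    liability <- sim_trait(tree, "lambda", lambda = lambda, seed = seed)
  } else {
    liability <- align_to_tips(liability, tree$tip.label)
  }
  cut <- sort(liability)[n0]
  stats::setNames(as.integer(liability > cut), tree$tip.label)
}

#' Default configuration for the synthetic study dataset
#'
#' Defaults encode the study conditions of a species-level floral UV survey:
#' 177 species, tree height 30 (Myr scale), exactly 86 patterned species,
#' flower-color composition 140 yellow / 30 white / 7 red with 94% of
#' patterned species yellow, predictor means/sds on the published scales,
#' a target predictor correlation structure (altitude positively correlated
#' with UV-B, negatively with temperature), binary-state coefficients on
#' standardized predictors (temperature -2.764, precipitation 1.653,
#' UV-B 2.831, intercept 0.259; response absent = 1), and a UVP regression
#' for patterned species (intercept 0.45, altitude 2.85e-4 per m,
#' temperature -2.70e-4 per degree) with logit-scale residual noise.
#'
#' @param ... Named overrides of any default element.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_tips = 177L,
    height = 30,
    n_patterned = 86L,
    n_trees = 200L,
    branch_jitter_sd = 0.1,
    n_nni = 2L,
    # predictor marginal scales (published means; sds ~ range/4)
    pred_means = c(latitude = 43.04, altitude = 1705, temperature = 4.89,
                   precipitation = 729.2, uvb = 3003),
    pred_sds = c(latitude = 11, altitude = 1000, temperature = 7,
                 precipitation = 550, uvb = 1100),
    # target Pearson correlations among predictors
    pred_cor = matrix(c(
      #       lat    alt   temp  prec   uvb
      1.00, -0.20, -0.60, -0.10, -0.45,  # latitude
      -0.20,  1.00, -0.28, -0.21,  0.84,  # altitude
      -0.60, -0.28,  1.00,  0.30, -0.30,  # temperature
      -0.10, -0.21,  0.30,  1.00, -0.25,  # precipitation
      -0.45,  0.84, -0.30, -0.25,  1.00), # uvb
      5, 5, byrow = TRUE,
      dimnames = list(c("latitude", "altitude", "temperature",
                        "precipitation", "uvb"),
                      c("latitude", "altitude", "temperature",
                        "precipitation", "uvb"))),
    lambda_pred = 0.5,        # signal of predictors (weak-moderate)
    # binary state: logistic coefficients on standardized predictors
    # (absent = 1), plus a lambda-damped liability term
    binary_coef = c(intercept = 0.259, temperature = -2.764,
                    precipitation = 1.653, uvb = 2.831),
    binary_liability_sd = 2,
    lambda_binary = 0.6,
    # UVP of patterned species: linear model on centered raw predictors,
    # mapped to (0, 0.95) through a logit transform with residual noise
    uvp_coef = c(intercept = 0.45, altitude = 2.85e-4, temperature = -2.70e-4),
    uvp_resid_sd = 0.5,       # logit-scale residual sd
    lambda_uvp_resid = 0.2,
    # flower color counts and patterned-by-color targets
    color_counts = c(yellow = 140, white = 30, red = 7),
    patterned_by_color = c(yellow = 81, white = 2, red = 3)
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "sim_config")
}

#' Simulate a full study-scale dataset
#'
#' Generates an ultrametric tree (and optionally a perturbed tree set), five
#' collinear predictors with phylogenetic signal, a binary UV-pattern state
#' from a logistic model on the standardized predictors plus a
#' phylogenetically structured liability (thresholded to the exact target
#' patterned count), UVP values (patterned species from a logit-scale
#' regression on predictors, uniform species from Uniform(threshold, 1)),
#' and flower colors assigned to match the target pattern-by-color counts.
#' Realized predictor Pearson correlations are set exactly to the target
#' matrix by empirical whitening/recoloring of the simulated tip values.
#'
#' @param config A `sim_config` (see [sim_config()]).
#' @param seed Integer seed (required).
#' @param tree_set Also generate the perturbed tree set.
#' @return List with `tree`, `traits` (a `trait_table`), `trees` (a
#'   `tree_set`, when requested) and `config`.
#' @export
sim_study_dataset <- function(config = sim_config(), seed, tree_set = FALSE) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  cfg <- config
  C <- cfg$pred_cor
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) stop("infeasible correlation targets: matrix not ",
                           "positive definite", call. = FALSE)
  tree <- sim_yule_tree(cfg$n_tips, cfg$height, seed = seed)
  n <- cfg$n_tips
  set.seed(seed + 1L)

  # --- predictors: independent lambda-model traits, recolored to the exact
  #     target correlation, then scaled to the published means/sds
  Z <- sapply(seq_len(5L), function(j)
    sim_trait(tree, "lambda", lambda = cfg$lambda_pred, seed = seed + 10L + j))
  Z <- scale(Z)                                  # marginal mean 0 / sd 1
  W <- Z %*% backsolve(chol(stats::cor(Z)), diag(5L))  # whiten: cor(W) = I
  W <- scale(W %*% chol(C))                      # recolor: cor(W) = C exactly
  P <- sweep(sweep(W, 2L, cfg$pred_sds, "*"), 2L, cfg$pred_means, "+")
  colnames(P) <- colnames(C)
  rownames(P) <- tree$tip.label

  # --- binary pattern state: logistic linear predictor on standardized
  #     predictors + lambda-damped liability, thresholded to the exact count
  Pstd <- scale(P)
  b <- cfg$binary_coef
  lin <- b["intercept"] +
    Pstd[, "temperature"] * b["temperature"] +
    Pstd[, "precipitation"] * b["precipitation"] +
    Pstd[, "uvb"] * b["uvb"]
  liab_noise <- sim_trait(tree, "lambda", lambda = cfg$lambda_binary,
                          seed = seed + 2L)
  liab_noise <- liab_noise / stats::sd(liab_noise) * cfg$binary_liability_sd
  liability <- as.vector(lin) + liab_noise
  # low liability -> patterned (0); exactly n_patterned tips below the cut
  pattern_bin <- sim_binary_threshold(tree, prevalence = cfg$n_patterned / n,
                                      seed = seed + 3L, liability = liability)
  patterned <- pattern_bin == 0L

  # --- UVP: patterned species from the logit-mapped regression, uniform
  #     species uniform on [threshold, 1]
  set.seed(seed + 4L)
  uc <- cfg$uvp_coef
  m <- uc["intercept"] +
    uc["altitude"] * (P[, "altitude"] - mean(P[, "altitude"])) +
    uc["temperature"] * (P[, "temperature"] - mean(P[, "temperature"]))
  m <- pmin(pmax(m, 0.05), 0.90)
  eps <- sim_trait(tree, "lambda", lambda = cfg$lambda_uvp_resid,
                   seed = seed + 5L)
  eps <- eps / stats::sd(eps) * cfg$uvp_resid_sd
  uvp <- rep(NA_real_, n)
  uvp[patterned] <- UVP_THRESHOLD *
    stats::plogis(stats::qlogis(m[patterned] / UVP_THRESHOLD) + eps[patterned])
  uvp[patterned] <- pmin(uvp[patterned], UVP_THRESHOLD - 1e-4)
  uvp[!patterned] <- stats::runif(sum(!patterned), UVP_THRESHOLD, 1)

  # --- flower color: assigned within pattern class to match the target
  #     pattern-by-color counts (scaled if the config changes class sizes)
  color <- character(n)
  pc <- cfg$patterned_by_color
  uc_counts <- cfg$color_counts - pc
  n_pat <- sum(patterned)
  pat_cols <- rep(names(pc), times = round(pc / sum(pc) * n_pat))
  pat_cols <- c(pat_cols, rep("yellow", max(0, n_pat - length(pat_cols))))[seq_len(n_pat)]
  n_uni <- n - n_pat
  uni_cols <- rep(names(uc_counts), times = round(uc_counts / sum(uc_counts) * n_uni))
  uni_cols <- c(uni_cols, rep("yellow", max(0, n_uni - length(uni_cols))))[seq_len(n_uni)]
  color[patterned] <- sample(pat_cols)
  color[!patterned] <- sample(uni_cols)

  traits <- load_trait_table(data.frame(
    species = tree$tip.label,
    uvp = uvp,
    color = color,
    latitude = P[, "latitude"],
    altitude = P[, "altitude"],
    temperature = P[, "temperature"],
    precipitation = P[, "precipitation"],
    uvb = P[, "uvb"],
    stringsAsFactors = FALSE
  ))
  out <- list(tree = tree, traits = traits, config = cfg)
  if (tree_set) {
    out$trees <- sim_tree_set(tree, cfg$n_trees,
                              branch_jitter_sd = cfg$branch_jitter_sd,
                              n_nni = cfg$n_nni, seed = seed + 6L)
  }
  out
}

#' Simulate a specimen-level UVP table from species means
#'
#' Emulates measuring several herbarium specimens per species: specimen
#' counts are drawn uniformly between `min_specimens` and `max_specimens`,
#' and specimen UVP values scatter around the species mean with a within-
#' species standard deviation set by default to half the among-species
#' standard deviation (an among:within variance ratio of 4:1, i.e. about
#' 80% of UVP variance among species), truncated to [0, 1].
#'
#' @param traits A `trait_table` (species means in `uvp`).
#' @param min_specimens,max_specimens Range of specimens per species.
#' @param within_sd Within-species standard deviation; default
#'   `sd(traits$uvp) / 2`.
#' @param seed Integer seed (required).
#' @return Data.frame with columns `species`, `specimen_id`, `uvp`.
#' @export
sim_specimen_table <- function(traits, min_specimens = 1L, max_specimens = 10L,
                               within_sd = NULL, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  if (is.null(within_sd)) within_sd <- stats::sd(traits$uvp) / 2
  n_spec <- sample(min_specimens:max_specimens, nrow(traits), replace = TRUE)
  sp <- rep(traits$species, n_spec)
  mu <- rep(traits$uvp, n_spec)
  uvp <- pmin(pmax(mu + stats::rnorm(length(mu), 0, within_sd), 0), 1)
  data.frame(species = sp,
             specimen_id = paste0(sp, "_", unlist(lapply(n_spec, seq_len))),
             uvp = uvp, stringsAsFactors = FALSE)
}
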