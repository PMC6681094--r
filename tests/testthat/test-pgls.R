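test_that("star-tree PGLS reduces to ordinary least squares", {
  st <- star_tree(30, len = 2)
  set.seed(71)
  x <- named_rnorm(st)
  y <- 1 + 0.5 * x + named_rnorm(st, sd = 0.3)
  fit <- pgls_fit(y, x, st, model = "BM")
  ols <- lm(y ~ x)
  expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(unname(fit$se), unname(summary(ols)$coefficients[, "Std. Error"]),
               tolerance = 1e-8)
  expect_equal(unname(fit$p), unname(summary(ols)$coefficients[, "Pr(>|t|)"]),
               tolerance = 1e-8)
})

test_that("BM PGLS matches nlme::gls with a Brownian correlation", {
  skip_if_not_installed("nlme")
  tr <- sim_yule_tree(35, height = 1, seed = 81)
  x <- sim_trait(tr, "BM", seed = 82)
  y <- 0.3 + 0.8 * x + sim_trait(tr, "BM", seed = 83)
  fit <- pgls_fit(y, x, tr, model = "BM")
  d <- data.frame(y = y[tr$tip.label], x = x[tr$tip.label],
                  sp = tr$tip.label)
  ref <- nlme::gls(y ~ x, data = d,
                   correlation = ape::corBrownian(1, tr, form = ~sp),
                   method = "ML")
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$logL, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("intercept-only BM log-likelihood equals the lambda profile at 1", {
  tr <- sim_yule_tree(25, height = 1, seed = 91)
  x <- sim_trait(tr, "BM", seed = 92)
  fit <- pgls_fit(x, NULL, tr, model = "BM")
  lam <- suppressWarnings(pagel_lambda_ml(x, tr))
  expect_equal(fit$logL, floraluv:::lambda_loglik(1, x, vcv_from_tree(tr, "BM")),
               tolerance = 1e-8)
  expect_gte(lam$logL_hat + 1e-8, fit$logL)  # ML over lambda can only improve
})

test_that("OU nests BM: likelihood and AIC inequalities on BM data", {
  tr <- sim_yule_tree(40, height = 1, seed = 101)
  x <- sim_trait(tr, "BM", seed = 102)
  y <- 0.2 * x + sim_trait(tr, "BM", seed = 103)
  bm <- pgls_fit(y, x, tr, model = "BM")
  ou <- pgls_fit(y, x, tr, model = "OU")
  expect_gte(ou$logL, bm$logL - 1e-6)
  expect_lte(ou$aic, bm$aic + 2 + 1e-6)
  expect_s3_class(ou$alpha_profile, "data.frame")
  cmp <- compare_models(bm, ou)
  expect_gte(cmp$lr_stat, 0)
  expect_equal(cmp$delta_aic, 2 - cmp$lr_stat, tolerance = 1e-8)
})

test_that("OU fits detect strong stabilizing selection", {
  # alpha * T = 5: OU should beat BM in most replicates
  hits <- 0L
  n_sims <- 20L
  for (i in seq_len(n_sims)) {
    tr <- sim_yule_tree(80, height = 1, seed = 8000 + i)
    y <- sim_trait(tr, "OU", alpha = 5, seed = 8100 + i)
    bm <- pgls_fit(y, NULL, tr, model = "BM")
    ou <- pgls_fit(y, NULL, tr, model = "OU")
    if (compare_models(bm, ou)$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_sims, 0.8)
})

test_that("PGLS estimates are invariant to tip-order permutation", {
  tr <- sim_yule_tree(20, height = 1, seed = 111)
  x <- sim_trait(tr, "BM", seed = 112)
  y <- 0.5 + x + sim_trait(tr, "BM", seed = 113)
  f1 <- pgls_fit(y, x, tr, model = "BM")
  set.seed(1)
  perm <- sample(names(y))
  f2 <- pgls_fit(y[perm], x[perm], tr, model = "BM")
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$logL, f2$logL, tolerance = 1e-10)
})

test_that("model comparison refuses fits on different data", {
  tr <- sim_yule_tree(20, height = 1, seed = 121)
  x <- sim_trait(tr, "BM", seed = 122)
  y <- sim_trait(tr, "BM", seed = 123)
  y2 <- sim_trait(tr, "BM", seed = 124)
  bm <- pgls_fit(y, x, tr, model = "BM")
  ou2 <- pgls_fit(y2, x, tr, model = "OU")
  expect_error(compare_models(bm, ou2), "same data")
  expect_error(compare_models(ou2, bm), "BM fit first")
})

test_that("rank-deficient designs are rejected with the offending column", {
  tr <- sim_yule_tree(20, height = 1, seed = 131)
  x <- sim_trait(tr, "BM", seed = 132)
  X <- cbind(a = x, b = 2 * x)
  y <- sim_trait(tr, "BM", seed = 133)
  expect_error(pgls_fit(y, X, tr, model = "BM"), "collinear")
})

test_that("phylogenetic ANOVA: maximal separation and calibration", {
  tr <- sim_yule_tree(40, height = 1, seed = 141)
  y <- sim_trait(tr, "BM", seed = 142)
  grp <- setNames(factor(ifelse(y > median(y), "hi", "lo")), names(y))
  res <- phyl_anova(y, grp, tr, n_sims = 199, seed = 3)
  expect_equal(res$p_sim, 1 / 200)

  # type-I calibration: group labels independent of a BM trait
  rej <- vapply(1:100, function(i) {
    tri <- sim_yule_tree(30, height = 1, seed = 9000 + i)
    yi <- sim_trait(tri, "BM", seed = 9100 + i)
    set.seed(9200 + i)
    gi <- setNames(factor(sample(rep(c("a", "b"), each = 15))), names(yi))
    phyl_anova(yi, gi, tri, n_sims = 199, seed = 9300 + i)$p_sim <= 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.0)
  expect_lte(mean(rej), 0.12)

  expect_error(phyl_anova(y, setNames(factor(rep("a", 40)), names(y)), tr,
                          n_sims = 10, seed = 1), "2 groups")
})
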