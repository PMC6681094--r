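test_that("phylogenetic mean and rate: star tree, constants, hand-solved GLS", {
  st <- star_tree(3, len = 1)
  V <- vcv_from_tree(st, "BM")
  x <- setNames(c(1, 2, 3), st$tip.label)
  mr <- phylo_mean_rate(x, V)
  expect_equal(unname(mr$a_hat), 2)

  tr <- fixture_tree3()
  Vt <- vcv_from_tree(tr, "BM")
  const <- setNames(rep(4.2, 3), c("A", "B", "C"))
  mrc <- phylo_mean_rate(const, Vt)
  expect_equal(unname(mrc$a_hat), 4.2)
  expect_equal(as.numeric(mrc$rate), 0)

  # hand-solved GLS system for V = [[2,1,0],[1,2,0],[0,0,2]], x = (0,0,3):
  # V^-1 1 = (1/3, 1/3, 1/2); a = (1.5)/(7/6) = 9/7
  mr3 <- phylo_mean_rate(setNames(c(0, 0, 3), c("A", "B", "C")), Vt)
  expect_equal(unname(mr3$a_hat), 9 / 7, tolerance = 1e-12)
})

test_that("phylogenetic mean/rate agree with an independent GLS implementation", {
  skip_if_not_installed("phytools")
  set.seed(5)
  for (i in 1:4) {
    tr <- sim_yule_tree(25, height = 2, seed = 300 + i)
    X <- cbind(a = sim_trait(tr, "BM", seed = 400 + i),
               b = sim_trait(tr, "BM", seed = 500 + i))
    mr <- phylo_mean_rate(X, vcv_from_tree(tr, "BM"))
    pv <- phytools::phyl.vcv(X[tr$tip.label, ], ape::vcv(tr), lambda = 1)
    expect_equal(unname(mr$a_hat), unname(as.vector(pv$alpha)), tolerance = 1e-8)
    expect_equal(unname(as.matrix(mr$rate)), unname(pv$R), tolerance = 1e-8)
  }
})

test_that("Blomberg's K: star-tree exactness, affine invariance, oracle", {
  st <- star_tree(8, len = 3)
  set.seed(11)
  x <- named_rnorm(st)
  expect_equal(blomberg_k(x, st), 1, tolerance = 1e-10)

  tr <- sim_yule_tree(30, height = 1, seed = 21)
  y <- sim_trait(tr, "BM", seed = 22)
  k1 <- blomberg_k(y, tr)
  expect_equal(blomberg_k(3.7 * y - 11, tr), k1, tolerance = 1e-10)

  expect_error(blomberg_k(setNames(rep(1, 30), tr$tip.label), tr), "constant")

  skip_if_not_installed("picante")
  for (i in 1:5) {
    tri <- sim_yule_tree(20, height = 1, seed = 600 + i)
    xi <- sim_trait(tri, "BM", seed = 700 + i)
    expect_equal(blomberg_k(xi, tri),
                 as.numeric(picante::Kcalc(xi[tri$tip.label], tri)),
                 tolerance = 1e-8)
  }
})

test_that("K randomization test: p bounds, determinism, signal detection", {
  tr <- sim_yule_tree(60, height = 1, seed = 31)
  x <- sim_trait(tr, "BM", seed = 32)
  r1 <- k_randomization_test(x, tr, n_reps = 199, seed = 5)
  r2 <- k_randomization_test(x, tr, n_reps = 199, seed = 5)
  expect_identical(r1, r2)
  expect_gte(r1$p_value, 1 / 200)
  expect_lte(r1$p_value, 1)
  # strong BM signal on 60 tips should be detected
  expect_lte(r1$p_value, 0.05)
  expect_error(k_randomization_test(x, tr, n_reps = 0, seed = 1), "n_reps")
})

test_that("lambda ML matches an independent implementation and its invariants", {
  skip_if_not_installed("phytools")
  set.seed(8)
  for (i in 1:3) {
    tr <- sim_yule_tree(40, height = 1, seed = 800 + i)
    x <- sim_trait(tr, "lambda", lambda = 0.6, seed = 900 + i)
    mine <- pagel_lambda_ml(x, tr)
    ref <- phytools::phylosig(tr, x[tr$tip.label], method = "lambda", test = TRUE)
    expect_equal(mine$lambda_hat, min(ref$lambda, 1), tolerance = 0.02)
    expect_equal(mine$logL_at_zero, ref$logL0, tolerance = 1e-6)
    expect_gte(mine$lr_stat, 0)
    # affine invariance of the estimate
    mine2 <- pagel_lambda_ml(-2 * x + 7, tr)
    expect_equal(mine2$lambda_hat, mine$lambda_hat, tolerance = 1e-5)
  }
})

test_that("lambda on a star tree is flagged unidentifiable", {
  st <- star_tree(10)
  set.seed(2)
  expect_warning(res <- pagel_lambda_ml(named_rnorm(st), st), "unidentifiable")
  expect_equal(res$lambda_hat, 0)
  expect_equal(res$p_value, 1)
})

test_that("binary 0/1 traits are accepted with a model-mismatch warning", {
  tr <- sim_yule_tree(30, height = 1, seed = 41)
  y <- sim_binary_threshold(tr, prevalence = 0.5, seed = 42)
  expect_warning(res <- pagel_lambda_ml(y, tr), "binary")
  expect_true(res$lambda_hat >= 0 && res$lambda_hat <= 1)
})

test_that("phylogenetic standardization: star z-score, idempotence, errors", {
  # on a unit-height star the GLS mean/rate are the sample mean/variance
  st <- star_tree(12, len = 1)
  set.seed(13)
  X <- cbind(a = named_rnorm(st), b = named_rnorm(st) * 5 + 3)
  V <- vcv_from_tree(st, "BM")
  Z <- standardize_phylo(X, V)
  expect_equal(unclass(Z)[, ], unclass(scale(X))[, ], tolerance = 1e-10,
               ignore_attr = TRUE)

  # idempotence: standardizing a standardized matrix changes nothing
  tr <- sim_yule_tree(20, height = 1, seed = 51)
  Xt <- cbind(a = sim_trait(tr, "BM", seed = 52),
              b = sim_trait(tr, "BM", seed = 53))
  Vt <- vcv_from_tree(tr, "BM")
  Z1 <- standardize_phylo(Xt, Vt)
  Z2 <- standardize_phylo(Z1, Vt)
  expect_equal(unclass(Z2)[, ], unclass(Z1)[, ], tolerance = 1e-8,
               ignore_attr = TRUE)
  # a standardized matrix has GLS mean 0 and unit rate diagonal
  expect_equal(unname(attr(Z2, "a_hat")), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(diag(attr(Z2, "rate"))), c(1, 1), tolerance = 1e-10)

  expect_error(standardize_phylo(cbind(c = setNames(rep(1, 20), tr$tip.label)), Vt),
               "constant")
})
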