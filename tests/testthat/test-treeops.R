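test_that("Newick parsing validates structure and round-trips", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_equal(tree_height(tr), 2)

  tr2 <- parse_newick("(A:1,B:1);")
  expect_equal(length(tr2$tip.label), 2L)

  # round trip preserves topology and branch lengths
  set.seed(1)
  for (i in 1:5) {
    yule <- sim_yule_tree(15, height = 3, seed = i)
    back <- parse_newick(write_newick(yule))
    expect_equal(phangorn::RF.dist(yule, back), 0)
    expect_equal(ape::cophenetic.phylo(back)[yule$tip.label, yule$tip.label],
                 ape::cophenetic.phylo(yule), tolerance = 1e-9)
  }

  expect_error(parse_newick("((A:1,A:1):1,C:2);"), "duplicate tip")
  expect_error(parse_newick("(A,B);"), "branch length")
  expect_error(parse_newick("(A:1,B);"), "branch length")
  expect_error(parse_newick("((A:1,B:1:1,C:2);"), "malformed|branch length")
})

test_that("pruning preserves patristic distances and handles errors", {
  tr <- fixture_tree3()
  pruned <- prune_to_taxa(tr, c("A", "C"))
  expect_equal(sort(pruned$tip.label), c("A", "C"))
  expect_equal(unname(ape::cophenetic.phylo(pruned)["A", "C"]), 4)

  expect_identical(prune_to_taxa(tr, c("A", "B", "C")), tr)
  expect_error(prune_to_taxa(tr, "A"), "at least 2")
  expect_error(prune_to_taxa(tr, c("A", "Z")), "Z")

  # property: random keep-sets on random Yule trees
  set.seed(42)
  for (i in 1:10) {
    yule <- sim_yule_tree(20, height = 1, seed = 100 + i)
    keep <- sample(yule$tip.label, sample(2:15, 1))
    pr <- prune_to_taxa(yule, keep)
    expect_equal(ape::cophenetic.phylo(pr)[keep, keep],
                 ape::cophenetic.phylo(yule)[keep, keep], tolerance = 1e-9)
  }
})

test_that("ultrametricity check reports the max tip-height deviation", {
  expect_true(is_ultrametric(fixture_tree3())$ultrametric)
  expect_true(is_ultrametric(parse_newick("(A:1,B:1);"))$ultrametric)
  res <- is_ultrametric(parse_newick("((A:1,B:2):1,C:2);"))
  expect_false(res$ultrametric)
  expect_gt(res$max_deviation, 0.4)
})

test_that("VCV matrices match hand-computed values for all four models", {
  tr <- fixture_tree3()
  ord <- c("A", "B", "C")

  bm <- vcv_from_tree(tr, "BM")
  expect_equal(unclass(bm)[ord, ord],
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3,
                      dimnames = list(ord, ord)))

  lam <- vcv_from_tree(tr, "lambda", lambda = 0.5)
  expect_equal(unclass(lam)[ord, ord],
               matrix(c(2, 0.5, 0, 0.5, 2, 0, 0, 0, 2), 3,
                      dimnames = list(ord, ord)))

  un <- vcv_from_tree(tr, "unit", correlation = TRUE)
  expect_equal(unclass(un)[ord, ord],
               matrix(c(1, 0.5, 0, 0.5, 1, 0, 0, 0, 1), 3,
                      dimnames = list(ord, ord)))

  ou <- vcv_from_tree(tr, "OU", alpha = 0.5)
  expect_equal(ou["A", "B"], exp(-1) * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(ou["A", "A"], 1 - exp(-2), tolerance = 1e-12)
})

test_that("lambda = 1 equals BM and OU converges to BM as alpha -> 0", {
  tr <- sim_yule_tree(10, height = 2, seed = 9)
  expect_equal(unclass(vcv_from_tree(tr, "lambda", lambda = 1)),
               unclass(vcv_from_tree(tr, "BM")), tolerance = 1e-12,
               ignore_attr = TRUE)

  ou_cor <- unclass(vcv_from_tree(tr, "OU", alpha = 1e-8, correlation = TRUE))
  bm_cor <- unclass(vcv_from_tree(tr, "BM", correlation = TRUE))
  expect_equal(ou_cor, bm_cor, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("every VCV admits a Cholesky factorization after tiny jitter", {
  set.seed(3)
  for (i in 1:5) {
    tr <- sim_yule_tree(12, height = 1, seed = 200 + i)
    for (spec in list(list("BM"), list("lambda", lambda = 0.3),
                      list("unit"), list("OU", alpha = 2))) {
      V <- do.call(vcv_from_tree, c(list(tr, spec[[1]]), spec[-1]))
      ch <- chol(unclass(V) + diag(1e-10, nrow(V)))
      expect_true(all(is.finite(ch)))
    }
  }
})

test_that("VCV rejects invalid model parameters", {
  tr <- fixture_tree3()
  nonult <- parse_newick("((A:1,B:2):1,C:2);")
  expect_error(vcv_from_tree(nonult, "OU", alpha = 1), "ultrametric")
  expect_error(vcv_from_tree(tr, "OU", alpha = 0), "alpha")
  expect_error(vcv_from_tree(tr, "lambda", lambda = 1.2), "lambda")
  expect_error(vcv_from_tree(tr, "lambda", lambda = -0.1), "lambda")
})

test_that("tree sets read from newick-lines and NEXUS, with tip-set checks", {
  tmp <- tempfile(fileext = ".nwk")
  writeLines(rep(write_newick(fixture_tree3()), 3), tmp)
  ts <- read_tree_set(tmp)
  expect_length(ts, 3L)
  expect_s3_class(ts, "tree_set")

  # NEXUS with translate table
  tmp2 <- tempfile(fileext = ".nex")
  trees <- c(fixture_tree3(), fixture_tree3())
  class(trees) <- "multiPhylo"
  ape::write.nexus(trees, file = tmp2, translate = TRUE)
  ts2 <- read_tree_set(tmp2)
  expect_length(ts2, 2L)
  expect_setequal(ts2[[1]]$tip.label, c("A", "B", "C"))

  # empty file
  tmp3 <- tempfile()
  writeLines(character(0), tmp3)
  expect_error(read_tree_set(tmp3), "empty")

  # inconsistent tip sets
  tmp4 <- tempfile(fileext = ".nwk")
  writeLines(c("((A:1,B:1):1,C:2);", "((A:1,B:1):1,D:2);"), tmp4)
  expect_error(read_tree_set(tmp4), "inconsistent")
  ts4 <- read_tree_set(tmp4, prune_to_intersection = TRUE)
  expect_setequal(ts4[[1]]$tip.label, c("A", "B"))
})
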