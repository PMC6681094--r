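make_trait_df <- function(n = 4) {
  data.frame(
    species = paste0("sp", seq_len(n)),
    uvp = seq(0.1, 0.97, length.out = n),
    color = rep(c("yellow", "white"), length.out = n),
    latitude = runif(n, 20, 70), altitude = runif(n, 100, 4000),
    temperature = runif(n, -10, 15), precipitation = runif(n, 200, 2000),
    uvb = runif(n, 1500, 5500),
    stringsAsFactors = FALSE
  )
}

test_that("trait tables load, validate and classify", {
  df <- make_trait_df(3)
  tmp <- tempfile(fileext = ".csv")
  write.csv(df, tmp, row.names = FALSE)
  tt <- load_trait_table(tmp)
  expect_s3_class(tt, "trait_table")
  expect_equal(nrow(tt), 3L)
  expect_true(all(tt$pattern == ifelse(tt$uvp < 0.95, "patterned", "uniform")))
  expect_identical(tt$pattern_bin, as.integer(tt$pattern == "uniform"))

  bad <- df; bad$uvp[2] <- 1.2
  expect_error(load_trait_table(bad), "row.*2|2")
  expect_error(load_trait_table(df[, setdiff(names(df), "uvb")]), "uvb")
  bad2 <- df; bad2$color[1] <- "blue"
  expect_error(load_trait_table(bad2), "blue")
  bad3 <- rbind(df, df[1, ])
  expect_error(load_trait_table(bad3), "duplicate")
})

test_that("classification threshold behaves as a strict-below rule", {
  expect_equal(as.character(classify_uv_pattern(c(0.45, 0.95, 0.9499, 0, 1))),
               c("patterned", "uniform", "patterned", "patterned", "uniform"))
  expect_error(classify_uv_pattern(1.01), "outside")
  # the threshold is configurable and drives the derived columns identically
  df <- make_trait_df(4)
  tt <- load_trait_table(df, threshold = 0.5)
  expect_equal(sum(tt$pattern == "patterned"), sum(df$uvp < 0.5))
  expect_equal(tt$pattern_bin, as.integer(df$uvp >= 0.5))
})

test_that("species means and variance partition match hand cases", {
  # no within-group variance -> 100% among
  sp <- data.frame(species = rep(c("X", "Y"), each = 2),
                   specimen_id = 1:4, uvp = c(0, 0, 1, 1))
  res <- suppressWarnings(species_means_and_anova(sp))  # zero-residual fit
  expect_equal(res$anova$pct_variance_among, 100)
  expect_equal(res$means$uvp, c(0, 1))

  # identical within-group spread, same means -> 0% among, F = 0
  sp2 <- data.frame(species = rep(c("X", "Y"), each = 2),
                    specimen_id = 1:4, uvp = c(0, 1, 0, 1))
  res2 <- species_means_and_anova(sp2)
  expect_equal(res2$anova$pct_variance_among, 0)
  expect_equal(res2$anova$F, 0)

  # singletons feed the means but not the ANOVA df
  sp3 <- rbind(sp, data.frame(species = "Z", specimen_id = 5, uvp = 0.5))
  res3 <- suppressWarnings(species_means_and_anova(sp3))
  expect_equal(nrow(res3$means), 3L)
  expect_equal(res3$anova$df_among, 1L)   # 2 multi-specimen species
  expect_equal(res3$anova$df_within, 2L)

  expect_warning(
    species_means_and_anova(data.frame(species = c("X", "Y"),
                                       specimen_id = 1:2, uvp = c(0.1, 0.2))),
    "ANOVA")
})

test_that("variance partition recovers a known among:within ratio", {
  # 10 species x 5 specimens, among:within variance 4:1 -> ~80% among
  pct <- vapply(1:100, function(s) {
    set.seed(s)
    mu <- rnorm(10, 0.5, sqrt(4))
    d <- data.frame(species = rep(paste0("s", 1:10), each = 5),
                    specimen_id = 1:50,
                    uvp = rep(mu, each = 5) + rnorm(50, 0, 1))
    d$uvp <- (d$uvp - min(d$uvp)) / diff(range(d$uvp))  # map into [0,1]
    species_means_and_anova(d)$anova$pct_variance_among
  }, numeric(1))
  expect_gt(mean(pct), 75)
  expect_lt(mean(pct), 85)
})

test_that("pattern-by-color crosstab counts and percentages", {
  df <- data.frame(
    pattern = factor(c("patterned", "patterned", "uniform", "uniform"),
                     levels = c("patterned", "uniform")),
    color = factor(c("yellow", "yellow", "white", "white"),
                   levels = c("yellow", "white", "red")))
  ct <- color_pattern_crosstab(df)
  expect_equal(unname(ct$pct_patterned_by_color["yellow"]), 100)
  expect_equal(unname(ct$pct_patterned_by_color["white"]), 0)
  expect_equal(unname(ct$counts["patterned", "yellow"]), 2L)

  empty <- df[0, , drop = FALSE]
  ct0 <- color_pattern_crosstab(empty)
  expect_true(all(ct0$counts == 0))
  expect_true(all(ct0$pct_patterned_by_color == 0))
})

test_that("percentage of variance among species is label-invariant", {
  set.seed(7)
  d <- data.frame(species = rep(paste0("s", 1:6), each = 3),
                  specimen_id = 1:18, uvp = runif(18))
  a <- species_means_and_anova(d)$anova$pct_variance_among
  d2 <- d; d2$species <- factor(d$species, labels = sample(LETTERS[1:6]))
  b <- species_means_and_anova(d2)$anova$pct_variance_among
  expect_equal(a, b)
  expect_true(a >= 0 && a <= 100)
})
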