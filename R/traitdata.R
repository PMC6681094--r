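## Species-level trait tables: reading, validation, UV-pattern
## classification, specimen aggregation, and pattern-by-color tabulation.

TRAIT_COLUMNS <- c("species", "uvp", "color", "latitude", "altitude",
                   "temperature", "precipitation", "uvb")
COLOR_LEVELS <- c("yellow", "white", "red")

#' Default UV-pattern classification threshold
#'
#' Flowers with a detectable UV-reflective petal apex (UVP below the
#' threshold) are "patterned"; those at or above it are uniformly
#' UV-absorbing. The single constant is shared by every stage that subsets on
#' pattern state.
#' @export
UVP_THRESHOLD <- 0.95

#' Classify UV pattern from petal UV proportion
#'
#' @param uvp Numeric vector of petal UV proportions in `[0, 1]`.
#' @param threshold Classification threshold (default [UVP_THRESHOLD]).
#' @return Factor with levels `patterned` (uvp < threshold) and `uniform`
#'   (uvp >= threshold).
#' @examples
#' classify_uv_pattern(c(0.45, 0.95, 0.9499))
#' @export
classify_uv_pattern <- function(uvp, threshold = UVP_THRESHOLD) {
  if (anyNA(uvp) || any(uvp < 0 | uvp > 1)) {
    bad <- which(is.na(uvp) | uvp < 0 | uvp > 1)
    stop("uvp outside [0, 1] at position(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(ifelse(uvp < threshold, "patterned", "uniform"),
         levels = c("patterned", "uniform"))
}

#' Binary response coding for the pattern state
#'
#' The GEE response convention: UV pattern present = 0, pattern absent
#' (uniformly UV-absorbing) = 1. Positive regression coefficients therefore
#' mean "more likely uniformly UV-absorbing".
#'
#' @param pattern Factor from [classify_uv_pattern()] (or uvp values).
#' @param threshold Threshold used when raw uvp values are supplied.
#' @return Integer vector of 0 (patterned) / 1 (uniform).
#' @export
pattern_binary <- function(pattern, threshold = UVP_THRESHOLD) {
  if (is.numeric(pattern)) pattern <- classify_uv_pattern(pattern, threshold)
  as.integer(pattern == "uniform")
}

#' Load and validate a species-level trait table
#'
#' Required columns: `species, uvp, color, latitude, altitude, temperature,
#' precipitation, uvb`. Adds the derived `pattern` factor and its 0/1 coding
#' (`pattern_bin`, present = 0 / absent = 1).
#'
#' @param path CSV file path (UTF-8, header row) or a data.frame.
#' @param threshold UV-pattern classification threshold.
#' @return A validated `data.frame` of class `trait_table`.
#' @export
load_trait_table <- function(path, threshold = UVP_THRESHOLD) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing_cols <- setdiff(TRAIT_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$species)) {
    stop("duplicate species: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "),
         call. = FALSE)
  }
  num_cols <- setdiff(TRAIT_COLUMNS, c("species", "color"))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (anyNA(v) && !all(is.na(df[[cl]]) == is.na(v))) {
      stop("non-numeric values in column '", cl, "'", call. = FALSE)
    }
    df[[cl]] <- v
  }
  bad_uvp <- which(is.na(df$uvp) | df$uvp < 0 | df$uvp > 1)
  if (length(bad_uvp)) {
    stop("uvp outside [0, 1] in row(s): ", paste(bad_uvp, collapse = ", "),
         call. = FALSE)
  }
  bad_color <- setdiff(unique(df$color), COLOR_LEVELS)
  if (length(bad_color)) {
    stop("unknown color level(s): ", paste(bad_color, collapse = ", "),
         " (allowed: ", paste(COLOR_LEVELS, collapse = ", "), ")", call. = FALSE)
  }
  df$color <- factor(df$color, levels = COLOR_LEVELS)
  df$pattern <- classify_uv_pattern(df$uvp, threshold)
  df$pattern_bin <- pattern_binary(df$pattern)
  attr(df, "threshold") <- threshold
  class(df) <- c("trait_table", "data.frame")
  df
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("trait_table: %d species (%d patterned, %d uniform; threshold %.2f)\n",
              nrow(x), sum(x$pattern == "patterned"), sum(x$pattern == "uniform"),
              attr(x, "threshold")))
  NextMethod()
}

#' Species means of specimen-level UVP with an among-species ANOVA
#'
#' Aggregates a specimen table (`species, specimen_id, uvp`) to species
#' arithmetic means and partitions UVP variance among versus within species
#' with a one-way fixed-effect ANOVA. Species represented by a single
#' specimen contribute to the means but are excluded from the ANOVA, so the
#' among-species degrees of freedom equal (number of multi-specimen species)
#' minus 1.
#'
#' @param specimens Data.frame with columns `species`, `specimen_id`, `uvp`.
#' @return List with `means` (data.frame species/uvp/n_specimens) and
#'   `anova` (list `F`, `df_among`, `df_within`, `p`, `pct_variance_among`),
#'   the latter `NULL` with a warning when every species is a singleton.
#' @export
species_means_and_anova <- function(specimens) {
  stopifnot(all(c("species", "uvp") %in% names(specimens)))
  if (anyNA(specimens$uvp) || any(specimens$uvp < 0 | specimens$uvp > 1)) {
    stop("specimen uvp outside [0, 1]", call. = FALSE)
  }
  means <- stats::aggregate(uvp ~ species, data = specimens, FUN = mean)
  means$n_specimens <- as.integer(table(specimens$species)[means$species])
  multi <- specimens$species %in% means$species[means$n_specimens >= 2L]
  res <- list(means = means, anova = NULL)
  if (sum(multi) == 0L || length(unique(specimens$species[multi])) < 2L) {
    warning("fewer than 2 species with >= 2 specimens; ANOVA not computed",
            call. = FALSE)
    return(res)
  }
  sub <- specimens[multi, , drop = FALSE]
  fit <- stats::aov(uvp ~ factor(species), data = sub)
  at <- stats::anova(fit)
  ss_among <- at[["Sum Sq"]][1L]
  ss_within <- at[["Sum Sq"]][2L]
  ss_total <- ss_among + ss_within
  res$anova <- list(
    F = at[["F value"]][1L],
    df_among = at[["Df"]][1L],
    df_within = at[["Df"]][2L],
    p = at[["Pr(>F)"]][1L],
    pct_variance_among = if (ss_total > 0) 100 * ss_among / ss_total else NA_real_
  )
  res
}

#' Cross-tabulate UV pattern by human-visible flower color
#'
#' @param table A `trait_table` (or data.frame with `pattern` and `color`).
#' @return List with `counts` (pattern x color matrix), `pct_patterned_by_color`
#'   (per color, percentage of species that are patterned) and
#'   `pct_color_by_pattern` (per pattern state, percentage breakdown over
#'   colors). Percentages are unrounded.
#' @export
color_pattern_crosstab <- function(table) {
  stopifnot(all(c("pattern", "color") %in% names(table)))
  counts <- base::table(
    pattern = factor(table$pattern, levels = c("patterned", "uniform")),
    color = factor(table$color, levels = COLOR_LEVELS)
  )
  col_tot <- colSums(counts)
  row_tot <- rowSums(counts)
  pct_patterned_by_color <- ifelse(col_tot > 0, 100 * counts["patterned", ] / col_tot, 0)
  pct_color_by_pattern <- counts
  for (r in rownames(counts)) {
    pct_color_by_pattern[r, ] <-
      if (row_tot[r] > 0) 100 * counts[r, ] / row_tot[r] else 0
  }
  list(counts = unclass(counts),
       pct_patterned_by_color = pct_patterned_by_color,
       pct_color_by_pattern = unclass(pct_color_by_pattern))
}
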