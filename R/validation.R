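#' Point-biserial correlation between a binary label and a biomarker
#'
#' The Pearson correlation between the 0/1 class variable and a continuous
#' biomarker, with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Pairs with a missing biomarker value are dropped listwise.
#'
#' @param labels Binary vector (logical, 0/1, or two-level factor/character;
#'   for character the alphabetically later level codes as 1).
#' @param values Numeric biomarker vector, same length.
#' @return One-row tibble: `r`, `n`, `statistic`, `p_value`.
#' @export
point_biserial <- function(labels, values) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.integer(factor(labels)) - 1L
  labels <- as.numeric(labels)
  keep <- !is.na(labels) & !is.na(values)
  labels <- labels[keep]; values <- values[keep]
  assert_that(length(unique(labels)) == 2,
              "both classes must be present after listwise deletion")
  assert_that(sd(values) > 0, "biomarker values are constant")
  n <- length(labels)
  r <- cor(labels, values)
  if (1 - r^2 < 64 * .Machine$double.eps) {
    # perfect (anti)ordering: t diverges; p is 0 for n > 2, undefined at n = 2
    tstat <- sign(r) * Inf
    p <- if (n > 2) 0 else NA_real_
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  tibble(r = r, n = n, statistic = tstat, p_value = p)
}

#' Meng-Rosenthal-Rubin correlated correlation test
#'
#' Tests whether two correlations `r1` and `r2`, measured against the same
#' biomarker on the same sample, differ -- accounting for the correlation
#' `r12` between the two label variables. Uses Fisher z transforms with
#' `rbar2 = (r1^2 + r2^2) / 2`, `f = min(1, (1 - r12) / (2 (1 - rbar2)))`,
#' `h = (1 - f * rbar2) / (1 - rbar2)` and
#' `Z = (z1 - z2) * sqrt((n - 3) / (2 (1 - r12) h))`, two-sided normal p.
#'
#' @param r1,r2 Correlations of the two label variables with the biomarker.
#' @param r12 Correlation between the two label variables.
#' @param n Common sample size (> 3).
#' @return One-row tibble: `r1`, `r2`, `r12`, `n`, `z`, `p_value`.
#' @export
#' @examples
#' correlated_correlation_test(0.6, 0.3, 0.5, 100)
correlated_correlation_test <- function(r1, r2, r12, n) {
  assert_that(all(abs(c(r1, r2, r12)) <= 1), "correlations must be in [-1,1]")
  assert_that(n > 3, "need n > 3")
  assert_that(abs(r1) < 1 && abs(r2) < 1,
              "|r| = 1 is degenerate (Fisher z diverges)")
  rbar2 <- (r1^2 + r2^2) / 2
  assert_that(1 - rbar2 > 0, "1 - mean squared correlation must be positive")
  f <- min(1, (1 - r12) / (2 * (1 - rbar2)))
  h <- (1 - f * rbar2) / (1 - rbar2)
  z <- (atanh(r1) - atanh(r2)) * sqrt((n - 3) / (2 * (1 - r12) * h))
  tibble(r1 = r1, r2 = r2, r12 = r12, n = n, z = z,
         p_value = 2 * pnorm(-abs(z)))
}

#' Correlate conversion definitions with external biomarkers
#'
#' Runs [point_biserial()] for every (definition, biomarker) pair on a
#' one-row-per-subject table, with listwise deletion per pair. Layout mirrors
#' a correlation-table report: one row per pair with `r`, `n`, `p_value`.
#'
#' @param data Tibble, one row per subject.
#' @param definitions Character vector of binary label column names.
#' @param biomarkers Character vector of numeric biomarker column names.
#' @return Tibble with columns `definition`, `biomarker`, `r`, `n`,
#'   `statistic`, `p_value`.
#' @export
biomarker_correlations <- function(data, definitions, biomarkers) {
  grid <- tidyr::expand_grid(definition = definitions, biomarker = biomarkers)
  purrr::pmap_dfr(grid, function(definition, biomarker) {
    bind_cols(tibble(definition = definition, biomarker = biomarker),
              point_biserial(data[[definition]], data[[biomarker]]))
  })
}

#' Compare two conversion definitions on the same biomarkers
#'
#' For each biomarker, computes both definitions' point-biserial correlations
#' on the subjects with complete data, the label-label correlation `r12`, and
#' the Meng-Rosenthal-Rubin test of the difference.
#'
#' @param data Tibble, one row per subject.
#' @param def1,def2 Binary label column names.
#' @param biomarkers Numeric biomarker column names.
#' @return Tibble with one row per biomarker: `r1`, `r2`, `r12`, `n`, `z`,
#'   `p_value`.
#' @export
compare_definitions <- function(data, def1, def2, biomarkers) {
  purrr::map_dfr(biomarkers, function(bm) {
    keep <- complete.cases(data[, c(def1, def2, bm)])
    d <- data[keep, ]
    to01 <- function(v) if (is.character(v) || is.factor(v))
      as.integer(factor(v)) - 1L else as.numeric(v)
    l1 <- to01(d[[def1]]); l2 <- to01(d[[def2]])
    r1 <- cor(l1, d[[bm]])
    r2 <- cor(l2, d[[bm]])
    r12 <- cor(l1, l2)
    bind_cols(tibble(biomarker = bm),
              correlated_correlation_test(r1, r2, r12, nrow(d)))
  })
}

#' Exclude subjects converting only at their final visit
#'
#' When validating the by-trajectory definition against final-visit region
#' volumes, subjects whose only AD-side (negative) observed score occurs at
#' their final available visit would let the same scan define the label and
#' the biomarker; they are excluded from those tests only (the full MCI
#' population is used for all other validation).
#'
#' @param scores A [score_trajectories()] tibble (observed visits only).
#' @param labels Optional [conversion_labels()] tibble; when supplied, only
#'   converters-by-trajectory (`CT`) can be excluded -- a nonconverter's
#'   stray final-visit negative score is noise, not a conversion.
#' @return Tibble `subject_id`, `keep` (FALSE = excluded).
#' @export
exclude_final_visit_converters <- function(scores, labels = NULL) {
  mask <- scores %>%
    group_by(.data$subject_id) %>%
    summarise(
      keep = {
        neg <- .data$visit[.data$score < 0]
        !(length(neg) > 0 && all(neg == max(.data$visit)))
      },
      .groups = "drop"
    )
  if (!is.null(labels)) {
    ct <- labels$subject_id[labels$by_trajectory == "CT"]
    mask$keep <- mask$keep | !(mask$subject_id %in% ct)
  }
  mask
}

#' Per-class biomarker summary and standardized separation
#'
#' Group means and standard deviations of a biomarker under a binary
#' labeling, plus the standardized mean gap `|m1 - m0| / pooled SD` -- the
#' quantity visualized by per-class Gaussian curves over the histograms.
#'
#' @param labels Binary vector.
#' @param values Numeric vector.
#' @return A `histogram_separation` list: `by_class` tibble (`class`, `n`,
#'   `mean`, `sd`) and `gap` (standardized mean difference).
#' @export
histogram_separation <- function(labels, values) {
  keep <- !is.na(labels) & !is.na(values)
  labels <- labels[keep]; values <- values[keep]
  classes <- sort(unique(labels))
  assert_that(length(classes) == 2, "both classes must be present")
  by_class <- tibble(class = as.character(classes)) %>%
    mutate(n = purrr::map_int(classes, ~ sum(labels == .x)),
           mean = purrr::map_dbl(classes, ~ mean(values[labels == .x])),
           sd = purrr::map_dbl(classes, ~ sd(values[labels == .x])))
  assert_that(all(by_class$n >= 2), "each class needs >= 2 members")
  pooled <- sqrt(sum((by_class$n - 1) * by_class$sd^2) /
                   (sum(by_class$n) - 2))
  structure(list(by_class = by_class,
                 gap = abs(diff(by_class$mean)) / pooled),
            class = "histogram_separation")
}

#' @export
print.histogram_separation <- function(x, ...) {
  print(x$by_class)
  cat("standardized gap:", signif(x$gap, 4), "\n")
  invisible(x)
}
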