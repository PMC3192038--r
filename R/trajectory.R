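#' Score every visit of each MCI subject with an AD-Control classifier
#'
#' Applies [signed_distance()] separately to each subject visit, producing
#' the per-subject phenotypical score trajectory (one `(visit, age, score)`
#' point per available visit, in visit order). Positive scores are on the
#' Control side of the decision boundary, negative on the AD side.
#'
#' @param data Tibble with columns `subject_id`, `visit`, `age`, one row per
#'   scan, aligned row-for-row with `features`.
#' @param features Matrix of preprocessed features (same preprocessing as the
#'   model's training data).
#' @param model A [train_margin_model()] AD-Control fit.
#' @return A `score_trajectories` tibble: `subject_id`, `visit`, `age`,
#'   `score`, sorted by subject then visit.
#' @export
score_trajectories <- function(data, features, model) {
  assert_that(nrow(data) == nrow(features),
              "data and features must align row-for-row")
  assert_that(nrow(data) > 0, "no visits to score")
  out <- data %>%
    select("subject_id", "visit", "age") %>%
    mutate(score = signed_distance(model, features)) %>%
    arrange(.data$subject_id, .data$visit)
  class(out) <- c("score_trajectories", class(out))
  out
}

#' Fit a line to a score trajectory and extend it to six nominal visits
#'
#' Ordinary least squares of score versus age over the observed points. The
#' extended score at nominal visit `k` is the line evaluated at
#' `baseline_age + (k - 1) * visit_interval` (baseline = the earliest
#' observed visit, shifted to its nominal slot when the first visits are
#' missing). A single observed point gives a constant (slope 0) line.
#'
#' @param points Tibble with columns `visit`, `age`, `score` (>= 1 row).
#' @param visit_interval Nominal inter-visit spacing in years.
#' @return List with `slope`, `intercept` (score-vs-age line), and
#'   `extended`, the scores at nominal visits 1..6.
#' @export
fit_and_extend <- function(points, visit_interval = 0.5) {
  assert_that(nrow(points) >= 1, "need at least one observed point")
  if (nrow(points) == 1 || length(unique(points$age)) == 1) {
    slope <- 0
    intercept <- mean(points$score)
  } else {
    am <- mean(points$age)
    slope <- sum((points$age - am) * (points$score - mean(points$score))) /
      sum((points$age - am)^2)
    intercept <- mean(points$score) - slope * am
  }
  first_visit <- points$visit[which.min(points$visit)]
  baseline_age <- points$age[which.min(points$visit)] -
    (first_visit - 1) * visit_interval
  ages6 <- baseline_age + (0:5) * visit_interval
  list(slope = slope, intercept = intercept,
       extended = intercept + slope * ages6)
}

#' Conversion label from an extended score trajectory
#'
#' With `s1` and `s6` the extended scores at nominal visits 1 and 6 (negative
#' = AD side, zero counted as Control side): a trajectory that starts on the
#' AD side and ends on the Control side is an `outlier` (these subjects are
#' omitted from downstream experiments); one that starts on the AD side or
#' reaches it by visit 6 is a converter-by-trajectory (`CT`); anything else
#' is a nonconverter-by-trajectory (`NT`).
#'
#' @param extended Numeric vector of 6 extended scores (from a fitted line).
#' @return One of `"CT"`, `"NT"`, `"outlier"`.
#' @export
#' @examples
#' label_by_trajectory(seq(2, -1, length.out = 6))  # crosses to AD side: CT
label_by_trajectory <- function(extended) {
  assert_that(length(extended) == 6, "need exactly 6 extended scores")
  s1 <- extended[1]; s6 <- extended[6]
  if (s1 < 0 && s6 > 0) return("outlier")
  if (s1 < 0 || s6 < 0) return("CT")
  "NT"
}

#' Conversion label from a CDR course
#'
#' Requires a baseline CDR of 0.5 (questionable dementia) -- otherwise the
#' label is `undefined`. A subject is a converter-by-CDR (`C-CDR`) when any
#' later visit rises above 0.5 and a nonconverter-by-CDR (`N-CDR`) when every
#' visit stays at 0.5.
#'
#' @param cdr Numeric vector of per-visit CDR values in `{0, 0.5, 1, 2, 3}`,
#'   baseline first.
#' @return One of `"C-CDR"`, `"N-CDR"`, `"undefined"`.
#' @export
label_by_cdr <- function(cdr) {
  assert_that(length(cdr) >= 1, "empty CDR sequence")
  assert_that(all(cdr %in% c(0, 0.5, 1, 2, 3)),
              "CDR values must be in {0, 0.5, 1, 2, 3}")
  if (cdr[1] != 0.5) return("undefined")
  if (any(cdr[-1] > 0.5)) return("C-CDR")
  if (all(cdr == 0.5)) return("N-CDR")
  # courses dipping below 0.5 without ever rising: no rise means no conversion
  "N-CDR"
}

#' Conversion flag from the average MMSE score
#'
#' Declares conversion when the subject's MMSE, averaged over all visits,
#' falls strictly below the cutoff. Averaging over visits damps the
#' within-subject noisiness of single cognitive assessments.
#'
#' @param mmse Numeric vector of per-visit MMSE scores.
#' @param cutoff Threshold on the visit-averaged MMSE.
#' @return `TRUE` (converter) or `FALSE`.
#' @export
label_by_mmse_threshold <- function(mmse, cutoff) {
  assert_that(length(mmse) >= 1, "need at least one MMSE value")
  mean(mmse) < cutoff
}

#' Conversion-by-union label
#'
#' A subject converts by-union when they convert either by-trajectory or
#' by-CDR. Trajectory outliers are excluded before this definition applies.
#'
#' @param by_trajectory `"CT"` or `"NT"` (not `"outlier"`).
#' @param by_cdr `"C-CDR"`, `"N-CDR"` or `"undefined"`.
#' @return `"converter"` or `"nonconverter"`.
#' @export
label_by_union <- function(by_trajectory, by_cdr) {
  assert_that(all(by_trajectory != "outlier"),
              "outliers must be excluded before by-union labeling")
  ifelse(by_trajectory == "CT" | by_cdr == "C-CDR",
         "converter", "nonconverter")
}

#' Does the baseline scan already classify as AD?
#'
#' @param model An AD-Control [train_margin_model()] fit.
#' @param baseline_features Numeric vector or 1-row matrix of preprocessed
#'   baseline-visit features.
#' @return `TRUE` when the baseline signed distance is negative (AD side);
#'   a score of exactly 0 counts as the Control side.
#' @export
converts_at_baseline <- function(model, baseline_features) {
  signed_distance(model, baseline_features)[1] < 0
}

#' Derive all conversion labels for an MCI population
#'
#' Combines the per-subject trajectory line fit ([fit_and_extend()],
#' [label_by_trajectory()]), the CDR course ([label_by_cdr()]) and the union
#' rule into one labels table. `conversion_visit` is the first observed visit
#' whose score is negative (NA when no observed score is); `converts_at_baseline`
#' flags a negative score at the earliest observed visit. `by_union` is NA for
#' trajectory outliers, which downstream experiments exclude.
#'
#' @param scores A [score_trajectories()] tibble.
#' @param meta Tibble with `subject_id`, `visit`, `cdr` (and optionally
#'   `mmse`) covering the scored subjects.
#' @param visit_interval Nominal inter-visit spacing in years.
#' @return A `conversion_labels` tibble: `subject_id`, `by_trajectory`,
#'   `by_cdr`, `by_union`, `converts_at_baseline`, `conversion_visit`,
#'   `slope`, `intercept`, `s1`, `s6`.
#' @export
conversion_labels <- function(scores, meta, visit_interval = 0.5) {
  per_subject <- scores %>%
    arrange(.data$subject_id, .data$visit) %>%
    group_by(.data$subject_id) %>%
    dplyr::group_modify(function(pts, key) {
      fe <- fit_and_extend(pts, visit_interval = visit_interval)
      neg <- pts$visit[pts$score < 0]
      tibble(
        by_trajectory = label_by_trajectory(fe$extended),
        converts_at_baseline = pts$score[1] < 0,
        conversion_visit = if (length(neg) > 0) min(neg) else NA_integer_,
        slope = fe$slope, intercept = fe$intercept,
        s1 = fe$extended[1], s6 = fe$extended[6]
      )
    }) %>%
    ungroup()
  cdr_tab <- meta %>%
    filter(.data$subject_id %in% per_subject$subject_id) %>%
    arrange(.data$subject_id, .data$visit) %>%
    group_by(.data$subject_id) %>%
    summarise(by_cdr = label_by_cdr(.data$cdr), .groups = "drop")
  out <- per_subject %>%
    left_join(cdr_tab, by = "subject_id") %>%
    mutate(by_union = ifelse(
      .data$by_trajectory == "outlier", NA_character_,
      label_by_union(ifelse(.data$by_trajectory == "outlier", "NT",
                            .data$by_trajectory), .data$by_cdr))) %>%
    select("subject_id", "by_trajectory", "by_cdr", "by_union",
           "converts_at_baseline", "conversion_visit", "slope", "intercept",
           "s1", "s6")
  class(out) <- c("conversion_labels", class(out))
  out
}
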