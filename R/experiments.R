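#' Random per-class train/test split
#'
#' Samples `per_class_train_n` subjects per class uniformly without
#' replacement; the remainder forms the test set. Deterministic per seed.
#'
#' @param labels Tibble with columns `subject_id` and `label`.
#' @param per_class_train_n Training subjects per class.
#' @param seed Integer seed.
#' @return A `split_plan` tibble: `subject_id`, `label`, `role`
#'   (`"train"`/`"test"`), with attributes `scheme` and `seed`.
#' @export
split_random <- function(labels, per_class_train_n, seed = 1) {
  assert_that(all(c("subject_id", "label") %in% names(labels)),
              "labels needs subject_id and label columns")
  sizes <- table(labels$label)
  assert_that(all(sizes >= per_class_train_n),
              "a class has fewer members than per_class_train_n")
  set.seed(seed)
  train_ids <- unlist(lapply(split(labels$subject_id, labels$label),
                             sample, size = per_class_train_n),
                      use.names = FALSE)
  out <- labels %>%
    mutate(role = ifelse(.data$subject_id %in% train_ids, "train", "test"))
  structure(out, scheme = "random", seed = seed,
            class = c("split_plan", class(out)))
}

#' Shared ("identical") train/test split for comparing two definitions
#'
#' Builds one training set and one test set shared by the by-CDR and
#' by-trajectory classifiers. A fraction of the converters-by-CDR who are
#' also CT is sampled and age-matched with NT-and-N-CDR partners; likewise a
#' fraction of the C-CDR-but-NT cell is matched with CT-and-N-CDR partners.
#' The training set is the union of the four matched groups (so each
#' classifier reads its own class labels off the same subjects); the
#' unsampled remainder of the two C-CDR cells is a "special" set held out of
#' the shared test set; everyone else is the test set.
#'
#' @param labels Tibble with `subject_id`, `age`, `by_trajectory`
#'   (`"CT"`/`"NT"`; outliers excluded beforehand) and `by_cdr`
#'   (`"C-CDR"`/`"N-CDR"`; `undefined` rows are dropped).
#' @param fraction Fraction of each C-CDR cell put into training.
#' @param tolerance_years Age-matching tolerance.
#' @param seed Integer seed.
#' @return A `split_plan` tibble: `subject_id`, `age`, `by_trajectory`,
#'   `by_cdr`, `role` (`"train"`, `"test"`, `"special"`).
#' @export
split_identical <- function(labels, fraction = 0.75, tolerance_years = 1.0,
                            seed = 1) {
  need <- c("subject_id", "age", "by_trajectory", "by_cdr")
  assert_that(all(need %in% names(labels)),
              paste("labels needs columns:", paste(need, collapse = ", ")))
  assert_that(all(labels$by_trajectory != "outlier"),
              "exclude trajectory outliers before splitting")
  labels <- filter(labels, .data$by_cdr != "undefined")
  cell <- function(traj, cdr)
    filter(labels, .data$by_trajectory == traj, .data$by_cdr == cdr)
  ccdr_ct <- cell("CT", "C-CDR")
  ccdr_nt <- cell("NT", "C-CDR")
  ncdr_nt <- cell("NT", "N-CDR")
  ncdr_ct <- cell("CT", "N-CDR")
  assert_that(nrow(ccdr_ct) > 0 && nrow(ccdr_nt) > 0 &&
                nrow(ncdr_nt) > 0 && nrow(ncdr_ct) > 0,
              "all four by-CDR x by-trajectory cells must be non-empty")
  set.seed(seed)
  pick_matched <- function(src, partners) {
    n_want <- max(1L, round(fraction * nrow(src)))
    src <- slice(src, sample(n()))  # random order, then greedy max matching
    m <- age_match(
      tibble(id = src$subject_id, age = src$age),
      tibble(id = partners$subject_id, age = partners$age),
      tolerance_years = tolerance_years
    )
    if (nrow(m) < n_want)
      abort("matching infeasible: not enough age-matched partners")
    keep <- m[sample(nrow(m), n_want), ]
    list(sampled = keep$id_a, partners = keep$id_b)
  }
  g1 <- pick_matched(ccdr_ct, ncdr_nt)
  g2 <- pick_matched(ccdr_nt, ncdr_ct)
  train_ids <- c(g1$sampled, g1$partners, g2$sampled, g2$partners)
  special_ids <- setdiff(c(ccdr_ct$subject_id, ccdr_nt$subject_id),
                         c(g1$sampled, g2$sampled))
  out <- labels %>%
    mutate(role = dplyr::case_when(
      .data$subject_id %in% train_ids ~ "train",
      .data$subject_id %in% special_ids ~ "special",
      TRUE ~ "test"
    ))
  structure(out, scheme = "identical", seed = seed, fraction = fraction,
            class = c("split_plan", class(out)))
}

#' Per-class and overall test accuracy
#'
#' @param truth,pred Character vectors of true and predicted labels.
#' @param positive The nonconverter-side class label; the other class is
#'   reported as the converter class.
#' @return One-row tibble: `n_converters`, `accuracy_converters`,
#'   `n_nonconverters`, `accuracy_nonconverters`, `n_total`,
#'   `accuracy_overall`. A class absent from the test set yields `NA`
#'   accuracy for that class.
#' @export
evaluate_predictions <- function(truth, pred, positive) {
  assert_that(length(truth) == length(pred) && length(truth) > 0,
              "truth and pred must be equal-length, non-empty")
  truth <- as.character(truth); pred <- as.character(pred)
  conv <- truth != positive
  acc <- function(mask) if (any(mask)) mean(pred[mask] == truth[mask])
  else NA_real_
  tibble(
    n_converters = sum(conv),
    accuracy_converters = acc(conv),
    n_nonconverters = sum(!conv),
    accuracy_nonconverters = acc(!conv),
    n_total = length(truth),
    accuracy_overall = mean(pred == truth)
  )
}

#' Majority vote over an ensemble of subsample classifiers
#'
#' Combines the decisions of an odd number of classifiers, each trained on a
#' distinct offset of the same stride-3 feature subsampling (27 offsets cover
#' the whole volume), by majority vote.
#'
#' @param models List of [train_margin_model()] fits (odd count) sharing
#'   class labels; if models carry an `"offset"` attribute the offsets must
#'   be pairwise distinct.
#' @param xs List of feature matrices, one per model, row-aligned across
#'   models.
#' @return Character vector of majority labels, one per row.
#' @export
ensemble_vote <- function(models, xs) {
  assert_that(length(models) %% 2 == 1, "model count must be odd")
  assert_that(length(models) == length(xs), "one feature matrix per model")
  offs <- lapply(models, attr, "offset")
  if (all(!vapply(offs, is.null, TRUE))) {
    keys <- vapply(offs, paste, "", collapse = ",")
    assert_that(!anyDuplicated(keys), "ensemble offsets must not overlap")
  }
  pos <- unique(vapply(models, `[[`, "", "positive"))
  neg <- unique(vapply(models, `[[`, "", "negative"))
  assert_that(length(pos) == 1 && length(neg) == 1,
              "models must share class labels")
  votes <- vapply(seq_along(models), function(i)
    signed_distance(models[[i]], xs[[i]]) >= 0,
    logical(nrow(xs[[1]])))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
  ifelse(rowSums(votes) > length(models) / 2, pos, neg)
}

# Stage-1 training-set rules: the AD class is individual AD visit images with
# CDR >= 1; the Control class is initial visits of participants whose CDR is
# 0 at every visit. Classes are balanced by <=1-year age matching.
ad_control_rows <- function(meta) {
  control_ok <- meta %>%
    group_by(.data$subject_id) %>%
    summarise(all_zero = all(.data$cdr == 0), .groups = "drop")
  ctrl <- meta %>%
    mutate(row = dplyr::row_number()) %>%
    filter(.data$group == "Control") %>%
    left_join(control_ok, by = "subject_id") %>%
    filter(.data$all_zero) %>%
    group_by(.data$subject_id) %>%
    filter(.data$visit == min(.data$visit)) %>%
    ungroup()
  ad <- meta %>%
    mutate(row = dplyr::row_number()) %>%
    filter(.data$group == "AD", .data$cdr >= 1)
  list(control = ctrl, ad = ad)
}

#' Train the stage-1 AD-Control classifier from a cohort
#'
#' Applies the training-set composition rules (AD visit images with CDR >= 1;
#' initial visits of Controls at CDR 0 throughout), age-matches the classes
#' at `tolerance_years`, age-adjusts every feature using the Control samples,
#' scales to `[0,1]` on the training set, and trains the linear max-margin
#' classifier with Controls scoring positive.
#'
#' @param cohort An `mci_cohort`.
#' @param C Regularization constant; `NULL` (default) selects it by
#'   bootstrap validation ([select_C()]) on the preprocessed training set.
#' @param tolerance_years Age-matching tolerance.
#' @param c_grid,n_bootstrap,seed Passed to [select_C()] when `C` is `NULL`.
#' @return List with `model`, `preprocess` (to apply to new scans), and
#'   `train_meta`.
#' @export
train_ad_control <- function(cohort, C = NULL, tolerance_years = 1.0,
                             c_grid = 2^(-5:5), n_bootstrap = 30, seed = 1) {
  rows <- ad_control_rows(cohort$meta)
  assert_that(nrow(rows$control) > 0 && nrow(rows$ad) > 0,
              "cohort lacks eligible Control or AD training scans")
  m <- age_match(
    tibble(id = rows$control$row, age = rows$control$age),
    tibble(id = rows$ad$row, age = rows$ad$age),
    tolerance_years = tolerance_years
  )
  assert_that(nrow(m) >= 2, "age matching left too few AD-Control pairs")
  train_rows <- c(m$id_a, m$id_b)
  y <- rep(c("Control", "AD"), each = nrow(m))
  x <- cohort$features[train_rows, , drop = FALSE]
  ages <- cohort$meta$age[train_rows]
  prep <- fit_preprocess(x, ages, control_mask = y == "Control")
  xs <- apply_preprocess(prep, x, ages)
  if (is.null(C))
    C <- as.numeric(select_C(xs, y, c_grid = c_grid,
                             n_bootstrap = n_bootstrap, seed = seed,
                             positive = "Control"))
  model <- train_margin_model(xs, y, C = C, positive = "Control")
  list(model = model, preprocess = prep,
       train_meta = cohort$meta[train_rows, ])
}

#' Score and label the MCI population of a cohort
#'
#' Applies a stage-1 AD-Control fit to every MCI visit (after the fit's own
#' preprocessing) and derives the full conversion-labels table.
#'
#' @param cohort An `mci_cohort`.
#' @param adcn A [train_ad_control()] result.
#' @return List with `scores` ([score_trajectories()]) and `labels`
#'   ([conversion_labels()]).
#' @export
label_cohort <- function(cohort, adcn) {
  mci <- which(cohort$meta$group == "MCI")
  assert_that(length(mci) > 0, "cohort has no MCI scans")
  x <- apply_preprocess(adcn$preprocess,
                        cohort$features[mci, , drop = FALSE],
                        cohort$meta$age[mci])
  scores <- score_trajectories(cohort$meta[mci, ], x, adcn$model)
  iv <- if (!is.null(cohort$config)) cohort$config$visit_interval else 0.5
  labels <- conversion_labels(scores, cohort$meta, visit_interval = iv)
  list(scores = scores, labels = labels)
}

definition_classes <- function(definition) {
  switch(definition,
    by_trajectory = c(positive = "NT", converter = "CT"),
    by_cdr = c(positive = "N-CDR", converter = "C-CDR"),
    by_union = c(positive = "nonconverter", converter = "converter"),
    abort("unknown definition"))
}

#' Two-stage trajectory-bootstrapped prognosis pipeline
#'
#' Stage 1 trains the AD-Control classifier ([train_ad_control()]) and scores
#' every MCI visit to derive conversion labels ([label_cohort()]); trajectory
#' outliers are removed. Stage 2 then, over `n_trials` train/test trials,
#' trains a baseline-scan classifier per conversion definition (training
#' classes age-matched, features age-adjusted on the nonconverter class and
#' unit-scaled) and evaluates it on held-out MCI subjects. Under the
#' `"random"` scheme each definition gets its own same-sized random split;
#' under `"identical"` all definitions share one [split_identical()] plan per
#' trial.
#'
#' @param cohort An `mci_cohort` with Control, AD and MCI groups.
#' @param definitions Subset of `"by_trajectory"`, `"by_cdr"`, `"by_union"`.
#' @param scheme `"random"` or `"identical"`.
#' @param per_class_train_n Training subjects per class (random scheme);
#'   default 80% of the smaller class.
#' @param n_trials Number of train/test trials.
#' @param C Regularization constant for both stages; `NULL` (default)
#'   selects each classifier's constant by bootstrap validation on its own
#'   training set, the procedure used for every classifier in this framework.
#' @param c_grid,n_bootstrap_C Grid and resample count for that selection.
#' @param tolerance_years Age-matching tolerance.
#' @param fraction Training fraction of the scarce cells (identical scheme).
#' @param seed Integer seed; trial `t` uses `seed + 7919 * t`.
#' @return A `two_stage_result`: list with `adcn` (stage-1 fit), `scores`,
#'   `labels`, `trials` (per trial x definition accuracy tibble) and
#'   `summary` (mean and SD across trials per definition).
#' @export
run_two_stage <- function(cohort, definitions = "by_trajectory",
                          scheme = c("random", "identical"),
                          per_class_train_n = NULL, n_trials = 10, C = NULL,
                          c_grid = 2^(-5:5), n_bootstrap_C = 30,
                          tolerance_years = 1.0, fraction = 0.75, seed = 1) {
  scheme <- match.arg(scheme)
  assert_that(all(definitions %in% c("by_trajectory", "by_cdr", "by_union")),
              "unknown conversion definition")
  adcn <- train_ad_control(cohort, C = C, tolerance_years = tolerance_years,
                           c_grid = c_grid, n_bootstrap = n_bootstrap_C,
                           seed = seed)
  lab <- label_cohort(cohort, adcn)
  labels <- filter(lab$labels, .data$by_trajectory != "outlier")

  base_meta <- cohort$meta %>%
    filter(.data$group == "MCI") %>%
    group_by(.data$subject_id) %>%
    filter(.data$visit == min(.data$visit)) %>%
    ungroup()
  base_rows <- match(paste0(base_meta$subject_id, "_v", base_meta$visit),
                     rownames(cohort$features))
  base_x <- cohort$features[base_rows, , drop = FALSE]
  rownames(base_x) <- base_meta$subject_id
  base_age <- setNames(base_meta$age, base_meta$subject_id)

  fit_eval <- function(train_ids, test_ids, def_labels, positive,
                       trial_seed) {
    lab_of <- setNames(def_labels$label, def_labels$subject_id)
    tr_a <- def_labels$subject_id[def_labels$subject_id %in% train_ids &
                                    def_labels$label == positive]
    tr_b <- setdiff(intersect(def_labels$subject_id, train_ids), tr_a)
    m <- age_match(tibble(id = tr_a, age = base_age[tr_a]),
                   tibble(id = tr_b, age = base_age[tr_b]),
                   tolerance_years = tolerance_years)
    assert_that(nrow(m) >= 2, "age matching left too few training pairs")
    ids <- c(m$id_a, m$id_b)
    x <- base_x[ids, , drop = FALSE]
    ages <- base_age[ids]
    prep <- fit_preprocess(x, ages, control_mask = lab_of[ids] == positive)
    xs <- apply_preprocess(prep, x, ages)
    C_trial <- C %||% as.numeric(select_C(xs, lab_of[ids], c_grid = c_grid,
                                          n_bootstrap = n_bootstrap_C,
                                          seed = trial_seed,
                                          positive = positive))
    model <- train_margin_model(xs, lab_of[ids], C = C_trial,
                                positive = positive)
    te <- intersect(def_labels$subject_id, test_ids)
    xt <- apply_preprocess(prep, base_x[te, , drop = FALSE], base_age[te])
    pred <- ifelse(signed_distance(model, xt) >= 0, model$positive,
                   model$negative)
    evaluate_predictions(lab_of[te], pred, positive = positive)
  }

  trials <- list()
  for (t in seq_len(n_trials)) {
    trial_seed <- seed + 7919L * t
    shared_plan <- NULL
    if (scheme == "identical")
      shared_plan <- split_identical(
        labels %>%
          mutate(age = base_age[.data$subject_id]) %>%
          select("subject_id", "age", "by_trajectory", "by_cdr"),
        fraction = fraction, tolerance_years = tolerance_years,
        seed = trial_seed)
    for (def in definitions) {
      cls <- definition_classes(def)
      def_labels <- labels %>%
        mutate(label = .data[[def]]) %>%
        filter(!is.na(.data$label), .data$label != "undefined") %>%
        select("subject_id", "label")
      if (scheme == "random") {
        nn <- per_class_train_n %||%
          floor(0.8 * min(table(def_labels$label)))
        plan <- split_random(def_labels, nn, seed = trial_seed)
        train_ids <- plan$subject_id[plan$role == "train"]
        test_ids <- plan$subject_id[plan$role == "test"]
      } else {
        train_ids <- shared_plan$subject_id[shared_plan$role == "train"]
        test_ids <- shared_plan$subject_id[shared_plan$role == "test"]
      }
      res <- fit_eval(train_ids, test_ids, def_labels, cls[["positive"]],
                      trial_seed)
      trials[[length(trials) + 1]] <-
        bind_cols(tibble(trial = t, definition = def, scheme = scheme), res)
    }
  }
  trials <- bind_rows(trials)
  summary <- trials %>%
    group_by(.data$definition) %>%
    summarise(n_trials = n(),
              mean_accuracy = mean(.data$accuracy_overall),
              sd_accuracy = sd(.data$accuracy_overall),
              mean_accuracy_converters = mean(.data$accuracy_converters,
                                              na.rm = TRUE),
              mean_accuracy_nonconverters = mean(.data$accuracy_nonconverters,
                                                 na.rm = TRUE),
              .groups = "drop")
  structure(list(adcn = adcn, scores = lab$scores, labels = lab$labels,
                 trials = trials, summary = summary),
            class = "two_stage_result")
}

#' @export
print.two_stage_result <- function(x, ...) {
  cat("<two_stage_result> stage-1 margin ", signif(x$adcn$model$margin, 4),
      "; MCI labels: ", sep = "")
  print(table(x$labels$by_trajectory))
  print(x$summary)
  invisible(x)
}
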