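#' One step of recursive feature elimination (RFE)
#'
#' Returns the active feature with the smallest weight magnitude in the
#' current SVM solution, ties broken toward the lowest feature index.
#'
#' @param model A [train_margin_model()] fit.
#' @return The feature name to remove, with its position in the active set in
#'   attribute `"index"`.
#' @export
rfe_step <- function(model, active = model$active) {
  assert_that(length(active) >= 2, "need at least two active features")
  w <- model$w[names(model$w) %in% active]
  j <- which.min(abs(w))  # first minimum = lowest index on ties
  structure(names(w)[j], index = j)
}

#' One step of margin-based feature elimination (MFE)
#'
#' Evaluates, for every active feature, the margin of the classifier
#' restricted to the active set minus that feature (weights zeroed, bias
#' re-centered by the margin-maximal midpoint rule; see [margin_of()]), and
#' returns the feature whose removal leaves the largest margin. Ties break
#' toward the lowest feature index.
#'
#' @param model A [train_margin_model()] fit.
#' @param x,y Training matrix and labels.
#' @return The feature name to remove (attribute `"index"` = position in the
#'   active set, `"margin"` = post-removal margin).
#' @export
mfe_step <- function(model, x, y, active = model$active) {
  assert_that(length(active) >= 2, "need at least two active features")
  stats <- restricted_removal_stats(model, x, y, active = active)
  ok <- !is.na(stats$margin)
  if (!any(ok)) abort("every candidate removal zeroes the weight vector")
  cand <- ifelse(ok, stats$margin, -Inf)
  j <- which.max(cand)
  structure(stats$feature[j], index = j, margin = stats$margin[j])
}

#' One step of MFE with slack for non-separable retained sets
#'
#' When the restricted projection still separates the training classes the
#' criterion is the restricted margin and the choice coincides with
#' [mfe_step()]. When a candidate's restricted classifier misclassifies
#' training points, that candidate is scored by the negated total hinge
#' violation at the decision boundary, `-sum(max(0, -y_i s_S(x_i)))`, so the
#' removal that least violates the training labels is preferred; any
#' separable candidate dominates every non-separable one.
#'
#' @inheritParams mfe_step
#' @return The feature name to remove (attributes as in [mfe_step()], plus
#'   `"criterion"`).
#' @export
mfe_slack_step <- function(model, x, y, active = model$active) {
  assert_that(length(active) >= 2, "need at least two active features")
  stats <- restricted_removal_stats(model, x, y, active = active)
  ok <- !is.na(stats$margin)
  if (!any(ok)) abort("every candidate removal zeroes the weight vector")
  crit <- ifelse(stats$separable, stats$margin, -stats$violation)
  crit[!ok] <- -Inf
  j <- which.max(crit)
  structure(stats$feature[j], index = j, margin = stats$margin[j],
            criterion = crit[j])
}

#' Backward feature elimination with elimination trace
#'
#' Starting from a classifier trained on all features, removes one feature
#' per step -- by RFE (smallest weight), MFE (largest restricted margin), or
#' the MFE / MFE-slack hybrid (margin criterion while the restricted set is
#' separable, slack criterion otherwise) -- retraining the classifier every
#' `retrain_every` removals. At each retrain point an out-of-bootstrap
#' misclassification estimate of the current feature subset can be recorded
#' for the stopping rule.
#'
#' @param x,y Training matrix and labels.
#' @param method `"mfe"`, `"rfe"` or `"mfe_hybrid"`.
#' @param C Regularization constant for the retrained classifiers.
#' @param retrain_every Retrain after this many removals (default: 10% of the
#'   starting feature count).
#' @param n_bootstrap Out-of-bootstrap resamples for the validation-error
#'   estimates recorded at retrain points; 0 disables them.
#' @param min_features Stop eliminating when this many features remain.
#' @param seed Integer seed (bootstrap resampling).
#' @param positive Passed to [train_margin_model()].
#' @return An `elimination_trace`: tibble with columns `step` (0 = before any
#'   removal), `feature` (removed), `margin` (post-removal restricted margin),
#'   `val_error`, `retrained`; attributes `initial_features`, `final_model`,
#'   `method`.
#' @export
run_elimination <- function(x, y, method = c("mfe", "rfe", "mfe_hybrid"),
                            C = 1, retrain_every = NULL, n_bootstrap = 0,
                            min_features = 1, seed = 1, positive = NULL) {
  method <- match.arg(method)
  if (is.null(colnames(x))) colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
  p0 <- ncol(x)
  if (is.null(retrain_every)) retrain_every <- max(1L, ceiling(0.1 * p0))
  set.seed(seed)
  active <- colnames(x)
  model <- train_margin_model(x, y, C = C, positive = positive)
  oob_error <- function(feats) {
    if (n_bootstrap <= 0) return(NA_real_)
    errs <- vapply(seq_len(n_bootstrap), function(b) {
      idx <- unlist(lapply(split(seq_len(nrow(x)), as.character(y)),
                           function(ii) sample(ii, length(ii), replace = TRUE)),
                    use.names = FALSE)
      oob <- setdiff(seq_len(nrow(x)), unique(idx))
      if (length(oob) == 0) return(NA_real_)
      m <- train_margin_model(x[idx, feats, drop = FALSE], y[idx], C = C,
                              positive = positive)
      pred <- ifelse(signed_distance(m, x[oob, feats, drop = FALSE]) >= 0,
                     m$positive, m$negative)
      mean(pred != as.character(y)[oob])
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }
  rows <- list(tibble(step = 0L, feature = NA_character_,
                      margin = margin_of(model, x, y),
                      val_error = oob_error(active), retrained = TRUE))
  step <- 0L
  since_retrain <- 0L
  while (length(active) > min_features) {
    step <- step + 1L
    pick <- switch(method,
      rfe = rfe_step(model, active = active),
      mfe = mfe_step(model, x, y, active = active),
      mfe_hybrid = mfe_slack_step(model, x, y, active = active))
    removed <- as.character(pick)
    active <- setdiff(active, removed)
    rec_margin <- tryCatch(
      margin_of(model, x, y, subset = intersect(model$active, active)),
      error = function(e) NA_real_)
    since_retrain <- since_retrain + 1L
    retrain <- since_retrain >= retrain_every || length(active) <= min_features
    val <- NA_real_
    if (retrain) {
      model <- train_margin_model(x[, active, drop = FALSE], y, C = C,
                                  positive = positive)
      val <- oob_error(active)
      since_retrain <- 0L
    }
    rows[[length(rows) + 1]] <- tibble(step = step, feature = removed,
                                       margin = rec_margin, val_error = val,
                                       retrained = retrain)
  }
  trace <- bind_rows(rows)
  structure(trace,
            initial_features = colnames(x), final_model = model,
            method = method, C = C,
            class = c("elimination_trace", class(trace)))
}

#' Stopping point of an elimination trace
#'
#' Optionally smooths the recorded out-of-bootstrap validation errors
#' (centered moving average over the steps that carry estimates; the default
#' window of 1 leaves them as-is, since the out-of-bootstrap averaging is
#' itself a smoother) and stops at the smallest retained-set size -- i.e. the
#' latest step -- whose (smoothed) error is within `epsilon` of the minimum
#' over all steps. `epsilon = 0` gives the exact argmin with ties broken
#' toward fewer features. Test data are never consulted.
#'
#' @param trace An [run_elimination()] trace with `val_error` estimates.
#' @param epsilon Tolerance above the minimum smoothed validation error.
#' @param smooth_window Odd centered moving-average window (1 = none).
#' @return The stop step index (0 = keep all features), with the retained
#'   feature set in attribute `"retained"`.
#' @export
stop_point <- function(trace, epsilon = 0.01, smooth_window = 1) {
  assert_that(nrow(trace) > 0, "empty elimination trace")
  est <- which(!is.na(trace$val_error))
  assert_that(length(est) > 0, "trace carries no validation estimates")
  v <- trace$val_error[est]
  half <- (smooth_window - 1) %/% 2
  sm <- vapply(seq_along(v), function(i) {
    win <- max(1, i - half):min(length(v), i + half)
    mean(v[win])
  }, numeric(1))
  eligible <- est[sm <= min(sm) + epsilon]
  stop_step <- trace$step[max(eligible)]
  init <- attr(trace, "initial_features")
  removed <- trace$feature[!is.na(trace$feature) & trace$step <= stop_step]
  structure(stop_step, retained = setdiff(init, removed))
}

#' Retained feature set at a given step of a trace
#'
#' @param trace An `elimination_trace`.
#' @param step Step index (default: the last step).
#' @return Character vector of retained feature names.
#' @export
retained_at <- function(trace, step = max(trace$step)) {
  init <- attr(trace, "initial_features")
  removed <- trace$feature[!is.na(trace$feature) & trace$step <= step]
  setdiff(init, removed)
}
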