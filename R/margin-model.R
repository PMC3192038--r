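#' Train a soft-margin linear maximum-margin classifier
#'
#' Fits the standard soft-margin linear SVM (through libsvm, via e1071) and
#' stores the primal weight vector and bias in geometry-friendly form. The
#' orientation is normalized so that the `positive` class (by convention the
#' Control, or nonconverter-by-trajectory, class) has the larger mean training
#' score; the sign of `(w, b)` is flipped if needed. The signed distance of a
#' sample to the decision boundary is `s(x) = (w.x + b) / ||w||`; positive
#' scores are on the `positive` side.
#'
#' @param x Numeric matrix (rows = samples); columns should be preprocessed
#'   (age-adjusted, unit-scaled) the same way at train and test time.
#' @param y Factor or vector with exactly two distinct classes.
#' @param C Soft-margin regularization constant.
#' @param positive Class label assigned positive scores. Defaults to
#'   `"Control"`/`"NT"`/`"nonconverter"` when one is present, else the first
#'   level.
#' @return A `margin_model`: list with `w` (named), `b`, `C`, `positive`,
#'   `negative`, `active` (feature names), `margin` (minimum training signed
#'   distance), `train_ids`.
#' @export
train_margin_model <- function(x, y, C = 1, positive = NULL) {
  y <- as.character(y)
  classes <- unique(y)
  assert_that(length(classes) == 2, "exactly two classes required")
  assert_that(is.matrix(x) && ncol(x) >= 1, "x must be a matrix with features")
  if (is.null(positive)) {
    conv <- intersect(c("Control", "NT", "nonconverter"), classes)
    positive <- if (length(conv) > 0) conv[1] else classes[1]
  }
  assert_that(positive %in% classes, "positive must be one of the classes")
  negative <- setdiff(classes, positive)
  if (is.null(colnames(x))) colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
  yf <- factor(y, levels = c(positive, negative))
  fit <- e1071::svm(x, yf, kernel = "linear", cost = C, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  assert_that(sqrt(sum(w^2)) > 0, "degenerate SVM solution: zero weight vector")
  scores <- (x %*% w + b) / sqrt(sum(w^2))
  if (mean(scores[y == positive]) < mean(scores[y == negative])) {
    w <- -w; b <- -b; scores <- -scores
  }
  ysign <- ifelse(y == positive, 1, -1)
  model <- structure(
    list(w = setNames(as.numeric(w), colnames(x)), b = b, C = C,
         positive = positive, negative = negative,
         active = colnames(x),
         margin = min(ysign * scores),
         train_ids = rownames(x) %||% NULL),
    class = "margin_model"
  )
  model
}

#' @export
print.margin_model <- function(x, ...) {
  cat("<margin_model> ", length(x$active), " features, C = ", x$C,
      ", training margin = ", signif(x$margin, 4),
      "\n  positive (", x$positive, ") scores > 0; negative (", x$negative,
      ") scores < 0\n", sep = "")
  invisible(x)
}

#' Signed distance to the decision boundary
#'
#' Computes `s(x) = (w.x + b) / ||w||` for each row of `x`. Positive scores
#' lie on the model's positive-convention (Control / NT) side; the magnitude
#' is the Euclidean distance to the separating hyperplane.
#'
#' @param model A [train_margin_model()] fit.
#' @param x Matrix (or vector) over the model's active features; extra
#'   columns are ignored by name, missing ones are an error.
#' @return Numeric vector of signed distances.
#' @export
signed_distance <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1,
                                   dimnames = list(NULL, names(model$w)))
  if (!is.null(colnames(x))) {
    assert_that(all(names(model$w) %in% colnames(x)),
                "x lacks some of the model's active features")
    x <- x[, names(model$w), drop = FALSE]
  } else {
    assert_that(ncol(x) == length(model$w),
                "dimension mismatch with the model's active feature set")
  }
  drop((x %*% model$w + model$b) / sqrt(sum(model$w^2)))
}

# +1/-1 encoding of labels relative to the model's positive convention
class_signs <- function(model, y) {
  y <- as.character(y)
  assert_that(all(y %in% c(model$positive, model$negative)),
              "labels must match the model's two classes")
  ifelse(y == model$positive, 1, -1)
}

#' Margin of a classifier restricted to a feature subset
#'
#' Zeroes the weight vector outside `subset`, re-centers the bias by the
#' margin-maximal 1-D rule (the midpoint of the two class-extreme restricted
#' projections), and returns the minimum signed distance over the training
#' points: `min_i y_i (w_S . x_i + b_S) / ||w_S||`. Negative when the
#' restricted projection no longer separates the classes.
#'
#' @param model A [train_margin_model()] fit.
#' @param x,y Training matrix and labels.
#' @param subset Character vector of retained feature names (default: the
#'   full active set).
#' @return The restricted margin (scalar, possibly negative).
#' @export
margin_of <- function(model, x, y, subset = model$active) {
  assert_that(all(subset %in% model$active), "subset must lie in the active set")
  w_s <- model$w
  w_s[!(names(w_s) %in% subset)] <- 0
  nrm <- sqrt(sum(w_s^2))
  if (nrm == 0) abort("restricted weight vector is zero on this subset")
  ysign <- class_signs(model, y)
  proj <- drop(x[, names(model$w), drop = FALSE] %*% w_s)
  b_s <- -(min(proj[ysign > 0]) + max(proj[ysign < 0])) / 2
  min(ysign * (proj + b_s)) / nrm
}

# Vectorized single-feature-removal criteria for elimination. For each
# candidate feature j in `active`, evaluates the classifier restricted to
# active \ {j} (weights zeroed outside): restricted margin (midpoint bias
# rule), separability, and total hinge violation at the boundary. One matrix
# op per class extreme; used by mfe_step / mfe_slack_step.
restricted_removal_stats <- function(model, x, y, active = model$active) {
  ysign <- class_signs(model, y)
  # zeroing weights outside `active` is equivalent to dropping those columns
  w <- model$w[names(model$w) %in% active]
  xm <- x[, names(w), drop = FALSE]
  proj_full <- drop(xm %*% w)
  # candidate j: proj_j = proj_full - x_j * w_j   (n x p)
  pmat <- proj_full - sweep(xm, 2, w, "*")
  norm2 <- sum(w^2) - w^2
  pos <- ysign > 0
  min_pos <- apply(pmat[pos, , drop = FALSE], 2, min)
  max_neg <- apply(pmat[!pos, , drop = FALSE], 2, max)
  b_s <- -(min_pos + max_neg) / 2
  smat <- sweep(pmat, 2, b_s, "+") * ysign    # y_i * (proj + b_S), n x p
  raw_margin <- apply(smat, 2, min)
  nrm <- sqrt(pmax(norm2, 0))
  margin <- ifelse(nrm > 0, raw_margin / nrm, NA_real_)
  violation <- colSums(pmax(-smat, 0)) / ifelse(nrm > 0, nrm, 1)  # pmax keeps dims of its first arg
  tibble(feature = names(w), norm = as.numeric(nrm),
         margin = as.numeric(margin),
         separable = !is.na(margin) & margin > 0,
         violation = as.numeric(ifelse(nrm > 0, violation, NA_real_)))
}

#' Select the regularization constant by bootstrap validation
#'
#' For each candidate `C`, trains on bootstrap resamples (drawn within class,
#' with replacement) and averages the misclassification rate on the
#' out-of-bootstrap samples; returns the `C` with the smallest average error,
#' breaking ties toward the smallest `C`.
#'
#' @param x,y Training matrix and labels.
#' @param c_grid Candidate values (default `2^(-5:5)`).
#' @param n_bootstrap Number of resamples.
#' @param seed Integer seed making the resamples reproducible.
#' @param positive Passed to [train_margin_model()].
#' @return The selected `C`, with the per-`C` error table in attribute
#'   `"oob"`.
#' @export
select_C <- function(x, y, c_grid = 2^(-5:5), n_bootstrap = 30, seed = 1,
                     positive = NULL) {
  assert_that(length(c_grid) >= 1, "C grid must be non-empty")
  c_grid <- sort(c_grid)
  y <- as.character(y)
  set.seed(seed)
  errs <- matrix(NA_real_, n_bootstrap, length(c_grid))
  n <- nrow(x)
  for (b in seq_len(n_bootstrap)) {
    idx <- unlist(lapply(split(seq_len(n), y), function(ii)
      sample(ii, length(ii), replace = TRUE)), use.names = FALSE)
    oob <- setdiff(seq_len(n), unique(idx))
    if (length(oob) == 0 || length(unique(y[oob])) == 0) next
    for (ci in seq_along(c_grid)) {
      m <- train_margin_model(x[idx, , drop = FALSE], y[idx],
                              C = c_grid[ci], positive = positive)
      pred <- ifelse(signed_distance(m, x[oob, , drop = FALSE]) >= 0,
                     m$positive, m$negative)
      errs[b, ci] <- mean(pred != y[oob])
    }
  }
  mean_err <- colMeans(errs, na.rm = TRUE)
  best <- c_grid[which.min(mean_err)]  # which.min takes first = smallest C
  structure(best, oob = tibble(C = c_grid, oob_error = mean_err))
}

#' Serialize a margin model to JSON / read it back
#'
#' Stores the weight vector, bias, regularization constant, active feature
#' set, orientation convention and training ids in a plain-text JSON file;
#' `read_margin_model()` reconstructs an equivalent model.
#'
#' @param model A [train_margin_model()] fit.
#' @param path JSON file path.
#' @return `write_margin_model()` the path (invisibly); `read_margin_model()`
#'   a `margin_model`.
#' @export
write_margin_model <- function(model, path) {
  jsonlite::write_json(
    list(w = as.list(model$w), b = model$b, C = model$C,
         positive = model$positive, negative = model$negative,
         active = model$active, margin = model$margin,
         train_ids = model$train_ids),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_margin_model
#' @export
read_margin_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(w = unlist(raw$w), b = raw$b, C = raw$C, positive = raw$positive,
         negative = raw$negative, active = raw$active, margin = raw$margin,
         train_ids = raw$train_ids),
    class = "margin_model"
  )
}
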