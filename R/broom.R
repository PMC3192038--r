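#' Tidy a margin model
#'
#' @param x A [train_margin_model()] fit.
#' @param ... Unused.
#' @return Tibble with one row per active feature: `feature`, `weight`,
#'   `abs_weight`.
#' @export
tidy.margin_model <- function(x, ...) {
  tibble(feature = names(x$w), weight = as.numeric(x$w),
         abs_weight = abs(as.numeric(x$w)))
}

#' @rdname tidy.margin_model
#' @return `glance()`: one-row tibble with `n_features`, `C`, `margin`,
#'   `positive`, `negative`.
#' @export
glance.margin_model <- function(x, ...) {
  tibble(n_features = length(x$active), C = x$C, margin = x$margin,
         positive = x$positive, negative = x$negative)
}

#' Tidy an elimination trace
#'
#' @param x An [run_elimination()] trace.
#' @param ... Unused.
#' @return The trace as a plain tibble with a `n_retained` column added.
#' @export
tidy.elimination_trace <- function(x, ...) {
  p0 <- length(attr(x, "initial_features"))
  as_tibble(x) %>% mutate(n_retained = p0 - .data$step)
}

#' @rdname tidy.elimination_trace
#' @param epsilon Stopping tolerance passed to [stop_point()] when the trace
#'   carries validation estimates.
#' @return `glance()`: one-row tibble with `method`, `n_initial`, `n_steps`,
#'   and (when estimates exist) `stop_step` and `n_retained_at_stop`.
#' @export
glance.elimination_trace <- function(x, epsilon = 0.01, ...) {
  out <- tibble(method = attr(x, "method"),
                n_initial = length(attr(x, "initial_features")),
                n_steps = max(x$step))
  if (any(!is.na(x$val_error))) {
    sp <- stop_point(x, epsilon = epsilon)
    out$stop_step <- as.integer(sp)
    out$n_retained_at_stop <- length(attr(sp, "retained"))
  }
  out
}

#' Tidy / summarize a two-stage pipeline result
#'
#' @param x A [run_two_stage()] result.
#' @param ... Unused.
#' @return `tidy()`: the per-trial accuracy tibble. `glance()`: the
#'   across-trial summary (mean and SD of overall accuracy per definition).
#' @export
tidy.two_stage_result <- function(x, ...) x$trials

#' @rdname tidy.two_stage_result
#' @export
glance.two_stage_result <- function(x, ...) x$summary
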