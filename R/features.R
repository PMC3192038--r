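#' Feature-space tables
#'
#' A feature space maps each feature index to a tissue class (`GM`, `WM` or
#' `ventricle`), a 0-based voxel coordinate on the acquisition grid, and an
#' integer atlas region label (0 = background). It is stored as a tibble with
#' columns `feature`, `tissue`, `x`, `y`, `z`, `region` and attributes `step`,
#' `offset` (the subsampling stride and phase) and `grid_shape`.
#'
#' @param df Tibble with columns `feature`, `tissue`, `x`, `y`, `z`, `region`.
#' @param step Subsampling stride (keep one voxel in every `step` per axis).
#' @param offset Integer 3-vector in `[0, step)^3`, the subsample phase.
#' @param grid_shape Integer 3-vector, full grid dimensions.
#' @return A `feature_space` tibble.
#' @export
feature_space <- function(df, step = 1L, offset = c(0L, 0L, 0L), grid_shape) {
  need <- c("feature", "tissue", "x", "y", "z", "region")
  assert_that(all(need %in% names(df)),
              paste("feature space needs columns:", paste(need, collapse = ", ")))
  assert_that(all(df$x >= 0 & df$x < grid_shape[1]) &&
                all(df$y >= 0 & df$y < grid_shape[2]) &&
                all(df$z >= 0 & df$z < grid_shape[3]),
              "feature coordinates must lie within grid_shape")
  structure(as_tibble(df), step = as.integer(step),
            offset = as.integer(offset), grid_shape = as.integer(grid_shape),
            class = c("feature_space", class(as_tibble(df))))
}

write_feature_space <- function(space, path) {
  jsonlite::write_json(
    list(step = attr(space, "step"), offset = attr(space, "offset"),
         grid_shape = attr(space, "grid_shape"),
         table = as.data.frame(space)),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  invisible(path)
}

read_feature_space <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- as_tibble(raw$table)
  tab$x <- as.integer(tab$x); tab$y <- as.integer(tab$y)
  tab$z <- as.integer(tab$z); tab$region <- as.integer(tab$region)
  feature_space(tab, step = raw$step, offset = raw$offset,
                grid_shape = raw$grid_shape)
}

#' Grid-subsample a volumetric map
#'
#' Reduces a 3D tissue-density map to the voxels at coordinates
#' `offset + step * k` along each axis (0-based, row-major order), i.e. keeps
#' one voxel and skips `step - 1` along each dimension. A stride of 6
#' ("skip five") yields 216 distinct offsets; a stride of 3 ("skip two")
#' yields 27. The union of the subsamples over all `step^3` offsets
#' partitions the full grid.
#'
#' @param volume 3D numeric array.
#' @param step Stride, integer >= 1.
#' @param offset Integer 3-vector with components in `[0, step)`.
#' @param tissue Tissue tag recorded in the returned feature space fragment.
#' @param atlas Optional integer-labeled 3D array (same shape) giving each
#'   voxel's region; defaults to 0 (background) everywhere.
#' @return List with `values` (named feature vector) and `space`
#'   (a [feature_space()] fragment for the kept voxels).
#' @export
#' @examples
#' vol <- array(seq_len(27), c(3, 3, 3))
#' subsample_grid(vol, step = 3, offset = c(1, 1, 1))$values
subsample_grid <- function(volume, step, offset = c(0L, 0L, 0L),
                           tissue = "GM", atlas = NULL) {
  dims <- dim(volume)
  assert_that(length(dims) == 3, "volume must be a 3D array")
  step <- as.integer(step)
  offset <- as.integer(offset)
  assert_that(step >= 1, "step must be >= 1")
  assert_that(length(offset) == 3 && all(offset >= 0) && all(offset < step),
              "offset components must lie in [0, step)")
  axis_idx <- function(o, d) if (o > d - 1L) integer(0) else seq(o, d - 1L, by = step)
  ix <- axis_idx(offset[1], dims[1])
  iy <- axis_idx(offset[2], dims[2])
  iz <- axis_idx(offset[3], dims[3])
  assert_that(length(ix) > 0 && length(iy) > 0 && length(iz) > 0,
              "subsample is empty for this step/offset/volume")
  # row-major order over kept coordinates: x fastest, matching R array layout
  grid <- expand.grid(x = ix, y = iy, z = iz)
  vals <- volume[cbind(grid$x + 1L, grid$y + 1L, grid$z + 1L)]
  regions <- if (is.null(atlas)) rep(0L, nrow(grid)) else
    as.integer(atlas[cbind(grid$x + 1L, grid$y + 1L, grid$z + 1L)])
  nm <- sprintf("%s_%03d_%03d_%03d", tissue, grid$x, grid$y, grid$z)
  space <- feature_space(
    tibble(feature = nm, tissue = tissue, x = as.integer(grid$x),
           y = as.integer(grid$y), z = as.integer(grid$z), region = regions),
    step = step, offset = offset, grid_shape = dims
  )
  list(values = setNames(vals, nm), space = space)
}

#' All subsample offsets for a stride
#'
#' @param step Stride; there are `step^3` offsets.
#' @return Tibble with columns `ox`, `oy`, `oz`, one row per offset.
#' @export
subsample_offsets <- function(step) {
  step <- as.integer(step)
  g <- expand.grid(ox = 0:(step - 1), oy = 0:(step - 1), oz = 0:(step - 1))
  as_tibble(g[order(g$oz, g$oy, g$ox), , drop = FALSE])
}

#' Assemble the union feature vector from per-tissue subsamples
#'
#' Concatenates gray-matter, white-matter and ventricle subsamples (in that
#' order) produced by [subsample_grid()] at the same step and offset, keeping
#' the tissue tags in the combined feature space.
#'
#' @param gm,wm,vent Results of [subsample_grid()] for the three tissue maps;
#'   `vent` (or `wm`) may be `NULL`/empty, with a warning.
#' @return List with `values` and `space` as in [subsample_grid()].
#' @export
assemble_features <- function(gm, wm = NULL, vent = NULL) {
  parts <- list(gm, wm, vent)
  parts <- parts[!vapply(parts, is.null, TRUE)]
  assert_that(length(parts) >= 1, "at least one tissue subsample required")
  if (length(parts) < 3)
    warn("fewer than three tissue maps supplied; feature set is their union")
  steps <- vapply(parts, function(p) attr(p$space, "step"), 1L)
  offs <- vapply(parts, function(p) paste(attr(p$space, "offset"),
                                          collapse = ","), "")
  assert_that(length(unique(steps)) == 1 && length(unique(offs)) == 1,
              "tissue subsamples must share step and offset")
  values <- do.call(c, lapply(parts, `[[`, "values"))
  tab <- bind_rows(lapply(parts, function(p) as_tibble(p$space)))
  assert_that(!anyDuplicated(tab$feature),
              "duplicate feature names across tissue fragments")
  space <- feature_space(tab, step = steps[1],
                         offset = attr(parts[[1]]$space, "offset"),
                         grid_shape = attr(parts[[1]]$space, "grid_shape"))
  list(values = values, space = space)
}

#' Per-feature [0,1] scaling learned on a training set
#'
#' `fit_unit_scaling()` records the per-feature training minimum and maximum;
#' `apply_scaling()` maps any matrix through the training affine map
#' `(x - min) / (max - min)`. Training values land in `[0,1]`; test values may
#' fall outside (no clipping, preserving the affine geometry the linear
#' classifier relies on). Constant features map to 0.
#'
#' @param x Numeric matrix, rows = samples.
#' @param params A `scaling_params` from `fit_unit_scaling()`.
#' @return `fit_unit_scaling()`: a `scaling_params` tibble (`feature`, `min`,
#'   `max`); `apply_scaling()`: the rescaled matrix.
#' @export
fit_unit_scaling <- function(x) {
  assert_that(is.matrix(x) && nrow(x) >= 1, "training matrix must be non-empty")
  structure(
    tibble(feature = colnames(x) %||% as.character(seq_len(ncol(x))),
           min = apply(x, 2, min), max = apply(x, 2, max)),
    class = c("scaling_params", class(tibble())))
}

#' @rdname fit_unit_scaling
#' @export
apply_scaling <- function(params, x) {
  assert_that(ncol(x) == nrow(params), "feature count mismatch with scaling")
  rng <- params$max - params$min
  out <- sweep(x, 2, params$min, "-")
  const <- rng <= 0
  rng[const] <- 1
  out <- sweep(out, 2, rng, "/")
  out[, const] <- 0
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-feature linear age adjustment fit on control-class samples
#'
#' `fit_age_model()` fits, for every feature, an ordinary least-squares line
#' of feature value versus age using only the designated control-class
#' samples (Controls for the AD-Control classifier; NT subjects for the CT-NT
#' classifier). `apply_age_adjust()` subtracts the line, extrapolated at each
#' sample's age, from all samples, removing the normal-aging trend while
#' leaving age-orthogonal group structure intact.
#'
#' @param x Numeric matrix, rows = samples.
#' @param ages Numeric vector of ages, one per row.
#' @param control_mask Logical vector marking the samples the line is fit on.
#' @param model An `age_model` from `fit_age_model()`.
#' @return `fit_age_model()`: an `age_model` tibble (`feature`, `intercept`,
#'   `slope`); `apply_age_adjust()`: the adjusted matrix.
#' @export
fit_age_model <- function(x, ages, control_mask) {
  assert_that(length(ages) == nrow(x) && length(control_mask) == nrow(x),
              "ages and control_mask must match rows of x")
  a <- ages[control_mask]
  assert_that(length(unique(a)) >= 2,
              "need >= 2 distinct control ages to fit the age model")
  xa <- x[control_mask, , drop = FALSE]
  am <- mean(a)
  sxx <- sum((a - am)^2)
  slope <- as.numeric(colSums((a - am) * xa) / sxx)
  intercept <- as.numeric(colMeans(xa)) - slope * am
  structure(
    tibble(feature = colnames(x) %||% as.character(seq_len(ncol(x))),
           intercept = intercept, slope = slope),
    class = c("age_model", class(tibble())))
}

#' @rdname fit_age_model
#' @export
apply_age_adjust <- function(model, x, ages) {
  assert_that(ncol(x) == nrow(model), "feature count mismatch with age model")
  assert_that(length(ages) == nrow(x), "one age per row required")
  x - outer(rep(1, nrow(x)), model$intercept) - outer(ages, model$slope)
}

#' Age-match two groups by maximum bipartite matching
#'
#' Pairs each sample in group A with at most one sample in group B such that
#' every pair differs in age by at most `tolerance_years`, and the number of
#' pairs is the maximum achievable (maximum matching on the compatibility
#' graph). Used to balance classes before classifier training.
#'
#' @param group_a,group_b Data frames with columns `id` and `age`.
#' @param tolerance_years Maximum allowed within-pair age separation.
#' @return Tibble with columns `id_a`, `id_b`, `age_a`, `age_b`; zero rows if
#'   no compatible pair exists.
#' @export
#' @examples
#' age_match(data.frame(id = "a", age = 70), data.frame(id = "b", age = 70.5))
age_match <- function(group_a, group_b, tolerance_years = 1.0) {
  assert_that(nrow(group_a) > 0 && nrow(group_b) > 0,
              "both groups must be non-empty")
  na <- nrow(group_a); nb <- nrow(group_b)
  comp <- which(abs(outer(group_a$age, group_b$age, "-")) <= tolerance_years,
                arr.ind = TRUE)
  if (nrow(comp) == 0)
    return(tibble(id_a = group_a$id[0], id_b = group_b$id[0],
                  age_a = numeric(0), age_b = numeric(0)))
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, na), rep(TRUE, nb)),
    edges = as.vector(t(cbind(comp[, 1], na + comp[, 2])))
  )
  m <- igraph::max_bipartite_match(g)$matching
  ia <- which(!is.na(m[seq_len(na)]))
  ib <- m[ia] - na
  tibble(id_a = group_a$id[ia], id_b = group_b$id[ib],
         age_a = group_a$age[ia], age_b = group_b$age[ib])
}

#' Fit and apply the standard pre-classifier preprocessing
#'
#' The preprocessing applied before every classifier training: per-feature
#' age adjustment (line fit on the control-convention samples,
#' [fit_age_model()]) followed by `[0,1]` scaling learned on the training
#' rows ([fit_unit_scaling()]). `apply_preprocess()` maps any new scans --
#' e.g. the MCI visits scored by a [train_ad_control()] fit -- through the
#' same transforms.
#'
#' @param x_train Training matrix (rows = scans).
#' @param ages_train Ages for the training rows.
#' @param control_mask Logical; the rows the age lines are fit on.
#' @param params A `preprocess_params` from `fit_preprocess()`.
#' @param x,ages Matrix and ages to transform.
#' @return `fit_preprocess()`: a `preprocess_params` list (`age_model`,
#'   `scaling`); `apply_preprocess()`: the transformed matrix.
#' @export
fit_preprocess <- function(x_train, ages_train, control_mask) {
  age_model <- fit_age_model(x_train, ages_train, control_mask)
  adj <- apply_age_adjust(age_model, x_train, ages_train)
  scaling <- fit_unit_scaling(adj)
  structure(list(age_model = age_model, scaling = scaling),
            class = "preprocess_params")
}

#' @rdname fit_preprocess
#' @export
apply_preprocess <- function(params, x, ages) {
  apply_scaling(params$scaling,
                apply_age_adjust(params$age_model, x, ages))
}
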