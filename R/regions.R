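#' Union of retained feature sets over elimination trials
#'
#' Robustness device: the final retained voxel set is the union of the
#' retained sets from several independent feature-elimination trials (each
#' run on a different random training subset). A single trial returns its own
#' set unchanged.
#'
#' @param retained_sets List of character vectors of feature names, all drawn
#'   from the same feature space.
#' @param space Optional [feature_space()] to validate the names against.
#' @return Character vector, the union.
#' @export
union_over_trials <- function(retained_sets, space = NULL) {
  assert_that(length(retained_sets) >= 1, "need at least one retained set")
  out <- unique(unlist(retained_sets, use.names = FALSE))
  if (!is.null(space))
    assert_that(all(out %in% space$feature),
                "retained features not present in the feature space")
  out
}

#' Per-region retained-voxel fractions
#'
#' For every atlas region, computes the fraction of the region's features (in
#' the subsampled feature space -- the set the classifier could have
#' retained) that survive elimination. Background (region 0) is excluded.
#'
#' @param retained Character vector of retained feature names.
#' @param space A [feature_space()] covering all retained features.
#' @return A `region_report` tibble with columns `region`, `n_features`,
#'   `n_retained`, `fraction`, sorted by fraction descending then region.
#' @export
region_retention <- function(retained, space) {
  assert_that(all(retained %in% space$feature),
              "every retained feature must have a feature-space entry")
  tab <- space %>%
    as_tibble() %>%
    filter(.data$region != 0) %>%
    group_by(.data$region) %>%
    summarise(n_features = n(),
              n_retained = sum(.data$feature %in% retained),
              .groups = "drop") %>%
    mutate(fraction = .data$n_retained / .data$n_features) %>%
    arrange(dplyr::desc(.data$fraction), .data$region)
  structure(tab, class = c("region_report", class(tab)))
}

#' Select biomarker regions by retained-fraction threshold
#'
#' Keeps the regions whose retained fraction is at least `threshold`
#' (inclusive), sorted by fraction descending then region label. The 0.125
#' default is the knee read off the sorted retained-percentage curve of the
#' AD-Control diagnostic case; [find_knee()] offers an automatic alternative.
#'
#' @param report A [region_retention()] report (or tibble with `region` and
#'   `fraction`).
#' @param threshold Minimum retained fraction.
#' @return Tibble of selected rows of `report`.
#' @export
select_regions <- function(report, threshold = 0.125) {
  report %>%
    filter(.data$fraction >= threshold) %>%
    arrange(dplyr::desc(.data$fraction), .data$region)
}

#' Knee of the sorted retained-fraction curve
#'
#' Locates the point of maximum discrete curvature (second difference) of the
#' descending sorted fraction curve -- an automated stand-in for reading the
#' knee off the plot by eye.
#'
#' @param report A [region_retention()] report.
#' @return The fraction at the knee, usable as a `threshold` for
#'   [select_regions()]; `NA` when fewer than 3 regions.
#' @export
find_knee <- function(report) {
  f <- sort(report$fraction, decreasing = TRUE)
  if (length(f) < 3) return(NA_real_)
  curv <- diff(diff(f))
  f[which.max(curv) + 1L]
}

#' Export retained voxels as a NIfTI overlay in atlas space
#'
#' Writes a volume (same grid as the feature space) whose retained-feature
#' voxels carry their atlas region label and all other voxels are 0, for
#' overlay on a registered atlas. Requires RNifti.
#'
#' @param retained Character vector of retained feature names.
#' @param space A [feature_space()] covering them.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return The path, invisibly.
#' @export
write_overlay_mask <- function(retained, space, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    abort("overlay export requires the RNifti package")
  assert_that(all(retained %in% space$feature),
              "retained features must belong to the feature space")
  gs <- attr(space, "grid_shape")
  vol <- array(0L, dim = gs)
  sel <- space$feature %in% retained
  vol[cbind(space$x[sel] + 1L, space$y[sel] + 1L, space$z[sel] + 1L)] <-
    space$region[sel]
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}
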