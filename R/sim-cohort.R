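#' Configuration for the synthetic longitudinal cohort simulator
#'
#' Bundles and validates every knob of [simulate_cohort()]. Defaults describe a
#' cohort of the size and composition typical of large longitudinal aging
#' studies (180 controls, 300 MCI, 120 AD followed at six-month intervals for
#' up to six visits), with a standardized AD-vs-Control separation of 1.2 on
#' the informative features.
#'
#' @param n_control,n_ad,n_mci Number of Control / AD / MCI subjects.
#' @param n_features Number of voxel features per scan.
#' @param n_regions Number of (non-background) atlas regions.
#' @param grid_shape Integer 3-vector, the voxel grid the features live on;
#'   `prod(grid_shape)` must be at least `n_features`.
#' @param visits_per_subject Nominal number of visits (1--6).
#' @param visit_interval Years between nominal visits.
#' @param age_range Length-2 numeric, baseline age range in years.
#' @param effect_size_d Standardized AD-minus-Control mean separation on each
#'   informative feature (in units of `noise_sd`).
#' @param informative_fraction Fraction of features carrying group signal.
#' @param age_slope_sd SD of the per-feature linear age trend (units/year).
#' @param noise_sd Per-feature residual SD (total, between-subject).
#' @param subject_effect_fraction Fraction of the residual variance that is a
#'   stable per-subject offset (anatomical individuality, constant across a
#'   subject's visits); the remainder is independent per-visit scan noise.
#'   The default of 0 makes visit residuals independent, so that with no
#'   planted group effect the derived conversion labels carry no structure a
#'   baseline classifier could learn; raise it to emulate the stable
#'   test-retest anatomy of real morphometric data.
#' @param converter_fraction Fraction of MCI subjects whose latent score
#'   trajectory is planted to be on the AD side by visit 6.
#' @param missing_visit_prob Probability that a non-baseline visit is missing.
#' @param cdr_miss_rate Probability that a planted converter shows no CDR
#'   rise over its visits (clinically silent physiological conversion; the
#'   dominant direction of trajectory/CDR disagreement).
#' @param cdr_false_rate Probability that a planted nonconverter shows a
#'   spurious CDR rise; kept small so converters-by-CDR stay scarce.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#'
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_control = 10, n_ad = 10, n_mci = 10, seed = 1)
sim_config <- function(n_control = 180, n_ad = 120, n_mci = 300,
                       n_features = 100, n_regions = 8,
                       grid_shape = c(6L, 6L, 6L),
                       visits_per_subject = 6L, visit_interval = 0.5,
                       age_range = c(55, 90),
                       effect_size_d = 1.2, informative_fraction = 0.1,
                       age_slope_sd = 0.02, noise_sd = 1,
                       subject_effect_fraction = 0,
                       converter_fraction = 0.5, missing_visit_prob = 0.1,
                       cdr_miss_rate = 0.65, cdr_false_rate = 0.08,
                       seed = 1L) {
  cfg <- list(
    n_control = as.integer(n_control), n_ad = as.integer(n_ad),
    n_mci = as.integer(n_mci), n_features = as.integer(n_features),
    n_regions = as.integer(n_regions), grid_shape = as.integer(grid_shape),
    visits_per_subject = as.integer(visits_per_subject),
    visit_interval = visit_interval, age_range = as.numeric(age_range),
    effect_size_d = effect_size_d,
    informative_fraction = informative_fraction,
    age_slope_sd = age_slope_sd, noise_sd = noise_sd,
    subject_effect_fraction = subject_effect_fraction,
    converter_fraction = converter_fraction,
    missing_visit_prob = missing_visit_prob,
    cdr_miss_rate = cdr_miss_rate, cdr_false_rate = cdr_false_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  assert_that(cfg$n_control >= 0 && cfg$n_ad >= 0 && cfg$n_mci >= 0,
              "subject counts must be non-negative")
  assert_that(cfg$n_features >= 1 && cfg$n_regions >= 1,
              "n_features and n_regions must be positive")
  assert_that(length(cfg$grid_shape) == 3 && all(cfg$grid_shape >= 1),
              "grid_shape must be 3 positive integers")
  assert_that(prod(cfg$grid_shape) >= cfg$n_features,
              "grid_shape product must be >= n_features")
  assert_that(cfg$visits_per_subject >= 1 && cfg$visits_per_subject <= 6,
              "visits_per_subject must be in 1..6")
  probs <- c(cfg$informative_fraction, cfg$converter_fraction,
             cfg$missing_visit_prob, cfg$cdr_miss_rate, cfg$cdr_false_rate,
             cfg$subject_effect_fraction)
  assert_that(all(probs >= 0 & probs <= 1), "probabilities must be in [0,1]")
  assert_that(cfg$visit_interval > 0 && cfg$noise_sd >= 0 &&
                cfg$age_slope_sd >= 0,
              "visit_interval must be positive; SDs non-negative")
  assert_that(diff(cfg$age_range) > 0, "age_range must be increasing")
  if (cfg$converter_fraction > 0 && cfg$n_mci == 0)
    abort("impossible config: converter_fraction > 0 with n_mci = 0")
  invisible(cfg)
}

# Latent disease coordinate: +1 = Control prototype, -1 = AD prototype, 0 = the
# AD-Control decision boundary. MCI subjects carry a line in age; a planted
# converter is a subject whose line is below 0 at nominal visit 6.
draw_latent_lines <- function(n_mci, converter_fraction, visits, interval) {
  n_conv <- round(n_mci * converter_fraction)
  converter <- rep(c(TRUE, FALSE), c(n_conv, n_mci - n_conv))
  l1 <- ifelse(converter, runif(n_mci, -1.0, 0.4), runif(n_mci, 0.15, 1.2))
  l6 <- ifelse(converter, runif(n_mci, -1.2, -0.15), runif(n_mci, 0.15, 1.2))
  slope_per_visit <- (l6 - l1) / 5
  list(converter = converter, l1 = l1, l6 = l6,
       slope_per_visit = slope_per_visit)
}

#' Simulate a seeded longitudinal cohort with planted ground truth
#'
#' Generates per-visit voxel features and clinical metadata for Control, AD
#' and MCI subjects. Controls sit at a Control prototype, ADs are offset by
#' `effect_size_d` standard deviations on the informative features, and every
#' feature gains a linear age trend shared across groups. Each MCI subject
#' carries a latent scalar trajectory (a line in age, +1 = Control prototype,
#' -1 = AD prototype) that modulates the informative-feature means; the
#' subject is a planted converter exactly when that line is on the AD side
#' (below zero) at nominal visit 6. CDR courses, MMSE, CSF markers and a
#' hippocampal volume track the latent state with configurable noise, so
#' clinically defined and trajectory-defined conversion can disagree: a
#' `cdr_miss_rate` fraction of converters stay at CDR 0.5 throughout
#' (physiological change without clinical manifestation), while a small
#' `cdr_false_rate` fraction of nonconverters rise spuriously.
#'
#' @param config A [sim_config()].
#' @return A list with components
#'   \describe{
#'     \item{cohort}{`mci_cohort`: `meta` (one row per observed visit),
#'       `features` (matrix, rows aligned with `meta`), `space`
#'       (a feature-space tibble, see [feature_space()]), `config`.}
#'     \item{truth}{`planted_truth`: `subjects` (per-MCI latent line,
#'       converter flag, latent conversion visit), `informative` (logical mask
#'       over features), `trajectories` (latent score at every nominal visit).}
#'   }
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_control = 6, n_ad = 6, n_mci = 6,
#'                                   n_features = 20, seed = 42))
#' dplyr::count(sim$cohort$meta, group)
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  p <- config$n_features
  V <- config$visits_per_subject
  iv <- config$visit_interval

  n_info <- max(1L, round(p * config$informative_fraction))
  informative <- seq_len(p) <= n_info  # deterministic mask: first block
  feature_names <- sprintf("f%04d", seq_len(p))

  centers <- runif(p, 0.3, 0.7)
  # half-separation per informative feature; latent +1/-1 spans effect_size_d
  delta <- ifelse(informative, config$effect_size_d * config$noise_sd / 2, 0)
  age_slopes <- rnorm(p, 0, config$age_slope_sd)
  age_center <- mean(config$age_range)

  groups <- rep(c("Control", "AD", "MCI"),
                c(config$n_control, config$n_ad, config$n_mci))
  n_subj <- length(groups)
  subject_ids <- sprintf("S%04d", seq_len(n_subj))
  base_age <- runif(n_subj, config$age_range[1],
                    config$age_range[2] - (V - 1) * iv)

  mci_idx <- which(groups == "MCI")
  lat <- if (length(mci_idx) > 0)
    draw_latent_lines(length(mci_idx), config$converter_fraction, V, iv)
  else list(converter = logical(0), l1 = numeric(0), l6 = numeric(0),
            slope_per_visit = numeric(0))

  # latent value for any subject at nominal visit k
  latent_at <- function(i, k) {
    if (groups[i] == "Control") return(rep(1, length(k)))
    if (groups[i] == "AD") return(rep(-1, length(k)))
    j <- match(i, mci_idx)
    lat$l1[j] + lat$slope_per_visit[j] * (k - 1)
  }

  # visit schedule: baseline always observed, later visits drop out i.i.d.
  observed <- lapply(seq_len(n_subj), function(i) {
    keep <- c(TRUE, runif(V - 1) >= config$missing_visit_prob)
    which(keep)
  })

  # CDR courses
  cdr_course <- function(i) {
    k <- seq_len(V)
    if (groups[i] == "Control") return(rep(0, V))
    if (groups[i] == "AD") return(rep(1, V))
    j <- match(i, mci_idx)
    course <- rep(0.5, V)
    if (lat$converter[j]) {
      if (runif(1) >= config$cdr_miss_rate && V >= 2) {
        conv_k <- which(latent_at(i, k) < 0)[1]
        rise <- max(2L, ifelse(is.na(conv_k), V, conv_k))
        if (rise <= V) course[rise:V] <- 1
      }
    } else if (runif(1) < config$cdr_false_rate && V >= 2) {
      rise <- sample(2:V, 1)
      course[rise:V] <- 1
    }
    course
  }

  meta_rows <- list()
  feat_rows <- list()
  truth_traj <- list()
  for (i in seq_len(n_subj)) {
    ks <- observed[[i]]
    ages <- base_age[i] + (ks - 1) * iv
    lat_k <- latent_at(i, ks)
    cdr_i <- cdr_course(i)[ks]
    mmse <- round(pmin(30, pmax(0, 26.5 + 2 * lat_k + rnorm(length(ks), 0, 1))))
    l_end <- latent_at(i, V)
    tau <- 90 - 25 * l_end + rnorm(1, 0, 15)
    ptau <- 35 - 8 * l_end + rnorm(1, 0, 8)
    abeta42 <- 160 + 40 * l_end + rnorm(1, 0, 25)
    hip <- 3.5 + 0.6 * lat_k + rnorm(length(ks), 0, 0.25)
    meta_rows[[i]] <- tibble(
      subject_id = subject_ids[i], group = groups[i], visit = ks,
      age = ages, cdr = cdr_i, mmse = as.numeric(mmse),
      tau = tau, ptau = ptau, abeta42 = abeta42,
      region_volume_hippocampus = hip
    )
    mu <- outer(lat_k, delta) + rep(centers, each = length(ks)) +
      outer(ages - age_center, age_slopes)
    tau <- config$noise_sd * sqrt(config$subject_effect_fraction)
    sigma_v <- config$noise_sd * sqrt(1 - config$subject_effect_fraction)
    subj_offset <- rnorm(p, 0, tau)
    feat_rows[[i]] <- mu + rep(subj_offset, each = length(ks)) +
      matrix(rnorm(length(ks) * p, 0, sigma_v), length(ks), p)
    if (groups[i] == "MCI") {
      allk <- seq_len(V)
      truth_traj[[i]] <- tibble(
        subject_id = subject_ids[i], visit = allk,
        age = base_age[i] + (allk - 1) * iv,
        latent_score = latent_at(i, allk),
        observed = allk %in% ks
      )
    }
  }

  meta <- bind_rows(meta_rows)
  features <- do.call(rbind, feat_rows)
  colnames(features) <- feature_names
  rownames(features) <- paste0(meta$subject_id, "_v", meta$visit)

  space <- simulated_feature_space(config, feature_names)

  truth_subjects <- tibble(
    subject_id = subject_ids[mci_idx],
    converter = lat$converter,
    latent_baseline = lat$l1,
    latent_final = lat$l6,
    latent_slope_per_year = lat$slope_per_visit / iv
  )
  truth_subjects$conversion_visit <- purrr::map2_int(
    mci_idx, seq_along(mci_idx),
    function(i, j) {
      if (!lat$converter[j]) return(NA_integer_)
      as.integer(which(latent_at(i, seq_len(V)) < 0)[1])
    }
  )

  cohort <- structure(
    list(meta = meta, features = features, space = space, config = config),
    class = "mci_cohort"
  )
  truth <- structure(
    list(subjects = truth_subjects, informative = informative,
         trajectories = if (length(truth_traj) > 0)
           bind_rows(truth_traj[!vapply(truth_traj, is.null, TRUE)])
         else tibble(subject_id = character(), visit = integer(),
                     age = numeric(), latent_score = numeric(),
                     observed = logical())),
    class = "planted_truth"
  )
  list(cohort = cohort, truth = truth)
}

# Deterministic feature space for a simulated cohort: features occupy the
# first n_features voxels of the grid (row-major), split into near-equal
# GM / WM / ventricle blocks; the atlas tiles the grid into n_regions
# contiguous row-major slabs labeled 1..n_regions.
simulated_feature_space <- function(config, feature_names) {
  p <- config$n_features
  gs <- config$grid_shape
  lin <- seq_len(p) - 1L
  x <- lin %% gs[1]
  y <- (lin %/% gs[1]) %% gs[2]
  z <- lin %/% (gs[1] * gs[2])
  tissue <- rep(c("GM", "WM", "ventricle"),
                c(ceiling(p / 3), ceiling(p / 3),
                  p - 2 * ceiling(p / 3)))[seq_len(p)]
  region_of <- pmin(config$n_regions,
                    (lin * config$n_regions) %/% prod(gs) + 1L)
  feature_space(
    tibble(feature = feature_names, tissue = tissue,
           x = as.integer(x), y = as.integer(y), z = as.integer(z),
           region = as.integer(region_of)),
    step = 1L, offset = c(0L, 0L, 0L), grid_shape = gs
  )
}

#' @export
print.mci_cohort <- function(x, ...) {
  cat("<mci_cohort> ", dplyr::n_distinct(x$meta$subject_id), " subjects, ",
      nrow(x$meta), " scans, ", ncol(x$features), " features\n", sep = "")
  print(dplyr::count(dplyr::distinct(x$meta, .data$subject_id, .data$group),
                     .data$group))
  invisible(x)
}

required_meta_cols <- c("subject_id", "group", "visit", "age", "cdr", "mmse")

#' Write / read a cohort to plain-text files
#'
#' `write_cohort()` serializes the metadata to `meta.csv`, the feature matrix
#' to one TSV per visit index (`features_v<k>.tsv`, first column `subject_id`),
#' the feature space to `feature_space.json`, the simulator configuration to
#' `config.json`, and (optionally) planted truth to `truth.json`. With
#' `nifti = TRUE` each scan is additionally exported as per-tissue NIfTI
#' volumes plus an integer-labeled atlas volume (requires RNifti).
#' `read_cohort()` reverses the round trip: `read_cohort(write_cohort(c))`
#' reproduces the cohort.
#'
#' @param cohort An `mci_cohort`.
#' @param directory Output/input directory.
#' @param truth Optional `planted_truth` to serialize alongside.
#' @param nifti Also write per-scan NIfTI tissue volumes and the atlas.
#' @return `write_cohort()` the directory (invisibly); `read_cohort()` a list
#'   with `cohort` and (if present on disk) `truth`.
#' @export
write_cohort <- function(cohort, directory, truth = NULL, nifti = FALSE) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$meta, file.path(directory, "meta.csv"))
  for (k in sort(unique(cohort$meta$visit))) {
    rows <- which(cohort$meta$visit == k)
    df <- bind_cols(tibble(subject_id = cohort$meta$subject_id[rows]),
                    as_tibble(cohort$features[rows, , drop = FALSE]))
    readr::write_tsv(df, file.path(directory, sprintf("features_v%d.tsv", k)))
  }
  write_feature_space(cohort$space, file.path(directory, "feature_space.json"))
  jsonlite::write_json(unclass(cohort$config),
                       file.path(directory, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(subjects = truth$subjects, informative = truth$informative,
           trajectories = truth$trajectories),
      file.path(directory, "truth.json"), auto_unbox = FALSE, digits = NA,
      dataframe = "columns", na = "null"
    )
  }
  if (nifti) write_cohort_nifti(cohort, directory)
  invisible(directory)
}

write_cohort_nifti <- function(cohort, directory) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    abort("NIfTI export requires the RNifti package")
  gs <- attr(cohort$space, "grid_shape")
  voldir <- file.path(directory, "volumes")
  dir.create(voldir, showWarnings = FALSE)
  sp <- cohort$space
  lin <- sp$x + gs[1] * sp$y + gs[1] * gs[2] * sp$z + 1L
  for (r in seq_len(nrow(cohort$meta))) {
    scan <- rownames(cohort$features)[r]
    for (tis in unique(sp$tissue)) {
      vol <- array(0, dim = gs)
      sel <- sp$tissue == tis
      vol[lin[sel]] <- cohort$features[r, sp$feature[sel]]
      RNifti::writeNifti(RNifti::asNifti(vol),
                         file.path(voldir, sprintf("%s_%s.nii.gz", scan, tis)))
    }
  }
  atlas <- array(0L, dim = gs)
  atlas[lin] <- sp$region
  RNifti::writeNifti(RNifti::asNifti(atlas),
                     file.path(directory, "atlas.nii.gz"))
  invisible(directory)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(directory) {
  meta_path <- file.path(directory, "meta.csv")
  assert_that(file.exists(meta_path), "meta.csv not found in directory")
  meta <- readr::read_csv(meta_path, show_col_types = FALSE)
  missing_cols <- setdiff(required_meta_cols, names(meta))
  if (length(missing_cols) > 0)
    abort(paste0("metadata is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  meta$visit <- as.integer(meta$visit)
  feat_files <- list.files(directory, "^features_v[0-9]+\\.tsv$",
                           full.names = TRUE)
  blocks <- purrr::map(feat_files, function(f) {
    df <- readr::read_tsv(f, show_col_types = FALSE)
    k <- as.integer(sub("^features_v([0-9]+)\\.tsv$", "\\1", basename(f)))
    list(visit = k, subject_id = df$subject_id,
         mat = as.matrix(df[, -1, drop = FALSE]))
  })
  dims <- unique(vapply(blocks, function(b) ncol(b$mat), 1L))
  if (length(dims) > 1)
    abort("feature dimension mismatch across visit files")
  features <- matrix(NA_real_, nrow(meta), if (length(dims)) dims else 0L)
  if (length(blocks) > 0) colnames(features) <- colnames(blocks[[1]]$mat)
  for (b in blocks) {
    rows <- match(paste0(b$subject_id, "_v", b$visit),
                  paste0(meta$subject_id, "_v", meta$visit))
    assert_that(!anyNA(rows), "feature rows with no matching metadata row")
    features[rows, ] <- b$mat
  }
  rownames(features) <- paste0(meta$subject_id, "_v", meta$visit)
  space <- read_feature_space(file.path(directory, "feature_space.json"))
  cfg_path <- file.path(directory, "config.json")
  config <- if (file.exists(cfg_path)) {
    raw <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    do.call(sim_config, raw[names(raw) %in% names(formals(sim_config))])
  } else NULL
  cohort <- structure(
    list(meta = as_tibble(meta), features = features, space = space,
         config = config),
    class = "mci_cohort"
  )
  truth_path <- file.path(directory, "truth.json")
  truth <- NULL
  if (file.exists(truth_path)) {
    raw <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    truth <- structure(
      list(subjects = as_tibble(raw$subjects),
           informative = as.logical(raw$informative),
           trajectories = as_tibble(raw$trajectories)),
      class = "planted_truth"
    )
  }
  list(cohort = cohort, truth = truth)
}
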