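test_that("identical seeds give bit-identical cohorts", {
  cfg <- sim_config(n_control = 8, n_ad = 8, n_mci = 8, n_features = 12,
                    grid_shape = c(3L, 3L, 3L), seed = 7)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort$meta, s2$cohort$meta)
  expect_identical(s1$cohort$features, s2$cohort$features)
  expect_identical(s1$truth$subjects, s2$truth$subjects)
})

test_that("zero effect size leaves AD and Control features exchangeable", {
  sim <- simulate_cohort(sim_config(n_control = 120, n_ad = 120, n_mci = 0,
                                    converter_fraction = 0,
                                    n_features = 20, grid_shape = c(3L, 3L, 3L),
                                    effect_size_d = 0, age_slope_sd = 0,
                                    visits_per_subject = 1L, seed = 5))
  meta <- sim$cohort$meta
  ps <- vapply(seq_len(ncol(sim$cohort$features)), function(j)
    stats::t.test(sim$cohort$features[meta$group == "AD", j],
                  sim$cohort$features[meta$group == "Control", j])$p.value,
    numeric(1))
  # no per-feature group difference should survive Bonferroni
  expect_gt(min(ps) * length(ps), 0.05)
})

test_that("planted effect size is recovered empirically at large n", {
  cfg <- sim_config(n_control = 250, n_ad = 250, n_mci = 0,
                    converter_fraction = 0, n_features = 20,
                    grid_shape = c(3L, 3L, 3L), effect_size_d = 1.0,
                    age_slope_sd = 0, visits_per_subject = 1L, seed = 2)
  sim <- simulate_cohort(cfg)
  meta <- sim$cohort$meta
  info <- which(sim$truth$informative)
  d_hat <- vapply(info, function(j) {
    a <- sim$cohort$features[meta$group == "AD", j]
    b <- sim$cohort$features[meta$group == "Control", j]
    (mean(b) - mean(a)) / sqrt((var(a) + var(b)) / 2)
  }, numeric(1))
  expect_lt(abs(mean(d_hat) - cfg$effect_size_d), 0.1 * cfg$effect_size_d)
})

test_that("converter_fraction 0 plants no converters; fraction respected", {
  s0 <- small_cohort(seed = 3, converter_fraction = 0)
  expect_equal(sum(s0$truth$subjects$converter), 0)
  expect_true(all(is.na(s0$truth$subjects$conversion_visit)))
  s5 <- small_cohort(seed = 3, converter_fraction = 0.5)
  expect_equal(sum(s5$truth$subjects$converter), 20)
})

test_that("impossible config errors", {
  expect_error(sim_config(n_mci = 0, converter_fraction = 0.5), "impossible")
  expect_error(sim_config(n_features = 200, grid_shape = c(3L, 3L, 3L)),
               "grid_shape")
  expect_error(sim_config(missing_visit_prob = 1.5), "probabilities")
})

test_that("planted latent trajectories satisfy the label geometry", {
  sim <- small_cohort(seed = 11)
  subj <- sim$truth$subjects
  # converters are on the AD side at visit 6; nonconverters positive throughout
  expect_true(all(subj$latent_final[subj$converter] < 0))
  expect_true(all(subj$latent_final[!subj$converter] > 0))
  expect_true(all(subj$latent_baseline[!subj$converter] > 0))
  # conversion visit defined iff converter, and matches the latent line
  expect_true(all(!is.na(subj$conversion_visit) == subj$converter))
  traj <- sim$truth$trajectories
  for (sid in subj$subject_id[subj$converter]) {
    tr <- traj[traj$subject_id == sid, ]
    first_neg <- min(tr$visit[tr$latent_score < 0])
    expect_equal(first_neg, subj$conversion_visit[subj$subject_id == sid])
  }
})

test_that("CDR courses follow group rules", {
  sim <- small_cohort(seed = 13)
  meta <- sim$cohort$meta
  expect_true(all(meta$cdr[meta$group == "Control"] == 0))
  ad_max <- tapply(meta$cdr[meta$group == "AD"],
                   meta$subject_id[meta$group == "AD"], max)
  expect_true(all(ad_max >= 1))
  base <- meta %>% dplyr::filter(group == "MCI") %>%
    dplyr::group_by(subject_id) %>%
    dplyr::summarise(b = cdr[which.min(visit)])
  expect_true(all(base$b == 0.5))
})

test_that("baseline visits are always observed and schedules are nominal", {
  sim <- small_cohort(seed = 17)
  meta <- sim$cohort$meta
  per <- meta %>% dplyr::group_by(subject_id) %>%
    dplyr::summarise(has_base = 1 %in% visit,
                     spacing_ok = all(abs(diff(age) -
                       0.5 * diff(visit)) < 1e-9))
  expect_true(all(per$has_base))
  expect_true(all(per$spacing_ok))
})

test_that("cohort round-trips through plain-text files", {
  sim <- small_cohort(seed = 19)
  dir <- withr::local_tempdir()
  write_cohort(sim$cohort, dir, truth = sim$truth)
  back <- read_cohort(dir)
  expect_equal(back$cohort$meta, sim$cohort$meta)
  expect_equal(back$cohort$features, sim$cohort$features)
  expect_equal(as.data.frame(back$cohort$space),
               as.data.frame(sim$cohort$space))
  expect_equal(unclass(back$cohort$config), unclass(sim$cohort$config))
  expect_equal(back$truth$subjects$converter, sim$truth$subjects$converter)
  expect_equal(back$truth$informative, sim$truth$informative)
})

test_that("read_cohort names the missing metadata column", {
  sim <- small_cohort(seed = 23)
  dir <- withr::local_tempdir()
  write_cohort(sim$cohort, dir)
  meta <- readr::read_csv(file.path(dir, "meta.csv"), show_col_types = FALSE)
  readr::write_csv(meta[, setdiff(names(meta), "age")],
                   file.path(dir, "meta.csv"))
  expect_error(read_cohort(dir), "age")
})

test_that("a cohort without MCI subjects writes valid files with empty slice", {
  sim <- simulate_cohort(sim_config(n_control = 6, n_ad = 6, n_mci = 0,
                                    converter_fraction = 0, n_features = 10,
                                    grid_shape = c(3L, 3L, 3L), seed = 2))
  expect_equal(nrow(sim$truth$subjects), 0)
  dir <- withr::local_tempdir()
  write_cohort(sim$cohort, dir, truth = sim$truth)
  back <- read_cohort(dir)
  expect_equal(sum(back$cohort$meta$group == "MCI"), 0)
  expect_equal(nrow(back$cohort$meta), nrow(sim$cohort$meta))
})

test_that("NIfTI export round-trips scan volumes and atlas", {
  skip_if_not_installed("RNifti")
  sim <- simulate_cohort(sim_config(n_control = 2, n_ad = 2, n_mci = 2,
                                    n_features = 12, grid_shape = c(3L, 3L, 3L),
                                    visits_per_subject = 2L, seed = 4))
  dir <- withr::local_tempdir()
  write_cohort(sim$cohort, dir, nifti = TRUE)
  atlas <- RNifti::readNifti(file.path(dir, "atlas.nii.gz"))
  sp <- sim$cohort$space
  expect_equal(dim(atlas), attr(sp, "grid_shape"))
  scan <- rownames(sim$cohort$features)[1]
  gm <- RNifti::readNifti(file.path(dir, "volumes",
                                    paste0(scan, "_GM.nii.gz")))
  sel <- sp$tissue == "GM"
  got <- gm[cbind(sp$x[sel] + 1, sp$y[sel] + 1, sp$z[sel] + 1)]
  expect_equal(as.numeric(got), unname(sim$cohort$features[1, sp$feature[sel]]),
               tolerance = 1e-6)
})
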