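test_that("score_trajectories gives one point per visit reproducing scores", {
  inst <- make_separable_instance(n = 10, p = 4, seed = 1)
  m <- train_margin_model(inst$x, inst$y, C = 10, positive = "A")
  meta <- tibble(subject_id = rep(c("s1", "s2"), c(6, 1)),
                 visit = c(1:6, 1L), age = c(70 + (0:5) / 2, 80))
  x <- matrix(rnorm(7 * 4), 7, 4, dimnames = list(NULL, colnames(inst$x)))
  tr <- score_trajectories(meta, x, m)
  expect_equal(nrow(tr), 7)
  expect_equal(sum(tr$subject_id == "s1"), 6)
  expect_equal(sum(tr$subject_id == "s2"), 1)
  expect_equal(tr$score, signed_distance(m, x)[order(meta$subject_id,
                                                     meta$visit)])
})

test_that("fit_and_extend continues an exact line and handles one point", {
  pts <- tibble(visit = c(1, 2, 4), age = 70 + c(0, 0.5, 1.5),
                score = 2 - 0.8 * c(0, 0.5, 1.5))
  fe <- fit_and_extend(pts)
  expect_equal(fe$slope, -0.8, tolerance = 1e-12)
  expect_equal(fe$extended, 2 - 0.8 * (0:5) * 0.5, tolerance = 1e-12)
  single <- fit_and_extend(tibble(visit = 1, age = 75, score = 2))
  expect_equal(single$slope, 0)
  expect_equal(single$extended, rep(2, 6))
})

test_that("missing early visits are shifted to their nominal slots", {
  # first observed visit is 3: nominal visit-1 age is two intervals earlier
  pts <- tibble(visit = c(3, 5), age = c(71, 72), score = c(1, 0))
  fe <- fit_and_extend(pts, visit_interval = 0.5)
  expect_equal(fe$extended[3], 1, tolerance = 1e-12)
  expect_equal(fe$extended[5], 0, tolerance = 1e-12)
  expect_equal(fe$extended[1], 2, tolerance = 1e-12)  # extrapolated back
})

test_that("noisy planted slopes are recovered within 3 SE", {
  set.seed(77)
  ok <- 0
  n_rep <- 40
  for (r in seq_len(n_rep)) {
    ages <- 70 + (0:3) * 0.5
    true_slope <- -0.4
    sc <- 1 + true_slope * (ages - 70) + rnorm(4, 0, 0.1)
    fe <- fit_and_extend(tibble(visit = 1:4, age = ages, score = sc))
    ref <- lm(sc ~ ages)
    expect_equal(fe$slope, unname(coef(ref)[2]), tolerance = 1e-10)
    se_true <- 0.1 / sqrt(sum((ages - mean(ages))^2))  # known noise SD
    if (abs(fe$slope - true_slope) <= 3 * se_true) ok <- ok + 1
  }
  expect_gte(ok, n_rep - 2)  # 3 true-sigma SE covers ~99.7%
})

test_that("trajectory labeling follows the side-of-boundary rules", {
  lab <- function(s1, s6) label_by_trajectory(seq(s1, s6, length.out = 6))
  expect_equal(lab(2, 1), "NT")
  expect_equal(lab(2, -1), "CT")     # crosses to the AD side
  expect_equal(lab(-1, -2), "CT")    # starts on the AD side
  expect_equal(lab(-1, 1), "outlier")
  expect_equal(lab(0, 1), "NT")      # zero counts as Control side
  expect_error(label_by_trajectory(c(1, 2, 3)), "6")
})

test_that("labeling is invariant to uniform positive rescaling of scores", {
  set.seed(5)
  for (r in 1:50) {
    ext <- seq(runif(1, -2, 2), runif(1, -2, 2), length.out = 6)
    expect_equal(label_by_trajectory(ext), label_by_trajectory(13.7 * ext))
  }
})

test_that("CDR labeling requires baseline 0.5 and detects any rise", {
  expect_equal(label_by_cdr(c(0.5, 0.5, 1.0)), "C-CDR")
  expect_equal(label_by_cdr(rep(0.5, 6)), "N-CDR")
  expect_equal(label_by_cdr(c(1.0, 1.0)), "undefined")
  expect_equal(label_by_cdr(c(0, 0, 0)), "undefined")
  expect_equal(label_by_cdr(0.5), "N-CDR")
  expect_error(label_by_cdr(numeric(0)), "empty")
  expect_error(label_by_cdr(c(0.5, 0.7)), "CDR values")
})

test_that("MMSE threshold conversion is strict and monotone in the cutoff", {
  expect_true(label_by_mmse_threshold(c(23.8, 24.0), 24))
  expect_false(label_by_mmse_threshold(c(24, 24), 24))  # strict <
  sim <- small_cohort(seed = 9)
  mm <- sim$cohort$meta %>%
    filter(group == "MCI") %>%
    group_by(subject_id) %>%
    summarise(m = mean(mmse))
  counts <- vapply(c(24, 23, 22),
                   function(cut) sum(mm$m < cut), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("union labeling ORs the two definitions and rejects outliers", {
  expect_equal(label_by_union("NT", "C-CDR"), "converter")
  expect_equal(label_by_union("CT", "N-CDR"), "converter")
  expect_equal(label_by_union("NT", "N-CDR"), "nonconverter")
  expect_error(label_by_union("outlier", "N-CDR"), "outlier")
})

test_that("converts_at_baseline follows the sign convention", {
  x <- matrix(c(-1, 1), ncol = 1, dimnames = list(NULL, "f"))
  m <- train_margin_model(x, c("AD", "Control"), C = 1000,
                          positive = "Control")
  one <- function(v) matrix(v, 1, 1, dimnames = list(NULL, "f"))
  expect_false(converts_at_baseline(m, one(0.5)))
  expect_true(converts_at_baseline(m, one(-0.05)))
  expect_false(converts_at_baseline(m, one(0)))  # zero = Control side
})

test_that("conversion_labels integrates trajectory, CDR and union rules", {
  scores <- bind_rows(
    tibble(subject_id = "nt", visit = 1:6, age = 70 + (0:5) / 2,
           score = 1 + (0:5) * 0.01),
    tibble(subject_id = "ct", visit = 1:6, age = 72 + (0:5) / 2,
           score = 1 - (0:5) * 0.5),
    tibble(subject_id = "out", visit = 1:6, age = 74 + (0:5) / 2,
           score = -1 + (0:5) * 0.5)
  )
  meta <- tibble(subject_id = rep(c("nt", "ct", "out"), each = 6),
                 visit = rep(1:6, 3),
                 cdr = c(rep(0.5, 6), rep(c(0.5, 1), c(3, 3)), rep(0.5, 6)))
  lab <- conversion_labels(scores, meta)
  lab <- lab[match(c("nt", "ct", "out"), lab$subject_id), ]
  expect_equal(lab$by_trajectory, c("NT", "CT", "outlier"))
  expect_equal(lab$by_cdr, c("N-CDR", "C-CDR", "N-CDR"))
  expect_equal(lab$by_union, c("nonconverter", "converter", NA))
  expect_equal(lab$converts_at_baseline, c(FALSE, FALSE, TRUE))
  expect_equal(lab$conversion_visit, c(NA_integer_, 4L, 1L))
})

test_that("labels on noiseless latent trajectories recover planted truth", {
  sim <- small_cohort(seed = 33)
  truth <- sim$truth
  obs <- truth$trajectories %>% filter(observed)
  scores <- obs %>%
    rename(score = latent_score) %>%
    select(subject_id, visit, age, score)
  lab <- conversion_labels(scores, sim$cohort$meta)
  merged <- dplyr::inner_join(lab, truth$subjects, by = "subject_id")
  expect_true(all(merged$by_trajectory != "outlier"))
  expect_equal(merged$by_trajectory == "CT", merged$converter)
  # when scores sit exactly on the line, an AD-side baseline forces CT or
  # outlier (under scan noise the fitted line may overrule the observed point)
  expect_gt(sum(lab$converts_at_baseline), 0)
  expect_true(all(lab$by_trajectory[lab$converts_at_baseline] %in%
                    c("CT", "outlier")))
})
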