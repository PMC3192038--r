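test_that("rfe_step removes the smallest-magnitude weight, ties low", {
  m <- structure(list(w = c(a = 0.5, b = -0.1, c = 2), b = 0, C = 1,
                      positive = "P", negative = "N",
                      active = c("a", "b", "c"), margin = 1),
                 class = "margin_model")
  expect_equal(as.character(rfe_step(m)), "b")
  m$w <- c(a = 0.3, b = 0.3, c = 0.3)
  expect_equal(as.character(rfe_step(m)), "a")  # tie -> lowest index
  m$active <- "a"
  expect_error(rfe_step(m), "two")
})

test_that("rfe_step equals the exhaustive argmin on random weight vectors", {
  set.seed(42)
  for (r in 1:200) {
    p <- sample(2:12, 1)
    w <- round(rnorm(p), 3)  # rounding forces occasional exact ties
    nm <- sprintf("f%02d", seq_len(p))
    m <- structure(list(w = setNames(w, nm), b = 0, C = 1, positive = "P",
                        negative = "N", active = nm, margin = 1),
                   class = "margin_model")
    brute <- nm[which(abs(w) == min(abs(w)))[1]]
    expect_identical(as.character(rfe_step(m)), brute)
  }
})

test_that("mfe_step matches exhaustive search over single removals", {
  for (s in 1:25) {
    inst <- make_separable_instance(n = sample(8:40, 1), p = sample(3:12, 1),
                                    seed = 300 + s)
    m <- train_margin_model(inst$x, inst$y, C = 100, positive = "A")
    ysign <- ifelse(inst$y == "A", 1, -1)
    feats <- names(m$w)
    cand <- vapply(feats, function(f) {
      sub <- setdiff(feats, f)
      if (sum(m$w[sub]^2) == 0) return(-Inf)
      oracle_margin(m$w, inst$x, ysign, sub)
    }, numeric(1))
    pick <- mfe_step(m, inst$x, inst$y)
    expect_identical(as.character(pick), feats[which.max(cand)])
    expect_equal(attr(pick, "margin"), max(cand), tolerance = 1e-9)
  }
})

test_that("a zero-weight feature is removed when strictly best or tied-first", {
  inst <- make_separable_instance(n = 16, p = 4, seed = 8)
  x <- cbind(inst$x, dead = rep(0, nrow(inst$x)))
  m <- train_margin_model(x, inst$y, C = 100, positive = "A")
  # zero-weight column: removal leaves the margin exactly unchanged
  expect_lt(abs(m$w["dead"]), 1e-9)
  full <- margin_of(m, x, inst$y)
  expect_equal(margin_of(m, x, inst$y, subset = setdiff(names(m$w), "dead")),
               full, tolerance = 1e-12)
})

test_that("mfe dominates rfe's choice at every step (per-step optimality)", {
  worse <- 0
  for (s in 1:30) {
    inst <- make_separable_instance(n = 20, p = 8, seed = 500 + s)
    m <- train_margin_model(inst$x, inst$y, C = 100, positive = "A")
    feats <- names(m$w)
    mfe_pick <- as.character(mfe_step(m, inst$x, inst$y))
    rfe_pick <- as.character(rfe_step(m))
    mm <- margin_of(m, inst$x, inst$y, subset = setdiff(feats, mfe_pick))
    mr <- margin_of(m, inst$x, inst$y, subset = setdiff(feats, rfe_pick))
    if (mm < mr - 1e-12) worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("mfe_slack_step reduces to mfe_step on separable data", {
  for (s in 1:10) {
    inst <- make_separable_instance(n = 18, p = 6, seed = 700 + s)
    m <- train_margin_model(inst$x, inst$y, C = 100, positive = "A")
    expect_identical(as.character(mfe_slack_step(m, inst$x, inst$y)),
                     as.character(mfe_step(m, inst$x, inst$y)))
  }
})

test_that("mfe_slack prefers the removal that un-violates a planted error", {
  # one P point sits far on the wrong side of f2 only; dropping f2
  # un-violates it (f1 alone separates), dropping f1 does not
  x <- cbind(f1 = c(1, 1.2, 1.4, 1.1, -1, -1.2),
             f2 = c(0.5, -0.5, 0, -6, 0.2, -0.2))
  y <- c("P", "P", "P", "P", "N", "N")
  m <- structure(list(w = c(f1 = 1, f2 = 1), b = 0, C = 1,
                      positive = "P", negative = "N",
                      active = c("f1", "f2"), margin = NA),
                 class = "margin_model")
  pick <- mfe_slack_step(m, x, y)
  # brute force over the two candidates with the same criterion definition
  crit <- vapply(c("f1", "f2"), function(drop_f) {
    sub <- setdiff(c("f1", "f2"), drop_f)
    mar <- oracle_margin(m$w, x, ifelse(y == "P", 1, -1), sub)
    if (mar > 0) return(mar)
    w_s <- ifelse(names(m$w) %in% sub, m$w, 0)
    proj <- as.numeric(x %*% w_s)
    b_s <- -(min(proj[y == "P"]) + max(proj[y != "P"])) / 2
    sc <- ifelse(y == "P", 1, -1) * (proj + b_s) / sqrt(sum(w_s^2))
    -sum(pmax(0, -sc))
  }, numeric(1))
  expect_identical(as.character(pick), names(which.max(crit)))
  expect_identical(as.character(pick), "f2")
  expect_true(is.finite(attr(pick, "criterion")))
})

test_that("run_elimination produces a coherent trace", {
  inst <- make_separable_instance(n = 20, p = 5, seed = 12)
  tr <- run_elimination(inst$x, inst$y, method = "mfe", C = 100,
                        retrain_every = 1, positive = "A")
  removals <- tr$feature[!is.na(tr$feature)]
  expect_equal(max(tr$step), 4)           # 5 features -> 4 removals max
  expect_equal(length(removals), 4)
  expect_false(anyDuplicated(removals) > 0)
  expect_true(all(removals %in% colnames(inst$x)))
  expect_equal(retained_at(tr, 2),
               setdiff(colnames(inst$x), removals[1:2]))
  # recorded margins match an independent margin_of recomputation
  m0 <- train_margin_model(inst$x, inst$y, C = 100, positive = "A")
  first <- margin_of(m0, inst$x, inst$y,
                     subset = setdiff(colnames(inst$x), removals[1]))
  expect_equal(tr$margin[tr$step == 1], first, tolerance = 1e-9)
})

test_that("elimination is deterministic under a fixed seed", {
  inst <- make_separable_instance(n = 16, p = 6, seed = 13)
  t1 <- run_elimination(inst$x, inst$y, method = "mfe_hybrid", C = 10,
                        n_bootstrap = 5, seed = 4, positive = "A")
  t2 <- run_elimination(inst$x, inst$y, method = "mfe_hybrid", C = 10,
                        n_bootstrap = 5, seed = 4, positive = "A")
  expect_identical(as_tibble(t1), as_tibble(t2))
})

test_that("elimination keeps informative features on planted-truth data", {
  fractions <- vapply(1:10, function(s) {
    set.seed(900 + s)
    n <- 60; p <- 100; n_info <- 10
    y <- rep(c("P", "N"), each = n / 2)
    x <- matrix(rnorm(n * p, 0, 1), n, p)
    x[, 1:n_info] <- x[, 1:n_info] + ifelse(y == "P", 0.9, -0.9)
    colnames(x) <- sprintf("f%03d", 1:p)
    tr <- run_elimination(x, y, method = "mfe_hybrid", C = 1,
                          retrain_every = 10, min_features = 15,
                          seed = s, positive = "P")
    surv <- retained_at(tr)
    # fraction of the planted informative features among the 15 survivors
    mean(sprintf("f%03d", 1:n_info) %in% surv)
  }, numeric(1))
  expect_gte(median(fractions), 0.8)
})

test_that("stop_point follows the tolerance and tie rules", {
  base <- tibble(step = 0:5, feature = c(NA, sprintf("f%d", 1:5)),
                 margin = 1, val_error = NA_real_, retrained = TRUE)
  mk <- function(vals) {
    tr <- base
    tr$val_error <- vals
    structure(tr, initial_features = sprintf("f%d", 1:6),
              class = c("elimination_trace", class(tr)))
  }
  flat <- mk(rep(0.2, 6))
  expect_equal(as.integer(stop_point(flat)), 5)  # flat -> smallest set
  sharp <- mk(c(0.5, 0.5, 0.05, 0.5, 0.5, 0.5))
  expect_equal(as.integer(stop_point(sharp, epsilon = 0)), 2)
  expect_equal(attr(stop_point(sharp, epsilon = 0), "retained"),
               sprintf("f%d", c(3, 4, 5, 6)))
  tied <- mk(c(0.3, 0.1, 0.3, 0.1, 0.3, 0.3))
  expect_equal(as.integer(stop_point(tied, epsilon = 0)), 3)
  expect_error(stop_point(mk(rep(NA_real_, 6))), "estimates")
})
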