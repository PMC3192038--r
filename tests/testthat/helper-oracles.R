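suppressMessages(library(dplyr))
suppressMessages(library(tibble))

# Independent oracles used across the suite. These deliberately use plain
# loops / enumeration, not the package's vectorized code paths.

# Restricted-margin oracle: zero w outside `subset`, midpoint bias over the
# class-extreme projections, explicit min over points.
oracle_margin <- function(w, x, ysign, subset) {
  w_s <- ifelse(names(w) %in% subset, w, 0)
  nrm <- sqrt(sum(w_s^2))
  stopifnot(nrm > 0)
  proj <- as.numeric(x %*% w_s)
  b_s <- -(min(proj[ysign > 0]) + max(proj[ysign < 0])) / 2
  vals <- vapply(seq_along(proj),
                 function(i) ysign[i] * (proj[i] + b_s) / nrm, numeric(1))
  min(vals)
}

# Exhaustive maximum bipartite matching by recursion over group A.
oracle_max_matching <- function(ages_a, ages_b, tol = 1.0) {
  best <- 0L
  recurse <- function(i, used_b, count) {
    if (i > length(ages_a)) {
      best <<- max(best, count)
      return(invisible())
    }
    # upper bound prune
    if (count + (length(ages_a) - i + 1) <= best) return(invisible())
    recurse(i + 1L, used_b, count)  # leave a_i unmatched
    for (j in seq_along(ages_b)) {
      if (!used_b[j] && abs(ages_a[i] - ages_b[j]) <= tol) {
        used_b[j] <- TRUE
        recurse(i + 1L, used_b, count + 1L)
        used_b[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, length(ages_b)), 0L)
  best
}

# Random separable two-class instance with a known separating direction.
make_separable_instance <- function(n = 20, p = 6, gap = 1.5, seed = 1) {
  set.seed(seed)
  dir <- rnorm(p)
  dir <- dir / sqrt(sum(dir^2))
  n1 <- ceiling(n / 2)
  x <- matrix(rnorm(n * p), n, p)
  x <- x - outer(as.numeric(x %*% dir), dir)      # remove along-dir component
  shift <- c(runif(n1, gap / 2, gap), -runif(n - n1, gap / 2, gap))
  x <- x + outer(shift, dir)
  colnames(x) <- sprintf("f%02d", seq_len(p))
  y <- rep(c("A", "B"), c(n1, n - n1))
  list(x = x, y = y)
}

small_cohort <- function(seed = 7, ...) {
  simulate_cohort(sim_config(n_control = 30, n_ad = 25, n_mci = 40,
                             n_features = 30, grid_shape = c(4L, 4L, 4L),
                             seed = seed, ...))
}
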