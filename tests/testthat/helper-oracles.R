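# Independent oracles used to validate the package's statistics.  These are
# deliberately naive implementations (textbook loops, brute-force
# enumeration) kept separate from the code paths they check.

# Textbook product-limit estimator: loop over distinct times, events before
# censorings at ties.
km_oracle <- function(time, event, grid) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  steps <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    steps[i] <- s
  }
  vapply(grid, function(t) {
    j <- sum(ut <= t)
    if (j == 0L) 1 else steps[j]
  }, numeric(1))
}

# Multi-group logrank by direct observed-minus-expected tallying with the
# hypergeometric covariance, chi-square on g-1 groups.
logrank_oracle <- function(time, event, group) {
  group <- factor(group)
  g <- nlevels(group)
  ut <- sort(unique(time[event == 1]))
  oe <- numeric(g)
  V <- matrix(0, g, g)
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(time == t & event == 1)
    ng <- vapply(levels(group), function(l) sum(at_risk & group == l),
                 numeric(1))
    dg <- vapply(levels(group), function(l)
      sum(time == t & event == 1 & group == l), numeric(1))
    oe <- oe + dg - d * ng / n
    if (n > 1) {
      Vt <- (diag(ng) * n - outer(ng, ng)) * d * (n - d) / (n^2 * (n - 1))
      V <- V + Vt
    }
  }
  idx <- seq_len(g - 1L)
  drop(t(oe[idx]) %*% solve(V[idx, idx, drop = FALSE]) %*% oe[idx])
}

# Naive complete-linkage agglomeration; returns sorted merge heights.
complete_linkage_oracle <- function(D) {
  D <- as.matrix(D)
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- 0L
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq.int(i + 1L, length(clusters))) {
        h <- max(D[clusters[[i]], clusters[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# Area between two step curves via stats::stepfun evaluated at segment
# midpoints of the merged knot set (exact for piecewise-constant curves).
area_oracle <- function(c1, c2) {
  knots <- sort(unique(c(c1$time, c2$time)))
  f1 <- stats::stepfun(c1$time[-1], c1$surv)
  f2 <- stats::stepfun(c2$time[-1], c2$surv)
  mids <- (knots[-1] + knots[-length(knots)]) / 2
  sum(diff(knots) * abs(f1(mids) - f2(mids)))
}

# Brute-force partial rank: maximum tree distance over all leaf pairs that
# share the attribute's feature.
partial_rank_oracle <- function(family, tree, attribute) {
  lab <- apply(family$labels, 1L, paste, collapse = ",")
  feat <- family$labels[, attribute]
  best <- 0
  m <- length(lab)
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      if (feat[i] == feat[j])
        best <- max(best, tree_distance(tree, lab[i], lab[j]))
    }
  }
  best
}

# Small random cohort with genotypes and survival for property tests.
random_cohort <- function(n = 80, m = 3, seed = 1) {
  simulate_cohort(sim_config(n_samples = n, n_markers = m, seed = seed))
}

# A curve family built from a random cohort's first `e` markers.
random_family <- function(seed, n = 60, m = 2) {
  co <- random_cohort(n = n, m = m, seed = seed)
  suppressMessages(build_family(co$genotypes, co$survival))
}

# Hand-built km_curve for distance tests.
make_curve <- function(grid, surv, label = NULL) {
  structure(list(time = grid, surv = surv, n = NA_integer_, label = label),
            class = "km_curve")
}

# Memoised heavy fixtures shared across test files.
.fixtures <- new.env(parent = emptyenv())

null_1k_fixture <- function() {
  if (is.null(.fixtures$null_1k)) {
    .fixtures$null_1k <- suppressMessages(
      calibrate_null(1000, n_markers = 140, seed = 424243))
  }
  .fixtures$null_1k
}
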