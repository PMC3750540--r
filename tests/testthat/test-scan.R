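test_that("pair enumeration is complete, ordered and duplicate-free", {
  for (n in c(2, 3, 10, 140)) {
    ids <- sprintf("M%03d", seq_len(n))
    pr <- marker_pairs(ids)
    expect_equal(nrow(pr), n * (n - 1) / 2)
    expect_true(all(pr[, 1] < pr[, 2]))          # no (a,a), no (b,a) twins
    expect_equal(anyDuplicated(paste(pr[, 1], pr[, 2])), 0L)
  }
  expect_equal(marker_pairs(c("a", "b", "c")),
               cbind(marker_a = c("a", "a", "b"),
                     marker_b = c("b", "c", "c")))
  expect_error(marker_pairs("a"), "at least 2")
})

test_that("the scan is deterministic and invariant to chunking", {
  co <- suppressWarnings(simulate_cohort(
    sim_config(200, n_markers = 7, n_affected_pairs = 1, seed = 55)))
  full <- geninter(co$genotypes, co$survival)
  again <- geninter(co$genotypes, co$survival)
  expect_identical(full$results, again$results)

  # partitioned pair iterator merges to the identical result set
  pr <- marker_pairs(colnames(co$genotypes))
  chunks <- split(seq_len(nrow(pr)), rep(1:3, length.out = nrow(pr)))
  parts <- lapply(chunks, function(idx)
    geninter(co$genotypes, co$survival, pairs = pr[idx, , drop = FALSE]))
  merged <- do.call(rbind, lapply(parts, function(x) x$results))
  key <- function(d) paste(d$marker_a, d$marker_b)
  merged <- merged[order(key(merged)), ]
  rownames(merged) <- NULL
  fullr <- full$results[order(key(full$results)), ]
  rownames(fullr) <- NULL
  expect_equal(merged, fullr)

  # sorted by decreasing rank; one row per unordered pair
  expect_true(all(diff(full$results$rank) <= 1e-15))
  expect_equal(nrow(full$results), choose(7, 2))
})

test_that("scan output contract: untestable pairs, thresholds, TSV export", {
  co <- simulate_cohort(sim_config(150, n_markers = 5, seed = 19))
  g <- co$genotypes
  g[, 1] <- "AA"  # monomorphic marker
  g[, 2] <- "BB"  # pair (1,2) has a single combination -> untestable
  fit <- geninter(g, co$survival)
  row12 <- fit$results[fit$results$marker_a == "M001" &
                       fit$results$marker_b == "M002", ]
  expect_true(is.na(row12$rank))   # reported missing, not 0
  expect_equal(row12$n_groups, 1L)

  null <- suppressMessages(calibrate_null(150, n_markers = 20, seed = 5))
  fit2 <- geninter(g, co$survival, null = null, p_cutoff = 0.5)
  expect_true(all(fit2$results$p_value < 0.5))
  fit3 <- geninter(g, co$survival, null = null, top_k = 3)
  expect_equal(nrow(fit3$results), 3L)
  expect_true(all(!is.na(fit3$results$fdr_p)))
  expect_true(all(fit3$results$fdr_p >= fit3$results$p_value))

  f <- withr::local_tempfile(fileext = ".tsv")
  write_results(fit3, f)
  back <- utils::read.delim(f)
  expect_equal(names(back), c("marker_a", "marker_b", "rank", "p_value",
                              "fdr_p", "n_groups", "n_samples"))
  expect_equal(back$rank, fit3$results$rank, tolerance = 1e-12)
})

test_that("a fully null scan flags about the nominal fraction of pairs", {
  null <- null_1k_fixture()
  co <- simulate_cohort(sim_config(1000, n_markers = 140, seed = 171717))
  fit <- geninter(co$genotypes, co$survival, null = null)
  p <- fit$results$p_value
  frac <- mean(p < 0.01, na.rm = TRUE)
  # nominal 1%, generous band for the gamma approximation error
  expect_gt(frac, 0.002)
  expect_lt(frac, 0.035)
})

test_that("single-marker scan handles null and monomorphic markers", {
  co <- random_cohort(n = 200, m = 4, seed = 23)
  g <- co$genotypes
  g[, 4] <- "AB"
  sm <- single_marker_scan(g, co$survival)
  expect_equal(nrow(sm), 4L)
  expect_true(is.na(sm$p_value[sm$marker == "M004"]))  # untestable
  expect_true(all(sm$fdr_p >= sm$p_value, na.rm = TRUE))

  # two groups with identical survival patterns: no effect, p = 1
  gg <- cbind(m1 = rep(c("AA", "BB"), each = 4))
  rownames(gg) <- sprintf("s%d", 1:8)
  ss <- data.frame(sample = rownames(gg), time = rep(c(10, 20, 30, 40), 2),
                   event = rep(1L, 8))
  sm2 <- single_marker_scan(gg, ss)
  expect_equal(sm2$p_value, 1)
})

test_that("pairwise logrank scan shares the pair enumeration and finds effects", {
  maf <- rep(0.4, 4)
  fr <- cbind(AA = (1 - maf)^2, AB = 2 * maf * (1 - maf), BB = maf^2)
  co <- simulate_cohort(sim_config(800, genotype_freqs = fr,
                                   n_affected_pairs = 1, seed = 99))
  lr <- pairwise_logrank_scan(co$genotypes, co$survival)
  expect_equal(nrow(lr), choose(4, 2))
  truth_row <- lr$marker_a == co$truth$marker_a &
               lr$marker_b == co$truth$marker_b
  expect_lt(lr$p_value[truth_row], 1e-6)  # strong synergistic effect
})

test_that("a synergistic pair ranks high while its markers are silent alone", {
  maf <- rep(0.35, 6)
  fr <- cbind(AA = (1 - maf)^2, AB = 2 * maf * (1 - maf), BB = maf^2)
  co <- simulate_cohort(sim_config(1000, genotype_freqs = fr,
                                   n_affected_pairs = 1, seed = 7001))
  fit <- geninter(co$genotypes, co$survival)
  top <- fit$results[1, ]
  expect_equal(c(top$marker_a, top$marker_b),
               c(co$truth$marker_a, co$truth$marker_b))
  expect_gt(top$rank, 0.4)

  sm <- single_marker_scan(co$genotypes, co$survival)
  hit <- sm$marker %in% unlist(co$truth)
  # the double-homozygote group is ~1% of carriers of either marker, so
  # single-marker effects stay modest
  expect_true(all(sm$fdr_p[hit] > 0.001))
})

test_that("ROC machinery: perfect, random and monotone behaviour", {
  truth <- data.frame(marker_a = c("m1", "m2"), marker_b = c("m5", "m6"))
  pr <- marker_pairs(paste0("m", 1:8))
  set.seed(3)
  df <- data.frame(marker_a = pr[, 1], marker_b = pr[, 2],
                   p_value = runif(nrow(pr), 0.2, 1))
  key <- paste(df$marker_a, df$marker_b)
  pos <- key %in% c("m1 m5", "m2 m6")
  df$p_value[pos] <- c(1e-6, 2e-6)

  roc <- roc_curve(df, truth)
  expect_true(any(roc$tpr == 1 & roc$fpr == 0))  # perfect separation
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_equal(roc$fpr[nrow(roc)], 1)

  op <- operating_point(df, truth, p_cutoff = 0.01)
  expect_equal(op$tp, 2L); expect_equal(op$fp, 0L)
  expect_equal(op$tpr, 1); expect_equal(op$fpr, 0)

  # random scores track the diagonal
  set.seed(11)
  big <- marker_pairs(paste0("x", 1:30))
  rnd <- data.frame(marker_a = big[, 1], marker_b = big[, 2],
                    p_value = runif(nrow(big)))
  rt <- data.frame(marker_a = paste0("x", 1:20),
                   marker_b = paste0("x", 21:40 %% 30 + 1))
  rt <- rt[rt$marker_a != rt$marker_b, ][1:15, ]
  rt[] <- t(apply(rt, 1, sort))
  roc_r <- roc_curve(rnd, rt)
  expect_lt(mean(abs(roc_r$tpr - roc_r$fpr)), 0.2)

  expect_error(operating_point(df, data.frame(marker_a = "zz",
                                              marker_b = "m1")),
               "absent")

  # averaging identical repetitions reproduces the single curve
  avg <- roc_evaluate(list(df, df), list(truth, truth))
  single <- roc_curve(df, truth, thresholds = avg$threshold)
  expect_equal(avg$tpr, single$tpr)
  expect_equal(avg$fpr, single$fpr)
})
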