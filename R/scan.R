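#' Enumerate unordered marker pairs
#'
#' @param markers Character vector of marker IDs.
#' @return A two-column character matrix, one row per unordered pair
#'   (`C(n, 2)` rows), ordered lexicographically by first then second
#'   marker position.
#' @export
marker_pairs <- function(markers) {
  n <- length(markers)
  if (n < 2L) stop("need at least 2 markers to form pairs")
  idx <- utils::combn(n, 2L)
  cbind(marker_a = markers[idx[1L, ]], marker_b = markers[idx[2L, ]])
}

# Core pairwise rank scan.  Sorts the cohort once (events before censorings
# at tied times), then for each pair calls the C++ kernel for the
# area-distance matrix of the genotype-combination Kaplan-Meier curves and
# condenses it into the normalized rank.  `pairs` may restrict the scan to
# a subset of rows of marker_pairs(); chunked scans merge to identical
# results.
scan_ranks <- function(geno, surv, pairs = NULL, t_n = NULL,
                       min_group_size = 1L) {
  surv <- as_survival_table(surv)
  if (nrow(geno) != nrow(surv))
    stop("genotypes and survival must be aligned (see align_cohort)")
  dosage <- genotype_dosage(geno)
  ord <- order(surv$time, -surv$event)
  ts <- surv$time[ord]
  ev <- surv$event[ord]
  dos <- dosage[ord, , drop = FALSE]
  if (is.null(t_n)) t_n <- max(ts)
  if (is.null(pairs)) pairs <- marker_pairs(colnames(geno))
  ai <- match(pairs[, 1L], colnames(geno))
  bi <- match(pairs[, 2L], colnames(geno))
  if (any(is.na(ai)) || any(is.na(bi)))
    stop("pair refers to a marker absent from the genotype matrix")
  np <- nrow(pairs)
  rank <- rep(NA_real_, np)
  n_groups <- integer(np)
  n_samples <- integer(np)
  any_missing <- anyNA(dos)
  for (i in seq_len(np)) {
    ga <- dos[, ai[i]]
    gb <- dos[, bi[i]]
    code <- ga * 3L + gb
    if (any_missing) {
      keep <- !is.na(code)
      code_i <- code[keep]; ts_i <- ts[keep]; ev_i <- ev[keep]
    } else {
      code_i <- code; ts_i <- ts; ev_i <- ev
    }
    if (min_group_size > 1L) {
      sizes <- tabulate(code_i + 1L, nbins = 9L)
      ok <- sizes[code_i + 1L] >= min_group_size
      code_i <- code_i[ok]; ts_i <- ts_i[ok]; ev_i <- ev_i[ok]
    }
    n_samples[i] <- length(code_i)
    if (length(code_i) == 0L) next
    kern <- .km_area_kernel(code_i, ts_i, ev_i)
    n_groups[i] <- length(kern$codes)
    if (n_groups[i] < 2L || t_n <= 0) next
    rank[i] <- .rank_from_distances(kern$D, kern$codes, t_n)
  }
  data.frame(marker_a = pairs[, 1L], marker_b = pairs[, 2L],
             rank = rank, n_groups = n_groups, n_samples = n_samples,
             stringsAsFactors = FALSE)
}

#' Pairwise genotype-survival interaction scan
#'
#' Evaluates the normalized rank statistic for every unordered marker pair:
#' Kaplan-Meier curves per genotype-combination group, area-between-curves
#' distances, complete-linkage clustering, and cluster-tree distances within
#' genotype equivalence classes, averaged over the two markers and
#' normalized by the cohort's last follow-up time.  When a calibrated
#' [gamma null][calibrate_null()] is supplied, each rank receives an
#' upper-tail p-value, with Benjamini-Hochberg correction for scans of at
#' most `fdr_max_pairs` pairs (beyond that, p-values only order the pairs).
#'
#' @param genotypes Genotype matrix (letter or dosage codes), samples x
#'   markers.
#' @param survival Survival table (`sample`, `time`, `event`) aligned to
#'   `genotypes`; unaligned inputs are aligned on their shared samples.
#' @param null Optional `gamma_null` from [calibrate_null()] or
#'   [read_gamma_null()].
#' @param p_cutoff Optional reporting threshold: keep pairs with
#'   `p_value < p_cutoff`.
#' @param top_k Optional reporting threshold: keep the `top_k` highest
#'   ranks.
#' @param min_group_size Minimum samples per genotype-combination group
#'   (default 1).
#' @param t_n Normalization: `"cohort"` (default) uses the cohort-wide last
#'   follow-up time for every pair, keeping ranks comparable across pairs;
#'   `"family"` uses each pair's own last follow-up time.
#' @param fdr Apply BH correction (default: yes for scans up to
#'   `fdr_max_pairs` pairs).
#' @param fdr_max_pairs Pair count above which FDR is skipped by default
#'   (default 1e5).
#' @param pairs Optional subset of pairs to evaluate (two-column matrix), a
#'   chunk of [marker_pairs()]; chunked scans merge to the full scan.
#' @return An object of class `geninter`: list with `results` (data frame
#'   `marker_a`, `marker_b`, `rank`, `p_value`, `fdr_p`, `n_groups`,
#'   `n_samples`, sorted by decreasing rank), `t_n`, `null`, `n_markers`,
#'   `n_samples` and `call`.  Untestable pairs (fewer than two genotype
#'   groups) carry `NA` rank.
#' @examples
#' cohort <- simulate_cohort(sim_config(200, n_markers = 6, seed = 7))
#' fit <- geninter(cohort$genotypes, cohort$survival)
#' head(fit$results)
#' @export
geninter <- function(genotypes, survival, null = NULL, p_cutoff = NULL,
                     top_k = NULL, min_group_size = 1L,
                     t_n = c("cohort", "family"), fdr = NULL,
                     fdr_max_pairs = 1e5, pairs = NULL) {
  cl <- match.call()
  if (is.character(genotypes) && length(genotypes) == 1L)
    genotypes <- read_genotypes(genotypes)
  survival <- as_survival_table(survival)
  if (!identical(rownames(genotypes), survival$sample)) {
    aligned <- align_cohort(genotypes, survival)
    genotypes <- aligned$genotypes
    survival <- aligned$survival
  }
  t_n <- match.arg(t_n)
  t_n_val <- if (t_n == "cohort") max(survival$time) else NULL
  res <- scan_ranks(genotypes, survival, pairs = pairs, t_n = t_n_val,
                    min_group_size = min_group_size)
  res$p_value <- NA_real_
  res$fdr_p <- NA_real_
  if (!is.null(null)) {
    ok <- !is.na(res$rank)
    res$p_value[ok] <- rank_pvalue(res$rank[ok], null)
    if (is.null(fdr)) fdr <- nrow(res) <= fdr_max_pairs
    if (fdr) res$fdr_p <- bh_fdr(res$p_value)
  }
  res <- res[order(-res$rank, res$marker_a, res$marker_b,
                   na.last = TRUE), ]
  rownames(res) <- NULL
  if (!is.null(p_cutoff))
    res <- res[!is.na(res$p_value) & res$p_value < p_cutoff, , drop = FALSE]
  if (!is.null(top_k))
    res <- utils::head(res, top_k)
  res <- res[c("marker_a", "marker_b", "rank", "p_value", "fdr_p",
               "n_groups", "n_samples")]
  structure(list(results = res, t_n = t_n_val, null = null,
                 n_markers = ncol(genotypes), n_samples = nrow(genotypes),
                 min_group_size = min_group_size, call = cl),
            class = "geninter")
}

#' @export
print.geninter <- function(x, ...) {
  cat("Geninter pairwise survival-interaction scan\n")
  cat("  ", x$n_markers, " markers, ", x$n_samples, " samples, ",
      nrow(x$results), " pair(s) reported\n", sep = "")
  if (!is.null(x$t_n))
    cat("  rank normalization t_n = ", format(x$t_n, digits = 5),
        " months (cohort)\n", sep = "")
  if (is.null(x$null)) {
    cat("  no null model supplied: ranks only, no p-values\n")
  }
  cat("\nTop pairs:\n")
  print(utils::head(x$results, 5L), digits = 4)
  invisible(x)
}

#' @export
summary.geninter <- function(object, n = 10L, ...) {
  res <- object$results
  out <- list(n_pairs = nrow(res),
              n_testable = sum(!is.na(res$rank)),
              rank_quantiles = stats::quantile(res$rank,
                  c(0, 0.5, 0.9, 0.99, 1), na.rm = TRUE),
              n_significant = if (all(is.na(res$fdr_p))) NA_integer_
                              else sum(res$fdr_p < 0.05, na.rm = TRUE),
              top = utils::head(res, n))
  class(out) <- "summary.geninter"
  out
}

#' @export
print.summary.geninter <- function(x, ...) {
  cat(x$n_pairs, "pairs scanned,", x$n_testable, "testable\n")
  cat("rank quantiles:\n")
  print(x$rank_quantiles, digits = 4)
  if (!is.na(x$n_significant))
    cat(x$n_significant, "pair(s) with FDR-corrected p < 0.05\n")
  cat("\nTop pairs:\n")
  print(x$top, digits = 4)
  invisible(x)
}

#' Plot scan diagnostics
#'
#' `which = "ranks"` draws the rank histogram with the fitted gamma null
#' density (when available); `which = "volcano"` draws -log10 p against
#' rank.
#'
#' @param x A `geninter` object.
#' @param which `"ranks"` or `"volcano"`.
#' @param ... Passed to the underlying plot.
#' @return The object, invisibly.
#' @export
plot.geninter <- function(x, which = c("ranks", "volcano"), ...) {
  which <- match.arg(which)
  res <- x$results
  if (which == "ranks") {
    hist(res$rank, breaks = 50, freq = FALSE, xlab = "Rank",
         main = "Rank distribution", ...)
    if (!is.null(x$null))
      curve(stats::dgamma(t, shape = x$null$shape, scale = x$null$scale),
            xname = "t", add = TRUE, col = "red3", lwd = 2)
  } else {
    if (all(is.na(res$p_value)))
      stop("volcano plot needs p-values; supply a null model to geninter()")
    plot(res$rank, -log10(res$p_value), xlab = "Rank",
         ylab = "-log10 p", ...)
  }
  invisible(x)
}

#' Single-marker logrank scan
#'
#' One multi-group logrank test per marker across its (up to three)
#' genotype groups, with BH correction over markers.  Used to verify that
#' members of a synergistic pair show no individual survival effect.
#'
#' @inheritParams geninter
#' @return Data frame with `marker`, `chi_square`, `df`, `p_value`,
#'   `fdr_p`, `n_groups`; monomorphic markers are untestable (`NA`).
#' @export
single_marker_scan <- function(genotypes, survival) {
  survival <- as_survival_table(survival)
  if (!identical(rownames(genotypes), survival$sample)) {
    aligned <- align_cohort(genotypes, survival)
    genotypes <- aligned$genotypes
    survival <- aligned$survival
  }
  res <- lapply(colnames(genotypes), function(mk) {
    g <- genotypes[, mk]
    keep <- !is.na(g)
    groups <- unique(g[keep])
    if (length(groups) < 2L) {
      return(data.frame(marker = mk, chi_square = NA_real_, df = NA_integer_,
                        p_value = NA_real_, n_groups = length(groups)))
    }
    lr <- logrank_test(survival$time[keep], survival$event[keep], g[keep])
    data.frame(marker = mk, chi_square = lr$chi_square, df = lr$df,
               p_value = lr$p_value, n_groups = lr$n_groups)
  })
  out <- do.call(rbind, res)
  out$fdr_p <- bh_fdr(out$p_value)
  out[c("marker", "chi_square", "df", "p_value", "fdr_p", "n_groups")]
}

#' Pairwise logrank scan
#'
#' The comparator method: one multi-group logrank test per marker pair over
#' its (up to nine) genotype-combination groups.
#'
#' @inheritParams geninter
#' @return Data frame with `marker_a`, `marker_b`, `chi_square`, `df`,
#'   `p_value`, `n_groups`; pairs with fewer than two groups are `NA`.
#' @export
pairwise_logrank_scan <- function(genotypes, survival, pairs = NULL) {
  survival <- as_survival_table(survival)
  if (!identical(rownames(genotypes), survival$sample)) {
    aligned <- align_cohort(genotypes, survival)
    genotypes <- aligned$genotypes
    survival <- aligned$survival
  }
  if (is.null(pairs)) pairs <- marker_pairs(colnames(genotypes))
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    ga <- genotypes[, pairs[i, 1L]]
    gb <- genotypes[, pairs[i, 2L]]
    keep <- !is.na(ga) & !is.na(gb)
    combo <- paste(ga[keep], gb[keep], sep = "|")
    out <- data.frame(marker_a = pairs[i, 1L], marker_b = pairs[i, 2L],
                      chi_square = NA_real_, df = NA_integer_,
                      p_value = NA_real_,
                      n_groups = length(unique(combo)))
    if (out$n_groups >= 2L) {
      lr <- logrank_test(survival$time[keep], survival$event[keep], combo)
      out$chi_square <- lr$chi_square
      out$df <- lr$df
      out$p_value <- lr$p_value
    }
    out
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
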