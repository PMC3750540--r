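.pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

.result_frame <- function(results) {
  df <- if (inherits(results, "geninter")) results$results
        else as.data.frame(results)
  need <- c("marker_a", "marker_b", "p_value")
  if (!all(need %in% names(df)))
    stop("results must carry marker_a, marker_b and p_value")
  df
}

#' Classification rates of a scan against simulator ground truth
#'
#' A pair counts as positive only when it is exactly an affected pair of
#' the truth list; a pair sharing one marker with a truth pair is a
#' negative.  Pairs without a p-value (untestable) are never flagged.
#'
#' @param results A `geninter` object, or any data frame with `marker_a`,
#'   `marker_b` and `p_value` (e.g. from [pairwise_logrank_scan()]).
#' @param truth Data frame of affected pairs (`marker_a`, `marker_b`), as
#'   in [simulate_cohort()]'s output.
#' @param p_cutoff Nominal p-value threshold; a pair is flagged when
#'   `p_value < p_cutoff` (default 0.01).
#' @return A list with `tp`, `fp`, `tn`, `fn`, `tpr = TP / (TP + FN)` and
#'   `fpr = FP / (FP + TN)`.
#' @export
operating_point <- function(results, truth, p_cutoff = 0.01) {
  df <- .result_frame(results)
  keys <- .pair_key(df$marker_a, df$marker_b)
  truth_keys <- if (nrow(truth)) .pair_key(truth$marker_a, truth$marker_b)
                else character(0)
  if (!all(truth_keys %in% keys))
    stop("truth pair(s) absent from the scan results")
  is_pos <- keys %in% truth_keys
  flagged <- !is.na(df$p_value) & df$p_value < p_cutoff
  tp <- sum(flagged & is_pos)
  fp <- sum(flagged & !is_pos)
  fn <- sum(!flagged & is_pos)
  tn <- sum(!flagged & !is_pos)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_)
}

#' Empirical ROC curve of one scan
#'
#' Sweeps the p-value threshold over all distinct observed p-values plus 0
#' and 1 (an exact empirical ROC, no binning) and records the true and
#' false positive rates at each threshold.
#'
#' @inheritParams operating_point
#' @param thresholds Optional threshold grid; defaults to the observed
#'   p-values plus 0 and 1.
#' @return Data frame with `threshold`, `tpr`, `fpr`, non-decreasing in
#'   `threshold`.
#' @export
roc_curve <- function(results, truth, thresholds = NULL) {
  df <- .result_frame(results)
  keys <- .pair_key(df$marker_a, df$marker_b)
  truth_keys <- if (nrow(truth)) .pair_key(truth$marker_a, truth$marker_b)
                else character(0)
  if (!all(truth_keys %in% keys))
    stop("truth pair(s) absent from the scan results")
  is_pos <- keys %in% truth_keys
  p <- df$p_value
  if (is.null(thresholds))
    thresholds <- sort(unique(c(0, 1, p[!is.na(p)])))
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  tpr <- fpr <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    flagged <- !is.na(p) & p <= thresholds[i]
    tpr[i] <- if (n_pos > 0) sum(flagged & is_pos) / n_pos else NA_real_
    fpr[i] <- if (n_neg > 0) sum(flagged & !is_pos) / n_neg else NA_real_
  }
  data.frame(threshold = thresholds, tpr = tpr, fpr = fpr)
}

#' Average ROC curve over repeated simulations
#'
#' Evaluates each repetition's scan on the union of all observed p-value
#' thresholds and averages the true/false positive rates pointwise, the
#' standard way of summarising simulation benchmarks.
#'
#' @param results_list List of scan results (one per repetition).
#' @param truth_list List of matching truth tables.
#' @param thresholds Optional shared threshold grid.
#' @return Data frame with `threshold`, `tpr`, `fpr` averaged over
#'   repetitions.
#' @export
roc_evaluate <- function(results_list, truth_list, thresholds = NULL) {
  stopifnot(length(results_list) == length(truth_list),
            length(results_list) >= 1L)
  if (is.null(thresholds)) {
    pv <- unlist(lapply(results_list,
                        function(r) .result_frame(r)$p_value))
    thresholds <- sort(unique(c(0, 1, pv[!is.na(pv)])))
  }
  curves <- mapply(function(r, tr) roc_curve(r, tr, thresholds = thresholds),
                   results_list, truth_list, SIMPLIFY = FALSE)
  data.frame(threshold = thresholds,
             tpr = rowMeans(sapply(curves, `[[`, "tpr")),
             fpr = rowMeans(sapply(curves, `[[`, "fpr")))
}

#' Simulation benchmark at a nominal p-value cutoff
#'
#' Repeats the full study loop: simulate a cohort with known affected
#' pairs, scan all marker pairs, score ranks against a simulation-calibrated
#' gamma null (or, for the comparator, take multi-group logrank p-values),
#' and measure the true/false positive rates at the nominal cutoff,
#' averaged over repetitions.
#'
#' @param n_samples Cohort size per repetition (default 10000).
#' @param n_markers Marker count (default 140, i.e. 9730 pairs).
#' @param n_affected Number of disjoint affected pairs per cohort
#'   (default 5).
#' @param n_reps Number of seeded repetitions (default 5).
#' @param p_cutoff Nominal p-value threshold (default 0.01).
#' @param seed Master seed; calibration and repetition seeds derive from
#'   it.
#' @param method `"geninter"` (rank + gamma null) or `"logrank"`
#'   (comparator).
#' @param calibration_n Cohort size of the null calibration (default: match
#'   `n_samples`).
#' @param null Optional pre-computed `gamma_null` reused across
#'   repetitions.
#' @return A list with `tpr`, `fpr` (averages over repetitions, as
#'   fractions), `per_rep` (data frame of per-repetition counts and rates),
#'   `null`, and `scans`/`truths` for downstream ROC analysis.
#' @export
simulation_benchmark <- function(n_samples = 10000L, n_markers = 140L,
                                 n_affected = 5L, n_reps = 5L,
                                 p_cutoff = 0.01, seed = 1L,
                                 method = c("geninter", "logrank"),
                                 calibration_n = n_samples, null = NULL) {
  method <- match.arg(method)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_reps + 1L)
  if (method == "geninter" && is.null(null)) {
    null <- calibrate_null(calibration_n, n_markers, seed = seeds[1L])
  }
  scans <- vector("list", n_reps)
  truths <- vector("list", n_reps)
  per_rep <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cohort <- simulate_cohort(sim_config(
      n_samples = n_samples, n_markers = n_markers,
      n_affected_pairs = n_affected, seed = seeds[r + 1L]))
    res <- if (method == "geninter") {
      geninter(cohort$genotypes, cohort$survival, null = null)
    } else {
      pairwise_logrank_scan(cohort$genotypes, cohort$survival)
    }
    op <- operating_point(res, cohort$truth, p_cutoff = p_cutoff)
    scans[[r]] <- .result_frame(res)
    truths[[r]] <- cohort$truth
    per_rep[[r]] <- data.frame(rep = r, seed = seeds[r + 1L],
                               tp = op$tp, fp = op$fp, tn = op$tn,
                               fn = op$fn, tpr = op$tpr, fpr = op$fpr)
  }
  per_rep <- do.call(rbind, per_rep)
  list(tpr = mean(per_rep$tpr), fpr = mean(per_rep$fpr),
       per_rep = per_rep, null = null, scans = scans, truths = truths,
       p_cutoff = p_cutoff, method = method)
}
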