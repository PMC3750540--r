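#' Simulation configuration for genotype-survival cohorts
#'
#' Defines the generating model used throughout calibration and
#' benchmarking.  Genotypes are drawn independently per marker from
#' per-marker genotype probabilities; null survival times are uniform on
#' (0, `max_survival`] months (mean `max_survival / 2`); samples carrying
#' the rare (minor-allele) homozygote at BOTH markers of an affected pair
#' have their survival redrawn from an exponential distribution with mean
#' `affected_mean` months, truncated at `max_survival`; finally an exact
#' fraction `censoring_fraction` of the cohort, chosen uniformly at random,
#' is flagged censored at its drawn time.
#'
#' @param n_samples Cohort size.
#' @param n_markers Number of markers (ignored when `genotype_freqs` or
#'   `reference_genotypes` fixes it).
#' @param genotype_freqs Optional markers x 3 matrix of (AA, AB, BB)
#'   probabilities per marker, rows summing to 1.
#' @param reference_genotypes Optional genotype matrix from which
#'   frequencies are estimated via [estimate_frequencies()].
#' @param maf_threshold Minor-allele-frequency filter used when estimating
#'   frequencies from a reference (default 0.05; markers must exceed it).
#' @param max_survival Maximum follow-up in months (default 360).
#' @param n_affected_pairs Number of disjoint marker pairs with an induced
#'   synergistic effect (default 0 = null cohort).
#' @param affected_mean Mean survival in months of the affected
#'   double-rare-homozygote group (default 22.5).
#' @param censoring_fraction Fraction of the cohort censored (default 0.20).
#' @param seed Integer seed; every random draw of [simulate_cohort()]
#'   derives from it.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_samples, n_markers = NULL, genotype_freqs = NULL,
                       reference_genotypes = NULL, maf_threshold = 0.05,
                       max_survival = 360, n_affected_pairs = 0L,
                       affected_mean = 22.5, censoring_fraction = 0.20,
                       seed = 1L) {
  if (!is.null(reference_genotypes)) {
    genotype_freqs <- estimate_frequencies(reference_genotypes, maf_threshold)
  }
  if (!is.null(genotype_freqs)) {
    genotype_freqs <- as.matrix(genotype_freqs)
    if (ncol(genotype_freqs) != 3L)
      stop("genotype_freqs must have 3 columns (AA, AB, BB)")
    if (any(genotype_freqs < 0) ||
        any(abs(rowSums(genotype_freqs) - 1) > 1e-8))
      stop("per-marker genotype probabilities must be non-negative and sum to 1")
    n_markers <- nrow(genotype_freqs)
  }
  if (is.null(n_markers)) stop("n_markers is required without genotype_freqs")
  n_markers <- as.integer(n_markers)
  n_samples <- as.integer(n_samples)
  if (n_samples < 1L || n_markers < 1L) stop("need n_samples >= 1, n_markers >= 1")
  if (2L * n_affected_pairs > n_markers)
    stop("each marker may appear in at most one affected pair: need 2 * n_affected_pairs <= n_markers")
  if (censoring_fraction < 0 || censoring_fraction >= 1)
    stop("censoring_fraction must be in [0, 1)")
  if (max_survival <= 0 || affected_mean <= 0)
    stop("max_survival and affected_mean must be positive")
  structure(list(n_samples = n_samples, n_markers = n_markers,
                 genotype_freqs = genotype_freqs,
                 maf_threshold = maf_threshold,
                 max_survival = max_survival,
                 n_affected_pairs = as.integer(n_affected_pairs),
                 affected_mean = affected_mean,
                 censoring_fraction = censoring_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Empirical genotype frequencies of a reference cohort
#'
#' Counts (AA, AB, BB) fractions per marker among called genotypes and
#' retains markers whose minor allele frequency strictly exceeds the
#' threshold.  The minor allele is determined per marker; MAF =
#' (2 * minor homozygotes + heterozygotes) / (2 * called).
#'
#' @param geno A genotype matrix (letter codes).
#' @param maf_threshold MAF filter, default 0.05.
#' @return A markers x 3 matrix with columns AA, AB, BB and an `maf`
#'   attribute; markers failing the filter are dropped.
#' @export
estimate_frequencies <- function(geno, maf_threshold = 0.05) {
  if (nrow(geno) == 0L) stop("reference genotype matrix is empty")
  counts <- t(apply(geno, 2L, function(col) {
    c(sum(col == "AA", na.rm = TRUE), sum(col == "AB", na.rm = TRUE),
      sum(col == "BB", na.rm = TRUE))
  }))
  called <- rowSums(counts)
  if (any(called == 0L)) stop("marker with no called genotypes")
  freq <- counts / called
  colnames(freq) <- GENOTYPE_CODES
  f_b <- (2 * counts[, 3L] + counts[, 2L]) / (2 * called)
  maf <- pmin(f_b, 1 - f_b)
  keep <- maf > maf_threshold
  if (!any(keep))
    stop("no marker exceeds the MAF threshold of ", maf_threshold)
  out <- freq[keep, , drop = FALSE]
  attr(out, "maf") <- maf[keep]
  out
}

# Rare (minor-allele) homozygote column index per marker: BB when the B
# allele is the minor one, AA otherwise.
.rare_homozygote <- function(freqs) {
  f_b <- freqs[, "BB"] + freqs[, "AB"] / 2
  ifelse(f_b <= 0.5, "BB", "AA")
}

#' Simulate a genotype-survival cohort with known ground truth
#'
#' See [sim_config()] for the generating model.  When the configuration
#' carries no genotype frequencies, per-marker minor allele frequencies are
#' drawn uniformly on (0.05, 0.5) and genotype probabilities follow
#' Hardy-Weinberg proportions.  Affected pairs are disjoint random marker
#' pairs; the induced effect applies to samples homozygous for the minor
#' allele at both markers of a pair.  All randomness derives from
#' `config$seed`, so equal configurations yield identical cohorts.
#'
#' @param config A `sim_config`.
#' @return An object of class `sim_cohort`: list with `genotypes` (letter
#'   matrix), `survival` (sample/time/event table), `truth` (data frame of
#'   affected pairs `marker_a`, `marker_b`), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  m <- config$n_markers
  freqs <- config$genotype_freqs
  if (is.null(freqs)) {
    maf <- runif(m, 0.05, 0.5)
    freqs <- cbind(AA = (1 - maf)^2, AB = 2 * maf * (1 - maf), BB = maf^2)
  }
  marker_ids <- sprintf("M%03d", seq_len(m))
  sample_ids <- sprintf("S%05d", seq_len(n))
  rownames(freqs) <- marker_ids

  dosage <- matrix(0L, n, m, dimnames = list(sample_ids, marker_ids))
  for (j in seq_len(m)) {
    dosage[, j] <- sample.int(3L, n, replace = TRUE, prob = freqs[j, ]) - 1L
  }

  time <- runif(n, 0, config$max_survival)

  truth <- data.frame(marker_a = character(0), marker_b = character(0),
                      stringsAsFactors = FALSE)
  if (config$n_affected_pairs > 0L) {
    perm <- sample.int(m)
    rare <- .rare_homozygote(freqs)
    rare_dosage <- ifelse(rare == "BB", 2L, 0L)
    rate <- 1 / config$affected_mean
    p_trunc <- pexp(config$max_survival, rate)
    for (k in seq_len(config$n_affected_pairs)) {
      a <- perm[2L * k - 1L]
      b <- perm[2L * k]
      hit <- dosage[, a] == rare_dosage[a] & dosage[, b] == rare_dosage[b]
      if (!any(hit)) {
        warning("affected pair (", marker_ids[a], ", ", marker_ids[b],
                ") has no double-rare-homozygote carrier in this cohort")
      } else {
        # exponential survival, mean affected_mean, truncated at max_survival
        time[hit] <- qexp(runif(sum(hit)) * p_trunc, rate)
      }
      pair <- sort(c(marker_ids[a], marker_ids[b]))
      truth[k, ] <- pair
    }
    truth <- truth[order(truth$marker_a, truth$marker_b), , drop = FALSE]
    rownames(truth) <- NULL
  }

  event <- rep(1L, n)
  n_cens <- round(config$censoring_fraction * n)
  if (n_cens > 0L) event[sample.int(n, n_cens)] <- 0L

  geno <- matrix(GENOTYPE_CODES[dosage + 1L], n, m,
                 dimnames = list(sample_ids, marker_ids))
  surv <- data.frame(sample = sample_ids, time = time, event = event,
                     stringsAsFactors = FALSE)
  structure(list(genotypes = geno, survival = surv, truth = truth,
                 config = config, genotype_freqs = freqs),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated cohort: ", nrow(x$genotypes), " samples x ",
      ncol(x$genotypes), " markers, ",
      sum(x$survival$event == 0L), " censored, ",
      nrow(x$truth), " affected pair(s)\n", sep = "")
  invisible(x)
}
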