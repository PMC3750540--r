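#' Fit a gamma null distribution to rank statistics by moment matching
#'
#' Under the null hypothesis of no survival effect the rank statistic of a
#' marker pair is well approximated by a gamma distribution.  The shape and
#' scale are set from the sample mean and variance of a collection of null
#' ranks: `k = mean^2 / var`, `theta = var / mean`, which reproduce the
#' fitting sample's first two moments exactly (`k * theta = mean`,
#' `k * theta^2 = var`).
#'
#' @param ranks Numeric vector of null ranks (>= 100 values, all >= 0, with
#'   positive variance).
#' @param calibration Optional list of metadata (cohort size, marker count,
#'   seed) recorded with the fit.
#' @return An object of class `gamma_null`: list with `shape`, `scale`,
#'   `n_ranks`, `mean`, `var` and `calibration`.
#' @export
fit_gamma <- function(ranks, calibration = NULL) {
  ranks <- as.numeric(ranks)
  if (length(ranks) < 100L)
    stop("need at least 100 null ranks to fit the gamma null")
  if (any(!is.finite(ranks)) || any(ranks < 0))
    stop("null ranks must be finite and non-negative")
  mu <- mean(ranks)
  s2 <- stats::var(ranks)
  if (s2 <= 0) stop("null ranks have zero variance; cannot fit a gamma")
  structure(list(shape = mu^2 / s2, scale = s2 / mu,
                 n_ranks = length(ranks), mean = mu, var = s2,
                 calibration = calibration),
            class = "gamma_null")
}

#' @export
print.gamma_null <- function(x, ...) {
  cat("Gamma null distribution: shape k = ", format(x$shape, digits = 5),
      ", scale theta = ", format(x$scale, digits = 5),
      " (fit on ", x$n_ranks, " null ranks)\n", sep = "")
  if (!is.null(x$calibration)) {
    cal <- x$calibration
    cat("  calibration: n_samples = ", cal$n_samples,
        ", n_markers = ", cal$n_markers,
        ", seed = ", cal$seed, "\n", sep = "")
  }
  invisible(x)
}

#' Upper-tail p-value of a rank under the gamma null
#'
#' `p = 1 - F_Gamma(rank; k, theta)`: large ranks (strong combinatorial
#' survival separation) map to small p-values.
#'
#' @param rank Rank value(s) >= 0.
#' @param null A `gamma_null`.
#' @return Upper-tail probabilities, same length as `rank`.
#' @export
rank_pvalue <- function(rank, null) {
  stopifnot(inherits(null, "gamma_null"))
  if (any(rank < 0, na.rm = TRUE)) stop("ranks must be non-negative")
  stats::pgamma(rank, shape = null$shape, scale = null$scale,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' adjusted values are >= raw values and capped at 1.
#'
#' @param p P-values in [0, 1] (NA allowed for untestable pairs).
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Calibrate the gamma null to a cohort size by simulation
#'
#' Simulates a fully null cohort (no affected pairs) of the requested size,
#' computes the rank of every marker pair, and fits the gamma null by
#' moment matching.  Because the null rank distribution shifts with cohort
#' size, the calibration cohort should match the size of the cohort being
#' scanned.
#'
#' @param n_samples Calibration cohort size.
#' @param n_markers Calibration marker count (C(n_markers, 2) null ranks).
#' @param seed Integer seed for the calibration simulation.
#' @param config Optional `sim_config` overriding the default null
#'   configuration; its `n_affected_pairs` must be 0.
#' @param min_group_size Passed to the scan.
#' @return A `gamma_null` with calibration metadata and the null `ranks`
#'   retained for diagnostics.
#' @export
calibrate_null <- function(n_samples, n_markers = 140L, seed = 1L,
                           config = NULL, min_group_size = 1L) {
  if (is.null(config)) {
    config <- sim_config(n_samples = n_samples, n_markers = n_markers,
                         seed = seed)
  }
  if (config$n_affected_pairs != 0L)
    stop("calibration requires a null configuration (0 affected pairs)")
  cohort <- simulate_cohort(config)
  ranks <- scan_ranks(cohort$genotypes, cohort$survival,
                      min_group_size = min_group_size)$rank
  ranks <- ranks[!is.na(ranks)]
  null <- fit_gamma(ranks, calibration = list(
    n_samples = config$n_samples, n_markers = config$n_markers,
    seed = config$seed))
  null$ranks <- ranks
  null
}

#' Save / load a gamma null as a JSON sidecar
#'
#' Stores shape, scale and calibration metadata so scans can reuse a
#' calibration without re-simulating.
#'
#' @param null A `gamma_null`.
#' @param path JSON file path.
#' @return `write_gamma_null` returns the path invisibly;
#'   `read_gamma_null` returns a `gamma_null`.
#' @export
write_gamma_null <- function(null, path) {
  stopifnot(inherits(null, "gamma_null"))
  jsonlite::write_json(list(shape = null$shape, scale = null$scale,
                            n_ranks = null$n_ranks, mean = null$mean,
                            var = null$var, calibration = null$calibration),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gamma_null
#' @export
read_gamma_null <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(shape = x$shape, scale = x$scale, n_ranks = x$n_ranks,
                 mean = x$mean, var = x$var, calibration = x$calibration),
            class = "gamma_null")
}

#' Plot a gamma null fit against its calibration ranks
#'
#' @param x A `gamma_null` holding diagnostic `ranks` (as returned by
#'   [calibrate_null()]).
#' @param ... Passed to [graphics::hist()].
#' @return The null, invisibly.
#' @export
plot.gamma_null <- function(x, ...) {
  if (is.null(x$ranks))
    stop("no calibration ranks stored; plot requires calibrate_null() output")
  hist(x$ranks, freq = FALSE, breaks = 50,
       xlab = "Null rank", main = "Gamma null calibration", ...)
  curve(stats::dgamma(t, shape = x$shape, scale = x$scale), xname = "t",
        add = TRUE, col = "red3", lwd = 2)
  invisible(x)
}
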