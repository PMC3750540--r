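#' Partial rank of one attribute
#'
#' The partial rank of attribute `j` (a single marker of the tuple) is the
#' maximum class distance over the equivalence classes of `j`: the largest
#' cluster-tree separation between two curves that agree at marker `j` and
#' therefore differ only through the other marker(s).  A large partial rank
#' means the remaining markers modulate survival strongly within some fixed
#' genotype of marker `j`.
#'
#' @param family A `curve_family`.
#' @param tree The family's `curve_dendrogram` (built from its distance
#'   matrix).
#' @param attribute Attribute index `j` in `1..e`.
#' @return Partial rank in months (0 when all classes are singletons).
#' @export
partial_rank <- function(family, tree, attribute) {
  classes <- equivalence_classes(family, attribute)
  max(vapply(classes, class_distance, numeric(1), tree = tree))
}

#' Geninter rank of a curve family
#'
#' Runs the full per-family pipeline: area-distance matrix, complete-linkage
#' dendrogram, partial rank per attribute, and the final normalized rank
#' `(sum of partial ranks) / (e * t_n)`, a dimensionless value in [0, 1].
#' Larger ranks indicate stronger combinatorial separation of the survival
#' curves.
#'
#' @param family A `curve_family` with at least 2 curves and `t_n > 0`.
#' @param t_n Normalizing last time point in months.  Defaults to the
#'   family's own last follow-up time; pass the cohort-wide maximum follow-up
#'   to make ranks comparable across families (as the pairwise scan does).
#' @return An object of class `rank_result`: list with `marker_tuple`,
#'   `rank`, `partial_ranks`, `n_groups`, `n_samples`, `t_n`.
#' @export
geninter_rank <- function(family, t_n = NULL) {
  if (is.null(t_n)) t_n <- family$t_n
  m <- length(family$curves)
  if (m < 2L || t_n <= 0)
    stop("untestable family: need >= 2 curves and t_n > 0")
  tree <- complete_linkage(distance_matrix(family))
  e <- ncol(family$labels)
  pr <- vapply(seq_len(e), function(j) partial_rank(family, tree, j),
               numeric(1))
  names(pr) <- family$markers
  structure(list(marker_tuple = family$markers,
                 rank = sum(pr) / (e * t_n),
                 partial_ranks = pr,
                 n_groups = m,
                 n_samples = family$n_samples,
                 t_n = t_n),
            class = "rank_result")
}

#' @export
print.rank_result <- function(x, ...) {
  cat("Geninter rank for (", paste(x$marker_tuple, collapse = ", "), "): ",
      format(x$rank, digits = 5), "\n", sep = "")
  cat("  partial ranks (months):",
      paste(format(x$partial_ranks, digits = 5), collapse = ", "), "\n")
  cat("  groups:", x$n_groups, " samples:", x$n_samples,
      " t_n:", format(x$t_n, digits = 5), "\n")
  invisible(x)
}

# Fast per-pair rank from the C++ kernel output: D is the area-distance
# matrix over the groups present, `codes` their 0..8 combination codes
# (code = 3 * dosage_a + dosage_b).  Mirrors the module pipeline
# (complete_linkage -> partial_rank -> normalization) on precomputed D.
.rank_from_distances <- function(D, codes, t_n) {
  m <- nrow(D)
  hc <- stats::hclust(stats::as.dist(D), method = "complete")
  coph <- as.matrix(stats::cophenetic(hc))
  off <- coph
  diag(off) <- Inf
  lh <- apply(off, 1L, min)
  td <- matrix(0, m, m)
  for (j in seq_len(m - 1L)) {
    for (k in seq.int(j + 1L, m)) {
      td[j, k] <- td[k, j] <- .eq3_distance(coph[j, k], lh[j], lh[k])
    }
  }
  att <- cbind(codes %/% 3L, codes %% 3L)
  pr <- numeric(2L)
  for (a in 1:2) {
    best <- 0
    for (v in unique(att[, a])) {
      w <- which(att[, a] == v)
      if (length(w) > 1L) best <- max(best, max(td[w, w]))
    }
    pr[a] <- best
  }
  sum(pr) / (2 * t_n)
}
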