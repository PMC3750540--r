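#' Kaplan-Meier curve evaluated on a shared time grid
#'
#' Product-limit estimate of the survival function for one group, evaluated
#' as a right-continuous step function on a supplied grid.  At time 0 all
#' patients are alive, so the curve starts at 1.  Ties between events and
#' censorings at the same time are resolved with events first (the standard
#' KM convention).
#'
#' @param time Follow-up times in months.
#' @param event Event indicator, 1 = event, 0 = censored.
#' @param grid Strictly increasing evaluation grid starting at 0.  Defaults
#'   to the sorted union of 0 and the observed times.
#' @param label Optional label identifying the group (e.g. a genotype
#'   combination).
#' @return An object of class `km_curve`: list with `time` (the grid),
#'   `surv`, `n` and `label`.
#' @examples
#' km <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
#' km$surv  # 1, 2/3, 2/3, 0
#' @export
kaplan_meier <- function(time, event, grid = NULL, label = NULL) {
  if (length(time) == 0L) stop("empty group: no survival records")
  if (length(event) != length(time)) stop("time and event lengths differ")
  if (is.null(grid)) grid <- sort(unique(c(0, time)))
  if (grid[1L] != 0 || is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing and start at 0")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  # right-continuous evaluation: S(t) includes drops occurring at t
  step_t <- fit$time
  step_s <- fit$surv
  idx <- findInterval(grid, step_t)
  surv <- c(1, step_s)[idx + 1L]
  structure(list(time = grid, surv = surv, n = length(time), label = label),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve",
      if (!is.null(x$label)) paste0(" [", paste(x$label, collapse = ","), "]"),
      ": n = ", x$n, ", ", length(x$time), " grid points, final S = ",
      format(x$surv[length(x$surv)], digits = 4), "\n", sep = "")
  invisible(x)
}

#' Build the curve family of a marker tuple
#'
#' Groups samples by their genotype combination at the selected markers and
#' estimates one Kaplan-Meier curve per observed combination.  Samples
#' missing a call at any selected marker are dropped for this family only.
#' All curves share a common grid: the sorted union of 0 and the observed
#' follow-up times of the included samples; `t_n` is the grid's last time.
#'
#' @param geno Genotype matrix (letter codes), samples x markers.
#' @param surv Survival table aligned to `geno` (same sample order).
#' @param markers Marker IDs (or column indices) forming the tuple; defaults
#'   to all columns of `geno`.
#' @param min_group_size Minimum samples for a combination to contribute a
#'   curve (default 1).
#' @return An object of class `curve_family`: list with `curves` (list of
#'   `km_curve`), `labels` (m x e character matrix of genotype combinations),
#'   `markers`, `grid`, `t_n`, `n_samples`.
#' @export
build_family <- function(geno, surv, markers = colnames(geno),
                         min_group_size = 1L) {
  surv <- as_survival_table(surv)
  if (nrow(geno) != nrow(surv))
    stop("genotypes and survival must be aligned (see align_cohort)")
  sub <- geno[, markers, drop = FALSE]
  e <- ncol(sub)
  if (e < 1L) stop("select at least one marker")
  keep <- rowSums(is.na(sub)) == 0L
  sub <- sub[keep, , drop = FALSE]
  time <- surv$time[keep]
  event <- surv$event[keep]
  combo <- apply(sub, 1L, paste, collapse = "|")
  sizes <- table(combo)
  use <- names(sizes)[sizes >= min_group_size]
  if (length(use) == 0L)
    stop("untestable family: no genotype combination reaches min_group_size")
  in_use <- combo %in% use
  time <- time[in_use]; event <- event[in_use]; combo <- combo[in_use]
  grid <- sort(unique(c(0, time)))
  use <- sort(use)
  curves <- lapply(use, function(g) {
    sel <- combo == g
    kaplan_meier(time[sel], event[sel], grid = grid,
                 label = strsplit(g, "|", fixed = TRUE)[[1L]])
  })
  labels <- do.call(rbind, lapply(curves, `[[`, "label"))
  colnames(labels) <- colnames(sub)
  structure(list(curves = curves, labels = labels,
                 markers = colnames(sub), grid = grid,
                 t_n = max(grid), n_samples = length(time)),
            class = "curve_family")
}

#' @export
print.curve_family <- function(x, ...) {
  cat("Curve family over markers ", paste(x$markers, collapse = " x "),
      ": ", length(x$curves), " genotype-combination curves, ",
      x$n_samples, " samples, t_n = ", format(x$t_n, digits = 5),
      " months\n", sep = "")
  sizes <- vapply(x$curves, `[[`, numeric(1), "n")
  lab <- apply(x$labels, 1L, paste, collapse = ",")
  cat(paste0("  (", lab, "): n = ", sizes, collapse = "\n"), "\n")
  invisible(x)
}

#' Plot a curve family
#'
#' Draws the Kaplan-Meier step curves of all genotype-combination groups.
#'
#' @param x A `curve_family`.
#' @param col Colours recycled over curves.
#' @param ... Passed to `plot()`.
#' @return The family, invisibly.
#' @export
plot.curve_family <- function(x, col = seq_along(x$curves), ...) {
  plot(NULL, xlim = range(x$grid), ylim = c(0, 1),
       xlab = "Follow-up (months)", ylab = "Survival probability", ...)
  col <- rep_len(col, length(x$curves))
  for (i in seq_along(x$curves))
    lines(x$curves[[i]]$time, x$curves[[i]]$surv, type = "s", col = col[i])
  legend("bottomleft", legend = apply(x$labels, 1L, paste, collapse = ","),
         col = col, lty = 1, cex = 0.8, bty = "n")
  invisible(x)
}

#' Multi-group logrank test
#'
#' Standard (unweighted) logrank test comparing the survival distributions
#' of two or more groups, with the chi-square statistic referred to
#' `#groups - 1` degrees of freedom.
#'
#' @param time Follow-up times in months.
#' @param event Event indicator, 1 = event, 0 = censored.
#' @param group Group membership (factor or vector coercible to one).
#' @return A list with `chi_square`, `df`, `p_value`, `n_groups`.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2L)
    stop("untestable: logrank needs at least 2 non-empty groups")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  list(chi_square = unname(fit$chisq), df = df,
       p_value = stats::pchisq(fit$chisq, df, lower.tail = FALSE),
       n_groups = nlevels(group))
}
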