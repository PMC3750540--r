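#' Read a genotype matrix from a tab-separated file
#'
#' The expected layout is a header line `sample<TAB>marker1<TAB>...` followed
#' by one row per sample.  Calls may be letter codes (`AA`, `AB`, `BB`) or
#' minor-allele dosage codes (`0`, `1`, `2`); dosages are normalized to
#' letter codes (`0` = `AA`, `1` = `AB`, `2` = `BB`).  Any other token is
#' treated as missing, and the number of such cells is reported in a single
#' warning.
#'
#' @param path Path to a genotype TSV file.
#' @return A character matrix with samples as rows, markers as columns and
#'   entries in `AA`/`AB`/`BB`/`NA`.
#' @seealso [write_genotypes()], [read_survival()], [align_cohort()]
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   check.names = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("genotype file is empty or has no marker columns: ", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop("duplicate sample IDs in genotype file")
  geno <- as.matrix(df[, -1L, drop = FALSE])
  rownames(geno) <- ids
  as_genotype_matrix(geno)
}

#' Normalize a genotype matrix to letter codes
#'
#' Accepts letter calls (`AA`/`AB`/`BB`) and minor-allele dosage calls
#' (`0`/`1`/`2`) and returns letter codes; anything else becomes `NA` with a
#' warning giving the affected cell count.
#'
#' @param geno A character matrix with sample row names and marker column
#'   names.
#' @return A validated character genotype matrix.
#' @export
as_genotype_matrix <- function(geno) {
  geno <- as.matrix(geno)
  if (is.null(rownames(geno)) || is.null(colnames(geno)))
    stop("genotype matrix needs sample row names and marker column names")
  if (anyDuplicated(rownames(geno))) stop("duplicate sample IDs")
  if (anyDuplicated(colnames(geno))) stop("duplicate marker IDs")
  x <- toupper(trimws(as.character(geno)))
  out <- rep(NA_character_, length(x))
  out[x %in% GENOTYPE_CODES] <- x[x %in% GENOTYPE_CODES]
  dosage <- x %in% c("0", "1", "2")
  out[dosage] <- GENOTYPE_CODES[as.integer(x[dosage]) + 1L]
  known_na <- is.na(geno) | x %in% c("NA", "")
  n_bad <- sum(is.na(out) & !known_na)
  if (n_bad > 0L)
    warning(n_bad, " unrecognized genotype call(s) set to missing")
  matrix(out, nrow = nrow(geno), dimnames = dimnames(geno))
}

#' Read a survival table from a tab-separated file
#'
#' Expects columns `sample`, `time` (follow-up in months) and `event`
#' (1 = event observed, 0 = censored).
#'
#' @param path Path to a survival TSV file.
#' @return A `data.frame` with columns `sample`, `time`, `event`.
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop("survival file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t")
  need <- c("sample", "time", "event")
  if (!all(need %in% names(df)))
    stop("survival file must have columns: ", paste(need, collapse = ", "))
  as_survival_table(df[need])
}

#' Validate a survival table
#'
#' @param df A data frame with columns `sample`, `time`, `event`.
#' @return The validated data frame (sample coerced to character).
#' @export
as_survival_table <- function(df) {
  df <- as.data.frame(df)
  df$sample <- as.character(df$sample)
  df$time <- as.numeric(df$time)
  df$event <- as.numeric(df$event)
  if (anyDuplicated(df$sample)) stop("duplicate sample IDs in survival table")
  if (any(!is.finite(df$time)) || any(df$time < 0))
    stop("survival times must be finite and non-negative")
  if (!all(df$event %in% c(0, 1)))
    stop("event indicator must be 0 (censored) or 1 (event)")
  df$event <- as.integer(df$event)
  rownames(df) <- NULL
  df
}

#' Write a genotype matrix / survival table as TSV
#'
#' @param geno A genotype matrix as returned by [read_genotypes()].
#' @param df A survival table as returned by [read_survival()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  out <- data.frame(sample = rownames(geno), geno, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
write_survival <- function(df, path) {
  write.table(df[c("sample", "time", "event")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align genotype and survival inputs on their common samples
#'
#' Restricts both inputs to the intersection of their sample IDs, in the
#' genotype matrix's order.
#'
#' @param geno A genotype matrix.
#' @param surv A survival table.
#' @return A list with elements `genotypes` and `survival`, row-aligned.
#' @export
align_cohort <- function(geno, surv) {
  surv <- as_survival_table(surv)
  common <- intersect(rownames(geno), surv$sample)
  if (length(common) == 0L)
    stop("no samples shared between genotype and survival inputs")
  geno <- geno[common, , drop = FALSE]
  surv <- surv[match(common, surv$sample), , drop = FALSE]
  rownames(surv) <- NULL
  message(length(common), " samples aligned across genotype and survival inputs")
  list(genotypes = geno, survival = surv)
}

# Integer dosage view used by the scan kernels: 0 = AA, 1 = AB, 2 = BB, NA
# for missing.
genotype_dosage <- function(geno) {
  d <- match(geno, GENOTYPE_CODES) - 1L
  matrix(d, nrow = nrow(geno), dimnames = dimnames(geno))
}

#' Write scan results as TSV
#'
#' Columns: `marker_a`, `marker_b`, `rank`, `p_value`, `fdr_p`, `n_groups`,
#' `n_samples`.
#'
#' @param x A `geninter` scan object or its `results` data frame.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_results <- function(x, path) {
  df <- if (inherits(x, "geninter")) x$results else as.data.frame(x)
  need <- c("marker_a", "marker_b", "rank", "p_value", "fdr_p",
            "n_groups", "n_samples")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("result table lacks columns: ", paste(missing_cols, collapse = ", "))
  write.table(df[need], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
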