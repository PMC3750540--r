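#' Complete-linkage dendrogram over a curve family
#'
#' Farthest-neighbour agglomerative clustering of the family's curves using
#' the area-distance matrix.  The inter-cluster distance is the maximum
#' pairwise distance between members, so merge heights are non-decreasing.
#' The height of a leaf is defined as the height of its parent merge (its
#' first merge), and the height of the last common ancestor of two leaves
#' equals their cophenetic distance.
#'
#' @param D Symmetric non-negative distance matrix with labelled dimnames,
#'   or a `curve_family` (whose [distance_matrix()] is used).
#' @param method Linkage passed to [stats::hclust()]; complete linkage is
#'   the default and the only variant exercised by the rank statistic's
#'   validation.
#' @return An object of class `curve_dendrogram`: list with the `hclust`
#'   fit, `labels`, `leaf_heights` and the cophenetic matrix `lca_heights`.
#' @export
complete_linkage <- function(D, method = "complete") {
  if (inherits(D, "curve_family")) D <- distance_matrix(D)
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-8))
    stop("distance matrix must be symmetric")
  if (any(D < 0)) stop("distance matrix must be non-negative")
  if (nrow(D) < 2L) stop("need at least 2 curves to cluster")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- seq_len(nrow(D))
  hc <- stats::hclust(stats::as.dist(D), method = method)
  coph <- as.matrix(stats::cophenetic(hc))
  lab <- rownames(coph)
  off <- coph
  diag(off) <- Inf
  leaf_heights <- apply(off, 1L, min)
  structure(list(hclust = hc, labels = lab,
                 leaf_heights = leaf_heights, lca_heights = coph),
            class = "curve_dendrogram")
}

#' @export
print.curve_dendrogram <- function(x, ...) {
  cat("Complete-linkage dendrogram over", length(x$labels), "curves\n")
  cat("  merge heights:", paste(format(x$hclust$height, digits = 4),
                                collapse = ", "), "\n")
  invisible(x)
}

.resolve_leaf <- function(tree, leaf) {
  if (length(leaf) > 1L) leaf <- paste(leaf, collapse = ",")
  i <- match(leaf, tree$labels)
  if (is.na(i)) stop("unknown leaf: ", leaf)
  i
}

#' Cluster-tree distance between two leaves
#'
#' Let `H1`, `H2` be the heights of the two leaves (each the height of its
#' parent merge) and `Hmax` the height of their last common ancestor.  The
#' distance is `|Hmax - H1 - H2|` when `Hmax` differs from both leaf
#' heights, `|Hmax - H1|` when `Hmax = H2`, `|Hmax - H2|` when `Hmax = H1`,
#' and 0 when all three coincide (siblings).  On families built from
#' survival data the value lies in `[0, t_n]`.
#'
#' @param tree A `curve_dendrogram`.
#' @param leaf1,leaf2 Leaf labels (either the collapsed `"AA,BB"` form or a
#'   character vector of features).
#' @return Distance in months.
#' @export
tree_distance <- function(tree, leaf1, leaf2) {
  i <- .resolve_leaf(tree, leaf1)
  j <- .resolve_leaf(tree, leaf2)
  if (i == j) return(0)
  h1 <- unname(tree$leaf_heights[i])
  h2 <- unname(tree$leaf_heights[j])
  hmax <- tree$lca_heights[i, j]
  .eq3_distance(hmax, h1, h2)
}

.height_eq <- function(a, b) abs(a - b) <= 1e-9 * max(1, abs(a), abs(b))

.eq3_distance <- function(hmax, h1, h2) {
  e1 <- .height_eq(hmax, h1)
  e2 <- .height_eq(hmax, h2)
  if (e1 && e2) 0
  else if (e2) abs(hmax - h1)
  else if (e1) abs(hmax - h2)
  else abs(hmax - h1 - h2)
}

#' Equivalence classes of a family under one attribute
#'
#' Two curves are equivalent under attribute `j` (one of the markers) when
#' their genotype combinations share the same feature at position `j`; e.g.
#' the combinations `(BB, AA)` and `(BB, AB)` are equivalent under the
#' first marker, sharing `BB`.  For fixed `j` the classes partition the
#' family.
#'
#' @param family A `curve_family`.
#' @param attribute Attribute index `j` in `1..e`.
#' @return A list of `equivalence_class` objects: lists with
#'   `attribute`, `feature` and `members` (collapsed curve labels).
#' @export
equivalence_classes <- function(family, attribute) {
  e <- ncol(family$labels)
  if (attribute < 1L || attribute > e)
    stop("attribute index out of range 1..", e)
  feat <- family$labels[, attribute]
  lab <- apply(family$labels, 1L, paste, collapse = ",")
  lapply(sort(unique(feat)), function(v) {
    structure(list(attribute = attribute, feature = v,
                   members = lab[feat == v]),
              class = "equivalence_class")
  })
}

#' Maximum cluster-tree distance within an equivalence class
#'
#' @param cls An `equivalence_class`.
#' @param tree A `curve_dendrogram` whose leaves include the class members.
#' @return The maximum [tree_distance()] over all member pairs; 0 for a
#'   singleton class.
#' @export
class_distance <- function(cls, tree) {
  members <- cls$members
  if (length(members) < 2L) return(0)
  idx <- vapply(members, .resolve_leaf, integer(1), tree = tree)
  best <- 0
  for (a in seq_len(length(idx) - 1L)) {
    for (b in seq.int(a + 1L, length(idx))) {
      i <- idx[a]; j <- idx[b]
      d <- .eq3_distance(tree$lca_heights[i, j],
                         unname(tree$leaf_heights[i]),
                         unname(tree$leaf_heights[j]))
      if (d > best) best <- d
    }
  }
  best
}
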