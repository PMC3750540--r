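#' Area distance between two survival curves
#'
#' The distance is the area enclosed between two Kaplan-Meier step curves
#' evaluated on a shared grid `t_1 = 0 < t_2 < ... < t_n`:
#' sum over i = 2..n of `(t_i - t_{i-1}) * |S_j(t_{i-1}) - S_k(t_{i-1})|`,
#' i.e. rectangle areas with heights taken at the left endpoint of each
#' segment.  For right-continuous step curves whose jumps lie on the grid
#' this equals the exact integral of `|S_j - S_k|` over `[0, t_n]`.  The
#' result is in months x survival-probability and is bounded by `t_n`.
#'
#' @param c_j,c_k `km_curve` objects on the same grid.
#' @return Non-negative distance in months.
#' @export
area_distance <- function(c_j, c_k) {
  if (length(c_j$time) != length(c_k$time) || any(c_j$time != c_k$time))
    stop("curves must share the same time grid")
  n <- length(c_j$time)
  if (n < 2L) return(0)
  dt <- diff(c_j$time)
  sum(dt * abs(c_j$surv[-n] - c_k$surv[-n]))
}

#' Pairwise area-distance matrix of a curve family
#'
#' @param family A `curve_family` with at least two curves.
#' @return A symmetric m x m matrix with zero diagonal; dimnames are the
#'   collapsed genotype-combination labels.
#' @export
distance_matrix <- function(family) {
  m <- length(family$curves)
  if (m < 2L) stop("untestable family: need at least 2 curves for distances")
  lab <- apply(family$labels, 1L, paste, collapse = ",")
  D <- matrix(0, m, m, dimnames = list(lab, lab))
  for (j in seq_len(m - 1L)) {
    for (k in seq.int(j + 1L, m)) {
      D[j, k] <- D[k, j] <- area_distance(family$curves[[j]],
                                          family$curves[[k]])
    }
  }
  D
}
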