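#' Angular distance between two dihedral series (RMSDA)
#'
#' Root-mean-square deviation of angular values: each pairwise difference is
#' wrapped to (-180, 180] before squaring, and the mean is taken over the
#' 2(M - 1) angles of an M-residue fragment (8 angles for pentapeptides).
#'
#' @param a,b numeric dihedral series of equal length, degrees.
#' @return non-negative angular distance in degrees.
#' @examples
#' rmsda(rep(0, 8), rep(10, 8))  # 10
#' @export
rmsda <- function(a, b) {
  if (length(a) != length(b)) abort("dihedral series must have equal length")
  d <- wrap_angle(a - b)
  sqrt(mean(d^2))
}

#' Optimal rigid superposition of two point sets (Kabsch)
#'
#' Finds the proper rotation (determinant +1, so chirality is preserved) and
#' translation minimizing the RMSD between paired points, via the closed-form
#' SVD solution.  The aligned version of `p` is
#' `sweep(p, 2, centroid_p) %*% rotation + centroid_q` (row-vector convention).
#'
#' @param p,q n x 3 coordinate matrices (or x/y/z tibbles) with paired rows.
#' @return list with `rmsd` (Angstrom), `rotation` (3 x 3, det +1),
#'   `translation` (the centroid shift applied after rotation), and
#'   `degenerate` (TRUE when the points are collinear or coincident, in which
#'   case the minimizing rotation is not unique but the RMSD still is).
#' @examples
#' p <- matrix(rnorm(45), 15, 3)
#' kabsch_superpose(p, p)$rmsd  # 0
#' @export
kabsch_superpose <- function(p, q) {
  P <- as_coord_matrix(p)
  Q <- as_coord_matrix(q)
  if (nrow(P) != nrow(Q)) abort("point sets must have the same number of rows")
  if (nrow(P) < 3) abort("need at least 3 points")
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(tcrossprod(s$u, s$v)))
  if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  aligned <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((aligned - Qc)^2)))
  # rank deficiency of the cross-covariance: rotation about the degenerate
  # axis is free, RMSD unaffected
  degenerate <- s$d[2] < 1e-8 * max(s$d[1], 1e-12)
  list(rmsd = rmsd, rotation = R, translation = cq,
       centroid_p = cp, degenerate = degenerate)
}

#' Minimum RMSD between two fragments under rigid superposition
#'
#' @inheritParams kabsch_superpose
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(p, q) {
  kabsch_superpose(p, q)$rmsd
}
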