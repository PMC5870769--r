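# Superposition, RMSD, RMSD100 and internal-coordinate measurement.
# These are the evaluation layer: the optimizer's fitness is the superposed
# backbone RMSD computed here.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' equal-length point sets in 1:1 correspondence, via the SVD formulation
#' with reflection correction (determinant forced to +1). Applying
#' `rotation %*% p + translation` to each mobile point p gives the fitted
#' coordinates.
#'
#' @param mobile n x 3 matrix of points to move.
#' @param reference n x 3 matrix of target points.
#' @return A `SuperpositionResult`: list with `rotation` (3 x 3, det +1),
#'   `translation` (3-vector, Å) and `rmsd` (Å, the minimized value).
#' @export
superpose <- function(mobile, reference) {
  mobile <- as_coord_matrix(mobile)
  reference <- as_coord_matrix(reference)
  if (nrow(mobile) != nrow(reference)) {
    stop("point sets differ in length: mobile has ", nrow(mobile),
         ", reference has ", nrow(reference))
  }
  if (nrow(mobile) < 3) stop("superposition requires at least 3 points")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm)
  B <- sweep(reference, 2, cr)
  sv <- svd(crossprod(A, B))
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  # compute the rmsd from explicit residuals rather than the singular-value
  # identity: the latter loses ~1e-8 absolute accuracy to cancellation when
  # the point sets are near-identical copies
  resid <- A %*% t(R) - B
  structure(list(rotation = R, translation = as.numeric(cr - R %*% cm),
                 rmsd = sqrt(mean(rowSums(resid^2)))),
            class = "SuperpositionResult")
}

# fast path used inside optimization loops: minimized RMSD only
kabsch_rmsd <- function(mobile, reference) {
  cmA <- colMeans(mobile)
  cmB <- colMeans(reference)
  A <- sweep(mobile, 2, cmA)
  B <- sweep(reference, 2, cmB)
  sv <- svd(crossprod(A, B))
  d <- sign(det(sv$v) * det(sv$u))
  e0 <- sum(A^2) + sum(B^2)
  sqrt(max(0, (e0 - 2 * sum(sv$d * c(1, 1, d))) / nrow(A)))
}

as_coord_matrix <- function(x) {
  if (inherits(x, "Assembly")) return(x$xyz)
  if (inherits(x, "Primitive")) return(x$points)
  stopifnot(is.matrix(x), ncol(x) == 3)
  if (!all(is.finite(x))) stop("coordinates must be finite")
  x
}

#' Backbone RMSD between two assemblies
#'
#' Atoms are paired positionally: chains in order, residues in order within
#' each chain, and within each residue the fixed label order N, CA, C, O.
#' Both assemblies must therefore have matching chain/residue counts and
#' backbone-complete residues.
#'
#' @param a,b `Assembly` objects with equal residue counts per matched chain.
#' @param superposed if `TRUE` (default) the RMSD after optimal rigid-body
#'   superposition is reported; otherwise the raw RMSD in place.
#' @return An `RmsdReport`: list with `rmsd` (Å), `n_atoms`, `n_residues`
#'   and `rmsd100` (Å; `NA` when the residue count is below the domain of
#'   the normalization, see [rmsd100()]).
#' @export
backbone_rmsd <- function(a, b, superposed = TRUE) {
  ca <- chain_ids(a)
  cb <- chain_ids(b)
  na <- vapply(ca, function(ch) n_residues(a, ch), integer(1))
  nb <- vapply(cb, function(ch) n_residues(b, ch), integer(1))
  if (length(na) != length(nb) || any(na != nb)) {
    stop("residue counts differ per chain: a = [",
         paste(sprintf("%s:%d", ca, na), collapse = ", "), "], b = [",
         paste(sprintf("%s:%d", cb, nb), collapse = ", "), "]")
  }
  A <- backbone_coords(a)
  B <- backbone_coords(b)
  r <- if (superposed) kabsch_rmsd(A, B) else sqrt(mean(rowSums((A - B)^2)))
  nres <- sum(na)
  structure(list(rmsd = r, n_atoms = nrow(A), n_residues = nres,
                 rmsd100 = if (nres >= 20) rmsd100(r, nres) else NA_real_),
            class = "RmsdReport")
}

#' @export
print.RmsdReport <- function(x, ...) {
  cat(sprintf("backbone RMSD %.4f Å over %d atoms (%d residues)",
              x$rmsd, x$n_atoms, x$n_residues))
  if (!is.na(x$rmsd100)) cat(sprintf(", RMSD100 %.4f Å", x$rmsd100))
  cat("\n")
  invisible(x)
}

#' Length-normalized RMSD (RMSD100)
#'
#' Normalizes an RMSD to a 100-residue reference length so that fits of
#' structures of different sizes can be compared:
#' RMSD100 = RMSD / (1 + ln sqrt(N / 100)).
#' The denominator vanishes at N = 100/e^2 (about 13.5 residues), so the
#' function is restricted to N >= 20 where it is well behaved.
#'
#' @param rmsd RMSD in Å.
#' @param n_residues number of residues N.
#' @return RMSD100 in Å.
#' @export
rmsd100 <- function(rmsd, n_residues) {
  if (n_residues < 20) {
    stop("RMSD100 is defined here only for N >= 20 residues (the ",
         "normalization denominator vanishes near N = 13.5); got N = ",
         n_residues)
  }
  rmsd / (1 + log(sqrt(n_residues / 100)))
}

#' Signed dihedral (torsion) angle
#'
#' Torsion about the p2-p3 axis through the four points, IUPAC sign
#' convention: 0 for cis, 180 for trans, returned in (-180, 180] degrees.
#'
#' @param p1,p2,p3,p4 3-vectors.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sqrt(sum(b1^2)) < 1e-9 || sqrt(sum(b2^2)) < 1e-9 ||
      sqrt(sum(b3^2)) < 1e-9) {
    stop("degenerate dihedral: consecutive points coincide")
  }
  c12 <- cross3(b1, b2)
  c23 <- cross3(b2, b3)
  if (sum(c12^2) < 1e-18 || sum(c23^2) < 1e-18) {
    stop("degenerate dihedral: three consecutive points are collinear")
  }
  x <- sum(c12 * c23)
  y <- sum(cross3(c12, c23) * b2 / sqrt(sum(b2^2)))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180 + 1e-12) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Least-squares line through a point cloud
#'
#' Fits the axis of an (approximately) helical or linear set of points: the
#' line through the centroid along the principal axis of the centered cloud.
#' Used to recover helix axes, radii and inter-axis angles in tests and
#' diagnostics.
#'
#' @param points n x 3 matrix (n >= 3), or a `Primitive`.
#' @return List with `point` (centroid) and `direction` (unit 3-vector; sign
#'   chosen so the direction points from the first toward the last point).
#' @export
fit_axis <- function(points) {
  points <- as_coord_matrix(points)
  if (nrow(points) < 3) stop("axis fit requires at least 3 points")
  cen <- colMeans(points)
  X <- sweep(points, 2, cen)
  v <- svd(X, nu = 0, nv = 3)$v[, 1]
  if (sum(v * (points[nrow(points), ] - points[1, ])) < 0) v <- -v
  list(point = cen, direction = v)
}

# distances of points from a line given as list(point, direction)
point_line_distances <- function(points, axis) {
  X <- sweep(as_coord_matrix(points), 2, axis$point)
  along <- X %*% axis$direction
  sqrt(pmax(0, rowSums(X^2) - along^2))
}
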