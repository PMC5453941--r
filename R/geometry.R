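#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rotation and translation mapping `mobile` onto `target`,
#' with the determinant correction that excludes reflections (proper
#' rotations only, so chirality is never inverted).
#'
#' @param mobile,target N x 3 matrices of paired coordinates (N >= 3).
#' @return List with `rotation` (3 x 3), `translation` (length 3; the fit
#'   is `mobile %*% t(rotation) + translation`), and `rmsd` (Angstrom).
#' @export
kabsch_fit <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target) || ncol(mobile) != 3L || ncol(target) != 3L) {
    abort("`mobile` and `target` must be N x 3 with equal N.")
  }
  if (nrow(mobile) < 3L) abort("Superposition needs at least 3 points.")
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  s <- svd(crossprod(P, Q))        # H = P^T Q = U D V^T
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)        # rotation: fitted = P %*% t(R)
  fitted <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = as.numeric(ct - cm %*% t(R)), rmsd = rmsd)
}

apply_rigid <- function(xyz, rotation, translation) {
  sweep(xyz %*% t(rotation), 2, translation, `+`)
}

#' RMSD after optimal superposition
#' @param a,b N x 3 coordinate matrices.
#' @return RMSD in Angstrom.
#' @export
rmsd_fit <- function(a, b) kabsch_fit(a, b)$rmsd

#' Radius of gyration (mass-unweighted)
#'
#' All particles weigh equally (coarse-grained beads have near-uniform
#' mass).
#'
#' @param xyz N x 3 coordinate matrix.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(xyz) {
  xyz <- as.matrix(xyz)
  c <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, c)^2)))
}

# Minimum-image displacement of points relative to a reference point in an
# orthorhombic box.
min_image <- function(d, box) {
  d - sweep(round(sweep(d, 2, box, `/`)), 2, box, `*`)
}

# COM of selected rows under the minimum-image convention: all points are
# shifted to the image nearest the first point before averaging, so a
# cluster split across the periodic boundary gets the COM of its unwrapped
# copy.
com_min_image <- function(xyz, box) {
  ref <- xyz[1, , drop = TRUE]
  d <- min_image(sweep(xyz, 2, ref), box)
  ref + colMeans(d)
}
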