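#' Least-squares rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation R and translation t minimizing
#' `sum ||R x_mobile + t - x_reference||^2` over paired points, by singular
#' value decomposition of the cross-covariance with the determinant
#' correction that excludes reflections. The rotation angle is extracted as
#' `acos((trace(R) - 1)/2)` and the axis from the antisymmetric part of R
#' (eigen-decomposition near 180 degrees).
#'
#' @param mobile,reference Paired coordinates: n x 3 matrices or `atom_tbl`
#'   tibbles (rows taken in order; equal counts required, n >= 3,
#'   non-collinear).
#' @return An object of class `rigid_transform`: list with `rotation` (3x3),
#'   `translation` (length 3, Angstrom), `angle_deg` in [0, 180], `axis`
#'   (unit vector), `rmsd` (Angstrom after superposition), `n`.
#' @examples
#' x <- matrix(rnorm(30), ncol = 3)
#' tr <- superpose(x, x)          # identity, angle 0, rmsd 0
#' @export
superpose <- function(mobile, reference) {
  P <- if (is.data.frame(mobile)) coords_of(mobile) else as.matrix(mobile)
  Q <- if (is.data.frame(reference)) coords_of(reference) else as.matrix(reference)
  if (ncol(P) != 3 || ncol(Q) != 3) abort("coordinates must be n x 3")
  if (nrow(P) != nrow(Q)) {
    abort(sprintf("point counts differ: %d vs %d", nrow(P), nrow(Q)))
  }
  if (nrow(P) < 3) abort("need >= 3 paired points")

  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv_rank <- svd(Pc)$d
  if (sv_rank[2] < 1e-8 * max(sv_rank[1], 1)) {
    abort("points are collinear; superposition is degenerate")
  }

  H <- crossprod(Pc, Qc)        # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- as.numeric(cq - R %*% cp)

  fitted <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))

  ang_axis <- rotation_angle_axis(R)
  structure(
    list(rotation = R, translation = t_vec,
         angle_deg = ang_axis$angle_deg, axis = ang_axis$axis,
         rmsd = rmsd, n = nrow(P)),
    class = "rigid_transform")
}

rotation_angle_axis <- function(R) {
  tr <- sum(diag(R))
  cang <- min(1, max(-1, (tr - 1) / 2))
  angle <- acos(cang) * 180 / pi
  A <- R - t(R)
  v <- c(A[3, 2], A[1, 3], A[2, 1])
  nv <- sqrt(sum(v^2))
  if (nv > 1e-8) {
    axis <- v / nv
  } else if (angle > 90) {
    # near 180 degrees: axis is the eigenvector of R with eigenvalue +1
    e <- eigen(R)
    i <- which.min(abs(e$values - 1))
    axis <- Re(e$vectors[, i])
    axis <- axis / sqrt(sum(axis^2))
  } else {
    axis <- c(0, 0, 1)  # identity: axis undefined, conventional z
  }
  list(angle_deg = angle, axis = axis)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("Rigid transform: %.4g deg about (%.3f, %.3f, %.3f), rmsd %.4g A (n = %d)\n",
              x$angle_deg, x$axis[1], x$axis[2], x$axis[3], x$rmsd, x$n))
  invisible(x)
}

#' @method tidy rigid_transform
#' @export
tidy.rigid_transform <- function(x, ...) {
  tibble(angle_deg = x$angle_deg, axis_x = x$axis[1], axis_y = x$axis[2],
         axis_z = x$axis[3], rmsd = x$rmsd, n = x$n)
}

# apply a rigid_transform to an n x 3 matrix
apply_transform <- function(tr, X) {
  sweep(as.matrix(X) %*% t(tr$rotation), 2, tr$translation, "+")
}

#' Rotation angle reduced modulo an n-fold symmetry
#'
#' In an assembly with Cn rotational symmetry, rotations differing by
#' multiples of 360/n degrees are equivalent; the reported angle is reduced
#' into [0, 180/n] (for n = 5, [0, 36] degrees).
#'
#' @param transform A `rigid_transform`, or a rotation angle in degrees.
#' @param modulo_symmetry Symmetry order n >= 1 (default 1: plain [0, 180]).
#' @return The reduced angle in degrees.
#' @examples
#' rotation_angle(46, modulo_symmetry = 5)  # 26
#' @export
rotation_angle <- function(transform, modulo_symmetry = 1L) {
  ang <- if (inherits(transform, "rigid_transform")) {
    transform$angle_deg
  } else {
    as.numeric(transform)
  }
  n <- as.integer(modulo_symmetry)
  if (n < 1) abort("modulo_symmetry must be >= 1")
  period <- 360 / n
  a <- ang %% period
  pmin(a, period - a)
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues form; useful for constructing synthetic assemblies and in
#' brute-force cross-checks.
#'
#' @param angle_deg Rotation angle, degrees.
#' @param axis Rotation axis (length-3, need not be normalized).
#' @return A 3x3 proper rotation matrix.
#' @export
rotation_matrix <- function(angle_deg, axis = c(0, 0, 1)) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
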