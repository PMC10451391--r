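#' Canonical ellipsoid
#'
#' An ellipsoid in canonical form `x'^2/a^2 + y'^2/b^2 + z'^2/c^2 = 1`,
#' carried together with the rigid transform placing it in data coordinates.
#' The `c` semi-axis is the one aligned with the optical (z) axis.
#'
#' @param semi_axes length-3 positive vector `(a, b, c)` in mm.
#' @param rotation 3 x 3 orthonormal matrix (det +1) whose columns are the
#'   canonical x, y, z axes expressed in data coordinates.
#' @param center ellipsoid center in data coordinates (mm).
#' @return object of class `canonical_ellipsoid`.
#' @export
canonical_ellipsoid <- function(semi_axes, rotation = diag(3),
                                center = c(0, 0, 0)) {
  semi_axes <- as.numeric(semi_axes)
  stopifnot(length(semi_axes) == 3L, all(semi_axes > 0),
            all(dim(rotation) == c(3L, 3L)), length(center) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation is not orthonormal")
  if (det(rotation) < 0)
    stop("rotation must be proper (det +1)")
  structure(list(semi_axes = semi_axes, rotation = rotation,
                 center = as.numeric(center)),
            class = "canonical_ellipsoid")
}

#' @export
print.canonical_ellipsoid <- function(x, ...) {
  cat(sprintf("<ellipsoid: a=%.4f b=%.4f c=%.4f mm, center (%s) mm>\n",
              x$semi_axes[1], x$semi_axes[2], x$semi_axes[3],
              paste(sprintf("%.3f", x$center), collapse = ", ")))
  invisible(x)
}

#' Implicit quadric coefficients of a canonical ellipsoid
#'
#' Inverse of [to_canonical_ellipsoid()]: expands
#' `(p - t)' R D R' (p - t) = 1`, `D = diag(1/a^2, 1/b^2, 1/c^2)`,
#' into the ten unit-norm coefficients.
#'
#' @param e a `canonical_ellipsoid`.
#' @return a `quadric_coef` vector.
#' @export
ellipsoid_to_quadric <- function(e) {
  stopifnot(inherits(e, "canonical_ellipsoid"))
  D <- diag(1 / e$semi_axes^2)
  A <- e$rotation %*% D %*% t(e$rotation)
  t0 <- e$center
  b <- as.numeric(-2 * A %*% t0)
  k <- as.numeric(t(t0) %*% A %*% t0) - 1
  quadric_from_matrices(A, b, k)
}

#' Transform fitted quadric coefficients to canonical ellipsoid form
#'
#' Eigen-decomposes the quadratic-form matrix, translates to the quadric
#' center and checks the ellipsoid signature (all eigenvalues of one sign,
#' centered constant of the opposite sign).  The canonical `c` axis is the
#' eigenvector with the largest |z| component (the optical axis); of the
#' remaining two, the one with the largest |x| component becomes the `a`
#' axis.  Axis directions are signed so the rotation is right-handed.
#'
#' @param cf unit-norm quadric coefficients.
#' @return a [canonical_ellipsoid()].
#' @export
to_canonical_ellipsoid <- function(cf) {
  m <- quadric_matrices(cf)
  eg <- eigen(m$A, symmetric = TRUE)
  lam <- eg$values
  if (any(abs(lam) < 1e-12 * max(abs(lam))) ||
      length(unique(sign(lam))) != 1L)
    stop("not an ellipsoid: quadratic form has mixed or vanishing ",
         "eigenvalue signature")
  # center: 2 A t = -b
  t0 <- as.numeric(solve(m$A, -m$b / 2))
  k <- m$k - as.numeric(t(t0) %*% m$A %*% t0)  # Q = q'Aq + k about center
  if (sign(k) == sign(lam[1L]))
    stop("not an ellipsoid: no real surface (constant term has the same ",
         "sign as the quadratic form)")
  semi_all <- sqrt(-k / lam)
  V <- eg$vectors
  iz <- which.max(abs(V[3L, ]))
  rest <- setdiff(1:3, iz)
  ix <- rest[which.max(abs(V[1L, rest]))]
  iy <- setdiff(rest, ix)
  vz <- V[, iz] * sign(V[3L, iz] + (V[3L, iz] == 0))
  vx <- V[, ix] * sign(V[1L, ix] + (V[1L, ix] == 0))
  vy <- V[, iy]
  R <- cbind(vx, vy, vz)
  if (det(R) < 0) R[, 2L] <- -R[, 2L]
  dimnames(R) <- NULL
  canonical_ellipsoid(semi_all[c(ix, iy, iz)], R, t0)
}

#' Morpho-geometric parameters of a corneal ellipsoid
#'
#' The clinical descriptors of the fitted surface: apical radii of curvature
#' `Rx = a^2/c`, `Ry = b^2/c` (mm) and asphericities
#' `Qx = (a/c)^2 - 1`, `Qy = (b/c)^2 - 1` (dimensionless).  A sphere has
#' `Q = 0`; healthy prolate corneas have `Q` around -0.3, and `Q` drifts
#' toward -1 in advanced keratoconus.
#'
#' @param e a `canonical_ellipsoid`.
#' @return object of class `morpho_geometry`: list with `Rx`, `Ry`, `Qx`,
#'   `Qy`.
#' @export
morpho_parameters <- function(e) {
  stopifnot(inherits(e, "canonical_ellipsoid"))
  a <- e$semi_axes[1L]; b <- e$semi_axes[2L]; cc <- e$semi_axes[3L]
  structure(list(Rx = a^2 / cc, Ry = b^2 / cc,
                 Qx = (a / cc)^2 - 1, Qy = (b / cc)^2 - 1),
            class = "morpho_geometry")
}

#' @export
print.morpho_geometry <- function(x, ...) {
  cat(sprintf("Rx = %.4f mm, Ry = %.4f mm, Qx = %+.4f, Qy = %+.4f\n",
              x$Rx, x$Ry, x$Qx, x$Qy))
  invisible(x)
}

#' Quadric-order failure flag
#'
#' A reconstruction fails (`fq = 1`) when the fitted polynomial is no longer
#' a usable second-order surface: either the second-order coefficient block
#' `{a11, a12, a13, a22, a23, a33}` has (numerically) vanished, leaving a
#' plane-dominated solution, or the eigenvalue signature is not that of an
#' ellipsoid (the accepted quadric for a corneal cap).  Summed over a study
#' these flags form the failure quadric number, see [aggregate_fqn()].
#'
#' @param cf unit-norm quadric coefficients.
#' @param tol threshold on the norm of the second-order block.
#' @return integer 0 (valid) or 1 (failure).
#' @export
check_quadric_order <- function(cf, tol = 1e-6) {
  v <- as.numeric(cf)
  if (sqrt(sum(v[SECOND_ORDER_IDX]^2)) < tol) return(1L)
  ok <- tryCatch({ to_canonical_ellipsoid(cf); TRUE },
                 error = function(e) FALSE)
  if (ok) 0L else 1L
}
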