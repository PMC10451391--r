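# Fixed storage order of the ten quadric coefficients.  All code indexes
# coefficient vectors through this order; do not reorder.
QUADRIC_COEF_NAMES <- c("a11", "a12", "a13", "a10", "a22",
                        "a23", "a20", "a33", "a30", "a00")

# Indices of the second-order block {a11, a12, a13, a22, a23, a33} within
# the storage order above.
SECOND_ORDER_IDX <- c(1L, 2L, 3L, 5L, 6L, 8L)

#' Construct a normalized quadric coefficient vector
#'
#' A quadric surface is the zero set of
#' \deqn{Q(x,y,z) = a_{11}x^2 + a_{12}xy + a_{13}xz + a_{10}x + a_{22}y^2 +
#'   a_{23}yz + a_{20}y + a_{33}z^2 + a_{30}z + a_{00}.}
#' The ten coefficients are stored in the fixed order
#' `a11, a12, a13, a10, a22, a23, a20, a33, a30, a00` and, by default,
#' normalized to unit Euclidean norm with the sign fixed so that `a33 >= 0`
#' (if `a33 == 0`, the first nonzero second-order coefficient is made
#' positive).  Coefficients are dimensionless; coordinates are in mm.
#'
#' @param x numeric vector of length 10 in the storage order above.
#' @param normalize logical; project to the unit sphere and fix the sign.
#' @return a named numeric vector of class `quadric_coef`.
#' @export
#' @examples
#' # unit sphere x^2 + y^2 + z^2 - 1 = 0
#' s <- quadric_coefficients(c(1, 0, 0, 0, 1, 0, 0, 1, 0, -1))
#' evaluate_quadric(s, c(1, 0, 0))
quadric_coefficients <- function(x, normalize = TRUE) {
  x <- as.numeric(x)
  if (length(x) != 10L)
    stop("a quadric has exactly 10 coefficients; got ", length(x))
  if (any(!is.finite(x)))
    stop("quadric coefficients must be finite")
  if (normalize) x <- normalize_quadric(x)
  names(x) <- QUADRIC_COEF_NAMES
  structure(x, class = "quadric_coef")
}

#' @export
print.quadric_coef <- function(x, ...) {
  cat("Implicit quadric coefficients (unit norm, mm coordinates):\n")
  print(format(unclass(x), digits = 6), quote = FALSE)
  invisible(x)
}

# Unit-norm projection with canonical sign.  The all-zero vector is the
# trivial solution of the algebraic problem and is rejected outright.
normalize_quadric <- function(x) {
  n <- sqrt(sum(x^2))
  if (!is.finite(n) || n == 0)
    stop("all-zero coefficient vector: the trivial solution is excluded")
  x <- x / n
  blk <- x[SECOND_ORDER_IDX]
  if (x[8L] < 0) {
    x <- -x
  } else if (x[8L] == 0) {
    nz <- blk[blk != 0]
    if (length(nz) && nz[1L] < 0) x <- -x
  }
  x
}

# Symmetric-matrix form: Q(p) = p'Ap + b'p + k with
# A = [[a11, a12/2, a13/2], [., a22, a23/2], [., ., a33]], b = (a10,a20,a30).
quadric_matrices <- function(cf) {
  cf <- as.numeric(cf)
  A <- matrix(c(cf[1], cf[2] / 2, cf[3] / 2,
                cf[2] / 2, cf[5], cf[6] / 2,
                cf[3] / 2, cf[6] / 2, cf[8]), 3L, 3L)
  list(A = A, b = c(cf[4], cf[7], cf[9]), k = cf[10])
}

quadric_from_matrices <- function(A, b, k, normalize = TRUE) {
  quadric_coefficients(
    c(A[1, 1], 2 * A[1, 2], 2 * A[1, 3], b[1],
      A[2, 2], 2 * A[2, 3], b[2],
      A[3, 3], b[3], k),
    normalize = normalize)
}

#' Evaluate the implicit quadric polynomial
#'
#' @param cf a [quadric_coefficients()] vector (or any numeric length-10
#'   vector in the same order).
#' @param p a length-3 point `(x, y, z)` in mm, or an N x 3 matrix of points.
#' @return numeric vector of `Q(x, y, z)` values, one per point.
#' @export
evaluate_quadric <- function(cf, p) {
  cf <- as.numeric(cf)
  if (length(cf) != 10L) stop("need 10 coefficients")
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
  drop(design_matrix(p) %*% cf)
}

# N x 10 monomial design matrix in the fixed coefficient order.
design_matrix <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]; z <- p[, 3L]
  cbind(x * x, x * y, x * z, x, y * y, y * z, y, z * z, z, 1)
}

#' Mean squared algebraic residual of a quadric over a point cloud
#'
#' The objective minimized by every fitter in the package:
#' \eqn{(1/N) \sum_s Q(P_s)^2}.  It is not the reported goodness of fit
#' (see [elevation_mse()]); the algebraic residual is cheap and smooth,
#' which is what an optimizer wants, while the elevation MSE is the
#' clinically meaningful error measured along the instrument axis.
#'
#' @param cf quadric coefficients.
#' @param cloud a [point_cloud()] or an N x 3 matrix.
#' @return scalar mean squared residual.
#' @export
algebraic_fitness <- function(cf, cloud) {
  p <- cloud_points(cloud)
  if (nrow(p) == 0L) stop("empty point cloud")
  mean(evaluate_quadric(cf, p)^2)
}

#' Solve the quadric for elevation z at given (x, y)
#'
#' Solves \eqn{a_{33} z^2 + (a_{13}x + a_{23}y + a_{30}) z +
#' (a_{11}x^2 + a_{12}xy + a_{10}x + a_{22}y^2 + a_{20}y + a_{00}) = 0}.
#' When two real roots exist the one nearer `z_ref` is returned; when the
#' quadratic degenerates to a linear equation it is solved directly; when
#' no real root exists the node is flagged unresolved.
#'
#' @param cf quadric coefficients (unit norm assumed for the degeneracy
#'   thresholds to be meaningful).
#' @param x,y node coordinates in mm (vectors of equal length).
#' @param z_ref reference elevation(s) in mm used to pick the root branch;
#'   recycled to the length of `x`.
#' @return list with `z` (numeric, `NA` where unresolved) and `ok` (logical).
#' @export
solve_elevation <- function(cf, x, y, z_ref) {
  cf <- as.numeric(cf)
  n <- length(x)
  z_ref <- rep_len(z_ref, n)
  A <- cf[8L]
  B <- cf[3L] * x + cf[6L] * y + cf[9L]
  C <- cf[1L] * x^2 + cf[2L] * x * y + cf[4L] * x +
       cf[5L] * y^2 + cf[7L] * y + cf[10L]
  z <- rep(NA_real_, n)
  if (abs(A) < 1e-14) {
    lin <- abs(B) >= 1e-14
    z[lin] <- -C[lin] / B[lin]
  } else {
    disc <- B^2 - 4 * A * C
    real <- disc >= 0
    sq <- sqrt(pmax(disc, 0))
    # numerically stable pair of roots
    q <- -(B + sign(B + (B == 0)) * sq) / 2
    z1 <- q / A
    z2 <- ifelse(q != 0, C / q, -B / (2 * A))
    pick <- abs(z1 - z_ref) <= abs(z2 - z_ref)
    z[real] <- ifelse(pick, z1, z2)[real]
  }
  list(z = z, ok = !is.na(z))
}

#' Elevation mean squared error of a fitted quadric
#'
#' The reported goodness of fit: the surface is solved for z at exactly the
#' (x, y) nodes where elevations were acquired, giving adjusted elevations
#' \eqn{\hat Z}; the MSE is \eqn{(1/N')\sum(\hat Z - Z)^2} over the N' nodes
#' where a real root exists.  Nodes without a real root are excluded from
#' the average but counted in `unresolved`.
#'
#' @inheritParams algebraic_fitness
#' @return list with `mse` (mm^2) and `unresolved` (count).
#' @export
elevation_mse <- function(cf, cloud) {
  p <- cloud_points(cloud)
  if (nrow(p) == 0L) stop("empty point cloud")
  s <- solve_elevation(cf, p[, 1L], p[, 2L], z_ref = p[, 3L])
  if (!any(s$ok))
    stop("surface has no real elevation at any node: cannot compute MSE")
  list(mse = mean((s$z[s$ok] - p[s$ok, 3L])^2),
       unresolved = sum(!s$ok))
}

# --- preconditioning -------------------------------------------------------
#
# Quadric scatter matrices in raw mm units are badly conditioned (monomials
# span several orders of magnitude).  Every fitter centers the cloud on its
# centroid and scales the largest centroid distance to 1, fits in those
# coordinates, and maps the coefficients back analytically.

precondition_cloud <- function(p) {
  ctr <- colMeans(p)
  q <- sweep(p, 2L, ctr)
  s <- max(sqrt(rowSums(q^2)))
  if (s == 0) s <- 1
  list(points = q / s, center = ctr, scale = s)
}

#' Map quadric coefficients between data and preconditioned coordinates
#'
#' Preconditioned coordinates are `u = (p - center)/scale`.  Given the ten
#' coefficients of the quadric expressed in one frame, returns the unit-norm
#' coefficients of the same surface in the other.
#'
#' @param cf quadric coefficients.
#' @param center length-3 translation (mm).
#' @param scale positive scalar (mm).
#' @param to `"data"` if `cf` lives in preconditioned coordinates and the
#'   data-frame coefficients are wanted; `"scaled"` for the reverse.
#' @return a `quadric_coef` vector in the target frame.
#' @keywords internal
transform_quadric <- function(cf, center, scale, to = c("data", "scaled")) {
  to <- match.arg(to)
  m <- quadric_matrices(cf)
  t0 <- as.numeric(center); s <- scale
  if (to == "data") {
    A <- m$A / s^2
    b <- as.numeric(-2 * (m$A %*% t0) / s^2 + m$b / s)
    k <- as.numeric(t(t0) %*% m$A %*% t0) / s^2 - sum(m$b * t0) / s + m$k
  } else {
    A <- m$A * s^2
    b <- s * as.numeric(2 * (m$A %*% t0) + m$b)
    k <- as.numeric(t(t0) %*% m$A %*% t0) + sum(m$b * t0) + m$k
  }
  quadric_from_matrices(A, b, k)
}

# --- fit results -----------------------------------------------------------

#' Assemble a fit result
#'
#' Bundles fitted coefficients with the elevation MSE, the quadric-order
#' failure flag `fq` and convergence metadata.  Used by every fitter.
#'
#' @param cf fitted `quadric_coef` (data coordinates, unit norm).
#' @param cloud the fitted point cloud.
#' @param method_tag one of `"CORNEAGA"`, `"LSQ"`, `"SQP"`, `"DIRECT"`.
#' @param generations generation or iteration count.
#' @param converged logical convergence flag.
#' @param seed RNG seed used, or `NA`.
#' @return object of class `corneal_fit`: list with elements `coefficients`,
#'   `mse` (mm^2), `n_points`, `method_tag`, `generations`, `converged`,
#'   `fq` (0/1), `unresolved`, `seed`.
#' @export
fit_result <- function(cf, cloud, method_tag, generations = NA_integer_,
                       converged = NA, seed = NA_integer_) {
  p <- cloud_points(cloud)
  em <- tryCatch(elevation_mse(cf, p),
                 error = function(e) list(mse = NA_real_,
                                          unresolved = nrow(p)))
  structure(list(
    coefficients = cf,
    mse = em$mse,
    n_points = nrow(p),
    method_tag = method_tag,
    generations = generations,
    converged = converged,
    fq = check_quadric_order(cf),
    unresolved = em$unresolved,
    seed = seed
  ), class = "corneal_fit")
}

#' @export
print.corneal_fit <- function(x, ...) {
  cat(sprintf("<corneal_fit: %s>\n", x$method_tag))
  cat(sprintf("  points: %d   elevation MSE: %s mm^2   unresolved: %d\n",
              x$n_points, format(x$mse, digits = 5), x$unresolved))
  cat(sprintf("  generations/iterations: %s   converged: %s   fq: %d\n",
              x$generations, x$converged, x$fq))
  invisible(x)
}

#' Serialize / restore a fit result as JSON
#'
#' @param fit a `corneal_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  out <- unclass(fit)
  out$coefficients <- as.list(stats::setNames(as.numeric(out$coefficients),
                                              QUADRIC_COEF_NAMES))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$coefficients <- quadric_coefficients(
    as.numeric(x$coefficients[QUADRIC_COEF_NAMES]))
  structure(x, class = "corneal_fit")
}
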