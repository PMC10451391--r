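# Shared entry checks for all fitters.
check_cloud_for_fit <- function(cloud, min_points = 10L) {
  p <- cloud_points(cloud)
  if (nrow(p) == 0L) stop("empty point cloud")
  if (nrow(p) < min_points)
    stop("insufficient data: ", nrow(p), " points, need at least ",
         min_points)
  p
}

# Sphere of radius 7.8 mm (typical anterior cornea) centered on the cloud's
# axis, apex at the cloud's highest point; expressed in preconditioned
# coordinates.  Neutral, clinically plausible start for iterative fitters.
sphere_init <- function(p, pre, radius = 7.8) {
  ctr <- c(mean(p[, 1L]), mean(p[, 2L]), max(p[, 3L]) - radius)
  e <- canonical_ellipsoid(rep(radius, 3L), diag(3), ctr)
  transform_quadric(ellipsoid_to_quadric(e), pre$center, pre$scale,
                    to = "scaled")
}

#' Closed-form direct linear quadric fit (test oracle)
#'
#' The exact minimizer of the unit-norm algebraic problem: the coefficient
#' vector is the right singular vector of the N x 10 monomial design matrix
#' belonging to its smallest singular value.  Deterministic, no iteration;
#' serves as the reference against which the iterative fitters are judged.
#'
#' @param cloud a [point_cloud()] or N x 3 matrix (>= 10 points).
#' @return a `corneal_fit` with `method_tag = "DIRECT"`.
#' @export
fit_direct_linear <- function(cloud) {
  p <- check_cloud_for_fit(cloud)
  pre <- precondition_cloud(p)
  D <- design_matrix(pre$points)
  sv <- svd(D)
  # degenerate geometry (e.g. coplanar points): more than one vanishing
  # singular value means the quadric through the data is not unique
  if (sv$d[9L] < 1e-10 * sv$d[1L])
    stop("degenerate fit: design matrix rank < 9 ",
         "(points lie on a lower-order variety)")
  cf_scaled <- quadric_coefficients(sv$v[, 10L])
  cf <- transform_quadric(cf_scaled, pre$center, pre$scale, to = "data")
  fit_result(cf, p, "DIRECT", generations = 0L, converged = TRUE)
}

#' Weighted least-squares quadric fit (trust-region iteration)
#'
#' The classical baseline: minimizes the weighted mean squared algebraic
#' residual by damped trust-region Gauss-Newton (Levenberg-Marquardt via
#' \pkg{minpack.lm}), starting from a 7.8 mm sphere on the cloud axis.  The
#' trivial all-zero solution is excluded either by a unit-norm penalty
#' residual (default) or, with `constrain_a11 = TRUE`, by fixing
#' `a11 = 1` during the iteration.
#'
#' @param cloud a [point_cloud()] or N x 3 matrix (>= 10 points).
#' @param weights per-point non-negative weights, `"uniform"` (default) or
#'   `"radial"` for `1/(1 + (r/r_max)^2)` down-weighting of the noisier
#'   peripheral samples.
#' @param constrain_a11 fix `a11 = 1` instead of the norm penalty.
#' @return a `corneal_fit` with `method_tag = "LSQ"`.
#' @export
fit_lsq_trra <- function(cloud, weights = "uniform", constrain_a11 = FALSE) {
  p <- check_cloud_for_fit(cloud)
  N <- nrow(p)
  if (identical(weights, "uniform")) {
    w <- rep(1, N)
  } else if (identical(weights, "radial")) {
    r2 <- rowSums(p[, 1:2]^2)
    w <- 1 / (1 + r2 / max(r2))
  } else {
    w <- as.numeric(weights)
    if (length(w) != N || any(w < 0) || all(w == 0))
      stop("weights must be N non-negative values, not all zero")
  }
  pre <- precondition_cloud(p)
  Dw <- sqrt(w / sum(w)) * design_matrix(pre$points)
  init <- as.numeric(sphere_init(p, pre))
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-18,
                                     ptol = 1e-18)
  if (constrain_a11) {
    # residuals are linear in the nine free coefficients
    fit <- minpack.lm::nls.lm(
      par = init[-1L] / init[1L],
      fn = function(th) drop(Dw %*% c(1, th)),
      jac = function(th) Dw[, -1L, drop = FALSE],
      control = ctrl)
    cf_scaled <- quadric_coefficients(c(1, fit$par))
  } else {
    fit <- minpack.lm::nls.lm(
      par = init,
      fn = function(th) c(drop(Dw %*% th), sum(th^2) - 1),
      jac = function(th) rbind(Dw, 2 * th),
      control = ctrl)
    cf_scaled <- quadric_coefficients(fit$par)
  }
  if (inherits(fit, "try-error"))
    stop("degenerate fit: trust-region iteration failed")
  cf <- transform_quadric(cf_scaled, pre$center, pre$scale, to = "data")
  # info 1-4: tolerance met; 6-8: tolerances below attainable precision,
  # i.e. converged to the numerical limit.  5 is the iteration cap.
  fit_result(cf, p, "LSQ", generations = fit$niter,
             converged = fit$info %in% c(1:4, 6:8))
}

#' Sequential quadratic programming quadric fit
#'
#' Minimizes the algebraic residual under the unit-norm equality constraint
#' by damped Lagrange-Newton iteration on the KKT system (for a quadratic
#' objective with one quadratic constraint this is exactly the SQP step).
#' Like any local method it can settle on poor stationary points when the
#' cloud is heavily deformed or incomplete; such outcomes are reported
#' through the `converged` and `fq` flags rather than patched.
#'
#' @param cloud a [point_cloud()] or N x 3 matrix (>= 10 points).
#' @param init optional starting `quadric_coef` in data coordinates;
#'   default is the 7.8 mm sphere on the cloud axis.
#' @param max_iter iteration cap.
#' @return a `corneal_fit` with `method_tag = "SQP"`; solver failure yields
#'   a non-converged result, not an error.
#' @export
fit_sqp <- function(cloud, init = NULL, max_iter = 200L) {
  p <- check_cloud_for_fit(cloud)
  pre <- precondition_cloud(p)
  D <- design_matrix(pre$points)
  M <- crossprod(D) / nrow(D)
  a <- if (is.null(init)) as.numeric(sphere_init(p, pre))
       else as.numeric(transform_quadric(init, pre$center, pre$scale,
                                         to = "scaled"))
  a <- a / sqrt(sum(a^2))
  lam <- drop(t(a) %*% M %*% a)
  kkt <- function(a, lam) c(2 * drop(M %*% a) - 2 * lam * a,
                            sum(a^2) - 1)
  Fv <- kkt(a, lam)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    J <- rbind(cbind(2 * M - 2 * lam * diag(10), -2 * a),
               c(2 * a, 0))
    step <- tryCatch(solve(J, -Fv), error = function(e) NULL)
    if (is.null(step)) break
    # step halving keeps the KKT residual decreasing
    t_len <- 1
    ok <- FALSE
    for (h in 1:40) {
      a_new <- a + t_len * step[1:10]
      lam_new <- lam + t_len * step[11L]
      F_new <- kkt(a_new, lam_new)
      if (sum(F_new^2) < sum(Fv^2)) { ok <- TRUE; break }
      t_len <- t_len / 2
    }
    if (!ok) break
    a <- a_new; lam <- lam_new; Fv <- F_new
    if (sqrt(sum(Fv^2)) < 1e-12) { converged <- TRUE; break }
  }
  cf_scaled <- quadric_coefficients(a)
  cf <- transform_quadric(cf_scaled, pre$center, pre$scale, to = "data")
  fit_result(cf, p, "SQP", generations = it, converged = converged)
}
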