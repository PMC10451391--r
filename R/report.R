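#' Failure quadric number of a batch of reconstructions
#'
#' `FQN = sum(fq)` over a set of fits: the number of reconstructions whose
#' fitted surface is not a valid second-order (ellipsoidal) quadric.
#'
#' @param results list of `corneal_fit` objects (or bare 0/1 flags).
#' @return integer count.
#' @export
aggregate_fqn <- function(results) {
  if (length(results) == 0L) stop("no results")
  flags <- vapply(results, function(r)
    if (inherits(r, "corneal_fit")) r$fq else as.integer(r), integer(1))
  if (any(!flags %in% c(0L, 1L))) stop("fq flags must be 0 or 1")
  sum(flags)
}

# Dispatch a fit by method tag.
fit_with_method <- function(cloud, method, config = ga_config(),
                            seed = NULL) {
  method <- toupper(method)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  switch(method,
         CORNEAGA = , GA = fit_nsmvga(cloud, config),
         LSQ = fit_lsq_trra(cloud),
         SQP = fit_sqp(cloud),
         DIRECT = fit_direct_linear(cloud),
         stop("unknown method: ", method))
}

#' Batch comparison of reconstruction methods
#'
#' Fits every grid with every requested method and aggregates, per method
#' and group, the elevation MSE (mean, SD), the failure quadric number and
#' the morpho-geometric parameters (mean, SD of Rx, Ry, Qx, Qy over
#' non-failed fits).  A method failing on a grid is recorded as a failed
#' case, not an aborted batch.
#'
#' @param cases list of cases: each either a `polar_grid` or a list with a
#'   `grid` element (as produced by [make_ellipsoid_grid()] /
#'   [make_cohort()]; the truth's `group` label, when present, defines the
#'   grouping).
#' @param methods character subset of `c("CORNEAGA", "LSQ", "SQP")`
#'   (`"DIRECT"` also accepted).
#' @param config GA configuration used for the CORNEAGA method.
#' @param seed base seed; case i of a method uses `seed + i`.
#' @param path optional CSV output path for the aggregate table.
#' @return a `data.frame` with one row per method x group and stable
#'   columns `method, group, n, mse_mean, mse_sd, fqn, Rx_mean, Rx_sd,
#'   Ry_mean, Ry_sd, Qx_mean, Qx_sd, Qy_mean, Qy_sd, n_failed`; the
#'   per-case table is attached as attribute `"cases"`.
#' @export
compare_methods <- function(cases, methods = c("CORNEAGA", "LSQ"),
                            config = ga_config(), seed = 1L, path = NULL) {
  stopifnot(length(cases) >= 1L, length(methods) >= 1L)
  rows <- list()
  for (mi in seq_along(methods)) {
    m <- methods[[mi]]
    for (ci in seq_along(cases)) {
      case <- cases[[ci]]
      grid <- if (inherits(case, "polar_grid")) case else case$grid
      group <- if (!inherits(case, "polar_grid") &&
                   !is.null(case$truth$group)) case$truth$group else "all"
      row <- data.frame(method = toupper(m), group = group, case = ci,
                        mse = NA_real_, fq = 1L, Rx = NA_real_,
                        Ry = NA_real_, Qx = NA_real_, Qy = NA_real_,
                        failed = TRUE)
      ft <- tryCatch({
        cloud <- polar_to_cartesian(grid)
        fit_with_method(cloud, m, config, seed = seed + ci)
      }, error = function(e) NULL)
      if (!is.null(ft)) {
        row$mse <- ft$mse; row$fq <- ft$fq; row$failed <- FALSE
        if (ft$fq == 0L) {
          mg <- morpho_parameters(to_canonical_ellipsoid(ft$coefficients))
          row$Rx <- mg$Rx; row$Ry <- mg$Ry; row$Qx <- mg$Qx; row$Qy <- mg$Qy
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  per_case <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(
    split(per_case, list(per_case$method, per_case$group), drop = TRUE),
    function(d) data.frame(
      method = d$method[1L], group = d$group[1L], n = nrow(d),
      mse_mean = mean(d$mse, na.rm = TRUE),
      mse_sd = stats::sd(d$mse, na.rm = TRUE),
      fqn = sum(d$fq),
      Rx_mean = mean(d$Rx, na.rm = TRUE), Rx_sd = stats::sd(d$Rx,
                                                            na.rm = TRUE),
      Ry_mean = mean(d$Ry, na.rm = TRUE), Ry_sd = stats::sd(d$Ry,
                                                            na.rm = TRUE),
      Qx_mean = mean(d$Qx, na.rm = TRUE), Qx_sd = stats::sd(d$Qx,
                                                            na.rm = TRUE),
      Qy_mean = mean(d$Qy, na.rm = TRUE), Qy_sd = stats::sd(d$Qy,
                                                            na.rm = TRUE),
      n_failed = sum(d$failed))))
  rownames(agg) <- NULL
  if (!is.null(path)) utils::write.csv(agg, path, row.names = FALSE)
  attr(agg, "cases") <- per_case
  agg
}

#' Residual plot of a reconstruction
#'
#' Plots the signed elevation residual (fitted minus measured, micrometres)
#' against radial position, the standard visual check of where on the
#' cornea a modal fit is losing accuracy.
#'
#' @param x a `corneal_fit`.
#' @param cloud the point cloud the fit was computed on.
#' @param ... passed to [graphics::plot()].
#' @export
plot_fit_residuals <- function(x, cloud, ...) {
  p <- cloud_points(cloud)
  s <- solve_elevation(x$coefficients, p[, 1L], p[, 2L], z_ref = p[, 3L])
  r <- sqrt(rowSums(p[, 1:2]^2))
  res <- (s$z - p[, 3L]) * 1000
  graphics::plot(r[s$ok], res[s$ok], pch = ".", xlab = "radius (mm)",
                 ylab = "elevation residual (µm)",
                 main = sprintf("%s: MSE %.3g mm²", x$method_tag,
                                x$mse), ...)
  graphics::abline(h = 0, col = 2)
  invisible(x)
}
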