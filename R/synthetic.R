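#' Specification of a synthetic cornea
#'
#' Describes an ellipsoidal cornea by its clinical parameters (apical radii
#' `Rx`, `Ry` in mm and asphericities `Qx`, `Qy`), plus the acquisition
#' artifacts to emulate: Gaussian elevation noise, sentinel dropout and an
#' optional keratoconus-like cone deformation.  The ellipsoid is recovered
#' from the clinical parameters through `c = R/(1+Q)`, `a = R/sqrt(1+Q)`
#' (so that `a^2/c = R` and `(a/c)^2 - 1 = Q`).  When `Rx/(1+Qx)` and
#' `Ry/(1+Qy)` disagree, the shared `c` axis is their geometric mean, the
#' radii `Rx`, `Ry` are preserved and the realized asphericities are
#' recomputed from the actual axes (a true ellipsoid has one `c`).
#'
#' @param Rx,Ry apical radii of curvature, mm (> 0).
#' @param Qx,Qy asphericities; must satisfy `1 + Q > 0` (ellipsoidal
#'   regime).  Healthy corneas are prolate, `Q` around -0.3.
#' @param apex_offset apex position `(x, y, z)` in mm.
#' @param tilt_deg rotation of the ellipsoid about the x axis, degrees.
#' @param noise_sigma Gaussian elevation noise SD, mm.
#' @param dropout_fraction fraction of cells replaced by the -1000 sentinel.
#' @param dropout_mode `"random"` (scattered cells), `"wedge"` (a contiguous
#'   angular sector, as when the eyelid or tear film blanks a sector) or
#'   `"ring"` (outermost rings, as with limited scan coverage).
#' @param cone optional list `(amplitude, width, center)`: Gaussian
#'   protrusion in mm added to the elevations (see [add_cone()]).
#' @param seed RNG seed for noise and dropout.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(Rx = 7.8, Ry = 7.8, Qx = -0.3, Qy = -0.3,
                           apex_offset = c(0, 0, 0), tilt_deg = 0,
                           noise_sigma = 0, dropout_fraction = 0,
                           dropout_mode = c("random", "wedge", "ring"),
                           cone = NULL, seed = 1L) {
  dropout_mode <- match.arg(dropout_mode)
  stopifnot(Rx > 0, Ry > 0, 1 + Qx > 0, 1 + Qy > 0,
            noise_sigma >= 0, dropout_fraction >= 0, dropout_fraction < 1,
            length(apex_offset) == 3L)
  if (!is.null(cone))
    stopifnot(is.list(cone), cone$amplitude > 0, cone$width > 0,
              length(cone$center) == 2L)
  structure(list(Rx = Rx, Ry = Ry, Qx = Qx, Qy = Qy,
                 apex_offset = as.numeric(apex_offset),
                 tilt_deg = tilt_deg, noise_sigma = noise_sigma,
                 dropout_fraction = dropout_fraction,
                 dropout_mode = dropout_mode, cone = cone,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Realized ellipsoid of a spec: shared c axis, Rx/Ry preserved, Q recomputed.
realized_ellipsoid <- function(spec) {
  cx <- spec$Rx / (1 + spec$Qx)
  cy <- spec$Ry / (1 + spec$Qy)
  c0 <- if (isTRUE(all.equal(cx, cy))) cx else sqrt(cx * cy)
  a <- sqrt(spec$Rx * c0)
  b <- sqrt(spec$Ry * c0)
  R <- rot_x(spec$tilt_deg)
  center <- spec$apex_offset - as.numeric(R %*% c(0, 0, c0))
  list(ellipsoid = canonical_ellipsoid(c(a, b, c0), R, center),
       morpho = structure(list(Rx = spec$Rx, Ry = spec$Ry,
                               Qx = spec$Rx / c0 - 1,
                               Qy = spec$Ry / c0 - 1),
                          class = "morpho_geometry"))
}

#' Generate a synthetic polar elevation grid with known ground truth
#'
#' Samples the ellipsoid described by `spec` on the 24 x 256 polar grid
#' (the root
#' of the implicit quadric nearer the apex, i.e. the inner corneal cap),
#' adds the cone deformation, Gaussian noise and sentinel dropout in that
#' order.  Grid nodes falling outside the ellipsoid's xy footprint are
#' sentinel-coded and counted.
#'
#' @param spec a [synthetic_spec()].
#' @param dialect grid geometry, a [polar_grid_dialect()].
#' @return list with `grid` (a `polar_grid`) and `truth`: the exact
#'   `coefficients`, `morpho`, `ellipsoid` of the realized (un-deformed)
#'   surface, the `spec`, and `n_footprint_sentinels`.
#' @export
make_ellipsoid_grid <- function(spec, dialect = polar_grid_dialect()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  re <- realized_ellipsoid(spec)
  cf <- ellipsoid_to_quadric(re$ellipsoid)
  nr <- dialect$n_rings; nm <- dialect$n_meridians
  r <- seq_len(nr) * dialect$ring_spacing_mm
  th <- (seq_len(nm) - 1) * 2 * pi / nm
  X <- outer(r, th, function(ri, tj) ri * cos(tj))
  Y <- outer(r, th, function(ri, tj) ri * sin(tj))
  sol <- solve_elevation(cf, as.numeric(X), as.numeric(Y),
                         z_ref = spec$apex_offset[3L])
  Z <- matrix(sol$z, nr, nm)
  n_outside <- sum(!sol$ok)
  Z[!matrix(sol$ok, nr, nm)] <- SENTINEL
  grid <- polar_elevation_grid(Z, ring_spacing_mm = dialect$ring_spacing_mm)
  if (!is.null(spec$cone))
    grid <- add_cone(grid, spec$cone$amplitude, spec$cone$width,
                     spec$cone$center)
  with_seed(spec$seed, {
    if (spec$noise_sigma > 0) {
      valid <- grid$elevations != SENTINEL
      grid$elevations[valid] <- grid$elevations[valid] +
        stats::rnorm(sum(valid), 0, spec$noise_sigma)
    }
    if (spec$dropout_fraction > 0)
      grid <- apply_dropout(grid, spec$dropout_fraction, spec$dropout_mode)
  })
  list(grid = grid,
       truth = list(coefficients = cf, morpho = re$morpho,
                    ellipsoid = re$ellipsoid, spec = spec,
                    n_footprint_sentinels = n_outside))
}

# Sentinel dropout patterns.  `random` hits exactly floor(frac * ncells)
# cells; `wedge` blanks a contiguous sector of meridians; `ring` blanks the
# outermost rings.
apply_dropout <- function(grid, frac, mode) {
  nr <- length(grid$ring_radii); nm <- length(grid$meridian_angles)
  if (mode == "random") {
    k <- floor(frac * nr * nm)
    idx <- sample.int(nr * nm, k)
    grid$elevations[idx] <- SENTINEL
  } else if (mode == "wedge") {
    k <- round(frac * nm)
    if (k > 0) {
      start <- sample.int(nm, 1L)
      cols <- ((start - 1L + seq_len(k) - 1L) %% nm) + 1L
      grid$elevations[, cols] <- SENTINEL
    }
  } else {
    k <- round(frac * nr)
    if (k > 0)
      grid$elevations[seq.int(nr - k + 1L, nr), ] <- SENTINEL
  }
  grid
}

#' Add a keratoconus-like cone deformation to a grid
#'
#' Adds a Gaussian bump `amplitude * exp(-d^2 / (2 width^2))` to every
#' non-sentinel elevation, where `d` is the xy distance from the node to
#' the cone center.  Emulates the localized anterior protrusion of an
#' ectatic cornea; sentinels are untouched.
#'
#' @param grid a `polar_grid`.
#' @param amplitude bump height, mm (> 0; clinically ~0.02-0.1 mm).
#' @param width Gaussian SD of the bump footprint, mm.
#' @param center `(x, y)` position of the cone apex, mm.
#' @return the deformed `polar_grid`.
#' @export
add_cone <- function(grid, amplitude, width, center = c(0, 0)) {
  stopifnot(inherits(grid, "polar_grid"), amplitude >= 0, width > 0)
  nr <- length(grid$ring_radii); nm <- length(grid$meridian_angles)
  X <- outer(grid$ring_radii, grid$meridian_angles,
             function(ri, tj) ri * cos(tj))
  Y <- outer(grid$ring_radii, grid$meridian_angles,
             function(ri, tj) ri * sin(tj))
  d2 <- (X - center[1L])^2 + (Y - center[2L])^2
  bump <- amplitude * exp(-d2 / (2 * width^2))
  valid <- grid$elevations != SENTINEL
  grid$elevations[valid] <- grid$elevations[valid] + bump[valid]
  grid
}

# Cohort presets: per-eye parameter distributions loosely following the
# clinical structure of a control group and three keratoconus severity
# grades.  Cone amplitude grows with grade; asphericity drifts toward -1.
COHORT_PRESETS <- list(
  control = list(Q_mean = -0.31, Q_sd = 0.10, cone_amp = 0,
                 noise = 0.003),
  AK1 = list(Q_mean = -0.62, Q_sd = 0.15, cone_amp = 0.02, noise = 0.003),
  AK2 = list(Q_mean = -0.73, Q_sd = 0.15, cone_amp = 0.05, noise = 0.003),
  AK34 = list(Q_mean = -0.85, Q_sd = 0.15, cone_amp = 0.10, noise = 0.003)
)

#' Generate a cohort of synthetic corneas
#'
#' Draws `n` eyes from a preset group.  Controls are clean prolate
#' ellipsoids with 3 um elevation noise; the keratoconus presets add cone
#' deformations of increasing amplitude (0.02 / 0.05 / 0.10 mm) and draw
#' asphericity toward -1, mirroring advanced ectatic shapes.  Asphericities
#' are truncated to (-0.95, 0) to stay in the ellipsoidal regime.
#'
#' @param n number of eyes.
#' @param grade_preset `"control"`, `"AK1"`, `"AK2"` or `"AK34"`.
#' @param seed RNG seed; the whole cohort is reproducible from it.
#' @param dropout_fraction optional sentinel dropout applied to every eye.
#' @return list of `n` elements, each as returned by
#'   [make_ellipsoid_grid()], with a `group` label attached to each truth.
#' @export
make_cohort <- function(n, grade_preset = c("control", "AK1", "AK2", "AK34"),
                        seed = 1L, dropout_fraction = 0) {
  grade_preset <- match.arg(grade_preset)
  stopifnot(n >= 1L)
  ps <- COHORT_PRESETS[[grade_preset]]
  with_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      Rx <- stats::rnorm(1, 7.8, 0.25)
      Ry <- Rx + stats::rnorm(1, 0, 0.1)
      Qx <- pmin(pmax(stats::rnorm(1, ps$Q_mean, ps$Q_sd), -0.95), -0.05)
      Qy <- pmin(pmax(Qx + stats::rnorm(1, 0, 0.05), -0.95), -0.05)
      cone <- NULL
      if (ps$cone_amp > 0) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, 0.5, 2)
        cone <- list(amplitude = ps$cone_amp, width = 1.5,
                     center = rad * c(cos(ang), sin(ang)))
      }
      sp <- synthetic_spec(Rx = Rx, Ry = Ry, Qx = Qx, Qy = Qy,
                           noise_sigma = ps$noise,
                           dropout_fraction = dropout_fraction,
                           cone = cone,
                           seed = sample.int(2^30, 1L))
      out[[i]] <- make_ellipsoid_grid(sp)
      out[[i]]$truth$group <- grade_preset
    }
    out
  })
}

#' Write a synthetic case to disk (grid CSV + truth JSON sidecar)
#'
#' @param case one element of [make_cohort()] / [make_ellipsoid_grid()].
#' @param path_csv grid output path; the truth sidecar gets the same name
#'   with extension `.truth.json`.
#' @param dialect CSV dialect.
#' @return `path_csv`, invisibly.
#' @export
write_synthetic_case <- function(case, path_csv,
                                 dialect = polar_grid_dialect()) {
  write_polar_csv(case$grid, path_csv, dialect)
  tr <- case$truth
  side <- list(
    coefficients = as.list(stats::setNames(as.numeric(tr$coefficients),
                                           QUADRIC_COEF_NAMES)),
    morpho = unclass(tr$morpho),
    group = tr$group,
    n_footprint_sentinels = tr$n_footprint_sentinels,
    spec = unclass(tr$spec)[c("Rx", "Ry", "Qx", "Qy", "noise_sigma",
                              "dropout_fraction", "dropout_mode", "seed")])
  jsonlite::write_json(side, sub("\\.csv$", "", path_csv) |>
                         paste0(".truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path_csv)
}
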