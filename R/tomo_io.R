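# Sentinel the tomographer writes for an invalid elevation sample.  Part of
# the CSV format contract, compared with == on purpose: the value is exact.
SENTINEL <- -1000

#' CSV dialect of the polar elevation grid
#'
#' Vendor exports vary in delimiter and layout, so the reader is configured
#' through a dialect object rather than hard-coded.  The default matches a
#' Sirius-style export: comma separated, no header, one row per ring
#' (24 rows x 256 columns), rings spaced 0.2 mm apart starting at 0.2 mm,
#' meridians equally spaced with column 1 at 0 degrees.
#'
#' @param delimiter field separator.
#' @param n_rings,n_meridians expected grid dimensions.
#' @param ring_spacing_mm radial spacing in mm; ring i sits at `i * spacing`.
#' @param orientation `"rings_in_rows"` (default) or `"rings_in_cols"`.
#' @return a `polar_dialect` list.
#' @export
polar_grid_dialect <- function(delimiter = ",", n_rings = 24L,
                               n_meridians = 256L, ring_spacing_mm = 0.2,
                               orientation = c("rings_in_rows",
                                               "rings_in_cols")) {
  stopifnot(n_rings >= 1L, n_meridians >= 1L, ring_spacing_mm > 0)
  structure(list(delimiter = delimiter, n_rings = as.integer(n_rings),
                 n_meridians = as.integer(n_meridians),
                 ring_spacing_mm = ring_spacing_mm,
                 orientation = match.arg(orientation)),
            class = "polar_dialect")
}

#' Construct a polar elevation grid
#'
#' The raw sampling pattern of a Scheimpflug tomographer: elevations (mm)
#' on concentric rings crossed with equally spaced semi-meridians.  Invalid
#' acquisitions are coded exactly -1000.
#'
#' @param elevations numeric matrix, rings in rows, meridians in columns.
#' @param ring_radii radii in mm; defaults to `i * ring_spacing_mm`.
#' @param meridian_angles angles in radians in `[0, 2*pi)`; defaults to
#'   `(j - 1) * 2*pi / n_meridians`.
#' @param surface `"anterior"` or `"posterior"`.
#' @param ring_spacing_mm spacing used to build default radii.
#' @return object of class `polar_grid`.
#' @export
polar_elevation_grid <- function(elevations, ring_radii = NULL,
                                 meridian_angles = NULL,
                                 surface = c("anterior", "posterior"),
                                 ring_spacing_mm = 0.2) {
  surface <- match.arg(surface)
  elevations <- as.matrix(elevations)
  storage.mode(elevations) <- "double"
  nr <- nrow(elevations); nm <- ncol(elevations)
  if (nr < 1L || nm < 1L) stop("degenerate grid: ", nr, " x ", nm)
  if (is.null(ring_radii)) ring_radii <- seq_len(nr) * ring_spacing_mm
  if (is.null(meridian_angles))
    meridian_angles <- (seq_len(nm) - 1) * 2 * pi / nm
  if (length(ring_radii) != nr)
    stop("ring_radii length ", length(ring_radii), " != ", nr, " rings")
  if (length(meridian_angles) != nm)
    stop("meridian_angles length ", length(meridian_angles), " != ", nm)
  if (any(ring_radii <= 0) || any(diff(ring_radii) <= 0))
    stop("ring_radii must be strictly increasing and positive")
  if (meridian_angles[1L] != 0 || any(diff(meridian_angles) <= 0))
    stop("meridian_angles must start at 0 and increase")
  bad <- !is.finite(elevations)
  if (any(bad))
    stop("elevations must be finite numbers (use the -1000 sentinel ",
         "for invalid samples)")
  structure(list(ring_radii = as.numeric(ring_radii),
                 meridian_angles = as.numeric(meridian_angles),
                 elevations = elevations,
                 surface = surface),
            class = "polar_grid")
}

#' @export
print.polar_grid <- function(x, ...) {
  ns <- sum(x$elevations == SENTINEL)
  cat(sprintf(
    "<polar_grid: %s surface, %d rings x %d meridians, %d sentinel cells>\n",
    x$surface, length(x$ring_radii), length(x$meridian_angles), ns))
  invisible(x)
}

#' Read a polar elevation grid from CSV
#'
#' @param path file to read.
#' @param dialect a [polar_grid_dialect()].
#' @param surface surface label to attach.
#' @return a [polar_elevation_grid()].
#' @export
read_polar_csv <- function(path, dialect = polar_grid_dialect(),
                           surface = c("anterior", "posterior")) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  cells <- strsplit(lines, dialect$delimiter, fixed = TRUE)
  ncol_seen <- unique(lengths(cells))
  if (length(ncol_seen) != 1L)
    stop("ragged CSV: rows differ in field count (",
         paste(ncol_seen, collapse = ", "), ")")
  m <- matrix(NA_real_, length(cells), ncol_seen)
  for (i in seq_along(cells)) {
    v <- suppressWarnings(as.numeric(cells[[i]]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop(sprintf("non-numeric cell at row %d, column %d: '%s'",
                   i, j, cells[[i]][j]))
    }
    m[i, ] <- v
  }
  if (dialect$orientation == "rings_in_cols") m <- t(m)
  exp_dim <- c(dialect$n_rings, dialect$n_meridians)
  if (!all(dim(m) == exp_dim))
    stop(sprintf("wrong grid dimensions: expected %d x %d, found %d x %d",
                 exp_dim[1], exp_dim[2], nrow(m), ncol(m)))
  polar_elevation_grid(m, surface = match.arg(surface),
                       ring_spacing_mm = dialect$ring_spacing_mm)
}

#' Write a polar elevation grid to CSV
#'
#' Values are written with 17 significant digits so that reading the file
#' back reproduces the elevation matrix bit for bit; the -1000 sentinel is
#' written literally.
#'
#' @param grid a `polar_grid`.
#' @param path output file.
#' @param dialect a [polar_grid_dialect()] (delimiter/orientation used).
#' @return `path`, invisibly.
#' @export
write_polar_csv <- function(grid, path, dialect = polar_grid_dialect()) {
  stopifnot(inherits(grid, "polar_grid"))
  m <- grid$elevations
  if (dialect$orientation == "rings_in_cols") m <- t(m)
  lines <- apply(m, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = dialect$delimiter))
  tryCatch(writeLines(lines, path),
           error = function(e) stop("cannot write '", path, "': ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Construct a Cartesian point cloud
#'
#' @param points N x 3 matrix of (x, y, z) in mm.
#' @param ids optional N x 2 integer matrix of source (ring, meridian)
#'   indices (1-based).
#' @return object of class `point_cloud`.
#' @export
point_cloud <- function(points, ids = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be N x 3")
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y", "z")
  if (!is.null(ids)) {
    ids <- as.matrix(ids)
    if (nrow(ids) != nrow(points) || ncol(ids) != 2L)
      stop("ids must be N x 2 (ring, meridian)")
    colnames(ids) <- c("ring", "meridian")
  }
  structure(list(points = points, ids = ids), class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud: %d points, radius %.2f-%.2f mm>\n",
              nrow(x$points),
              min(sqrt(rowSums(x$points[, 1:2]^2))),
              max(sqrt(rowSums(x$points[, 1:2]^2)))))
  invisible(x)
}

# Accept a point_cloud or a bare matrix anywhere a cloud is expected.
cloud_points <- function(cloud) {
  if (inherits(cloud, "point_cloud")) return(cloud$points)
  p <- as.matrix(cloud)
  if (ncol(p) != 3L) stop("expected a point_cloud or an N x 3 matrix")
  p
}

#' Convert a polar elevation grid to a Cartesian point cloud
#'
#' Each non-sentinel cell (i, j) maps to
#' `(r_i cos(theta_j), r_i sin(theta_j), elevation)`; under the default grid
#' `r_i = i * 0.2` mm and `theta_j = (j - 1) * 2*pi/256`.  Sentinel cells
#' (value -1000) are eliminated.
#'
#' @param grid a `polar_grid`.
#' @return a [point_cloud()] with source (ring, meridian) ids.
#' @export
polar_to_cartesian <- function(grid) {
  stopifnot(inherits(grid, "polar_grid"))
  nr <- length(grid$ring_radii); nm <- length(grid$meridian_angles)
  keep <- grid$elevations != SENTINEL
  if (!any(keep))
    stop("all cells are sentinel: empty point cloud, fitting impossible")
  ring <- row(grid$elevations)[keep]
  mer <- col(grid$elevations)[keep]
  r <- grid$ring_radii[ring]
  th <- grid$meridian_angles[mer]
  point_cloud(cbind(r * cos(th), r * sin(th), grid$elevations[keep]),
              ids = cbind(ring, mer))
}
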