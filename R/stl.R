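# --- 2D Delaunay triangulation (Bowyer-Watson) -----------------------------
#
# Incremental insertion with circumcircle tests.  Written here because no
# installed package provides a planar Delaunay triangulation; adequate for
# the few thousand mesh samples used in STL export.

circumcircle <- function(ax, ay, bx, by, cx, cy) {
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(x = ux, y = uy, r2 = (ax - ux)^2 + (ay - uy)^2)
}

#' Delaunay triangulation of planar points
#'
#' Bowyer-Watson incremental triangulation.  Intended for well-distributed
#' sample sets (the mesh exporter uses a sunflower lattice, which avoids
#' the degenerate cocircular configurations of a regular polar grid).
#'
#' @param xy N x 2 matrix of point coordinates.
#' @return integer matrix, one row per triangle, vertex indices into `xy`.
#' @export
delaunay_triangulate <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 3L) stop("need at least 3 points")
  # super-triangle comfortably enclosing the data
  ctr <- colMeans(xy)
  span <- 4 * max(abs(sweep(xy, 2L, ctr))) + 1
  sup <- rbind(ctr + c(-20 * span, -span),
               ctr + c(20 * span, -span),
               ctr + c(0, 20 * span))
  V <- rbind(xy, sup)
  tri <- matrix(c(n + 1L, n + 2L, n + 3L), 1L)
  cc <- circumcircle(sup[1, 1], sup[1, 2], sup[2, 1], sup[2, 2],
                     sup[3, 1], sup[3, 2])
  ccx <- cc$x; ccy <- cc$y; ccr <- cc$r2
  for (i in seq_len(n)) {
    px <- V[i, 1L]; py <- V[i, 2L]
    bad <- which((px - ccx)^2 + (py - ccy)^2 <= ccr * (1 + 1e-12))
    # boundary of the cavity: edges of bad triangles that appear once
    e <- rbind(tri[bad, c(1L, 2L), drop = FALSE],
               tri[bad, c(2L, 3L), drop = FALSE],
               tri[bad, c(3L, 1L), drop = FALSE])
    key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    single <- !(key %in% key[duplicated(key)])
    e <- e[single, , drop = FALSE]
    new_tri <- cbind(e, i)
    k <- nrow(new_tri)
    a <- V[new_tri[, 1L], , drop = FALSE]
    b <- V[new_tri[, 2L], , drop = FALSE]
    cpt <- V[new_tri[, 3L], , drop = FALSE]
    nc <- circumcircle(a[, 1L], a[, 2L], b[, 1L], b[, 2L],
                       cpt[, 1L], cpt[, 2L])
    keep <- setdiff(seq_len(nrow(tri)), bad)
    tri <- rbind(tri[keep, , drop = FALSE], new_tri)
    ccx <- c(ccx[keep], nc$x); ccy <- c(ccy[keep], nc$y)
    ccr <- c(ccr[keep], nc$r2)
  }
  drop_sup <- rowSums(tri > n) > 0
  out <- tri[!drop_sup, , drop = FALSE]
  dimnames(out) <- NULL
  out
}

# Golden-angle sunflower sampling of a disc: near-uniform, never cocircular.
sunflower_disc <- function(n, radius, center = c(0, 0)) {
  k <- seq_len(n)
  golden <- pi * (3 - sqrt(5))
  r <- radius * sqrt((k - 0.5) / n)
  cbind(center[1L] + r * cos(k * golden),
        center[2L] + r * sin(k * golden))
}

#' Export a fitted quadric surface as a binary STL mesh
#'
#' Samples the surface elevation over a circular footprint centered on the
#' corneal apex (sunflower lattice, `resolution^2` samples), triangulates
#' the samples by planar Delaunay triangulation and writes a binary
#' little-endian STL (units mm).  The mesh is an open cap, not watertight;
#' facet normals point consistently into the +z hemisphere.
#'
#' @param cf fitted `quadric_coef` (must be a valid ellipsoid).
#' @param footprint_radius radius of the exported cap in mm.
#' @param resolution linear sampling resolution; `resolution^2` vertices.
#' @param path output `.stl` file.
#' @return `path`, invisibly; attributes `n_vertices` and `n_triangles`.
#' @export
export_stl <- function(cf, footprint_radius, resolution = 32L, path) {
  e <- to_canonical_ellipsoid(cf)
  xy <- sunflower_disc(as.integer(resolution)^2, footprint_radius,
                       center = e$center[1:2])
  z_ref <- e$center[3L] + 10 * max(e$semi_axes)  # force the upper branch
  sol <- solve_elevation(cf, xy[, 1L], xy[, 2L], z_ref = z_ref)
  if (any(!sol$ok))
    stop("footprint extends beyond the surface: ", sum(!sol$ok),
         " of ", nrow(xy), " sample nodes have no real elevation")
  verts <- cbind(xy, sol$z)
  tri <- delaunay_triangulate(xy)
  # orient counter-clockwise in xy so normals point to +z
  a <- verts[tri[, 1L], 1:2, drop = FALSE]
  b <- verts[tri[, 2L], 1:2, drop = FALSE]
  cpt <- verts[tri[, 3L], 1:2, drop = FALSE]
  area2 <- (b[, 1L] - a[, 1L]) * (cpt[, 2L] - a[, 2L]) -
           (b[, 2L] - a[, 2L]) * (cpt[, 1L] - a[, 1L])
  flip <- area2 < 0
  tri[flip, 2:3] <- tri[flip, 3:2]
  write_binary_stl(verts, tri, path)
  attr(path, "n_vertices") <- nrow(verts)
  attr(path, "n_triangles") <- nrow(tri)
  invisible(path)
}

write_binary_stl <- function(verts, tri, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC("corneal quadric cap (mm)", width = -80))
  writeBin(header[1:80], con)
  writeBin(as.integer(nrow(tri)), con, size = 4L, endian = "little")
  for (t in seq_len(nrow(tri))) {
    v1 <- verts[tri[t, 1L], ]; v2 <- verts[tri[t, 2L], ]
    v3 <- verts[tri[t, 3L], ]
    nrm <- c((v2[2] - v1[2]) * (v3[3] - v1[3]) -
               (v2[3] - v1[3]) * (v3[2] - v1[2]),
             (v2[3] - v1[3]) * (v3[1] - v1[1]) -
               (v2[1] - v1[1]) * (v3[3] - v1[3]),
             (v2[1] - v1[1]) * (v3[2] - v1[2]) -
               (v2[2] - v1[2]) * (v3[1] - v1[1]))
    nl <- sqrt(sum(nrm^2))
    if (nl > 0) nrm <- nrm / nl
    writeBin(as.numeric(c(nrm, v1, v2, v3)), con, size = 4L,
             endian = "little")
    writeBin(0L, con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a binary STL file
#'
#' Minimal reader for round-trip checks of [export_stl()] output.
#'
#' @param path `.stl` file.
#' @return list with `n_triangles`, `normals` and `vertices`
#'   (n x 3 x 3 array).
#' @export
read_binary_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80L))
  nt <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  normals <- matrix(NA_real_, nt, 3L)
  vertices <- array(NA_real_, c(nt, 3L, 3L))
  for (t in seq_len(nt)) {
    rec <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
    normals[t, ] <- rec[1:3]
    vertices[t, , ] <- matrix(rec[4:12], 3L, 3L, byrow = TRUE)
    readBin(con, "integer", 1L, size = 2L, endian = "little")
  }
  list(n_triangles = nt, normals = normals, vertices = vertices)
}
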