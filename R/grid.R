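# Conservative finite-volume grids for the isochoric chamber: 1D-radial
# (infinite cylinder) and 2D-axisymmetric (finite cylinder), with optional
# Type-316 steel wall cells.

#' Chamber geometry description
#'
#' @param kind `"radial1d"` (infinitely long cylinder, radial profile only) or
#'   `"axisym2d"` (finite cylinder, radial-axial profile).
#' @param radius Inner (water) radius in m.
#' @param height Internal height (or represented length for `radial1d`) in m.
#' @param wall_thickness Steel wall thickness in m; 0 applies the convective
#'   boundary directly on the water surface (rigid massless wall).
#' @return A `chamber_geometry` list.
#' @export
chamber_geometry <- function(kind = c("radial1d", "axisym2d"), radius,
                             height, wall_thickness = 0) {
  kind <- match.arg(kind)
  if (!is.finite(radius) || radius <= 0 || !is.finite(height) || height <= 0 ||
      !is.finite(wall_thickness) || wall_thickness < 0)
    stop("degenerate chamber geometry: radius and height must be positive, ",
         "wall thickness nonnegative", call. = FALSE)
  structure(list(kind = kind, radius = radius, height = height,
                 wall_thickness = wall_thickness),
            class = "chamber_geometry")
}

#' Build a conservative finite-volume grid
#'
#' Discretizes the chamber into annular (1D) or annular-ring (2D
#' axisymmetric) cells with a face aligned exactly on the water-steel
#' interface. In 2D the steel jacket (when present) surrounds the water on
#' the side, top, and bottom. Cell volumes are exact annulus volumes, so the
#' water-region volume equals the configured chamber volume to round-off.
#'
#' @param geometry A [chamber_geometry()].
#' @param resolution Number of cells across the water radius (minimum 8).
#' @return An object of class `iso_grid` with cell centers, volumes, material
#'   tags, and precomputed face geometry for assembly.
#' @export
build_grid <- function(geometry, resolution = 16L) {
  stopifnot(inherits(geometry, "chamber_geometry"))
  resolution <- as.integer(resolution)
  if (resolution < 8L)
    stop("resolution must be at least 8 cells across the water radius",
         call. = FALSE)
  a <- geometry$radius
  H <- geometry$height
  w <- geometry$wall_thickness
  dr <- a / resolution
  r_f <- seq(0, a, length.out = resolution + 1L)
  nw_r <- resolution
  if (w > 0) {
    n_wall <- max(4L, ceiling(w / dr))
    r_f <- c(r_f, a + seq_len(n_wall) * (w / n_wall))
  }
  nr <- length(r_f) - 1L

  if (geometry$kind == "radial1d") {
    z_f <- c(0, H)
  } else {
    dz <- min(2 * dr, H / 8)
    nz_w <- max(8L, ceiling(H / dz))
    z_f <- seq(0, H, length.out = nz_w + 1L)
    if (w > 0) {
      n_wz <- max(2L, ceiling(w / (H / nz_w)))
      z_f <- c(-rev(seq_len(n_wz)) * (w / n_wz), z_f,
               H + seq_len(n_wz) * (w / n_wz))
    }
  }
  nz <- length(z_f) - 1L
  r_c <- (r_f[-1] + r_f[-(nr + 1L)]) / 2
  z_c <- (z_f[-1] + z_f[-(nz + 1L)]) / 2
  dz_c <- diff(z_f)
  ring <- pi * diff(r_f^2)                    # ring cross-section area, m^2
  vol <- as.vector(outer(ring, dz_c))         # cell volumes, column-major (i,j)
  idx <- function(i, j) i + (j - 1L) * nr
  is_water <- as.vector(outer(r_c <= a + 1e-15,
                              z_c >= -1e-15 & z_c <= H + 1e-15, "&"))
  material <- ifelse(is_water, "water", "steel")

  # interior radial faces: owner (i,j) -- neighbour (i+1,j)
  io <- as.vector(outer(seq_len(nr - 1L), seq_len(nz), idx))
  rf_area <- as.vector(outer(2 * pi * r_f[2:nr], dz_c))
  rfaces <- list(owner = io, neigh = io + 1L, area = rf_area,
                 d_o = rep(r_f[2:nr] - r_c[1:(nr - 1L)], nz),
                 d_n = rep(r_c[2:nr] - r_f[2:nr], nz))
  # interior axial faces: owner (i,j) -- neighbour (i,j+1)
  afaces <- NULL
  if (nz > 1L) {
    io <- as.vector(outer(seq_len(nr), seq_len(nz - 1L), idx))
    afaces <- list(owner = io, neigh = io + nr, area = rep(ring, nz - 1L),
                   d_o = rep(z_f[2:nz] - z_c[1:(nz - 1L)], each = nr),
                   d_n = rep(z_c[2:nz] - z_f[2:nz], each = nr))
  }
  # boundary faces (convective): outer radius always; chamber ends in 2D
  b_cell <- idx(nr, seq_len(nz))
  b_area <- 2 * pi * r_f[nr + 1L] * dz_c
  b_d <- rep(r_f[nr + 1L] - r_c[nr], nz)
  if (nz > 1L) {
    b_cell <- c(b_cell, idx(seq_len(nr), 1L), idx(seq_len(nr), nz))
    b_area <- c(b_area, ring, ring)
    b_d <- c(b_d, rep(z_c[1] - z_f[1], nr), rep(z_f[nz + 1L] - z_c[nz], nr))
  }
  bfaces <- list(cell = b_cell, area = b_area, d = b_d)

  structure(list(
    geometry = geometry, nr = nr, nz = nz, n = nr * nz,
    r_f = r_f, z_f = z_f, r_c = r_c, z_c = z_c, vol = vol,
    material = material, water = is_water, n_water_r = nw_r,
    rfaces = rfaces, afaces = afaces, bfaces = bfaces
  ), class = "iso_grid")
}

#' @export
print.iso_grid <- function(x, ...) {
  cat(sprintf("<iso_grid> %s, %d x %d cells (%d water, %d steel)\n",
              x$geometry$kind, x$nr, x$nz, sum(x$water), sum(!x$water)))
  cat(sprintf("  water volume %.4g ml, total volume %.4g ml\n",
              1e6 * sum(x$vol[x$water]), 1e6 * sum(x$vol)))
  invisible(x)
}

#' Water-region volume of a grid
#' @param grid An `iso_grid`.
#' @return Volume in m^3.
#' @export
water_volume <- function(grid) sum(grid$vol[grid$water])

# Cell index closest to a physical location (r, z).
.probe_index <- function(grid, r, z = NULL) {
  i <- which.min(abs(grid$r_c - r))
  if (grid$nz == 1L || is.null(z)) return(i)
  j <- which.min(abs(grid$z_c - z))
  i + (j - 1L) * grid$nr
}
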