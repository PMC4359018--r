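#' Sampling grid of a 3D volume
#'
#' Describes the discrete grid on which all volumes in a simulation live:
#' the array shape, the physical voxel size, and the zero-padding factor
#' used when evaluating Fourier-domain field models (padding suppresses the
#' wrap-around leakage of the circular convolution).
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 8).
#' @param voxel_size numeric length 1 or 3, voxel edge length in mm (> 0).
#' @param pad_factor numeric length 1 or 3, >= 1. Each axis is zero-padded
#'   to `ceiling(shape * pad_factor)` before Fourier-domain convolution.
#'   Use 1 for kernel-consistent (periodic) simulation/inversion pairs.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(shape, voxel_size = c(1, 1, 1), pad_factor = 2) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 8L))
    stop("'shape' must be 3 integers, all >= 8")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("'voxel_size' must be positive (length 1 or 3)")
  if (length(pad_factor) == 1L) pad_factor <- rep(pad_factor, 3L)
  if (length(pad_factor) != 3L || any(pad_factor < 1))
    stop("'pad_factor' must be >= 1 (length 1 or 3)")
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size),
                 pad_factor = as.numeric(pad_factor)),
            class = "grid_spec")
}

.padded_shape <- function(grid) as.integer(ceiling(grid$shape * grid$pad_factor))

#' Acquisition context: field direction, strength and echo times
#'
#' @param B0_direction numeric length 3; direction of the main field. Must
#'   be non-zero; it is normalized to a unit vector.
#' @param B0_strength main field strength in tesla (> 0).
#' @param TE1,TE2 first and second echo times in seconds (TE2 > TE1).
#' @return An object of class `field_context` with elements
#'   `B0_direction` (unit vector), `B0_strength`, `larmor` (Hz per ppm),
#'   `TE1`, `TE2`.
#' @export
field_context <- function(B0_direction = c(0, 0, 1), B0_strength = 7,
                          TE1 = 0.007, TE2 = 0.020) {
  if (length(B0_direction) != 3L || !all(is.finite(B0_direction)))
    stop("'B0_direction' must be a finite 3-vector")
  nrm <- sqrt(sum(B0_direction^2))
  if (nrm < 1e-12) stop("'B0_direction' must be non-zero")
  if (!is.finite(B0_strength) || B0_strength <= 0)
    stop("'B0_strength' must be positive")
  if (TE2 <= TE1) stop("TE2 must exceed TE1")
  structure(list(B0_direction = B0_direction / nrm,
                 B0_strength = B0_strength,
                 larmor = larmor_scale(B0_strength),
                 TE1 = TE1, TE2 = TE2),
            class = "field_context")
}

#' Unit vector from polar angles relative to the z axis
#'
#' Convenience constructor for principal-axis / B0 directions:
#' returns `c(sin(theta) cos(phi), sin(theta) sin(phi), cos(theta))`.
#'
#' @param theta_deg polar angle from the z axis, degrees.
#' @param phi_deg azimuth in the x-y plane, degrees.
#' @return Unit 3-vector.
#' @export
polar_axis <- function(theta_deg, phi_deg = 0) {
  t <- theta_deg * pi / 180
  p <- phi_deg * pi / 180
  c(sin(t) * cos(p), sin(t) * sin(p), cos(t))
}

#' A 3D scalar field with physical units
#'
#' The common container for frequency maps (Hz), susceptibility maps (ppm),
#' relaxation-rate maps (s^-1) and dimensionless maps, together with its
#' grid and an optional mask of valid voxels.
#'
#' @param values 3D numeric array matching `grid$shape`.
#' @param grid a [grid_spec()].
#' @param units one of `"Hz"`, `"ppm"`, `"s^-1"`, `"dimensionless"`.
#' @param mask optional 3D logical array of the same shape.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, grid, units, mask = NULL) {
  units <- match.arg(units, c("Hz", "ppm", "s^-1", "dimensionless"))
  if (!inherits(grid, "grid_spec")) stop("'grid' must be a grid_spec")
  if (!identical(dim(values), NULL) && !all(dim(values) == grid$shape))
    stop("'values' dimensions do not match the grid")
  if (is.null(dim(values))) stop("'values' must be a 3D array")
  if (!is.null(mask)) {
    if (!all(dim(mask) == grid$shape)) stop("'mask' dimensions do not match the grid")
    mask <- array(as.logical(mask), dim = grid$shape)
    if (any(!is.finite(values[mask]))) stop("non-finite values inside mask")
  } else if (any(!is.finite(values))) {
    stop("non-finite values in volume")
  }
  structure(list(values = values, grid = grid, units = units, mask = mask),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume> %s, %d x %d x %d voxels (%.3g x %.3g x %.3g mm)\n",
              x$units, x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              x$grid$voxel_size[1], x$grid$voxel_size[2], x$grid$voxel_size[3]))
  rng <- range(if (is.null(x$mask)) x$values else x$values[x$mask])
  cat(sprintf("  range: [%.4g, %.4g]%s\n", rng[1], rng[2],
              if (is.null(x$mask)) "" else sprintf(", %d masked voxels", sum(x$mask))))
  invisible(x)
}

#' Voxelwise symmetric rank-2 susceptibility tensor field
#'
#' Stores the six unique components (xx, yy, zz, xy, xz, yz) of a symmetric
#' tensor per voxel, in ppm.
#'
#' @param xx,yy,zz,xy,xz,yz 3D numeric arrays matching `grid$shape`.
#' @param grid a [grid_spec()].
#' @return An object of class `symmetric_tensor_volume` with element
#'   `components`, a named list of the six arrays.
#' @export
symmetric_tensor_volume <- function(xx, yy, zz, xy, xz, yz, grid) {
  if (!inherits(grid, "grid_spec")) stop("'grid' must be a grid_spec")
  comps <- list(xx = xx, yy = yy, zz = zz, xy = xy, xz = xz, yz = yz)
  for (nm in names(comps)) {
    if (!all(dim(comps[[nm]]) == grid$shape))
      stop(sprintf("component '%s' dimensions do not match the grid", nm))
    if (any(!is.finite(comps[[nm]])))
      stop(sprintf("non-finite values in component '%s'", nm))
  }
  structure(list(components = comps, grid = grid),
            class = "symmetric_tensor_volume")
}

#' @export
print.symmetric_tensor_volume <- function(x, ...) {
  cat(sprintf("<symmetric_tensor_volume> %d x %d x %d voxels, 6 components (ppm)\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3]))
  invisible(x)
}

#' Build a tensor volume from an isotropic part and a cylindrically
#' symmetric anisotropic part
#'
#' Uses the convention `X = chi_I I + chi_A (3/2)(n n^T - I/3)`, under which
#' the parallel minus perpendicular eigenvalue difference (the overall
#' susceptibility anisotropy) equals `(3/2) chi_A`.
#'
#' @param chiI 3D array (or scalar) of isotropic susceptibility, ppm.
#' @param chiA 3D array (or scalar) of the anisotropy parameter, ppm.
#' @param axis either a unit 3-vector (uniform principal axis) or an array
#'   of dimension `c(shape, 3)` giving a per-voxel unit axis.
#' @param grid a [grid_spec()].
#' @return A [symmetric_tensor_volume()].
#' @export
cylsym_tensor <- function(chiI, chiA, axis, grid) {
  sh <- grid$shape
  expand <- function(v) if (length(v) == 1L) array(v, dim = sh) else v
  chiI <- expand(chiI); chiA <- expand(chiA)
  if (is.null(dim(axis)) && length(axis) == 3L) {
    n <- axis / sqrt(sum(axis^2))
    nx <- array(n[1], sh); ny <- array(n[2], sh); nz <- array(n[3], sh)
  } else {
    if (!all(dim(axis) == c(sh, 3L))) stop("'axis' must be a 3-vector or a c(shape, 3) array")
    nx <- array(axis[, , , 1], sh); ny <- array(axis[, , , 2], sh); nz <- array(axis[, , , 3], sh)
    nrm <- sqrt(nx^2 + ny^2 + nz^2)
    bad <- nrm < 1e-12 & chiA != 0
    if (any(bad)) stop("zero-length axis in voxels with non-zero chiA")
    nrm[nrm < 1e-12] <- 1
    nx <- nx / nrm; ny <- ny / nrm; nz <- nz / nrm
  }
  symmetric_tensor_volume(
    xx = chiI + 1.5 * chiA * (nx * nx - 1 / 3),
    yy = chiI + 1.5 * chiA * (ny * ny - 1 / 3),
    zz = chiI + 1.5 * chiA * (nz * nz - 1 / 3),
    xy = 1.5 * chiA * nx * ny,
    xz = 1.5 * chiA * nx * nz,
    yz = 1.5 * chiA * ny * nz,
    grid = grid)
}
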