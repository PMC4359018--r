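#' Normalize an FA map by a reference value
#'
#' Divides fractional anisotropy by the reference FA of coherently
#' oriented optic-nerve tissue (0.59), yielding the coherence weight used
#' to modulate both the anisotropy parameter and the microstructure
#' offset. Values above 1 are possible and deliberately not clipped.
#'
#' @param FA a [scalar_volume()] (dimensionless) or 3D array.
#' @param ref reference FA (> 0), default 0.59.
#' @return Same type as `FA`.
#' @export
fa_normalize <- function(FA, ref = 0.59) {
  if (ref <= 0) stop("'ref' must be > 0")
  if (inherits(FA, "scalar_volume"))
    scalar_volume(FA$values / ref, FA$grid, "dimensionless", mask = FA$mask)
  else FA / ref
}

#' Angle between the fiber axis and B0, per voxel
#'
#' `theta = arccos |v . h|` in degrees, folded into `[0, 90]` by the axial
#' symmetry of a fiber (v and -v are the same axis). Voxels with a zero
#' fiber vector get `NA`.
#'
#' @param fiber_dirs array of dimension `c(shape, 3)` of (unit) fiber
#'   vectors.
#' @param B0_direction unit 3-vector.
#' @return 3D array of angles in degrees (`NA` where undefined).
#' @export
fiber_angle_map <- function(fiber_dirs, B0_direction) {
  h <- B0_direction / sqrt(sum(B0_direction^2))
  sh <- dim(fiber_dirs)[1:3]
  vx <- array(fiber_dirs[, , , 1], sh)
  vy <- array(fiber_dirs[, , , 2], sh)
  vz <- array(fiber_dirs[, , , 3], sh)
  nrm <- sqrt(vx^2 + vy^2 + vz^2)
  d <- abs(vx * h[1] + vy * h[2] + vz * h[3]) / ifelse(nrm > 1e-12, nrm, NA)
  array(acos(pmin(1, d)) * 180 / pi, dim = sh)
}

#' Microstructure frequency-offset parameters
#'
#' @param A_fit amplitude of the sin-squared orientation dependence, Hz
#'   (default the optic-nerve estimate, -5.59 Hz).
#' @param b0 orientation-independent WM frequency offset, Hz (default 0).
#' @return An object of class `micro_params`.
#' @export
micro_params <- function(A_fit = -5.59, b0 = 0) {
  if (!is.finite(A_fit) || !is.finite(b0)) stop("parameters must be finite")
  structure(list(A_fit = A_fit, b0 = b0), class = "micro_params")
}

#' Local microstructure frequency-offset map
#'
#' `f_M = A_fit FA_n (sin^2 theta - 2/3) + b0` inside the WM mask and 0
#' elsewhere. The -2/3 term makes the average of `f_M` over a random
#' (isotropic) distribution of fiber orientations vanish, separating the
#' microstructure term from the orientation-independent offset `b0`.
#' This is a direct local map: microstructure shifts the resonance of the
#' water that samples it and is not a field source to be convolved.
#'
#' @param params a [micro_params()].
#' @param FA_n normalized-FA 3D array or scalar_volume (see
#'   [fa_normalize()]).
#' @param theta_map 3D array of fiber-to-field angles in degrees (see
#'   [fiber_angle_map()]).
#' @param wm_mask 3D logical array; the offset exists only in WM.
#' @param grid a [grid_spec()].
#' @return A [scalar_volume()] in Hz.
#' @export
micro_offset_map <- function(params, FA_n, theta_map, wm_mask, grid) {
  if (inherits(FA_n, "scalar_volume")) FA_n <- FA_n$values
  s2 <- sin(theta_map * pi / 180)^2
  f <- (params$A_fit * FA_n * (s2 - 2 / 3) + params$b0)
  f[!wm_mask] <- 0
  f[is.na(f)] <- 0
  scalar_volume(f, grid, "Hz", mask = NULL)
}

# assemble the voxelwise susceptibility tensor of a brain model:
# isotropic chi_I plus the zero-trace cylindrically symmetric part with
# per-voxel axis = fiber direction and magnitude = chi_A map
#' Susceptibility tensor field of a brain model
#'
#' @param model a [make_brain_model()] result.
#' @return A [symmetric_tensor_volume()].
#' @export
brain_tensor <- function(model) {
  cylsym_tensor(model$chiI$values, model$chiA$values, model$fiber_dirs,
                model$grid)
}

#' Compose frequency maps from a brain susceptibility model
#'
#' Builds the component frequency maps for one B0 direction:
#' `f_I` from the isotropic susceptibility map, `f_A` from the zero-trace
#' anisotropic tensor field (per-voxel axis = fiber direction, magnitude =
#' chi_A map) via the general tensor forward model, and `f_M` from the
#' local microstructure offset model; plus the composites
#' `f_IA = f_I + f_A` and `f_IAM = f_I + f_A + f_M`. All maps are masked
#' by the brain mask (values outside set to 0), mirroring in vivo data
#' where no frequency is available outside the brain.
#'
#' @param model a [make_brain_model()] result.
#' @param ctx a [field_context()].
#' @param include character subset of `c("iso", "aniso", "micro")`;
#'   excluded components are zero maps.
#' @param params a [micro_params()] (micro amplitude and b0 offset).
#' @return named list of [scalar_volume()]s in Hz:
#'   `f_I`, `f_A`, `f_M`, `f_IA`, `f_IAM`.
#' @export
compose <- function(model, ctx, include = c("iso", "aniso", "micro"),
                    params = micro_params()) {
  if (length(include) > 0)
    include <- match.arg(include, c("iso", "aniso", "micro"), several.ok = TRUE)
  g <- model$grid
  bm <- model$brain_mask
  zero <- function() scalar_volume(array(0, dim = g$shape), g, "Hz", mask = bm)
  msk <- function(v) {
    v$values[!bm] <- 0
    scalar_volume(v$values, g, "Hz", mask = bm)
  }
  fI <- if ("iso" %in% include) msk(simulate_iso_field(model$chiI, ctx)) else zero()
  fA <- if ("aniso" %in% include) {
    if (is.null(model$fiber_dirs)) stop("anisotropy requested but model has no fiber field")
    X <- brain_tensor(model)
    # remove the isotropic part: f_A is the purely anisotropic contribution
    XA <- symmetric_tensor_volume(
      X$components$xx - model$chiI$values, X$components$yy - model$chiI$values,
      X$components$zz - model$chiI$values, X$components$xy, X$components$xz,
      X$components$yz, g)
    msk(tensor_forward(XA, ctx))
  } else zero()
  fM <- if ("micro" %in% include) {
    th <- fiber_angle_map(model$fiber_dirs, ctx$B0_direction)
    msk(micro_offset_map(params, fa_normalize(model$FA)$values, th,
                         model$wm_mask, g))
  } else zero()
  fIA <- scalar_volume(fI$values + fA$values, g, "Hz", mask = bm)
  fIAM <- scalar_volume(fIA$values + fM$values, g, "Hz", mask = bm)
  list(f_I = fI, f_A = fA, f_M = fM, f_IA = fIA, f_IAM = fIAM)
}

#' Compose frequency maps for many B0 orientations
#'
#' Multi-orientation version of [compose()] that factors the
#' orientation-independent work (the Fourier transforms of the tensor
#' components and of the isotropic map) out of the per-orientation loop.
#'
#' @param model a [make_brain_model()] result.
#' @param orientations matrix of unit B0 row vectors (e.g.
#'   [hemisphere_orientations()]).
#' @param include,params as in [compose()].
#' @param B0_strength tesla.
#' @return list with one [compose()]-style named list per orientation.
#' @export
compose_orientations <- function(model, orientations,
                                 include = c("iso", "aniso", "micro"),
                                 params = micro_params(), B0_strength = 7) {
  if (length(include) > 0)
    include <- match.arg(include, c("iso", "aniso", "micro"), several.ok = TRUE)
  g <- model$grid
  bm <- model$brain_mask
  psh <- .padded_shape(g)
  f0 <- larmor_scale(B0_strength)
  zero <- function() scalar_volume(array(0, dim = g$shape), g, "Hz", mask = bm)

  chiI_hat <- if ("iso" %in% include)
    stats::fft(.pad_array(model$chiI$values, psh)) else NULL
  XA_hat <- NULL
  if ("aniso" %in% include) {
    X <- brain_tensor(model)
    XA_hat <- lapply(names(X$components), function(nm) {
      v <- X$components[[nm]]
      if (nm %in% c("xx", "yy", "zz")) v <- v - model$chiI$values
      stats::fft(.pad_array(v, psh))
    })
    names(XA_hat) <- names(X$components)
  }
  fa_n <- fa_normalize(model$FA)$values

  out <- vector("list", nrow(orientations))
  for (i in seq_len(nrow(orientations))) {
    h <- orientations[i, ]
    h <- h / sqrt(sum(h^2))
    ctx <- field_context(B0_direction = h, B0_strength = B0_strength)
    fI <- if ("iso" %in% include) {
      D <- .iso_kernel_arr(psh, g$voxel_size, h)
      v <- f0 * .crop_array(.ifft_re(chiI_hat * D), g$shape)
      v[!bm] <- 0
      scalar_volume(v, g, "Hz", mask = bm)
    } else zero()
    fA <- if ("aniso" %in% include) {
      coeff <- .tensor_coeff_arrs(psh, g$voxel_size, h)
      acc <- array(0 + 0i, dim = psh)
      for (nm in names(coeff)) acc <- acc + coeff[[nm]] * XA_hat[[nm]]
      v <- f0 * .crop_array(.ifft_re(acc), g$shape)
      v[!bm] <- 0
      scalar_volume(v, g, "Hz", mask = bm)
    } else zero()
    fM <- if ("micro" %in% include) {
      th <- fiber_angle_map(model$fiber_dirs, h)
      v <- micro_offset_map(params, fa_n, th, model$wm_mask, g)
      v$values[!bm] <- 0
      scalar_volume(v$values, g, "Hz", mask = bm)
    } else zero()
    fIA <- scalar_volume(fI$values + fA$values, g, "Hz", mask = bm)
    fIAM <- scalar_volume(fIA$values + fM$values, g, "Hz", mask = bm)
    out[[i]] <- list(f_I = fI, f_A = fA, f_M = fM, f_IA = fIA, f_IAM = fIAM)
  }
  out
}
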