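#' TKD inversion parameters
#'
#' @param threshold truncation threshold delta on the magnitude of the
#'   dipole kernel, in (0, 2/3).
#' @param variant `"standard"`: sign-preserving clipping of `1/D` at
#'   `1/delta`; `"fully_relaxed"`: the inverse kernel is set to the
#'   positive truncation value `+1/delta` over the whole sub-threshold
#'   region (sign discarded).
#' @param apply_correction multiply the reconstruction by the global
#'   correction factor compensating kernel truncation (default `TRUE`).
#' @return An object of class `tkd_params`.
#' @export
tkd_params <- function(threshold = 0.07,
                       variant = c("standard", "fully_relaxed"),
                       apply_correction = TRUE) {
  variant <- match.arg(variant)
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 2 / 3)
    stop("'threshold' must be in (0, 2/3)")
  structure(list(threshold = threshold, variant = variant,
                 apply_correction = apply_correction),
            class = "tkd_params")
}

#' Thresholded inverse dipole kernel
#'
#' The k-space division kernel of TKD QSM: `1/D` where `|D| >= delta`;
#' inside the truncation region (the conical surface where D is small)
#' the standard variant uses `sign(D)/delta` (with `sign(0)` taken as +1)
#' and the fully relaxed variant uses `+1/delta` throughout. A threshold
#' of 0.07 corresponds to a truncation value of about 14 in reciprocal
#' units.
#'
#' @param grid a [grid_spec()].
#' @param ctx a [field_context()].
#' @param params a [tkd_params()].
#' @return 3D numeric array on `grid$shape` (the acquisition grid; the
#'   inversion is kernel-consistent, unpadded).
#' @export
tkd_inverse_kernel <- function(grid, ctx, params = tkd_params()) {
  D <- .iso_kernel_arr(grid$shape, grid$voxel_size, ctx$B0_direction)
  dl <- params$threshold
  sgn <- ifelse(D >= 0, 1, -1)  # sign(0) -> +1
  if (params$variant == "standard") {
    ifelse(abs(D) >= dl, 1 / ifelse(D == 0, Inf, D), sgn / dl)
  } else {
    ifelse(abs(D) >= dl, 1 / ifelse(D == 0, Inf, D), 1 / dl)
  }
}

#' Global TKD amplitude correction factor
#'
#' Kernel truncation attenuates the reconstruction; the compensation is
#' `c = 1 / PSF(0)` where `PSF = IFT{ D * Dinv_tkd }` is the point-spread
#' function of forward-then-inverse kernel application and `PSF(0)` its
#' central value, `mean_k(D * Dinv)`. Tends to 1 as delta tends to 0 and
#' grows monotonically with delta.
#'
#' @inheritParams tkd_inverse_kernel
#' @return scalar correction factor (>= 1).
#' @export
tkd_correction_factor <- function(grid, ctx, params = tkd_params()) {
  D <- .iso_kernel_arr(grid$shape, grid$voxel_size, ctx$B0_direction)
  Dinv <- tkd_inverse_kernel(grid, ctx, params)
  1 / mean(D * Dinv)
}

#' TKD quantitative susceptibility mapping
#'
#' Direct dipole inversion `chi = c IFT{ Dinv_tkd FT{ f / f0 } }` (real
#' part), on the acquisition grid. The input frequency map should be
#' brain-masked and mean-referenced; when a mask is attached the masked
#' mean is removed before inversion and the output is masked the same
#' way. Linear in the input.
#'
#' @param freq a [scalar_volume()] in Hz.
#' @param ctx a [field_context()].
#' @param params a [tkd_params()].
#' @return A [scalar_volume()] in ppm.
#' @export
qsm_tkd <- function(freq, ctx, params = tkd_params()) {
  if (!inherits(freq, "scalar_volume") || freq$units != "Hz")
    stop("'freq' must be a scalar_volume in Hz")
  g <- freq$grid
  f <- freq$values
  if (!is.null(freq$mask)) {
    f[!freq$mask] <- 0
    f[freq$mask] <- f[freq$mask] - mean(f[freq$mask])
  }
  Dinv <- tkd_inverse_kernel(g, ctx, params)
  chi_c <- stats::fft(stats::fft(f / ctx$larmor) * Dinv, inverse = TRUE) /
    length(f)
  imag_ratio <- max(abs(Im(chi_c))) / max(max(abs(Re(chi_c))), 1e-300)
  if (imag_ratio > 1e-9)
    warning(sprintf("imaginary residue %.2g of signal after inversion", imag_ratio))
  chi <- Re(chi_c)
  if (params$apply_correction)
    chi <- chi * tkd_correction_factor(g, ctx, params)
  if (!is.null(freq$mask)) chi[!freq$mask] <- 0
  scalar_volume(chi, g, "ppm", mask = freq$mask)
}
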