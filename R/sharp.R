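#' SHARP filter parameters
#'
#' @param kernel_radius radius of the spherical-mean-value kernel, in
#'   voxels (> 0). Default 4.
#' @param tsvd_threshold truncation threshold for the deconvolution of
#'   `(delta - rho)`; Fourier coefficients of magnitude below this are
#'   zeroed. In (0, 1). The default 0.01 confines the stop band to the
#'   few lowest spatial frequencies when the kernel is small: with a
#'   4-voxel kernel a 0.05 threshold would reject structure at the scale
#'   of a compact embedded sample and leak its internal frequency offsets
#'   into the surrounding pass-band region.
#' @param erosion reliability erosion of the mask, in voxels (>= 1).
#'   Defaults to `ceiling(kernel_radius)`: the spherical mean is only
#'   fully supported that far inside the mask.
#' @return An object of class `sharp_params`.
#' @export
sharp_params <- function(kernel_radius = 4, tsvd_threshold = 0.01,
                         erosion = NULL) {
  if (kernel_radius <= 0) stop("'kernel_radius' must be > 0")
  if (tsvd_threshold <= 0 || tsvd_threshold >= 1)
    stop("'tsvd_threshold' must be in (0, 1)")
  if (is.null(erosion)) erosion <- ceiling(kernel_radius)
  if (erosion < 1) stop("'erosion' must be >= 1")
  structure(list(kernel_radius = kernel_radius,
                 tsvd_threshold = tsvd_threshold,
                 erosion = erosion),
            class = "sharp_params")
}

#' SHARP background field removal
#'
#' Sophisticated harmonic artifact reduction for phase data: fields that
#' are harmonic inside the mask (i.e. produced by susceptibility sources
#' outside it) satisfy the spherical-mean-value property and are
#' annihilated by convolution with `(delta - rho)`, where `rho` is a
#' normalized sphere. The masked SMV difference is then deconvolved by
#' truncated division in k-space to restore the pass-band (internal-source)
#' field. The output is only defined on the mask eroded by `erosion`
#' voxels, and its mean over that region is removed.
#'
#' @param freq a [scalar_volume()] in Hz.
#' @param mask 3D logical array of the reliable-signal region (e.g. the
#'   gel sphere or the brain); must be strictly inside the grid.
#' @param params a [sharp_params()].
#' @return list with elements `field` (scalar_volume, Hz, masked by the
#'   eroded mask) and `mask` (the eroded mask).
#' @export
sharp_filter <- function(freq, mask, params = sharp_params()) {
  if (!inherits(freq, "scalar_volume") || freq$units != "Hz")
    stop("'freq' must be a scalar_volume in Hz")
  sh <- freq$grid$shape
  if (!all(dim(mask) == sh)) stop("mask dimensions do not match the grid")
  mask <- mask != 0
  me <- erode_mask(mask, params$erosion)
  if (!any(me)) stop("mask too small: erosion by the kernel radius empties it")
  rho_hat <- Re(stats::fft(.sphere_kernel_arr(sh, params$kernel_radius)))
  C <- 1 - rho_hat
  smv <- .ifft_re(stats::fft(freq$values * mask) * C)
  smv[!me] <- 0
  Cinv <- ifelse(abs(C) > params$tsvd_threshold, 1 / C, 0)
  out <- .ifft_re(stats::fft(smv) * Cinv)
  out[!me] <- 0
  out[me] <- out[me] - mean(out[me])
  list(field = scalar_volume(out, freq$grid, "Hz", mask = me), mask = me)
}
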