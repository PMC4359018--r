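#' Binary dilation of a 3D mask by a spherical structuring element
#'
#' Dilation with a discrete Euclidean ball of the given radius (in voxels),
#' evaluated by Fourier convolution with the ball and thresholding the
#' (integer-valued) overlap count. The grid is treated as periodic, so the
#' mask must sit far enough from the array boundary that the dilated set
#' does not wrap.
#'
#' @param mask 3D logical array.
#' @param radius_vox dilation radius in voxels (>= 0).
#' @return 3D logical array.
#' @export
dilate_mask <- function(mask, radius_vox) {
  if (radius_vox < 0) stop("'radius_vox' must be >= 0")
  if (radius_vox == 0) return(mask != 0)
  sh <- dim(mask)
  ker <- .sphere_kernel_arr(sh, radius_vox)
  n_se <- round(1 / max(ker))
  cnt <- .ifft_re(stats::fft(array(as.numeric(mask != 0), dim = sh)) *
                    stats::fft(ker * n_se))
  round(cnt) > 0
}

#' Binary erosion of a 3D mask by a spherical structuring element
#'
#' Complement of the dilation of the complement; same conventions as
#' [dilate_mask()].
#'
#' @inheritParams dilate_mask
#' @return 3D logical array.
#' @export
erode_mask <- function(mask, radius_vox) {
  if (radius_vox < 0) stop("'radius_vox' must be >= 0")
  if (radius_vox == 0) return(mask != 0)
  !dilate_mask(!(mask != 0), radius_vox)
}
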