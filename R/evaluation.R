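#' Difference-from-truth map
#'
#' Voxelwise reconstruction minus ground truth, the basic artifact map.
#'
#' @param recon,truth [scalar_volume()]s with identical grids and units.
#' @return A [scalar_volume()] in the shared units.
#' @export
dft_map <- function(recon, truth) {
  if (recon$units != truth$units)
    stop(sprintf("unit mismatch: %s vs %s", recon$units, truth$units))
  if (!all(recon$grid$shape == truth$grid$shape))
    stop("inputs are on different grids")
  scalar_volume(recon$values - truth$values, recon$grid, recon$units,
                mask = recon$mask)
}

#' Standard deviation over a white-matter mask
#'
#' Population (divide-by-N) standard deviation of a map's values inside
#' the mask; used as the scalar heterogeneity / artifact metric.
#'
#' @param map a [scalar_volume()] or 3D array.
#' @param wm_mask 3D logical array (non-empty).
#' @return scalar SD in the map's units.
#' @export
wm_sd <- function(map, wm_mask) {
  v <- if (inherits(map, "scalar_volume")) map$values else map
  if (!any(wm_mask != 0)) stop("mask is empty")
  x <- v[wm_mask != 0]
  sqrt(mean((x - mean(x))^2))
}

#' Per-region mean and SD
#'
#' Mean, population SD and voxel count of a map over each named region
#' mask. Empty regions are skipped with a warning.
#'
#' @param map a [scalar_volume()] or 3D array.
#' @param masks named list of 3D logical arrays.
#' @return data.frame with columns `roi`, `mean`, `sd`, `n`.
#' @export
roi_stats <- function(map, masks) {
  v <- if (inherits(map, "scalar_volume")) map$values else map
  rows <- lapply(names(masks), function(nm) {
    m <- masks[[nm]] != 0
    if (!any(m)) {
      warning(sprintf("region '%s' is empty; skipped", nm))
      return(NULL)
    }
    x <- v[m]
    data.frame(roi = nm, mean = mean(x),
               sd = sqrt(mean((x - mean(x))^2)), n = sum(m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
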