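#' Write a scalar volume to NIfTI with a JSON sidecar
#'
#' The image is stored as NIfTI-1 in double precision (so volumes
#' round-trip bit-exactly) with the voxel size in the header; units and
#' grid metadata go to `<path>.json`. A mask, when present, is written as
#' `<stem>_mask.nii.gz`.
#'
#' @param vol a [scalar_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values, internal = FALSE)
  RNifti::pixdim(img) <- vol$grid$voxel_size
  RNifti::writeNifti(img, path, datatype = "double")
  sidecar <- sub("(\\.nii(\\.gz)?)$", "", path)
  jsonlite::write_json(
    list(units = vol$units, voxel_size = vol$grid$voxel_size,
         pad_factor = vol$grid$pad_factor, has_mask = !is.null(vol$mask)),
    paste0(sidecar, ".json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(vol$mask)) {
    mimg <- RNifti::asNifti(array(as.integer(vol$mask), dim = vol$grid$shape),
                            internal = FALSE)
    RNifti::pixdim(mimg) <- vol$grid$voxel_size
    RNifti::writeNifti(mimg, paste0(sidecar, "_mask.nii.gz"), datatype = "uint8")
  }
  invisible(path)
}

#' Read a scalar volume written by [write_volume()]
#'
#' @param path path to the NIfTI file.
#' @return A [scalar_volume()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  stem <- sub("(\\.nii(\\.gz)?)$", "", path)
  meta_path <- paste0(stem, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    g <- grid_spec(dim(vals), meta$voxel_size,
                   if (!is.null(meta$pad_factor)) meta$pad_factor else 2)
    units <- meta$units
    mask <- NULL
    mask_path <- paste0(stem, "_mask.nii.gz")
    if (isTRUE(meta$has_mask) && file.exists(mask_path))
      mask <- array(as.numeric(RNifti::readNifti(mask_path)) != 0,
                    dim = dim(vals))
    scalar_volume(vals, g, units, mask = mask)
  } else {
    vs <- attr(img, "pixdim")
    if (is.null(vs)) vs <- RNifti::pixdim(img)
    scalar_volume(vals, grid_spec(dim(vals), vs[1:3]), "dimensionless")
  }
}

#' Export a bulk susceptibility fit as JSON and CSV
#'
#' @param fit a [fit_bulk_chi()] result.
#' @param stem output path stem; writes `<stem>.json` and `<stem>.csv`.
#' @return `stem`, invisibly.
#' @export
write_fit_result <- function(fit, stem) {
  lst <- unclass(fit)
  jsonlite::write_json(lst, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(as.data.frame(lst), paste0(stem, ".csv"),
                   row.names = FALSE)
  invisible(stem)
}
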