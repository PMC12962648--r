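#' Read and write diffusion volumes as NIfTI-1 with FSL-style gradients
#'
#' `write_dwi()` writes `<prefix>.nii.gz`, `<prefix>.bval` (one
#' whitespace-separated row) and `<prefix>.bvec` (three rows: x, y, z
#' components). `read_dwi()` reads the triple back into a
#' `diffusion_volume`.
#'
#' @param dwi A `diffusion_volume`.
#' @param prefix Output path prefix.
#' @return `read_dwi()` returns a `diffusion_volume`; `write_dwi()` returns
#'   the written paths invisibly.
#' @export
write_dwi <- function(dwi, prefix) {
  stopifnot(inherits(dwi, "diffusion_volume"))
  nii <- paste0(prefix, ".nii.gz")
  img <- RNifti::asNifti(dwi$signal,
                         pixdim = rep(dwi$voxel_size, 3))
  RNifti::writeNifti(img, nii)
  bval <- paste0(prefix, ".bval")
  bvec <- paste0(prefix, ".bvec")
  writeLines(paste(format(dwi$scheme$bvals, trim = TRUE), collapse = " "), bval)
  writeLines(apply(dwi$scheme$bvecs, 1, function(r) {
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")
  }), bvec)
  invisible(c(nii, bval, bvec))
}

#' @rdname write_dwi
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param bval_path,bvec_path Gradient-table paths; default to `path` with
#'   the extensions swapped.
#' @param label Scheme label.
#' @export
read_dwi <- function(path, bval_path = NULL, bvec_path = NULL,
                     label = "loaded") {
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  if (is.null(bval_path)) bval_path <- paste0(stem, ".bval")
  if (is.null(bvec_path)) bvec_path <- paste0(stem, ".bvec")
  img <- RNifti::readNifti(path)
  sig <- array(as.numeric(img), dim = dim(img))
  if (length(dim(sig)) != 4) stop("expected a 4D DWI volume", call. = FALSE)
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- matrix(scan(bvec_path, quiet = TRUE), nrow = 3, byrow = TRUE)
  vx <- RNifti::pixdim(img)[1]
  structure(
    list(
      signal = sig,
      scheme = acquisition_scheme(bvals, bvecs, label),
      voxel_size = vx,
      brain_mask = array(TRUE, dim(sig)[1:3])
    ),
    class = "diffusion_volume"
  )
}

#' Write a scalar map as float32 NIfTI-1
#'
#' @param map 3D numeric array.
#' @param path Output `.nii.gz` path.
#' @param voxel_size Voxel edge length in mm.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, voxel_size = 1) {
  img <- RNifti::asNifti(map, pixdim = rep(voxel_size, 3), datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim = dim(img))
}

#' Write integer-label masks with a JSON sidecar
#'
#' Segmentations and ROI masks are written as integer NIfTI-1 volumes; the
#' label legend (and, for ROI sets, hemisphere/category/tumor side) goes to
#' a `.json` sidecar next to the volume.
#'
#' @param seg A `tumor_segmentation`.
#' @param prefix Output path prefix.
#' @return Written paths, invisibly.
#' @export
write_segmentation <- function(seg, prefix) {
  stopifnot(inherits(seg, "tumor_segmentation"))
  nii <- paste0(prefix, ".nii.gz")
  img <- RNifti::asNifti(seg$labels + 0L, pixdim = rep(seg$voxel_size, 3),
                         datatype = "int16")
  RNifti::writeNifti(img, nii)
  side <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(legend = as.list(seg$legend),
         tumor_side = seg$tumor_side,
         enhancing_volume_ml = seg$enhancing_volume_ml),
    side, auto_unbox = TRUE, digits = NA
  )
  invisible(c(nii, side))
}

#' @rdname write_segmentation
#' @param rois An `alps_roi_set`.
#' @export
write_rois <- function(rois, prefix) {
  stopifnot(inherits(rois, "alps_roi_set"))
  files <- character()
  for (side in c("left", "right")) {
    for (kind in c("proj", "assoc")) {
      nii <- sprintf("%s_%s_%s.nii.gz", prefix, side, kind)
      img <- RNifti::asNifti(rois[[side]][[kind]] + 0L,
                             pixdim = rep(rois$voxel_size, 3),
                             datatype = "int16")
      RNifti::writeNifti(img, nii)
      files <- c(files, nii)
    }
  }
  side <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(diameter_mm = rois$diameter_mm,
         category = as.list(rois$category),
         tumor_side = rois$tumor_side),
    side, auto_unbox = TRUE, digits = NA
  )
  invisible(c(files, side))
}

#' Read or write a cohort table
#'
#' Thin readr wrappers pinning the cohort CSV schema (`subject_id`, `site`,
#' `age`, `sex`, `alps_cnawm`, `alps_inawm`, `fw_cnawm`, `enh_vol_ml`,
#' `os_days`, `event`, plus any extra columns present).
#'
#' @param cohort Data frame.
#' @param path CSV path.
#' @return `read_cohort_csv()` returns a tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
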