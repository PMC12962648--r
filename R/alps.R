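ROI_CATEGORIES <- c("cNAWM", "iNAWM", "flair_tumor", "enhancing_tumor",
                    "excluded_necrosis")

#' Select the reference subject by template similarity
#'
#' Given FA maps registered to a common template grid, returns the subject
#' whose map has the smallest sum of squared differences (SSD) from the
#' template. Ties are broken deterministically by the lowest subject id.
#'
#' @param fa_maps Named list of 3D FA arrays on the template grid.
#' @param template 3D FA array.
#' @return The selected subject id (name), with the per-subject SSD vector
#'   attached as attribute `"ssd"`.
#' @export
select_reference <- function(fa_maps, template) {
  if (length(fa_maps) == 0) stop("empty FA map collection", call. = FALSE)
  if (is.null(names(fa_maps)) || any(!nzchar(names(fa_maps)))) {
    stop("`fa_maps` must be a named list of subject maps", call. = FALSE)
  }
  ssd <- vapply(fa_maps, function(m) {
    if (!identical(dim(m), dim(template))) {
      stop("FA map grid does not match the template grid", call. = FALSE)
    }
    sum((m - template)^2)
  }, numeric(1))
  ord <- order(ssd, names(ssd))
  sel <- names(ssd)[ord[1]]
  attr(sel, "ssd") <- ssd
  sel
}

#' Categorize ALPS ROIs against a tumor segmentation
#'
#' The hemisphere opposite the tumor is contralateral normal-appearing white
#' matter (cNAWM). The ipsilateral ROI pair (projection plus association) is
#' categorized by its overlap with tumor compartments, a single shared voxel
#' sufficing, with priority necrosis > enhancing > FLAIR-hyperintense; no
#' overlap gives iNAWM. Necrosis overlap marks the hemisphere excluded from
#' group comparisons.
#'
#' @param rois An `alps_roi_set` (see [make_rois()]).
#' @param seg A `tumor_segmentation` on the same grid.
#' @param tumor_side Tumor hemisphere; defaults to the segmentation's side.
#' @return The ROI set with `category` and `tumor_side` filled in.
#' @export
categorize_roi <- function(rois, seg, tumor_side = seg$tumor_side) {
  stopifnot(inherits(rois, "alps_roi_set"), inherits(seg, "tumor_segmentation"))
  if (!identical(dim(seg$labels), as.integer(rois$shape))) {
    stop("segmentation grid does not match ROI grid", call. = FALSE)
  }
  if (!tumor_side %in% c("left", "right")) {
    stop("`tumor_side` must be 'left' or 'right'", call. = FALSE)
  }
  left_hemi <- hemisphere_mask(rois$shape, "left")
  tum <- seg$labels > 0L
  if (any(tum & left_hemi) && any(tum & !left_hemi)) {
    stop("tumor voxels present in both hemispheres (bilateral tumors are excluded)",
         call. = FALSE)
  }
  ipsi <- tumor_side
  contra <- other_side(tumor_side)
  hit <- seg$labels[rois[[ipsi]]$proj | rois[[ipsi]]$assoc]
  cat_ipsi <- if (any(hit == 3L)) {
    "excluded_necrosis"
  } else if (any(hit == 2L)) {
    "enhancing_tumor"
  } else if (any(hit == 1L)) {
    "flair_tumor"
  } else {
    "iNAWM"
  }
  rois$category[[ipsi]] <- cat_ipsi
  rois$category[[contra]] <- "cNAWM"
  rois$tumor_side <- tumor_side
  rois
}

#' Compute the ALPS index for one hemisphere
#'
#' The DTI-ALPS index is the ratio of x-axis diffusivity (along perivascular
#' spaces, perpendicular to both fiber systems) to the fiber-axis
#' diffusivities perpendicular to it:
#' `ALPS = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)`,
#' all four terms being ROI means of the raw tensor-diagonal maps. ROI-mean
#' FA and MD are carried along for use as covariates.
#'
#' @param maps A [tensor_metrics()] result.
#' @param rois An `alps_roi_set`, ideally after [categorize_roi()].
#' @param hemisphere `"left"` or `"right"`.
#' @return A one-row tibble with the four diffusivity means, `alps`, ROI FA
#'   and MD means, the hemisphere, its category, and a `valid` flag (FALSE
#'   when the denominator is nonpositive or any mean is not finite, in which
#'   case `alps` is `NA` and the measurement must be excluded downstream).
#' @export
alps_index <- function(maps, rois, hemisphere = c("left", "right")) {
  stopifnot(inherits(maps, "scalar_maps"), inherits(rois, "alps_roi_set"))
  hemisphere <- match.arg(hemisphere)
  proj <- rois[[hemisphere]]$proj
  assoc <- rois[[hemisphere]]$assoc
  if (!any(proj) || !any(assoc)) stop("empty ROI mask", call. = FALSE)

  dxx_proj <- mean(maps$dxx[proj])
  dxx_assoc <- mean(maps$dxx[assoc])
  dyy_proj <- mean(maps$dyy[proj])
  dzz_assoc <- mean(maps$dzz[assoc])
  num <- (dxx_proj + dxx_assoc) / 2
  den <- (dyy_proj + dzz_assoc) / 2
  vals <- c(dxx_proj, dxx_assoc, dyy_proj, dzz_assoc)
  valid <- all(is.finite(vals)) && den > 0

  tibble::tibble(
    hemisphere = hemisphere,
    category = rois$category[[hemisphere]],
    dxx_proj = dxx_proj, dxx_assoc = dxx_assoc,
    dyy_proj = dyy_proj, dzz_assoc = dzz_assoc,
    alps = if (valid) num / den else NA_real_,
    fa_proj = mean(maps$fa[proj]), fa_assoc = mean(maps$fa[assoc]),
    md_proj = mean(maps$md[proj]), md_assoc = mean(maps$md[assoc]),
    valid = valid
  )
}

# analytic ALPS from ground-truth phantom tensors (oracle used in tests and
# the acceptance script: no simulation or fitting involved)
alps_from_phantom <- function(phantom, rois, hemisphere) {
  nvox <- prod(phantom$shape)
  d6 <- matrix(phantom$tensors, nvox, 6)
  proj <- as.vector(rois[[hemisphere]]$proj)
  assoc <- as.vector(rois[[hemisphere]]$assoc)
  num <- (mean(d6[proj, 1]) + mean(d6[assoc, 1])) / 2
  den <- (mean(d6[proj, 2]) + mean(d6[assoc, 3])) / 2
  num / den
}
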