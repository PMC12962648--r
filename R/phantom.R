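#' @importFrom rlang .data
#' @importFrom stats rnorm runif rbinom rlnorm var median pchisq pf qnorm sd
#' @importFrom utils head
NULL

# region label codes used throughout the phantom machinery
REGION_CODES <- c(background = 0L, projection = 1L, association = 2L,
                  tumor = 3L, csf = 4L)

#' Default phantom region layout
#'
#' Two hemispheres split at the x midline (x is the right-left axis). Each
#' hemisphere carries a projection-fiber block (corticospinal-tract-like,
#' principal axis z, superoinferior) and an adjacent association-fiber block
#' (principal axis y, anteroposterior), mimicking the white matter lateral to
#' the ventricular bodies where ALPS ROIs are placed.
#'
#' @param shape Integer length-3 grid dimensions.
#' @param lambda_par Axial fiber diffusivity in mm^2/s.
#' @param lambda_perp Radial fiber diffusivity in mm^2/s.
#' @param dxx_elevation Fractional elevation of the x-axis diffusivity in both
#'   fiber blocks, emulating water mobility along perivascular spaces (which
#'   run along x, perpendicular to both fiber systems). 0 gives ALPS = 1 in
#'   the noise-free limit; positive values raise it.
#' @return A list of region descriptors usable as `region_spec` in
#'   [make_phantom()].
#' @export
default_region_spec <- function(shape, lambda_par = 1.4e-3,
                                lambda_perp = 0.3e-3, dxx_elevation = 0) {
  stopifnot(length(shape) == 3, all(shape >= 12))
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  zr <- c(max(2L, round(nz * 0.2)), min(nz - 1L, round(nz * 0.8)))
  y_proj <- c(max(2L, round(ny * 0.15)), round(ny * 0.45))
  y_assoc <- c(round(ny * 0.55), min(ny - 1L, round(ny * 0.85)))
  x_left <- c(max(2L, round(nx * 0.1)), round(nx * 0.4))
  x_right <- c(round(nx * 0.6), min(nx - 1L, round(nx * 0.9)))
  dxx_p <- lambda_perp * (1 + dxx_elevation)
  diag_proj <- c(dxx_p, lambda_perp, lambda_par)
  diag_assoc <- c(dxx_p, lambda_par, lambda_perp)
  list(
    list(name = "proj_left", label = "projection", diag = diag_proj,
         bounds = list(x = x_left, y = y_proj, z = zr)),
    list(name = "assoc_left", label = "association", diag = diag_assoc,
         bounds = list(x = x_left, y = y_assoc, z = zr)),
    list(name = "proj_right", label = "projection", diag = diag_proj,
         bounds = list(x = x_right, y = y_proj, z = zr)),
    list(name = "assoc_right", label = "association", diag = diag_assoc,
         bounds = list(x = x_right, y = y_assoc, z = zr))
  )
}

#' Build a diffusion tensor phantom
#'
#' Constructs a 3D grid of axis-aligned diffusion tensors with known region
#' labels, baseline signal and free-water fractions, serving as ground truth
#' for the whole pipeline. Fiber regions are axis-aligned by construction:
#' projection fibers have their largest diagonal entry on z, association
#' fibers on y, so the principal eigenvector coincides with the region's
#' anatomical axis.
#'
#' @param shape Integer length-3 grid dimensions.
#' @param voxel_size Isotropic voxel edge length in mm.
#' @param region_spec List of region descriptors, each a list with `name`,
#'   `label` (one of projection/association/tumor/csf), `diag` (Dxx, Dyy, Dzz
#'   in mm^2/s), integer `bounds` (`x`, `y`, `z` index ranges, 1-based) and
#'   optional `fw` (free-water fraction in the region).
#' @param fw_field Optional free-water fraction: a single number applied
#'   everywhere, or a full 3D array. Overrides per-region `fw`.
#' @param s0 Baseline (b = 0) signal level.
#' @param background_adc Isotropic diffusivity of unlabeled voxels in mm^2/s.
#' @return An object of class `tensor_phantom` with fields `shape`,
#'   `voxel_size`, `tensors` (4D array, 6 components xx, yy, zz, xy, xz, yz),
#'   `s0`, `fw_true`, `region_labels` and the `region_spec` used.
#' @export
make_phantom <- function(shape = c(32, 32, 32), voxel_size = 1,
                         region_spec = default_region_spec(shape),
                         fw_field = NULL, s0 = 100,
                         background_adc = 0.8e-3) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape > 0), voxel_size > 0, s0 > 0)
  nvox <- prod(shape)
  d6 <- matrix(0, nvox, 6)
  d6[, 1:3] <- background_adc
  labels <- array(0L, shape)
  fw <- array(0, shape)
  fiber_axis <- array(NA_integer_, shape) # 3 = z (projection), 2 = y (association)

  for (reg in region_spec) {
    if (is.null(reg$diag) || length(reg$diag) != 3) {
      stop("each region needs a length-3 `diag` of axis diffusivities", call. = FALSE)
    }
    if (any(reg$diag < 0)) {
      stop(sprintf("region '%s' has a negative eigenvalue", reg$name), call. = FALSE)
    }
    b <- reg$bounds
    if (b$x[1] < 1 || b$x[2] > shape[1] || b$y[1] < 1 || b$y[2] > shape[2] ||
        b$z[1] < 1 || b$z[2] > shape[3]) {
      stop(sprintf("region '%s' does not fit within the grid", reg$name), call. = FALSE)
    }
    idx <- as.matrix(expand.grid(x = b$x[1]:b$x[2], y = b$y[1]:b$y[2],
                                 z = b$z[1]:b$z[2]))
    lin <- idx[, 1] + shape[1] * (idx[, 2] - 1L) + shape[1] * shape[2] * (idx[, 3] - 1L)
    code <- REGION_CODES[[reg$label]]
    if (code %in% REGION_CODES[c("projection", "association")]) {
      ax <- if (reg$label == "projection") 3L else 2L
      if (which.max(reg$diag) != ax) {
        stop(sprintf(
          "region '%s': principal diffusivity must lie on the %s axis",
          reg$name, c("x", "y", "z")[ax]
        ), call. = FALSE)
      }
      clash <- !is.na(fiber_axis[lin]) & fiber_axis[lin] != ax
      if (any(clash)) {
        stop("overlapping fiber regions with conflicting orientations", call. = FALSE)
      }
      fiber_axis[lin] <- ax
    }
    d6[lin, 1:3] <- matrix(reg$diag, length(lin), 3, byrow = TRUE)
    d6[lin, 4:6] <- 0
    labels[lin] <- code
    if (!is.null(reg$fw)) fw[lin] <- reg$fw
  }

  if (!is.null(fw_field)) {
    if (length(fw_field) == 1) fw[] <- fw_field else fw[] <- fw_field
  }
  if (any(fw < 0 | fw > 1)) stop("free-water fractions must lie in [0, 1]", call. = FALSE)

  structure(
    list(
      shape = shape, voxel_size = voxel_size,
      tensors = array(d6, c(shape, 6L)),
      s0 = array(s0, shape), fw_true = fw,
      region_labels = labels, region_spec = region_spec
    ),
    class = "tensor_phantom"
  )
}

#' @export
print.tensor_phantom <- function(x, ...) {
  cat(sprintf(
    "<tensor_phantom> %s grid, voxel %.3g mm; regions: %s\n",
    paste(x$shape, collapse = "x"), x$voxel_size,
    paste(names(table(x$region_labels[x$region_labels > 0]))
          , collapse = ", ")
  ))
  invisible(x)
}

# logical mask of one hemisphere (x is right-left; left = first half)
hemisphere_mask <- function(shape, side = c("left", "right")) {
  side <- match.arg(side)
  half <- floor(shape[1] / 2)
  m <- array(FALSE, shape)
  if (side == "left") m[1:half, , ] <- TRUE else m[(half + 1):shape[1], , ] <- TRUE
  m
}

other_side <- function(side) if (side == "left") "right" else "left"

#' Contralateral normal-appearing white matter mask
#'
#' White matter (fiber-region) voxels in the hemisphere opposite the tumor;
#' the summary mask over which mean free water is reported.
#'
#' @param phantom A [make_phantom()] object.
#' @param tumor_side `"left"` or `"right"`.
#' @return Logical 3D array.
#' @export
cnawm_mask <- function(phantom, tumor_side = c("left", "right")) {
  tumor_side <- match.arg(tumor_side)
  wm <- phantom$region_labels %in% REGION_CODES[c("projection", "association")]
  array(wm, phantom$shape) & hemisphere_mask(phantom$shape, other_side(tumor_side))
}

#' Place spherical ALPS ROIs in a phantom
#'
#' One projection-fiber and one association-fiber spherical ROI per
#' hemisphere, each centered at the centroid of its fiber block. Voxels whose
#' centers lie within `diameter_mm / 2` of the ROI center belong to the ROI.
#'
#' @param phantom A [make_phantom()] object.
#' @param diameter_mm Sphere diameter in mm (default 4, the conventional
#'   ALPS ROI size).
#' @return An object of class `alps_roi_set`: per hemisphere, logical
#'   `proj` and `assoc` masks, plus (initially unset) ROI categories and
#'   tumor side.
#' @export
make_rois <- function(phantom, diameter_mm = 4) {
  stopifnot(inherits(phantom, "tensor_phantom"), diameter_mm > 0)
  shape <- phantom$shape
  vx <- phantom$voxel_size
  radius <- diameter_mm / 2

  sphere_in_region <- function(code, side) {
    hemi <- hemisphere_mask(shape, side)
    reg <- array(phantom$region_labels == code, shape) & hemi
    if (!any(reg)) stop("fiber region missing in hemisphere ", side, call. = FALSE)
    idx <- which(reg, arr.ind = TRUE)
    ctr <- round(colMeans(idx))
    all_idx <- which(array(TRUE, shape), arr.ind = TRUE)
    d2 <- ((all_idx[, 1] - ctr[1])^2 + (all_idx[, 2] - ctr[2])^2 +
             (all_idx[, 3] - ctr[3])^2) * vx^2
    mask <- array(d2 <= radius^2, shape)
    if (!all(reg[mask])) {
      stop(sprintf(
        "a %.3g-mm ROI sphere does not fit inside the %s %s-fiber region",
        diameter_mm, side, names(REGION_CODES)[REGION_CODES == code]
      ), call. = FALSE)
    }
    mask
  }

  rois <- list()
  for (side in c("left", "right")) {
    rois[[side]] <- list(
      proj = sphere_in_region(REGION_CODES[["projection"]], side),
      assoc = sphere_in_region(REGION_CODES[["association"]], side)
    )
    if (any(rois[[side]]$proj & rois[[side]]$assoc)) {
      stop("projection and association ROIs overlap", call. = FALSE)
    }
  }
  structure(
    list(
      left = rois$left, right = rois$right,
      category = c(left = NA_character_, right = NA_character_),
      tumor_side = NA_character_,
      shape = shape, voxel_size = vx, diameter_mm = diameter_mm
    ),
    class = "alps_roi_set"
  )
}

#' @export
print.alps_roi_set <- function(x, ...) {
  cat(sprintf(
    "<alps_roi_set> %.3g-mm spheres; voxels L(proj/assoc) %d/%d, R %d/%d; categories: L=%s R=%s\n",
    x$diameter_mm, sum(x$left$proj), sum(x$left$assoc),
    sum(x$right$proj), sum(x$right$assoc),
    x$category[["left"]], x$category[["right"]]
  ))
  invisible(x)
}

#' Plant a tumor segmentation in a phantom
#'
#' Builds a nested three-compartment tumor label volume (necrotic core inside
#' enhancing rim inside FLAIR-hyperintense non-enhancing tissue) in the
#' requested hemisphere, positioned so that the ipsilateral ALPS ROI pair
#' does or does not intersect the requested label class. Contralateral ROIs
#' never touch the tumor (tumors are clipped at the midline; bilateral tumors
#' are an exclusion criterion upstream).
#'
#' @param phantom A [make_phantom()] object.
#' @param side Tumor hemisphere, `"left"` or `"right"`.
#' @param overlap_mode Which tumor compartment (if any) must reach the
#'   ipsilateral ROIs: `"none"`, `"flair"`, `"enhancing"` or `"necrosis"`.
#' @param rois ROI set used to steer placement; defaults to
#'   [make_rois()] on the phantom.
#' @param radii_mm Named radii (mm) of the nested necrosis/enhancing/flair
#'   spheres.
#' @return An object of class `tumor_segmentation`: integer `labels` volume,
#'   a `legend` mapping labels to compartment names, the enhancing volume in
#'   ml, and `tumor_side`.
#' @export
make_tumor_labels <- function(phantom, side = c("left", "right"),
                              overlap_mode = c("none", "flair", "enhancing", "necrosis"),
                              rois = make_rois(phantom),
                              radii_mm = c(necrosis = 2, enhancing = 4, flair = 7)) {
  side <- match.arg(side)
  overlap_mode <- match.arg(overlap_mode)
  stopifnot(radii_mm[["necrosis"]] < radii_mm[["enhancing"]],
            radii_mm[["enhancing"]] < radii_mm[["flair"]])
  shape <- phantom$shape
  vx <- phantom$voxel_size

  roi_pair <- rois[[side]]$proj | rois[[side]]$assoc
  assoc_idx <- which(rois[[side]]$assoc, arr.ind = TRUE)
  p <- round(colMeans(assoc_idx))
  roi_radius <- rois$diameter_mm / 2

  offset <- switch(overlap_mode,
    none = radii_mm[["flair"]] + roi_radius + 4,
    flair = radii_mm[["enhancing"]] + roi_radius + 1,
    enhancing = radii_mm[["necrosis"]] + roi_radius + 1,
    necrosis = 0
  )
  ctr <- p - c(0, 0, round(offset / vx))
  if (ctr[3] < 1) ctr <- p + c(0, 0, round(offset / vx))
  if (ctr[3] > shape[3]) {
    stop("tumor placement for this overlap mode does not fit on the grid", call. = FALSE)
  }

  all_idx <- which(array(TRUE, shape), arr.ind = TRUE)
  d <- sqrt(((all_idx[, 1] - ctr[1])^2 + (all_idx[, 2] - ctr[2])^2 +
               (all_idx[, 3] - ctr[3])^2)) * vx
  labels <- array(0L, shape)
  labels[d <= radii_mm[["flair"]]] <- 1L
  labels[d <= radii_mm[["enhancing"]]] <- 2L
  labels[d <= radii_mm[["necrosis"]]] <- 3L
  labels[!hemisphere_mask(shape, side)] <- 0L # tumors do not cross the midline

  contra <- rois[[other_side(side)]]$proj | rois[[other_side(side)]]$assoc
  if (any(labels[contra] > 0)) {
    stop("contralateral ROIs intersect the tumor; geometry impossible", call. = FALSE)
  }
  hit <- labels[roi_pair]
  ok <- switch(overlap_mode,
    none = all(hit == 0L),
    flair = any(hit == 1L) && !any(hit >= 2L),
    enhancing = any(hit == 2L) && !any(hit == 3L),
    necrosis = any(hit == 3L)
  )
  if (!ok) {
    stop(sprintf(
      "requested overlap mode '%s' is geometrically impossible on this grid",
      overlap_mode
    ), call. = FALSE)
  }

  structure(
    list(
      labels = labels,
      legend = c(`1` = "flair_hyperintense", `2` = "enhancing", `3` = "necrosis"),
      enhancing_volume_ml = sum(labels == 2L) * vx^3 / 1000,
      tumor_side = side, voxel_size = vx
    ),
    class = "tumor_segmentation"
  )
}

#' @export
print.tumor_segmentation <- function(x, ...) {
  cat(sprintf(
    "<tumor_segmentation> side %s; voxels flair/enh/necrosis %d/%d/%d; enhancing %.3f ml\n",
    x$tumor_side, sum(x$labels == 1L), sum(x$labels == 2L), sum(x$labels == 3L),
    x$enhancing_volume_ml
  ))
  invisible(x)
}

#' Simulate a diffusion-weighted acquisition from a phantom
#'
#' Forward bi-tensor signal model per voxel:
#' `S(b, g) = S0 * ((1 - f) * exp(-b g' D g) + f * exp(-b * d_iso))`
#' with `d_iso = 3.0e-3` mm^2/s (body-temperature free water), followed by
#' Rician (magnitude MRI) or Gaussian noise. SNR is defined on the b = 0
#' signal: `sigma = S0 / snr`.
#'
#' @param phantom A [make_phantom()] object.
#' @param scheme An [acquisition_scheme()].
#' @param snr Signal-to-noise ratio on b0; `Inf` disables noise.
#' @param seed Integer RNG seed; identical seeds give bit-identical output.
#' @param noise `"rician"` (default) or `"gaussian"`.
#' @param d_iso Isotropic free-water diffusivity in mm^2/s.
#' @return An object of class `diffusion_volume`: 4D `signal` array
#'   (x, y, z, volume), the `scheme`, `voxel_size` and a `brain_mask`.
#' @export
simulate_dwi <- function(phantom, scheme, snr = Inf, seed = NULL,
                         noise = c("rician", "gaussian"), d_iso = 3.0e-3) {
  stopifnot(inherits(phantom, "tensor_phantom"),
            inherits(scheme, "acquisition_scheme"))
  noise <- match.arg(noise)
  if (!is.numeric(snr) || length(snr) != 1 || snr <= 0) {
    stop("`snr` must be a positive number (Inf for noise-free)", call. = FALSE)
  }
  shape <- phantom$shape
  nvox <- prod(shape)
  nvol <- length(scheme$bvals)
  d6 <- matrix(phantom$tensors, nvox, 6)
  att_t <- tensor_attenuation(d6, scheme)            # nvox x nvol
  att_w <- exp(-outer(rep(1, nvox), scheme$bvals * d_iso))
  f <- as.vector(phantom$fw_true)
  s0 <- as.vector(phantom$s0)
  sig <- s0 * ((1 - f) * att_t + f * att_w)

  if (is.finite(snr)) {
    if (!is.null(seed)) set.seed(seed)
    sigma <- s0 / snr
    if (noise == "rician") {
      n1 <- matrix(rnorm(nvox * nvol), nvox, nvol) * sigma
      n2 <- matrix(rnorm(nvox * nvol), nvox, nvol) * sigma
      sig <- sqrt((sig + n1)^2 + n2^2)
    } else {
      sig <- sig + matrix(rnorm(nvox * nvol), nvox, nvol) * sigma
    }
  }

  structure(
    list(
      signal = array(sig, c(shape, nvol)),
      scheme = scheme,
      voxel_size = phantom$voxel_size,
      brain_mask = array(TRUE, shape)
    ),
    class = "diffusion_volume"
  )
}

#' @export
print.diffusion_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf(
    "<diffusion_volume> %s grid x %d volumes, scheme '%s'\n",
    paste(d[1:3], collapse = "x"), d[4], x$scheme$label
  ))
  invisible(x)
}
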