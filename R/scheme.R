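#' Diffusion acquisition scheme
#'
#' Bundles b-values and gradient directions for a DWI acquisition. Directions
#' of diffusion-weighted volumes must be unit vectors; b = 0 volumes carry a
#' zero direction. A scheme needs at least one b = 0 volume and at least six
#' unique non-zero directions so the diffusion tensor is identifiable.
#'
#' @param bvals Numeric vector of b-values in s/mm^2, one per volume.
#' @param bvecs 3 x n numeric matrix of gradient directions (columns are
#'   x, y, z components, one column per volume).
#' @param label Free-text scheme name.
#'
#' @return An object of class `acquisition_scheme`: a list with elements
#'   `bvals`, `bvecs` and `label`.
#' @export
acquisition_scheme <- function(bvals, bvecs, label = "custom") {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L || ncol(bvecs) != length(bvals)) {
    stop("`bvecs` must be a 3 x length(bvals) matrix", call. = FALSE)
  }
  if (any(bvals < 0)) stop("b-values must be nonnegative", call. = FALSE)
  dw <- bvals > 0
  if (!any(!dw)) stop("scheme must contain at least one b = 0 volume", call. = FALSE)
  if (any(dw)) {
    nrm <- sqrt(colSums(bvecs[, dw, drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6)) {
      stop("non-b0 directions must be unit vectors (|norm - 1| <= 1e-6)", call. = FALSE)
    }
  }
  uniq <- unique(round(t(bvecs[, dw, drop = FALSE]), 6))
  if (nrow(uniq) < 6L) {
    stop("at least 6 unique non-b0 directions are required", call. = FALSE)
  }
  structure(
    list(bvals = bvals, bvecs = bvecs, label = label),
    class = "acquisition_scheme"
  )
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat(sprintf(
    "<acquisition_scheme '%s'> %d volumes (%d b0), shells: %s s/mm^2\n",
    x$label, length(x$bvals), sum(x$bvals == 0),
    paste(sort(unique(x$bvals[x$bvals > 0])), collapse = ", ")
  ))
  invisible(x)
}

#' Quasi-uniform unit directions on the sphere
#'
#' Deterministic Fibonacci-spiral point set, adequate for simulated
#' single-shell acquisitions.
#'
#' @param n Number of directions.
#' @return A 3 x n matrix of unit vectors.
#' @export
fibonacci_directions <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  rbind(r * cos(phi), r * sin(phi), z)
}

#' Single-shell acquisition schemes
#'
#' `scheme_single_shell()` builds a generic b0 + one-shell scheme.
#' `scheme_upenn_like()` mirrors a b = 0 + 1000 s/mm^2 acquisition with a
#' configurable direction count (31-124 in the emulated cohort);
#' `scheme_ucsf_like()` mirrors a b = 0 + 2000 s/mm^2, 56-direction
#' acquisition.
#'
#' @param n_dirs Number of diffusion-weighted directions.
#' @param b Shell b-value in s/mm^2.
#' @param n_b0 Number of b = 0 volumes.
#' @param label Scheme name.
#' @return An [acquisition_scheme()].
#' @export
scheme_single_shell <- function(n_dirs = 31, b = 1000, n_b0 = 1,
                                label = sprintf("b%d_%ddir", b, n_dirs)) {
  bvals <- c(rep(0, n_b0), rep(b, n_dirs))
  bvecs <- cbind(matrix(0, 3, n_b0), fibonacci_directions(n_dirs))
  acquisition_scheme(bvals, bvecs, label)
}

#' @rdname scheme_single_shell
#' @export
scheme_upenn_like <- function(n_dirs = 31) {
  scheme_single_shell(n_dirs = n_dirs, b = 1000, label = "upenn_like")
}

#' @rdname scheme_single_shell
#' @export
scheme_ucsf_like <- function() {
  scheme_single_shell(n_dirs = 56, b = 2000, label = "ucsf_like")
}

# design row for the log-linear tensor model: ln S = ln S0 - b g' D g
# columns: lnS0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz
tensor_design <- function(scheme) {
  g <- scheme$bvecs
  b <- scheme$bvals
  cbind(
    1,
    -b * g[1, ]^2, -b * g[2, ]^2, -b * g[3, ]^2,
    -2 * b * g[1, ] * g[2, ], -2 * b * g[1, ] * g[3, ], -2 * b * g[2, ] * g[3, ]
  )
}

# per-volume attenuation exp(-b g' D g) for a matrix of tensors
# d6: nvox x 6 matrix (xx, yy, zz, xy, xz, yz); returns nvox x nvol
tensor_attenuation <- function(d6, scheme) {
  bq <- -tensor_design(scheme)[, -1, drop = FALSE] # nvol x 6, b g'(.)g weights
  exp(-(d6 %*% t(bq)))
}
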