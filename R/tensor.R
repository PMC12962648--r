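#' Fit a single diffusion tensor per voxel
#'
#' Two-pass weighted linear least squares on the log signal,
#' `ln S = ln S0 - b g' D g`: an ordinary LS pass provides predicted signals
#' whose squares serve as weights for the definitive WLS pass (the standard
#' compromise between robustness and asymptotic efficiency for log-linearized
#' tensor estimation). Voxels with nonpositive baseline signal are flagged
#' `fit_ok = FALSE` rather than erroring.
#'
#' @param dwi A `diffusion_volume` (see [simulate_dwi()] or [read_dwi()]).
#' @param mask Optional logical 3D array restricting the fit; defaults to the
#'   volume's `brain_mask` (or everything).
#' @return An object of class `tensor_field`: 4D `d` array of the 6 tensor
#'   components (xx, yy, zz, xy, xz, yz) in mm^2/s, baseline `s0`, logical
#'   `fit_ok`, and `voxel_size`.
#' @export
fit_tensor <- function(dwi, mask = NULL) {
  stopifnot(inherits(dwi, "diffusion_volume"))
  scheme <- dwi$scheme
  dims <- dim(dwi$signal)
  shape <- dims[1:3]
  nvol <- dims[4]
  if (nvol != length(scheme$bvals)) {
    stop("signal volume count does not match the acquisition scheme", call. = FALSE)
  }
  if (nvol < 7L) stop("fewer than 7 usable volumes", call. = FALSE)
  dw <- scheme$bvals > 0
  uniq <- unique(round(t(scheme$bvecs[, dw, drop = FALSE]), 6))
  if (nrow(uniq) < 6L || !any(!dw)) {
    stop("need >= 6 unique non-b0 directions and >= 1 b0 volume", call. = FALSE)
  }
  if (is.null(mask)) mask <- dwi$brain_mask
  if (is.null(mask)) mask <- array(TRUE, shape)
  if (!any(mask)) stop("mask is empty", call. = FALSE)

  nvox_all <- prod(shape)
  midx <- which(as.vector(mask))
  Y <- matrix(dwi$signal, nvox_all, nvol)[midx, , drop = FALSE]

  s0_hat <- rowMeans(Y[, !dw, drop = FALSE])
  ok <- s0_hat > 0 & apply(is.finite(Y), 1, all)
  X <- tensor_design(scheme)
  XtX <- crossprod(X)

  beta <- matrix(NA_real_, length(midx), 7)
  if (any(ok)) {
    Yok <- Y[ok, , drop = FALSE]
    # floor the signal at a small fraction of S0 so the log stays finite
    floorv <- pmax(1e-6 * s0_hat[ok], .Machine$double.xmin)
    L <- log(pmax(Yok, floorv))
    b_ols <- t(solve(XtX, crossprod(X, t(L)))) # nvox x 7

    # WLS pass: weights are squared predicted signals from the OLS fit.
    # X'WX for every voxel in one matmul over the 49 outer-product columns.
    W <- exp(2 * (b_ols %*% t(X)))             # nvox x nvol
    P <- t(apply(X, 1, tcrossprod))            # nvol x 49
    A <- W %*% P                               # nvox x 49
    Bv <- (W * L) %*% X                        # nvox x 7
    b_wls <- b_ols
    for (v in seq_len(nrow(Yok))) {
      M <- matrix(A[v, ], 7, 7)
      cf <- tryCatch(solve(M, Bv[v, ]), error = function(e) NULL)
      if (!is.null(cf) && all(is.finite(cf))) b_wls[v, ] <- cf
    }
    beta[ok, ] <- b_wls
  }

  d <- array(0, c(shape, 6L))
  dmat <- matrix(0, nvox_all, 6)
  dmat[midx[ok], ] <- beta[ok, 2:7, drop = FALSE]
  d[] <- dmat
  s0 <- array(0, shape)
  s0v <- numeric(nvox_all)
  s0v[midx[ok]] <- exp(beta[ok, 1])
  s0[] <- s0v
  fit_ok <- array(FALSE, shape)
  fov <- logical(nvox_all)
  fov[midx[ok]] <- TRUE
  fit_ok[] <- fov

  structure(
    list(d = d, s0 = s0, fit_ok = fit_ok, voxel_size = dwi$voxel_size,
         scheme = scheme, mask = mask),
    class = "tensor_field"
  )
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf(
    "<tensor_field> %s grid; %d voxels fit\n",
    paste(dim(x$fit_ok), collapse = "x"), sum(x$fit_ok)
  ))
  invisible(x)
}

# eigenvalues of symmetric 3x3 tensors, rows of an nvox x 6 matrix
# (xx, yy, zz, xy, xz, yz); returns nvox x 3, descending
tensor_eigenvalues <- function(d6) {
  n <- nrow(d6)
  ev <- matrix(NA_real_, n, 3)
  for (v in seq_len(n)) {
    M <- matrix(c(
      d6[v, 1], d6[v, 4], d6[v, 5],
      d6[v, 4], d6[v, 2], d6[v, 6],
      d6[v, 5], d6[v, 6], d6[v, 3]
    ), 3, 3)
    ev[v, ] <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  }
  ev
}

#' Scalar maps from a tensor field
#'
#' Derives fractional anisotropy, mean diffusivity, sorted eigenvalues, and
#' the raw axis diffusivities Dxx, Dyy, Dzz (the tensor diagonal in image
#' axes, *not* eigenvalues -- the ALPS index reads diffusion along fixed
#' anatomical axes). Negative eigenvalues are clamped at zero before FA/MD;
#' the raw diagonal is kept unclamped for the axis maps.
#'
#' @param tf A [fit_tensor()] result.
#' @return An object of class `scalar_maps` with 3D arrays `fa`, `md`,
#'   `dxx`, `dyy`, `dzz`, a 4D `eigenvalues` array (descending), and the
#'   propagated `fit_ok` mask.
#' @export
tensor_metrics <- function(tf) {
  stopifnot(inherits(tf, "tensor_field"))
  shape <- dim(tf$fit_ok)
  nvox <- prod(shape)
  d6 <- matrix(tf$d, nvox, 6)
  okv <- as.vector(tf$fit_ok)

  ev <- matrix(NA_real_, nvox, 3)
  if (any(okv)) ev[okv, ] <- tensor_eigenvalues(d6[okv, , drop = FALSE])
  evc <- pmax(ev, 0)
  md <- rowMeans(evc)
  ss <- rowSums(evc^2)
  dev2 <- rowSums((evc - md)^2)
  fa <- ifelse(ss > 0, sqrt(1.5 * dev2 / ss), 0)
  fa <- pmin(pmax(fa, 0), 1)

  to_arr <- function(v) array(v, shape)
  structure(
    list(
      fa = to_arr(fa), md = to_arr(md),
      dxx = to_arr(d6[, 1]), dyy = to_arr(d6[, 2]), dzz = to_arr(d6[, 3]),
      eigenvalues = array(evc, c(shape, 3L)),
      fit_ok = tf$fit_ok, voxel_size = tf$voxel_size
    ),
    class = "scalar_maps"
  )
}

#' @export
print.scalar_maps <- function(x, ...) {
  ok <- x$fit_ok
  cat(sprintf(
    "<scalar_maps> %s grid; FA median %.3f, MD median %.3g mm^2/s over %d fit voxels\n",
    paste(dim(ok), collapse = "x"),
    median(x$fa[ok]), median(x$md[ok]), sum(ok)
  ))
  invisible(x)
}
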