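#' Fit a ComBat location/scale harmonization model
#'
#' Per-feature model `y = alpha + X beta + gamma_site + delta_site * eps`:
#' features are standardized by the covariate-adjusted grand mean and pooled
#' variance, per-site location (`gamma`) and scale (`delta`) estimated on the
#' standardized scale, and -- when at least two features are available --
#' shrunk across features by parametric empirical Bayes (normal prior on
#' locations, inverse-gamma on variances, moment-matched, solved by the
#' usual fixed-point iteration). With a single feature the raw per-site
#' estimates are used (`eb_used = FALSE`). Biological covariates (age, sex)
#' are part of the standardization and are restored on adjustment, so their
#' effects survive harmonization.
#'
#' @param data Data frame with one row per subject.
#' @param features Character vector of biomarker columns to harmonize.
#' @param batch Name of the site/batch column.
#' @param covariates Character vector of covariate columns to preserve.
#' @param parametric Use parametric empirical-Bayes shrinkage (the only
#'   implemented flavor; `FALSE` keeps raw site estimates).
#' @return An object of class `combat_model`.
#' @export
combat_fit <- function(data, features, batch = "site",
                       covariates = c("age", "sex"), parametric = TRUE) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c(features, batch, covariates), names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  Yf <- as.matrix(data[, features, drop = FALSE])
  if (anyNA(Yf)) stop("missing feature values are not allowed", call. = FALSE)
  site <- factor(data[[batch]])
  sites <- levels(site)
  n_sites <- length(sites)
  if (n_sites < 2) stop("need at least 2 sites", call. = FALSE)
  n_b <- table(site)
  if (any(n_b < 3)) stop("need at least 3 subjects per site", call. = FALSE)
  n <- nrow(Yf)
  V <- length(features)

  Xcov <- if (length(covariates)) {
    as.matrix(data[, covariates, drop = FALSE])
  } else {
    matrix(0, n, 0)
  }
  B <- stats::model.matrix(~ 0 + site)
  design <- cbind(B, Xcov)

  # per-feature OLS with site intercepts + covariates
  Bhat <- solve(crossprod(design), crossprod(design, Yf)) # (n_sites + p) x V
  gamma_raw_mean <- Bhat[seq_len(n_sites), , drop = FALSE]
  beta_cov <- Bhat[-seq_len(n_sites), , drop = FALSE]
  alpha <- as.numeric(n_b / n) %*% gamma_raw_mean          # 1 x V weighted grand mean
  resid <- Yf - design %*% Bhat
  var_pooled <- colMeans(resid^2)
  if (any(var_pooled <= 0)) {
    stop("a feature has zero pooled residual variance", call. = FALSE)
  }

  stand_mean <- matrix(alpha, n, V, byrow = TRUE) + Xcov %*% beta_cov
  Z <- (Yf - stand_mean) / matrix(sqrt(var_pooled), n, V, byrow = TRUE)

  for (b in seq_len(n_sites)) {
    yb <- Yf[site == sites[b], , drop = FALSE]
    if (any(apply(yb, 2, function(v) length(unique(v))) < 2)) {
      stop("a site has a constant feature value; scale undefined", call. = FALSE)
    }
  }
  gamma_hat <- matrix(NA_real_, n_sites, V, dimnames = list(sites, features))
  delta2_hat <- gamma_hat
  for (b in seq_len(n_sites)) {
    zb <- Z[site == sites[b], , drop = FALSE]
    gamma_hat[b, ] <- colMeans(zb)
    # population (1/n) divisor, matching the pooled-variance convention, so
    # that harmonization is an exact no-op / fixed point when site effects
    # are absent or already removed
    delta2_hat[b, ] <- colMeans(sweep(zb, 2, colMeans(zb), `-`)^2)
  }
  if (any(delta2_hat <= 0 | !is.finite(delta2_hat))) {
    stop("a site has a constant feature value; scale undefined", call. = FALSE)
  }

  eb_used <- isTRUE(parametric) && V >= 2
  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  if (eb_used) {
    for (b in seq_len(n_sites)) {
      g <- gamma_hat[b, ]
      d2 <- delta2_hat[b, ]
      g_bar <- mean(g)
      t2 <- var(g)
      m <- mean(d2)
      s2 <- var(d2)
      a_prior <- (2 * s2 + m^2) / s2
      b_prior <- (m * s2 + m^3) / s2
      zb <- Z[site == sites[b], , drop = FALSE]
      nb <- nrow(zb)
      g_new <- g
      d_new <- d2
      change <- 1
      count <- 0
      while (change > 1e-4 && count < 100) {
        g_old <- g_new
        d_old <- d_new
        g_new <- (t2 * nb * g + d_new * g_bar) / (t2 * nb + d_new)
        sum2 <- colSums(sweep(zb, 2, g_new, `-`)^2)
        d_new <- (0.5 * sum2 + b_prior) / (nb / 2 + a_prior - 1)
        change <- max(abs(g_new - g_old) / abs(g_old),
                      abs(d_new - d_old) / d_old)
        count <- count + 1
      }
      gamma_star[b, ] <- g_new
      delta2_star[b, ] <- d_new
    }
  }

  structure(
    list(
      features = features, batch = batch, covariates = covariates,
      sites = sites, n_per_site = as.integer(n_b),
      alpha = stats::setNames(as.numeric(alpha), features),
      beta = beta_cov, var_pooled = var_pooled,
      gamma_star = gamma_star, delta_star = sqrt(delta2_star),
      gamma_hat = gamma_hat, delta_hat = sqrt(delta2_hat),
      eb_used = eb_used
    ),
    class = "combat_model"
  )
}

#' Apply a fitted ComBat model
#'
#' Standardizes each feature with the stored grand mean, covariate
#' coefficients and pooled variance, removes the shrunken per-site location
#' and scale, and restores the original scale and covariate structure.
#' Sites unseen at fit time are an error.
#'
#' @param model A [combat_fit()] object.
#' @param data Data frame with the model's feature, batch and covariate
#'   columns.
#' @return The input data with harmonized feature columns (a tibble).
#' @export
combat_apply <- function(model, data) {
  stopifnot(inherits(model, "combat_model"), is.data.frame(data))
  missing_cols <- setdiff(c(model$features, model$batch, model$covariates),
                          names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  site <- as.character(data[[model$batch]])
  unseen <- setdiff(unique(site), model$sites)
  if (length(unseen)) {
    stop("unseen site id(s): ", paste(unseen, collapse = ", "), call. = FALSE)
  }
  Yf <- as.matrix(data[, model$features, drop = FALSE])
  n <- nrow(Yf)
  V <- length(model$features)
  Xcov <- if (length(model$covariates)) {
    as.matrix(data[, model$covariates, drop = FALSE])
  } else {
    matrix(0, n, 0)
  }
  stand_mean <- matrix(model$alpha, n, V, byrow = TRUE) + Xcov %*% model$beta
  sdp <- matrix(sqrt(model$var_pooled), n, V, byrow = TRUE)
  Z <- (Yf - stand_mean) / sdp
  idx <- match(site, model$sites)
  Zadj <- (Z - model$gamma_star[idx, , drop = FALSE]) /
    model$delta_star[idx, , drop = FALSE]
  Yadj <- Zadj * sdp + stand_mean

  out <- tibble::as_tibble(data)
  keep_na <- is.na(Yf)
  Yadj[keep_na] <- NA_real_
  for (j in seq_len(V)) out[[model$features[j]]] <- Yadj[, j]
  out
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf(
    "<combat_model> %d features x %d sites; covariates: %s; EB shrinkage: %s\n",
    length(x$features), length(x$sites),
    paste(x$covariates, collapse = ", "), x$eb_used
  ))
  invisible(x)
}

#' Tidy a ComBat model
#'
#' @param x A `combat_model`.
#' @param ... Unused.
#' @return One row per site x feature with raw and shrunken location/scale
#'   estimates (standardized units).
#' @export
tidy.combat_model <- function(x, ...) {
  tidyr::expand_grid(site = x$sites, feature = x$features) |>
    dplyr::mutate(
      gamma_hat = as.vector(t(x$gamma_hat)),
      gamma_star = as.vector(t(x$gamma_star)),
      delta_hat = as.vector(t(x$delta_hat)),
      delta_star = as.vector(t(x$delta_star))
    )
}

#' @export
glance.combat_model <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$features),
    n_sites = length(x$sites),
    n = sum(x$n_per_site),
    eb_used = x$eb_used
  )
}

#' Serialize a ComBat model to JSON for audit
#'
#' @param model A `combat_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
combat_to_json <- function(model, path) {
  obj <- model
  class(obj) <- NULL
  obj$beta <- as.data.frame(obj$beta)
  for (nm in c("gamma_star", "delta_star", "gamma_hat", "delta_hat")) {
    obj[[nm]] <- as.data.frame(obj[[nm]])
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
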