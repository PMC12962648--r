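#' Specification for a synthetic multi-site survival cohort
#'
#' Defaults emulate the two-cohort GBM study design the package targets:
#' cohort sizes 277 and 269, age ~ N(63, 11), roughly 60% male, ALPS index
#' centered at 1.40 (SD 0.15), cNAWM free-water fraction centered at 0.21
#' (SD 0.05), and per-SD log hazard ratios of -0.3 for ALPS and +0.3 for FW
#' (matching multivariate HRs of about 0.75 and 1.34). Event times follow a
#' Weibull proportional-hazards model with a median around 15 months;
#' censoring is independent uniform, calibrated to the target fraction
#' (a free parameter -- real cohorts rarely report it).
#'
#' @param n_per_site Named integer vector of subjects per site.
#' @param site_effects Named list per site: `shift` and `scale` applied to
#'   each biomarker (named vectors over `alps_cnawm`, `alps_inawm`,
#'   `fw_cnawm`), defaulting to no distortion.
#' @param beta_alps,beta_fw,beta_age,beta_sex Planted log hazard ratios per
#'   SD (sex per category).
#' @param baseline_scale,baseline_shape Weibull baseline-hazard parameters
#'   (days).
#' @param censor_rate Target censoring fraction in `[0, 1)`.
#' @param alps_mean,alps_sd,fw_mean,fw_sd Biomarker distributions.
#' @param age_mean,age_sd Age distribution (years).
#' @param p_male Probability of sex = 1.
#' @param category_probs Ipsilateral ROI-category frequencies
#'   (iNAWM / FLAIR / enhancing / necrosis), defaulting to the relative
#'   frequencies observed in the emulated cohorts.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_site = c(UPENN = 277, UCSF = 269),
                        site_effects = NULL,
                        beta_alps = -0.3, beta_fw = 0.3,
                        beta_age = 0.25, beta_sex = 0,
                        baseline_scale = 550, baseline_shape = 1.2,
                        censor_rate = 0.3,
                        alps_mean = 1.40, alps_sd = 0.15,
                        fw_mean = 0.21, fw_sd = 0.05,
                        age_mean = 63, age_sd = 11,
                        p_male = 0.6,
                        category_probs = c(iNAWM = 0.68, flair_tumor = 0.25,
                                           enhancing_tumor = 0.05,
                                           excluded_necrosis = 0.02)) {
  if (is.null(names(n_per_site))) {
    names(n_per_site) <- paste0("site", seq_along(n_per_site))
  }
  if (censor_rate < 0 || censor_rate >= 1) {
    stop("`censor_rate` must lie in [0, 1)", call. = FALSE)
  }
  if (any(c(alps_sd, fw_sd, age_sd) <= 0)) stop("all sds must be > 0", call. = FALSE)
  if (any(n_per_site < 2)) stop("each site needs at least 2 subjects", call. = FALSE)
  if (is.null(site_effects)) {
    site_effects <- lapply(n_per_site, function(n) list(shift = 0, scale = 1))
    names(site_effects) <- names(n_per_site)
  }
  structure(
    list(
      n_per_site = n_per_site, site_effects = site_effects,
      beta_alps = beta_alps, beta_fw = beta_fw,
      beta_age = beta_age, beta_sex = beta_sex,
      baseline_scale = baseline_scale, baseline_shape = baseline_shape,
      censor_rate = censor_rate,
      alps_mean = alps_mean, alps_sd = alps_sd,
      fw_mean = fw_mean, fw_sd = fw_sd,
      age_mean = age_mean, age_sd = age_sd, p_male = p_male,
      category_probs = category_probs / sum(category_probs)
    ),
    class = "cohort_spec"
  )
}

site_effect_value <- function(eff, marker, what) {
  v <- eff[[what]]
  if (is.null(v)) return(if (what == "shift") 0 else 1)
  if (length(v) == 1 && is.null(names(v))) return(v)
  if (!is.null(names(v)) && marker %in% names(v)) return(v[[marker]])
  if (what == "shift") 0 else 1
}

#' Simulate a multi-site survival cohort
#'
#' Draws per-subject demographics and biomarkers, distorts the biomarkers by
#' per-site location/scale effects (shift first, then scaling about the site
#' mean, so the mean shift is preserved), and generates overall-survival
#' times from a Weibull proportional-hazards model with linear predictor
#' `beta_alps z(ALPS) + beta_fw z(FW) + beta_age z(age) + beta_sex sex`
#' (z-scores use the specification's own means/SDs, so planted betas are
#' exactly per-SD). Pre-distortion biomarkers are kept in `*_true` columns
#' for parameter-recovery testing.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer RNG seed; identical seeds reproduce the cohort
#'   bit-identically.
#' @return A tibble with columns `subject_id`, `site`, `age`, `sex`,
#'   `alps_cnawm`, `alps_inawm`, `fw_cnawm`, `enh_vol_ml`, `os_days`,
#'   `event`, plus `roi_category_ipsi`, `alps_ipsi`, eligibility fields
#'   (`bilateral`, `midline_shift_mm`) and ground-truth `*_true` columns.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  sites <- names(spec$n_per_site)
  n <- sum(spec$n_per_site)
  site <- rep(sites, times = spec$n_per_site)

  age <- rnorm(n, spec$age_mean, spec$age_sd)
  sex <- rbinom(n, 1, spec$p_male)
  alps_cnawm <- rnorm(n, spec$alps_mean, spec$alps_sd)
  # ipsilateral ALPS correlates with its contralateral counterpart
  alps_in_raw <- spec$alps_mean +
    0.5 * (alps_cnawm - spec$alps_mean) +
    sqrt(1 - 0.25) * rnorm(n, 0, spec$alps_sd)
  fw_cnawm <- pmax(rnorm(n, spec$fw_mean, spec$fw_sd), 0.01)
  enh_vol_ml <- rlnorm(n, log(15) - 0.5 * 0.7^2, 0.7)

  category <- sample(names(spec$category_probs), n, replace = TRUE,
                     prob = spec$category_probs)
  # tumor-overlap ROIs show depressed ALPS relative to NAWM
  alps_ipsi <- alps_in_raw - ifelse(
    category == "flair_tumor", 0.25,
    ifelse(category == "enhancing_tumor", 0.35,
           ifelse(category == "excluded_necrosis", 0.4, 0))
  )
  alps_inawm <- ifelse(category == "iNAWM", alps_ipsi, NA_real_)

  lp <- spec$beta_alps * (alps_cnawm - spec$alps_mean) / spec$alps_sd +
    spec$beta_fw * (fw_cnawm - spec$fw_mean) / spec$fw_sd +
    spec$beta_age * (age - spec$age_mean) / spec$age_sd +
    spec$beta_sex * sex
  u <- runif(n)
  t_event <- spec$baseline_scale *
    (-log(u) / exp(lp))^(1 / spec$baseline_shape)

  if (spec$censor_rate > 0) {
    # uniform censoring horizon calibrated so E[censored fraction] hits target
    frac <- function(cmax) mean(pmin(t_event, cmax) / cmax) - spec$censor_rate
    cmax <- tryCatch(
      stats::uniroot(frac, lower = min(t_event) * 1e-3,
                     upper = max(t_event) * 1e3)$root,
      error = function(e) max(t_event) / (1 - spec$censor_rate)
    )
    c_time <- runif(n, 0, cmax)
    os_days <- pmin(t_event, c_time)
    event <- as.integer(t_event <= c_time)
  } else {
    os_days <- t_event
    event <- rep(1L, n)
  }
  os_days <- pmax(os_days, 1)

  out <- tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    site = site, age = age, sex = sex,
    alps_cnawm_true = alps_cnawm,
    alps_inawm_true = alps_inawm,
    fw_cnawm_true = fw_cnawm,
    alps_cnawm = alps_cnawm, alps_inawm = alps_inawm, fw_cnawm = fw_cnawm,
    alps_ipsi = alps_ipsi,
    roi_category_ipsi = category,
    enh_vol_ml = enh_vol_ml,
    bilateral = runif(n) < 0.02,
    midline_shift_mm = abs(rnorm(n, 2, 2)),
    os_days = os_days, event = event
  )

  for (s in sites) {
    eff <- spec$site_effects[[s]]
    rows <- out$site == s
    # alps_ipsi is the ipsilateral ALPS measurement itself; it shares the
    # alps_inawm site effect so the two columns stay consistent
    for (marker in c("alps_cnawm", "alps_ipsi", "fw_cnawm")) {
      eff_name <- if (marker == "alps_ipsi") "alps_inawm" else marker
      shift <- site_effect_value(eff, eff_name, "shift")
      scale <- site_effect_value(eff, eff_name, "scale")
      y <- out[[marker]][rows] + shift
      m <- mean(y, na.rm = TRUE)
      out[[marker]][rows] <- m + scale * (y - m)
    }
  }
  out$alps_inawm <- ifelse(out$roi_category_ipsi == "iNAWM", out$alps_ipsi,
                           NA_real_)
  out
}

#' Simulate a cohort with a hazard change-point in one biomarker
#'
#' Event hazard is multiplied by `hr_below` for subjects whose metric falls
#' at or below `threshold` -- a step (change-point) rather than log-linear
#' effect -- which is the regime the survival-cutpoint scan is designed to
#' recover. Censoring is independent uniform at the target rate.
#'
#' @param n Number of subjects.
#' @param threshold True change-point location.
#' @param hr_below Hazard ratio of the at-or-below group versus above.
#' @param metric_mean,metric_sd Metric distribution.
#' @param baseline_scale,baseline_shape Weibull baseline (days).
#' @param censor_rate Target censoring fraction in `[0, 1)`.
#' @param seed Integer RNG seed.
#' @return A tibble with columns `metric`, `os_days`, `event`.
#' @export
simulate_changepoint_cohort <- function(n, threshold = 1.40, hr_below = 2,
                                        metric_mean = 1.40, metric_sd = 0.15,
                                        baseline_scale = 550,
                                        baseline_shape = 1.2,
                                        censor_rate = 0.2, seed = NULL) {
  stopifnot(n >= 2, hr_below > 0, censor_rate >= 0, censor_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  metric <- rnorm(n, metric_mean, metric_sd)
  lp <- log(hr_below) * (metric <= threshold)
  t_event <- baseline_scale * (-log(runif(n)) / exp(lp))^(1 / baseline_shape)
  if (censor_rate > 0) {
    frac <- function(cmax) mean(pmin(t_event, cmax) / cmax) - censor_rate
    cmax <- tryCatch(
      stats::uniroot(frac, lower = min(t_event) * 1e-3,
                     upper = max(t_event) * 1e3)$root,
      error = function(e) max(t_event) / (1 - censor_rate)
    )
    c_time <- runif(n, 0, cmax)
    os_days <- pmin(t_event, c_time)
    event <- as.integer(t_event <= c_time)
  } else {
    os_days <- t_event
    event <- rep(1L, n)
  }
  tibble::tibble(metric = metric, os_days = pmax(os_days, 1), event = event)
}
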