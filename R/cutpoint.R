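#' Scan candidate survival cutpoints for a biomarker
#'
#' Walks a regular threshold grid across the observed metric range (from
#' `ceil(min/step)*step` to `floor(max/step)*step`), dichotomizes at each
#' threshold (`value > threshold` is "high"), and records the two-group
#' log-rank p-value, hazard ratio (high vs low, per the group indicator) with
#' 95% CI, and group sizes. Thresholds whose smaller group falls below
#' `min_group_frac` of the cohort are skipped; the default 10% floor guards
#' against degenerate 1-vs-(n-1) splits and can be set to 0 to scan the full
#' range. No multiplicity correction is applied across the scan -- minimum-p
#' selection is anticonservative by construction, a property that is
#' documented and tested rather than corrected.
#'
#' @param data Data frame.
#' @param metric Biomarker column name.
#' @param step Grid step (e.g. 0.01 for the ALPS index, 0.001 for free
#'   water).
#' @param time,event Survival column names.
#' @param min_group_frac Minimum admissible fraction of subjects in the
#'   smaller group, in `[0, 0.5)`.
#' @return An object of class `cutpoint_scan`: a `scan` tibble (threshold,
#'   p, hr, ci_lo, ci_hi, n_low, n_high, significant), the selected
#'   `optimal_threshold`, and the selection-rule record.
#' @export
scan_cutpoints <- function(data, metric, step, time = "os_days",
                           event = "event", min_group_frac = 0.1) {
  stopifnot(is.data.frame(data), step > 0)
  if (min_group_frac < 0 || min_group_frac >= 0.5) {
    stop("`min_group_frac` must lie in [0, 0.5)", call. = FALSE)
  }
  d <- data.frame(value = data[[metric]], time = data[[time]],
                  event = data[[event]])
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  rng <- range(d$value)
  grid <- seq(ceiling(rng[1] / step) * step, floor(rng[2] / step) * step,
              by = step)
  grid <- round(grid / step) * step

  rows <- lapply(grid, function(thr) {
    high <- d$value > thr
    n_high <- sum(high)
    n_low <- n - n_high
    if (min(n_high, n_low) < max(1, ceiling(min_group_frac * n))) return(NULL)
    dd <- data.frame(time = d$time, event = d$event,
                     group = factor(ifelse(high, "high", "low"),
                                    levels = c("low", "high")))
    if (sum(dd$event) < 1) return(NULL)
    lr <- tryCatch(
      logrank_test(dd, time = "time", event = "event", group = "group"),
      error = function(e) NULL
    )
    if (is.null(lr)) return(NULL)
    tibble::tibble(
      threshold = thr, p = lr$p, hr = lr$hr,
      ci_lo = lr$ci_lo, ci_hi = lr$ci_hi,
      n_low = n_low, n_high = n_high,
      significant = lr$p < 0.05
    )
  })
  scan <- dplyr::bind_rows(rows)
  if (nrow(scan) < 2) {
    stop("fewer than 2 admissible thresholds", call. = FALSE)
  }
  obj <- structure(
    list(
      metric = metric, step = step, min_group_frac = min_group_frac,
      n = n, scan = scan,
      selection_rule = "argmin p; ties by max |log HR|; then lowest threshold"
    ),
    class = "cutpoint_scan"
  )
  obj$optimal_threshold <- select_optimal(obj)
  obj
}

#' Select the optimal threshold from a cutpoint scan
#'
#' The optimum is the threshold with the lowest log-rank p-value; ties are
#' broken by the largest absolute log hazard ratio (the most extreme HR in
#' either direction), then deterministically by the lowest threshold.
#'
#' @param scan A [scan_cutpoints()] result (or its `scan` tibble).
#' @return The selected threshold (numeric scalar).
#' @export
select_optimal <- function(scan) {
  s <- if (inherits(scan, "cutpoint_scan")) scan$scan else scan
  if (is.null(s) || nrow(s) == 0) stop("empty scan", call. = FALSE)
  ord <- order(s$p, -abs(log(s$hr)), s$threshold)
  s$threshold[ord[1]]
}

#' @export
print.cutpoint_scan <- function(x, ...) {
  best <- x$scan[x$scan$threshold == x$optimal_threshold, ]
  cat(sprintf(
    "<cutpoint_scan> '%s': %d thresholds (step %g); optimum %g (p = %.4g, HR = %.3f); %d significant\n",
    x$metric, nrow(x$scan), x$step, x$optimal_threshold, best$p, best$hr,
    sum(x$scan$significant)
  ))
  invisible(x)
}

#' @export
tidy.cutpoint_scan <- function(x, ...) x$scan

#' @export
glance.cutpoint_scan <- function(x, ...) {
  best <- x$scan[x$scan$threshold == x$optimal_threshold, ]
  tibble::tibble(
    metric = x$metric, n = x$n, n_thresholds = nrow(x$scan),
    optimal_threshold = x$optimal_threshold,
    p_optimal = best$p, hr_optimal = best$hr,
    n_significant = sum(x$scan$significant)
  )
}

#' Apply a fixed threshold to a (validation) cohort
#'
#' Dichotomizes at a pre-specified threshold without re-optimization --
#' the external-validation step -- and reports the log-rank test, hazard
#' ratio and per-group Kaplan-Meier medians.
#'
#' @param data Data frame.
#' @param metric Biomarker column name.
#' @param threshold Fixed threshold (warned about, not rejected, when
#'   outside the observed range).
#' @param time,event Survival column names.
#' @param high_is_favorable Direction bookkeeping stored with the result
#'   (the test itself is direction-agnostic).
#' @return A list of class `threshold_result`: `groups` (tibble of subject
#'   assignments), `logrank` (tibble), `medians` (months, per group).
#' @export
apply_threshold <- function(data, metric, threshold, time = "os_days",
                            event = "event", high_is_favorable = TRUE) {
  stopifnot(is.data.frame(data))
  d <- data.frame(value = data[[metric]], time = data[[time]],
                  event = data[[event]])
  d <- d[stats::complete.cases(d), , drop = FALSE]
  rng <- range(d$value)
  if (threshold < rng[1] || threshold > rng[2]) {
    warning("threshold lies outside the observed metric range", call. = FALSE)
  }
  d$group <- factor(ifelse(d$value > threshold, "high", "low"),
                    levels = c("low", "high"))
  if (any(table(d$group) == 0)) {
    stop("threshold produces an empty group", call. = FALSE)
  }
  lr <- logrank_test(d, time = "time", event = "event", group = "group")
  km <- km_estimate(d, time = "time", event = "event", group = "group")
  structure(
    list(
      metric = metric, threshold = threshold,
      high_is_favorable = high_is_favorable,
      groups = tibble::as_tibble(d[, c("value", "group", "time", "event")]),
      logrank = lr, medians = km$medians, km = km
    ),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "<threshold_result> '%s' at %g: log-rank p = %.4g, HR(high vs low) = %.3f\n",
    x$metric, x$threshold, x$logrank$p, x$logrank$hr
  ))
  print(x$medians)
  invisible(x)
}

#' Joint ALPS x FW three-group stratification
#'
#' Combines the two neurofluid markers at fixed thresholds into three
#' prognostic strata: `favorable` (high ALPS and low FW), `adverse` (low
#' ALPS and high FW) and `discordant` (the two mixed profiles pooled).
#' "High" means strictly above the threshold; the favorable FW side is
#' at-or-below its threshold. All three pairwise log-rank tests are run.
#'
#' @param data Data frame.
#' @param alps_thr,fw_thr Fixed thresholds for the ALPS and FW columns.
#' @param alps_col,fw_col Biomarker column names.
#' @param time,event Survival column names.
#' @return A list of class `joint_strata`: per-subject `strata` tibble,
#'   stratum `counts`, and a `pairwise` tibble of log-rank results.
#' @export
stratify_joint <- function(data, alps_thr, fw_thr,
                           alps_col = "alps_cnawm", fw_col = "fw_cnawm",
                           time = "os_days", event = "event") {
  stopifnot(is.data.frame(data))
  d <- data.frame(alps = data[[alps_col]], fw = data[[fw_col]],
                  time = data[[time]], event = data[[event]])
  d <- d[stats::complete.cases(d), , drop = FALSE]
  high_alps <- d$alps > alps_thr
  high_fw <- d$fw > fw_thr
  d$stratum <- factor(
    ifelse(high_alps & !high_fw, "favorable",
           ifelse(!high_alps & high_fw, "adverse", "discordant")),
    levels = c("favorable", "discordant", "adverse")
  )
  counts <- table(d$stratum)
  if (any(counts == 0)) {
    stop("empty stratum; sizes: ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
         call. = FALSE)
  }
  pairs <- utils::combn(levels(d$stratum), 2, simplify = FALSE)
  pairwise <- dplyr::bind_rows(lapply(pairs, function(pr) {
    dd <- d[d$stratum %in% pr, , drop = FALSE]
    dd$stratum <- droplevels(dd$stratum)
    lr <- logrank_test(dd, time = "time", event = "event", group = "stratum")
    dplyr::mutate(lr, comparison = paste(pr, collapse = " vs "),
                  .before = 1)
  }))
  km <- km_estimate(d, time = "time", event = "event", group = "stratum")
  structure(
    list(
      alps_threshold = alps_thr, fw_threshold = fw_thr,
      strata = tibble::as_tibble(d),
      counts = stats::setNames(as.integer(counts), names(counts)),
      pairwise = pairwise, medians = km$medians, km = km
    ),
    class = "joint_strata"
  )
}

#' @export
print.joint_strata <- function(x, ...) {
  cat(sprintf(
    "<joint_strata> ALPS > %g x FW <= %g: favorable %d / discordant %d / adverse %d\n",
    x$alps_threshold, x$fw_threshold,
    x$counts[["favorable"]], x$counts[["discordant"]], x$counts[["adverse"]]
  ))
  print(x$pairwise[, c("comparison", "chi2", "p", "hr")])
  invisible(x)
}

#' @export
tidy.joint_strata <- function(x, ...) x$pairwise

#' @export
glance.joint_strata <- function(x, ...) {
  tibble::tibble(
    alps_threshold = x$alps_threshold, fw_threshold = x$fw_threshold,
    n_favorable = x$counts[["favorable"]],
    n_discordant = x$counts[["discordant"]],
    n_adverse = x$counts[["adverse"]]
  )
}
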