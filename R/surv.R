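DAYS_PER_MONTH <- 30.44

#' One-way ANOVA with Tukey's post hoc test
#'
#' Compares a biomarker (typically the ALPS index) across ROI categories:
#' classical one-way ANOVA followed by Tukey honest significant differences
#' on all category pairs.
#'
#' @param data Data frame.
#' @param value Name of the numeric column.
#' @param group Name of the grouping column (>= 2 levels, each with >= 2
#'   observations).
#' @return A list of class `anova_tukey`: `f_statistic`, `p_value`,
#'   `df`, and `pairwise` (tibble of Tukey-adjusted pairwise contrasts).
#' @export
anova_tukey <- function(data, value, group) {
  stopifnot(is.data.frame(data))
  d <- data[!is.na(data[[value]]) & !is.na(data[[group]]), c(value, group)]
  names(d) <- c("value", "group")
  d$group <- factor(d$group)
  counts <- table(d$group)
  if (length(counts) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(counts < 2)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  fit <- stats::aov(value ~ group, data = d)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  pairwise <- tibble::tibble(
    contrast = rownames(tk),
    diff = tk[, "diff"], ci_lo = tk[, "lwr"], ci_hi = tk[, "upr"],
    p_adj = tk[, "p adj"]
  )
  f_stat <- s[["F value"]][1]
  structure(
    list(
      f_statistic = f_stat,
      p_value = if (f_stat == 0) 1 else s[["Pr(>F)"]][1],
      df = c(between = s[["Df"]][1], within = s[["Df"]][2]),
      pairwise = pairwise, fit = fit
    ),
    class = "anova_tukey"
  )
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("<anova_tukey> F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$f_statistic, x$p_value))
  print(x$pairwise)
  invisible(x)
}

#' @export
tidy.anova_tukey <- function(x, ...) x$pairwise

#' @export
glance.anova_tukey <- function(x, ...) {
  tibble::tibble(f_statistic = x$f_statistic, p_value = x$p_value,
                 df_between = x$df[1], df_within = x$df[2])
}

#' Median dichotomization
#'
#' Splits values at their median into `"high"` (value > median) and `"low"`
#' (value <= median; ties go low).
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @return A factor with levels `low`, `high`; `NA` in gives `NA` out.
#' @export
dichotomize_median <- function(values) {
  v <- values[!is.na(values)]
  if (length(unique(v)) < 2) {
    stop("all values identical; median split undefined", call. = FALSE)
  }
  med <- median(v)
  factor(ifelse(values > med, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator with Greenwood variance (via
#' [survival::survfit()]), optionally per group, with median survival
#' reported in months (`days / 30.44`). The median is the first time the
#' survival curve drops to or below 0.5 (the estimator's usual convention:
#' when the curve sits exactly at 0.5 over an interval, the interval
#' midpoint is reported).
#'
#' @param data Data frame.
#' @param time,event Column names for follow-up days and the event flag
#'   (1 = death observed).
#' @param group Optional grouping column name.
#' @return An object of class `km_curve`: a `curve` tibble (time, n_risk,
#'   n_event, n_censor, surv, std_err, ci, group) and a `medians` tibble.
#' @export
km_estimate <- function(data, time = "os_days", event = "event", group = NULL) {
  stopifnot(is.data.frame(data))
  d <- data.frame(time = data[[time]], event = data[[event]])
  if (any(d$time <= 0, na.rm = TRUE)) stop("survival times must be > 0", call. = FALSE)
  if (!is.null(group)) d$group <- factor(data[[group]])
  d <- d[stats::complete.cases(d), , drop = FALSE]
  fit <- if (is.null(group)) {
    survival::survfit(survival::Surv(time, event) ~ 1, data = d)
  } else {
    survival::survfit(survival::Surv(time, event) ~ group, data = d)
  }
  sf <- summary(fit, censored = TRUE)
  grp <- if (is.null(group)) {
    rep("all", length(sf$time))
  } else {
    sub("^group=", "", as.character(sf$strata))
  }
  curve <- tibble::tibble(
    group = grp, time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    n_censor = sf$n.censor, surv = sf$surv, std_err = sf$std.err,
    ci_lo = sf$lower, ci_hi = sf$upper
  )
  qt <- stats::quantile(fit, probs = 0.5)$quantile
  med_days <- if (is.null(group)) {
    stats::setNames(as.numeric(qt), "all")
  } else {
    stats::setNames(as.numeric(qt), sub("^group=", "", rownames(qt)))
  }
  medians <- tibble::tibble(
    group = names(med_days),
    median_days = as.numeric(med_days),
    median_months = as.numeric(med_days) / DAYS_PER_MONTH
  )
  structure(
    list(curve = curve, medians = medians, fit = fit,
         n = nrow(d), n_events = sum(d$event)),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, events = %d\n", x$n, x$n_events))
  print(x$medians)
  invisible(x)
}

#' @export
tidy.km_curve <- function(x, ...) x$curve

#' @export
glance.km_curve <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events,
                 n_groups = length(unique(x$curve$group)))
}

#' Two-group log-rank test with hazard ratio
#'
#' Standard observed-minus-expected log-rank statistic (1 df, hypergeometric
#' variance) via [survival::survdiff()], accompanied by the hazard ratio and
#' 95% CI from a univariate Cox fit on the group indicator (second factor
#' level versus first).
#'
#' @param data Data frame.
#' @param time,event Column names for follow-up time and event flag.
#' @param group Grouping column (exactly 2 nonempty levels).
#' @return A one-row tibble: `chi2`, `p`, `hr`, `ci_lo`, `ci_hi`,
#'   `n_per_group` (list column), `n_events`.
#' @export
logrank_test <- function(data, time = "os_days", event = "event", group) {
  stopifnot(is.data.frame(data))
  d <- data.frame(time = data[[time]], event = data[[event]],
                  group = factor(data[[group]]))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  d$group <- droplevels(d$group)
  if (nlevels(d$group) != 2) stop("need exactly 2 nonempty groups", call. = FALSE)
  if (sum(d$event) < 1) stop("no events observed", call. = FALSE)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  chi2 <- sd_$chisq
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  cx <- survival::coxph(survival::Surv(time, event) ~ group, data = d,
                        ties = "efron")
  beta <- unname(stats::coef(cx)[1])
  se <- sqrt(diag(cx$var))[1]
  tibble::tibble(
    chi2 = chi2, p = p,
    hr = exp(beta), ci_lo = exp(beta - 1.96 * se), ci_hi = exp(beta + 1.96 * se),
    n = nrow(d), n_events = sum(d$event),
    n_group1 = sum(d$group == levels(d$group)[1]),
    n_group2 = sum(d$group == levels(d$group)[2]),
    group_levels = paste(levels(d$group), collapse = " vs ")
  )
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood fit via [survival::coxph()] (Efron tie handling by
#' default). Continuous covariates are z-scored before fitting when
#' `standardize = TRUE`, so hazard ratios for biomarkers are per SD --
#' the natural reporting scale for indices with small dynamic range.
#'
#' @param data Data frame.
#' @param time,event Column names for follow-up time and event flag.
#' @param covariates Character vector of covariate column names.
#' @param ties `"efron"` or `"breslow"`.
#' @param standardize Z-score continuous covariates (columns with more than
#'   2 distinct values) before fitting.
#' @return An object of class `cox_fit`: a `results` tibble (term, beta, se,
#'   z, p, hr, ci_lo, ci_hi), `n`, `n_events`, `ties`, and the underlying
#'   `coxph` fit.
#' @export
cox_fit <- function(data, time = "os_days", event = "event", covariates,
                    ties = c("efron", "breslow"), standardize = TRUE) {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(data), length(covariates) >= 1)
  d <- data[, c(time, event, covariates), drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  names(d)[1:2] <- c(".time", ".event")
  for (cv in covariates) {
    x <- d[[cv]]
    if (!is.numeric(x)) {
      x <- as.numeric(factor(x)) - 1
      d[[cv]] <- x
    }
    ux <- unique(x)
    if (length(ux) < 2) {
      stop(sprintf("covariate '%s' is constant", cv), call. = FALSE)
    }
    if (standardize && length(ux) > 2) {
      d[[cv]] <- (x - mean(x)) / sd(x)
    }
  }
  n_events <- sum(d$.event)
  if (n_events < length(covariates) + 1) {
    stop("too few events for the number of covariates", call. = FALSE)
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = d, ties = ties,
                         control = survival::coxph.control(iter.max = 100))
  beta <- stats::coef(fit)
  if (any(!is.finite(beta)) || any(abs(beta) > 20)) {
    stop("Cox fit did not converge (possible monotone likelihood / separation)",
         call. = FALSE)
  }
  se <- sqrt(diag(fit$var))
  z <- beta / se
  results <- tibble::tibble(
    term = covariates,
    beta = unname(beta), se = unname(se), z = unname(z),
    p = 2 * stats::pnorm(-abs(unname(z))),
    hr = exp(unname(beta)),
    ci_lo = exp(unname(beta) - 1.96 * unname(se)),
    ci_hi = exp(unname(beta) + 1.96 * unname(se))
  )
  structure(
    list(results = results, n = nrow(d), n_events = n_events,
         ties = ties, standardized = standardize, fit = fit),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, ties = %s%s\n",
              x$n, x$n_events, x$ties,
              if (x$standardized) " (continuous covariates per SD)" else ""))
  print(x$results)
  invisible(x)
}

#' @export
tidy.cox_fit <- function(x, ...) x$results

#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events, ties = x$ties,
    loglik = x$fit$loglik[2],
    concordance = unname(x$fit$concordance["concordance"])
  )
}
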