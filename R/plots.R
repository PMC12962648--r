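#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_step geom_point
#'   geom_hline geom_vline labs theme_minimal facet_wrap scale_y_log10
NULL

#' Plot a cutpoint scan
#'
#' Two stacked panels mirroring the usual threshold-discovery figure:
#' log-rank p-value versus threshold (log scale, 0.05 reference line) and
#' hazard ratio with 95% CI versus threshold, with the selected optimum
#' marked.
#'
#' @param object A `cutpoint_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cutpoint_scan <- function(object, ...) {
  s <- object$scan
  long <- dplyr::bind_rows(
    tibble::tibble(threshold = s$threshold, value = s$p, lo = NA, hi = NA,
                   panel = "log-rank p"),
    tibble::tibble(threshold = s$threshold, value = s$hr, lo = s$ci_lo,
                   hi = s$ci_hi, panel = "HR (high vs low)")
  )
  ref <- tibble::tibble(panel = c("log-rank p", "HR (high vs low)"),
                        y = c(0.05, 1))
  ggplot(long, aes(x = .data$threshold, y = .data$value)) +
    geom_line() +
    geom_line(aes(y = .data$lo), linetype = "dashed", na.rm = TRUE) +
    geom_line(aes(y = .data$hi), linetype = "dashed", na.rm = TRUE) +
    geom_hline(data = ref, aes(yintercept = .data$y), linetype = "dotted") +
    geom_vline(xintercept = object$optimal_threshold, colour = "red") +
    facet_wrap(~panel, ncol = 1, scales = "free_y") +
    scale_y_log10() +
    labs(x = object$metric, y = NULL,
         title = sprintf("Cutpoint scan: %s (optimum %g)",
                         object$metric, object$optimal_threshold)) +
    theme_minimal()
}

#' Plot Kaplan-Meier curves
#'
#' @param object A `km_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_curve <- function(object, ...) {
  ggplot(object$curve,
         aes(x = .data$time / DAYS_PER_MONTH, y = .data$surv,
             colour = .data$group)) +
    geom_step() +
    labs(x = "Months", y = "Survival probability", colour = NULL) +
    theme_minimal()
}

#' @rdname autoplot.km_curve
#' @export
autoplot.threshold_result <- function(object, ...) {
  autoplot(object$km) +
    labs(title = sprintf("%s dichotomized at %g (log-rank p = %.3g)",
                         object$metric, object$threshold, object$logrank$p))
}

#' @rdname autoplot.km_curve
#' @export
autoplot.joint_strata <- function(object, ...) {
  autoplot(object$km) +
    labs(title = sprintf("Joint strata (ALPS > %g, FW <= %g)",
                         object$alps_threshold, object$fw_threshold))
}

#' Save the standard figure set of a cohort run
#'
#' Scan and Kaplan-Meier figures for both markers plus the joint strata.
#'
#' @param run A `cohort_run`.
#' @param dir Output directory.
#' @param width,height Device size in inches.
#' @return Invisibly, the files written.
#' @export
plot_cohort_run <- function(run, dir, width = 6, height = 5) {
  stopifnot(inherits(run, "cohort_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  figs <- list(
    scan_alps = autoplot(run$scans$alps),
    scan_fw = autoplot(run$scans$fw),
    km_alps = autoplot(run$validation$alps),
    km_fw = autoplot(run$validation$fw)
  )
  if (!is.null(run$joint)) figs$km_joint <- autoplot(run$joint)
  files <- character()
  for (nm in names(figs)) {
    f <- file.path(dir, paste0(nm, ".pdf"))
    ggplot2::ggsave(f, figs[[nm]], width = width, height = height)
    files <- c(files, f)
  }
  invisible(files)
}
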