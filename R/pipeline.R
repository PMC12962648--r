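#' Apply cohort eligibility filters
#'
#' Drops subjects with bilateral tumors or a midline shift strictly greater
#' than 5 mm (a shift of exactly 5 mm is retained), and blanks the
#' ipsilateral ALPS survival column for subjects whose ipsilateral ROIs
#' overlap tumor tissue or necrosis (those measurements are excluded from
#' survival analysis but the subjects stay for contralateral analyses).
#' Missing eligibility columns are tolerated with a warning. Exclusion
#' counts are attached as the `"exclusions"` attribute and reported.
#'
#' @param records Cohort data frame (one row per subject).
#' @param midline_limit_mm Strict exclusion limit in mm.
#' @param verbose Report exclusion counts with `message()`.
#' @return The filtered tibble with attribute `exclusions`.
#' @export
filter_cohort <- function(records, midline_limit_mm = 5, verbose = TRUE) {
  stopifnot(is.data.frame(records))
  out <- tibble::as_tibble(records)
  n0 <- nrow(out)
  excl <- c(bilateral = 0L, midline_shift = 0L, necrosis_overlap = 0L,
            tumor_overlap_alps = 0L)

  if ("bilateral" %in% names(out)) {
    drop <- !is.na(out$bilateral) & out$bilateral
    excl[["bilateral"]] <- sum(drop)
    out <- out[!drop, , drop = FALSE]
  } else {
    warning("no `bilateral` column; subjects kept", call. = FALSE)
  }
  if ("midline_shift_mm" %in% names(out)) {
    drop <- !is.na(out$midline_shift_mm) & out$midline_shift_mm > midline_limit_mm
    excl[["midline_shift"]] <- sum(drop)
    out <- out[!drop, , drop = FALSE]
  } else {
    warning("no `midline_shift_mm` column; subjects kept", call. = FALSE)
  }
  if ("roi_category_ipsi" %in% names(out)) {
    nec <- !is.na(out$roi_category_ipsi) &
      out$roi_category_ipsi == "excluded_necrosis"
    tum <- !is.na(out$roi_category_ipsi) &
      out$roi_category_ipsi %in% c("flair_tumor", "enhancing_tumor")
    excl[["necrosis_overlap"]] <- sum(nec)
    excl[["tumor_overlap_alps"]] <- sum(tum)
    if ("alps_inawm" %in% names(out)) {
      out$alps_inawm[nec | tum] <- NA_real_
    }
  }
  if (nrow(out) == 0) stop("empty cohort after filtering", call. = FALSE)
  if (verbose) {
    message(sprintf(
      "filter_cohort: %d -> %d subjects (bilateral %d, midline shift > %g mm %d); ipsilateral ALPS blanked for %d tumor-overlap and %d necrosis-overlap subjects",
      n0, nrow(out), excl[["bilateral"]], midline_limit_mm,
      excl[["midline_shift"]], excl[["tumor_overlap_alps"]],
      excl[["necrosis_overlap"]]
    ))
  }
  attr(out, "exclusions") <- excl
  out
}

#' Process one subject's imaging into a biomarker record
#'
#' Composes the per-subject imaging stages: single-tensor fit, scalar maps,
#' ROI categorization against the tumor segmentation, per-hemisphere ALPS
#' index, regularized bi-tensor free-water fit, and the mean free-water
#' fraction over the contralateral NAWM mask. Stage failures (nonconvergent
#' free water, invalid ALPS denominator) leave `NA` in the affected fields
#' with a warning rather than aborting, so cohort processing can quarantine
#' bad subjects.
#'
#' @param dwi A `diffusion_volume`.
#' @param seg A `tumor_segmentation`.
#' @param rois An `alps_roi_set`.
#' @param cnawm A logical 3D cNAWM mask for the free-water summary.
#' @param subject_id Identifier stored in the record.
#' @param clinical Optional one-row data frame of clinical fields merged
#'   into the record (age, sex, site, survival, ...).
#' @param fw_args List of arguments passed on to [fw_fit_bitensor()].
#' @return A one-row tibble (`subject_record`): ALPS and covariate means per
#'   hemisphere keyed by category (`alps_cnawm`, `alps_inawm` or tumor-
#'   overlap columns), `fw_cnawm`, ROI FA/MD, enhancing volume, tumor side
#'   and ROI categories.
#' @export
run_subject <- function(dwi, seg, rois, cnawm = NULL, subject_id = "subject",
                        clinical = NULL, fw_args = list()) {
  rois <- categorize_roi(rois, seg)
  tumor_side <- rois$tumor_side
  contra <- other_side(tumor_side)

  tf <- fit_tensor(dwi)
  maps <- tensor_metrics(tf)
  meas <- dplyr::bind_rows(
    alps_index(maps, rois, tumor_side),
    alps_index(maps, rois, contra)
  )

  rec <- tibble::tibble(
    subject_id = subject_id,
    tumor_side = tumor_side,
    roi_category_ipsi = rois$category[[tumor_side]],
    roi_category_contra = rois$category[[contra]],
    enh_vol_ml = seg$enhancing_volume_ml
  )
  for (i in seq_len(nrow(meas))) {
    m <- meas[i, ]
    col <- switch(m$category,
      cNAWM = "alps_cnawm", iNAWM = "alps_inawm",
      flair_tumor = "alps_flair", enhancing_tumor = "alps_enh",
      excluded_necrosis = "alps_necrosis"
    )
    if (!isTRUE(m$valid)) {
      warning(sprintf("subject %s: invalid ALPS denominator in %s hemisphere",
                      subject_id, m$hemisphere), call. = FALSE)
    }
    rec[[col]] <- m$alps
    if (m$category == "cNAWM") {
      rec$fa_proj <- m$fa_proj; rec$fa_assoc <- m$fa_assoc
      rec$md_proj <- m$md_proj; rec$md_assoc <- m$md_assoc
    }
  }

  if (is.null(cnawm)) {
    cnawm <- rois[[contra]]$proj | rois[[contra]]$assoc
  }
  rec$fw_cnawm <- tryCatch({
    fw <- do.call(fw_fit_bitensor, c(list(dwi = dwi), fw_args))
    fw_mean(fw, cnawm)$mean_fw
  }, error = function(e) {
    warning(sprintf("subject %s: free-water summary failed (%s)",
                    subject_id, conditionMessage(e)), call. = FALSE)
    NA_real_
  })

  if (!is.null(clinical)) {
    stopifnot(nrow(clinical) == 1)
    rec <- dplyr::bind_cols(rec,
                            clinical[, setdiff(names(clinical), names(rec)),
                                     drop = FALSE])
  }
  rec
}

#' Run the cohort-level analysis pipeline
#'
#' Orchestrates the tabular stages on a cohort of subject records (from
#' [simulate_cohort()] or collected [run_subject()] outputs): eligibility
#' filtering, ComBat harmonization across sites (fit on the pooled table,
#' preserving age and sex), ROI-category ANOVA with Tukey contrasts,
#' median-split log-rank tests, univariate and multivariate Cox models (the
#' clinical covariate set age/sex/enhancing volume, plus an extended set
#' adding ROI FA/MD when available), the cutpoint scans on the discovery
#' site (ALPS step 0.01, FW step 0.001), fixed-threshold validation on the
#' validation site, and the joint ALPS x FW three-group stratification.
#' The whole run is deterministic given its input table.
#'
#' @param records Cohort data frame; must carry `site`, survival columns and
#'   the biomarker columns.
#' @param discovery_site,validation_site Site labels taking the discovery
#'   (threshold-finding) and validation roles; defaults to the first and
#'   second site in the table.
#' @param harmonize Apply ComBat (requires >= 2 sites).
#' @param features Feature columns to harmonize jointly.
#' @param alps_step,fw_step Cutpoint grid steps.
#' @param min_group_frac Group-size floor for the scans.
#' @param verbose Forwarded to [filter_cohort()].
#' @return A list of class `cohort_run` with the raw and harmonized tables,
#'   `table1` category counts, `exclusions`, `anova`, `median_split`, `cox`,
#'   `scans`, `thresholds`, `validation` and `joint` components.
#' @export
run_cohort <- function(records,
                       discovery_site = NULL, validation_site = NULL,
                       harmonize = TRUE,
                       features = c("alps_cnawm", "alps_ipsi", "fw_cnawm"),
                       alps_step = 0.01, fw_step = 0.001,
                       min_group_frac = 0.1, verbose = TRUE) {
  stopifnot(is.data.frame(records))
  need <- c("site", "os_days", "event", "alps_cnawm", "fw_cnawm")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  sites <- unique(records$site)
  if (is.null(discovery_site)) discovery_site <- sites[1]
  if (is.null(validation_site)) {
    validation_site <- if (length(sites) >= 2) sites[2] else sites[1]
  }

  filtered <- filter_cohort(records, verbose = verbose)
  exclusions <- attr(filtered, "exclusions")

  harmonized <- filtered
  combat <- NULL
  if (harmonize) {
    if (length(sites) < 2) {
      stop("harmonization requires at least 2 sites", call. = FALSE)
    }
    feats <- intersect(features, names(filtered))
    feats <- feats[vapply(feats, function(f) !anyNA(filtered[[f]]), logical(1))]
    if (length(feats) == 0) stop("no complete features to harmonize", call. = FALSE)
    combat <- combat_fit(filtered, features = feats)
    harmonized <- combat_apply(combat, filtered)
    # iNAWM ALPS inherits the harmonized ipsilateral value where it is defined
    if (all(c("alps_ipsi", "alps_inawm") %in% names(harmonized))) {
      harmonized$alps_inawm <- ifelse(is.na(filtered$alps_inawm), NA_real_,
                                      harmonized$alps_ipsi)
    }
  }

  table1 <- if ("roi_category_ipsi" %in% names(harmonized)) {
    harmonized |>
      dplyr::count(.data$site, .data$roi_category_ipsi, name = "n") |>
      tidyr::pivot_wider(names_from = "roi_category_ipsi", values_from = "n",
                         values_fill = 0L)
  } else {
    dplyr::count(harmonized, .data$site, name = "n")
  }

  anova_res <- NULL
  if (all(c("alps_ipsi", "roi_category_ipsi") %in% names(harmonized))) {
    long <- dplyr::bind_rows(
      tibble::tibble(alps = harmonized$alps_cnawm, category = "cNAWM"),
      tibble::tibble(alps = harmonized$alps_ipsi,
                     category = harmonized$roi_category_ipsi)
    )
    long <- long[long$category != "excluded_necrosis", , drop = FALSE]
    anova_res <- tryCatch(anova_tukey(long, "alps", "category"),
                          error = function(e) NULL)
  }

  disc <- harmonized[harmonized$site == discovery_site, , drop = FALSE]
  valid <- harmonized[harmonized$site == validation_site, , drop = FALSE]

  median_split <- lapply(
    stats::setNames(nm = intersect(c("alps_cnawm", "alps_inawm", "fw_cnawm"),
                                   names(disc))),
    function(mk) {
      dd <- disc[!is.na(disc[[mk]]), , drop = FALSE]
      dd$grp <- dichotomize_median(dd[[mk]])
      logrank_test(dd, group = "grp")
    }
  )

  covar_sets <- list(clinical = c("age", "sex", "enh_vol_ml"))
  if (all(c("fa_proj", "fa_assoc", "md_proj", "md_assoc") %in% names(disc))) {
    covar_sets$extended <- c(covar_sets$clinical,
                             "fa_proj", "fa_assoc", "md_proj", "md_assoc")
  }
  cox_for <- function(tbl) {
    out <- list()
    for (mk in intersect(c("alps_cnawm", "alps_inawm", "fw_cnawm"), names(tbl))) {
      out[[paste0(mk, "_univariate")]] <- tryCatch(
        cox_fit(tbl, covariates = mk), error = function(e) NULL
      )
      for (cs in names(covar_sets)) {
        covs <- intersect(c(mk, covar_sets[[cs]]), names(tbl))
        out[[paste0(mk, "_", cs)]] <- tryCatch(
          cox_fit(tbl, covariates = covs), error = function(e) NULL
        )
      }
    }
    out
  }
  cox <- list(discovery = cox_for(disc), validation = cox_for(valid))

  scans <- list(
    alps = scan_cutpoints(disc, "alps_cnawm", step = alps_step,
                          min_group_frac = min_group_frac),
    fw = scan_cutpoints(disc, "fw_cnawm", step = fw_step,
                        min_group_frac = min_group_frac)
  )
  thresholds <- c(alps = scans$alps$optimal_threshold,
                  fw = scans$fw$optimal_threshold)

  validation <- list(
    alps = apply_threshold(valid, "alps_cnawm", thresholds[["alps"]]),
    fw = apply_threshold(valid, "fw_cnawm", thresholds[["fw"]],
                         high_is_favorable = FALSE)
  )
  joint <- tryCatch(
    stratify_joint(valid, thresholds[["alps"]], thresholds[["fw"]]),
    error = function(e) NULL
  )

  structure(
    list(
      cohort_raw = tibble::as_tibble(records),
      cohort_filtered = filtered, cohort_harmonized = harmonized,
      combat = combat, exclusions = exclusions, table1 = table1,
      anova = anova_res, median_split = median_split, cox = cox,
      scans = scans, thresholds = thresholds,
      validation = validation, joint = joint,
      discovery_site = discovery_site, validation_site = validation_site
    ),
    class = "cohort_run"
  )
}

#' @export
print.cohort_run <- function(x, ...) {
  cat(sprintf(
    "<cohort_run> %d subjects after filtering (discovery %s, validation %s)\n",
    nrow(x$cohort_harmonized), x$discovery_site, x$validation_site
  ))
  cat(sprintf("  thresholds: ALPS %g, FW %g\n",
              x$thresholds[["alps"]], x$thresholds[["fw"]]))
  cat(sprintf("  validation log-rank p: ALPS %.4g, FW %.4g\n",
              x$validation$alps$logrank$p, x$validation$fw$logrank$p))
  invisible(x)
}

#' Write the tabular outputs of a cohort run
#'
#' Persists the harmonized cohort, Cox summaries, cutpoint scans and a JSON
#' run manifest as plain-text files; byte-identical across repeated runs on
#' the same input.
#'
#' @param run A [run_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort_run <- function(run, dir) {
  stopifnot(inherits(run, "cohort_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wr <- function(df, name) {
    path <- file.path(dir, name)
    readr::write_csv(df, path)
    files <<- c(files, path)
  }
  wr(run$cohort_harmonized, "cohort_harmonized.csv")
  cox_rows <- dplyr::bind_rows(lapply(names(run$cox), function(role) {
    dplyr::bind_rows(lapply(names(run$cox[[role]]), function(nm) {
      fit <- run$cox[[role]][[nm]]
      if (is.null(fit)) return(NULL)
      dplyr::mutate(fit$results, model = nm, role = role, .before = 1)
    }))
  }))
  wr(cox_rows, "cox_results.csv")
  wr(run$scans$alps$scan, "scan_alps.csv")
  wr(run$scans$fw$scan, "scan_fw.csv")
  manifest <- list(
    n_subjects = nrow(run$cohort_harmonized),
    exclusions = as.list(run$exclusions),
    thresholds = as.list(run$thresholds),
    discovery_site = run$discovery_site,
    validation_site = run$validation_site,
    validation_p = list(alps = run$validation$alps$logrank$p,
                        fw = run$validation$fw$logrank$p)
  )
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  files <- c(files, mpath)
  invisible(files)
}
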