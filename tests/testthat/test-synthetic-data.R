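test_that("acquisition schemes enforce gradient-table invariants", {
  sch <- scheme_upenn_like(31)
  expect_equal(length(sch$bvals), 32)
  expect_equal(sum(sch$bvals == 0), 1)
  nrm <- sqrt(colSums(sch$bvecs[, sch$bvals > 0]^2))
  expect_true(all(abs(nrm - 1) <= 1e-6))

  expect_error(acquisition_scheme(c(0, 1000), cbind(c(0, 0, 0), c(0, 0, 2))),
               "unit vectors")
  expect_error(
    acquisition_scheme(rep(1000, 7), fibonacci_directions(7)),
    "b = 0"
  )
  few <- cbind(matrix(0, 3, 1), fibonacci_directions(5))
  expect_error(acquisition_scheme(c(0, rep(1000, 5)), few), "6 unique")
})

test_that("phantom construction matches the axis-aligned ground truth", {
  ph <- make_phantom(c(16, 16, 16))
  proj <- ph$region_labels == 1L
  nvox <- prod(ph$shape)
  d6 <- matrix(ph$tensors, nvox, 6)
  expect_true(all(d6[proj, 3] == 1.4e-3)) # Dzz axial
  expect_true(all(d6[proj, 1] == 0.3e-3)) # Dxx radial
  expect_true(all(d6[proj, 2] == 0.3e-3)) # Dyy radial
  expect_true(all(d6[, 4:6] == 0))
  expect_true(all(ph$fw_true == 0))

  assoc <- ph$region_labels == 2L
  expect_true(all(d6[assoc, 2] == 1.4e-3)) # principal axis y

  # closed-form FA of the fiber eigenvalues, via an independent oracle
  expect_equal(fa_closed_form(c(1.4e-3, 0.3e-3, 0.3e-3)), 0.752,
               tolerance = 0.001 / 0.752)

  expect_error(
    make_phantom(c(16, 16, 16), region_spec = list(list(
      name = "bad", label = "projection", diag = c(1e-3, 1e-3, -1e-3),
      bounds = list(x = c(1, 4), y = c(1, 4), z = c(1, 4))
    ))),
    "negative eigenvalue"
  )
  # conflicting fiber orientations on the same voxels must be rejected
  expect_error(
    make_phantom(c(16, 16, 16), region_spec = list(
      list(name = "p", label = "projection", diag = c(3e-4, 3e-4, 1.4e-3),
           bounds = list(x = c(1, 8), y = c(1, 8), z = c(1, 8))),
      list(name = "a", label = "association", diag = c(3e-4, 1.4e-3, 3e-4),
           bounds = list(x = c(4, 10), y = c(4, 10), z = c(4, 10)))
    )),
    "conflicting orientations"
  )
})

test_that("simulated signal follows the bi-tensor forward model", {
  # noise-free single-direction checks against the closed form
  ph <- fiber_phantom(c(8, 8, 8))
  sch <- acquisition_scheme(
    c(0, rep(1000, 6)),
    cbind(c(0, 0, 0), diag(3), fibonacci_directions(3))
  )
  dwi <- simulate_dwi(ph, sch, snr = Inf)
  s0 <- dwi$signal[1, 1, 1, 1]
  sz <- dwi$signal[1, 1, 1, 4] # g = (0,0,1) on the projection fiber
  expect_equal(sz / s0, exp(-1.4), tolerance = 1e-12)

  phw <- fiber_phantom(c(8, 8, 8), fw = 1)
  dww <- simulate_dwi(phw, sch, snr = Inf)
  ratios <- dww$signal[1, 1, 1, 2:7] / dww$signal[1, 1, 1, 1]
  expect_equal(unname(ratios), rep(exp(-3.0), 6), tolerance = 1e-12)

  # determinism and shape mismatch
  d1 <- simulate_dwi(ph, sch, snr = 20, seed = 99)
  d2 <- simulate_dwi(ph, sch, snr = 20, seed = 99)
  expect_identical(d1$signal, d2$signal)
  expect_error(simulate_dwi(ph, sch, snr = 0), "positive")
})

test_that("Rician noise level and bias behave as specified at snr = 30", {
  ph <- fiber_phantom(c(24, 24, 24)) # 13824 voxels
  sch <- scheme_single_shell(n_dirs = 6, n_b0 = 2)
  dwi <- simulate_dwi(ph, sch, snr = 30, seed = 4)
  s0 <- 100
  b0 <- as.vector(dwi$signal[, , , 1])
  # noise floor: empirical sd close to S0/30 at high SNR
  expect_equal(sd(b0), s0 / 30, tolerance = 0.1)
  # Rician mean exceeds the true signal (magnitude bias)
  expect_gt(mean(b0), s0)
  expect_lt(mean(b0) - s0, 3 * s0 / 30 / sqrt(length(b0)) + 0.05 * s0 / 30)
})

test_that("spherical ROIs have the stated geometry and containment", {
  ph <- make_phantom(c(32, 32, 32))
  rois <- make_rois(ph, diameter_mm = 4)
  masks <- list(rois$left$proj, rois$left$assoc, rois$right$proj,
                rois$right$assoc)
  expect_length(masks, 4)
  for (m in masks) expect_true(any(m))

  # voxel-center distance definition: every ROI voxel within 2 mm of center
  idx <- which(rois$left$proj, arr.ind = TRUE)
  ctr <- round(colMeans(idx))
  d <- sqrt(rowSums((idx - matrix(ctr, nrow(idx), 3, byrow = TRUE))^2))
  expect_true(all(d <= 2 + 1e-9))
  # and voxels just outside the radius are excluded
  expect_equal(sum(rois$left$proj), sum(d <= 2))

  # containment: ROI voxels all carry their fiber label
  expect_true(all(ph$region_labels[rois$left$proj] == 1L))
  expect_true(all(ph$region_labels[rois$right$assoc] == 2L))

  # a sphere larger than the fiber block must be rejected
  expect_error(make_rois(ph, diameter_mm = 40), "does not fit")
})

test_that("tumor labels honor the requested ROI overlap mode", {
  ph <- make_phantom(c(32, 32, 32))
  rois <- make_rois(ph)
  ipsi <- rois$left$proj | rois$left$assoc
  contra <- rois$right$proj | rois$right$assoc

  seg0 <- make_tumor_labels(ph, "left", "none", rois = rois)
  expect_true(all(seg0$labels[ipsi] == 0L))
  expect_true(all(seg0$labels[contra] == 0L))

  seg_f <- make_tumor_labels(ph, "left", "flair", rois = rois)
  expect_true(any(seg_f$labels[ipsi] == 1L))
  expect_false(any(seg_f$labels[ipsi] >= 2L))

  seg_e <- make_tumor_labels(ph, "left", "enhancing", rois = rois)
  expect_true(any(seg_e$labels[ipsi] == 2L))

  seg_n <- make_tumor_labels(ph, "left", "necrosis", rois = rois)
  expect_true(any(seg_n$labels[ipsi] == 3L))
  expect_true(all(seg_n$labels[contra] == 0L))

  # enhancing volume is count x voxel volume (in ml)
  expect_equal(seg_e$enhancing_volume_ml,
               sum(seg_e$labels == 2L) * ph$voxel_size^3 / 1000)
})

test_that("cohort simulator plants site effects, betas and censoring", {
  # censor_rate = 0 gives all events
  coh0 <- quick_cohort(seed = 1, n = 50, censor_rate = 0)
  expect_true(all(coh0$event == 1L))

  # planted +0.3 shift on site B shows up in the observed site means
  coh <- quick_cohort(seed = 2, n = 200, shift_b = 0.3)
  dm <- diff(tapply(coh$alps_cnawm, coh$site, mean))
  expect_equal(unname(dm), 0.3, tolerance = 0.15) # +- a few SE at n = 200
  # ground-truth columns stay undistorted
  expect_equal(unname(diff(tapply(coh$alps_cnawm_true, coh$site, mean))), 0,
               tolerance = 0.05)

  # determinism
  expect_identical(quick_cohort(seed = 7), quick_cohort(seed = 7))
  expect_error(simulate_cohort(cohort_spec(n_per_site = c(A = 1, B = 10))),
               "at least 2")

  # null cohort: median-split log-rank holds its size approximately
  reps <- 200
  rej <- 0
  set.seed(31)
  for (r in seq_len(reps)) {
    d <- simulate_cohort(
      cohort_spec(n_per_site = c(A = 30, B = 30), beta_alps = 0, beta_fw = 0,
                  beta_age = 0, censor_rate = 0.2)
    )
    d$grp <- dichotomize_median(d$alps_cnawm)
    if (logrank_test(d, group = "grp")$p < 0.05) rej <- rej + 1
  }
  expect_gt(rej / reps, 0.01)
  expect_lt(rej / reps, 0.10)
})
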