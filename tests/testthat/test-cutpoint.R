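test_that("the threshold grid follows the stated arithmetic", {
  set.seed(23)
  n <- 120
  d <- data.frame(
    metric = seq(1.00, 2.00, length.out = n),
    os_days = rexp(n) * 300 + 1,
    event = 1L
  )
  sc <- scan_cutpoints(d, "metric", step = 0.01, min_group_frac = 0)
  # 101 grid points on [1, 2]; endpoints drop out only via group emptiness
  full_grid <- seq(1.00, 2.00, by = 0.01)
  expect_equal(length(full_grid), 101)
  expect_true(all(round(sc$scan$threshold, 10) %in% round(full_grid, 10)))
  expect_true(all(diff(sc$scan$threshold) > 0))
  expect_equal(sc$scan$n_low + sc$scan$n_high, rep(n, nrow(sc$scan)))

  # group sizes match brute-force counting at every threshold
  for (i in sample(nrow(sc$scan), 10)) {
    thr <- sc$scan$threshold[i]
    expect_equal(sc$scan$n_high[i], sum(d$metric > thr))
  }

  expect_error(scan_cutpoints(d, "metric", step = 0.01, min_group_frac = 0.6),
               "min_group_frac")
})

test_that("optimum selection applies the p / |log HR| / threshold tie rule", {
  mk <- function(p, hr, thr) tibble::tibble(threshold = thr, p = p, hr = hr)
  # unique minimum p
  s1 <- mk(c(0.2, 0.01, 0.5), c(0.9, 0.8, 1.1), c(1, 2, 3))
  expect_equal(select_optimal(s1), 2)
  # tie on p: larger |log HR| wins (0.6 beats 0.8)
  s2 <- mk(c(0.03, 0.03), c(0.8, 0.6), c(1.1, 1.2))
  expect_equal(select_optimal(s2), 1.2)
  # full tie: lowest threshold
  s3 <- mk(c(0.03, 0.03), c(0.7, 0.7), c(1.4, 1.3))
  expect_equal(select_optimal(s3), 1.3)

  # randomized scans against a brute-force oracle
  set.seed(24)
  for (r in 1:50) {
    s <- tibble::tibble(
      threshold = sort(runif(20)),
      p = sample(round(runif(20, 0.001, 0.5), 2), 20, replace = TRUE),
      hr = round(runif(20, 0.4, 2.5), 1)
    )
    # oracle: explicit lexicographic loop
    best <- NULL
    for (i in seq_len(nrow(s))) {
      if (is.null(best)) {
        best <- i
      } else if (s$p[i] < s$p[best] ||
                 (s$p[i] == s$p[best] &&
                  abs(log(s$hr[i])) > abs(log(s$hr[best]))) ||
                 (s$p[i] == s$p[best] &&
                  abs(log(s$hr[i])) == abs(log(s$hr[best])) &&
                  s$threshold[i] < s$threshold[best])) {
        best <- i
      }
    }
    expect_equal(select_optimal(s), s$threshold[best])
  }
})

test_that("scan is deterministic and consistent with apply_threshold", {
  d <- simulate_changepoint_cohort(200, seed = 25)
  s1 <- scan_cutpoints(d, "metric", step = 0.01)
  s2 <- scan_cutpoints(d, "metric", step = 0.01)
  expect_identical(s1$scan, s2$scan)

  thr <- s1$optimal_threshold
  ap <- apply_threshold(d, "metric", thr)
  row <- s1$scan[s1$scan$threshold == thr, ]
  # same > / <= convention on both paths
  expect_equal(sum(ap$groups$group == "high"), row$n_high)
  expect_equal(ap$logrank$p, row$p)
  expect_equal(ap$logrank$hr, row$hr)

  # a threshold below the whole range puts everyone in "high": warned as
  # out-of-range, then rejected for the empty low group
  expect_warning(try(apply_threshold(d, "metric", min(d$metric) - 1),
                     silent = TRUE), "outside")
  expect_error(
    suppressWarnings(apply_threshold(d, "metric", min(d$metric) - 1)),
    "empty group"
  )
})

test_that("a planted hazard change-point is recovered by the scan", {
  hits <- 0
  reps <- 40
  for (r in seq_len(reps)) {
    d <- simulate_changepoint_cohort(300, threshold = 1.40, hr_below = 2,
                                     seed = 3000 + r)
    sc <- scan_cutpoints(d, "metric", step = 0.01)
    if (abs(sc$optimal_threshold - 1.40) <= 0.05) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.8)
})

test_that("minimum-p selection is anticonservative under the null", {
  # documented inflation property: selected p < 0.05 far more often than 5%
  set.seed(26)
  sig <- 0
  reps <- 60
  for (r in seq_len(reps)) {
    d <- data.frame(metric = rnorm(120), os_days = rexp(120) * 300 + 1,
                    event = 1L)
    sc <- scan_cutpoints(d, "metric", step = 0.05)
    best_p <- min(sc$scan$p)
    if (best_p < 0.05) sig <- sig + 1
  }
  expect_gt(sig / reps, 0.15)
})

test_that("joint stratification partitions the cohort with ordered risk", {
  coh <- simulate_cohort(
    cohort_spec(n_per_site = c(A = 250, B = 250), censor_rate = 0.2),
    seed = 27
  )
  js <- stratify_joint(coh, alps_thr = 1.40, fw_thr = 0.21)
  # strata partition the cohort
  expect_equal(sum(js$counts), nrow(js$strata))
  expect_equal(length(unique(js$strata$stratum)), 3)
  # brute-force classification oracle
  fav <- sum(coh$alps_cnawm > 1.40 & coh$fw_cnawm <= 0.21)
  adv <- sum(coh$alps_cnawm <= 1.40 & coh$fw_cnawm > 0.21)
  expect_equal(unname(js$counts[["favorable"]]), fav)
  expect_equal(unname(js$counts[["adverse"]]), adv)
  expect_equal(unname(js$counts[["discordant"]]), nrow(coh) - fav - adv)
  expect_equal(nrow(js$pairwise), 3)
  # planted effects: favorable stratum outlives adverse
  p_fa <- js$pairwise$p[js$pairwise$comparison == "favorable vs adverse"]
  hr_fa <- js$pairwise$hr[js$pairwise$comparison == "favorable vs adverse"]
  expect_lt(p_fa, 0.05)
  expect_gt(hr_fa, 1)

  # empty stratum errors with sizes listed
  one_sided <- dplyr::mutate(coh, alps_cnawm = 2, fw_cnawm = 0.1)
  expect_error(stratify_joint(one_sided, 1.40, 0.21), "empty stratum")
})
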