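test_that("single-feature fits fall back to raw site estimates", {
  coh <- quick_cohort(seed = 3, n = 80)
  m <- combat_fit(coh, features = "alps_cnawm")
  expect_false(m$eb_used)
  expect_equal(m$gamma_star, m$gamma_hat)
  expect_equal(m$delta_star, m$delta_hat)
})

test_that("planted location/scale site effects are estimated and removed", {
  feats <- c("alps_cnawm", "alps_ipsi", "fw_cnawm")
  coh <- plant_site_effects(quick_cohort(seed = 10, n = 200), feats)
  m <- combat_fit(coh, features = feats)
  expect_true(m$eb_used)

  # moment check: shrunken locations track the observed standardized site
  # mean difference (itself ~ planted shift / pooled sd up to sampling noise)
  pooled_sd <- sqrt(m$var_pooled[["alps_cnawm"]])
  gamma_diff <- diff(m$gamma_star[, "alps_cnawm"])
  obs_diff <- diff(tapply(coh$alps_cnawm, coh$site, mean))
  expect_equal(unname(gamma_diff), unname(obs_diff) / pooled_sd,
               tolerance = 0.03)
  expect_equal(unname(gamma_diff), 0.3 / pooled_sd, tolerance = 0.2)
  # shrunken scale ratio tracks the observed site sd ratio (~ planted x1.5)
  delta_ratio <- m$delta_star["B", "alps_cnawm"] / m$delta_star["A", "alps_cnawm"]
  obs_ratio <- unname(diff(log(tapply(coh$alps_cnawm, coh$site, sd))))
  expect_equal(unname(delta_ratio), exp(obs_ratio), tolerance = 0.05)
  expect_equal(unname(delta_ratio), 1.5, tolerance = 0.2)

  h <- combat_apply(m, coh)
  expect_lt(abs(diff(tapply(h$alps_cnawm, h$site, mean))), 0.02)
  sds <- tapply(h$alps_cnawm, h$site, sd)
  expect_equal(unname(sds[2] / sds[1]), 1, tolerance = 0.10)
  # pooled mean is preserved (the removed scale variance is not)
  expect_equal(mean(h$alps_cnawm), mean(coh$alps_cnawm), tolerance = 0.02)
})

test_that("covariate structure survives harmonization", {
  # identical age slope at both sites on top of site effects
  feats <- c("alps_cnawm", "alps_ipsi", "fw_cnawm")
  coh <- plant_site_effects(quick_cohort(seed = 20, n = 200),
                            c("alps_cnawm", "alps_ipsi"), shift = 0.3,
                            scale = 1)
  slope <- 0.01
  coh$alps_cnawm <- coh$alps_cnawm + slope * (coh$age - mean(coh$age))
  coh$alps_ipsi <- coh$alps_ipsi + slope * (coh$age - mean(coh$age))

  m <- combat_fit(coh, features = feats)
  fit_se <- summary(stats::lm(alps_cnawm ~ site + age + sex,
                              data = coh))$coefficients["age", "Std. Error"]
  expect_lt(abs(m$beta["age", "alps_cnawm"] - slope), 2 * fit_se)

  # the age association within each site is untouched by the adjustment
  h <- combat_apply(m, coh)
  for (s in c("A", "B")) {
    r_before <- cor(coh$age[coh$site == s], coh$alps_cnawm[coh$site == s])
    r_after <- cor(h$age[h$site == s], h$alps_cnawm[h$site == s])
    expect_lt(abs(r_before - r_after), 0.05)
  }
})

test_that("identical pseudo-sites leave the data untouched", {
  base <- quick_cohort(seed = 30, n = 100)
  dup <- base[base$site == "A", ]
  two <- dplyr::bind_rows(
    dplyr::mutate(dup, site = "S1"),
    dplyr::mutate(dup, site = "S2")
  )
  m <- combat_fit(two, features = "alps_cnawm", parametric = FALSE)
  expect_false(m$eb_used)
  expect_equal(max(abs(m$gamma_hat)), 0, tolerance = 1e-12)
  h <- combat_apply(m, two)
  expect_lt(max(abs(h$alps_cnawm - two$alps_cnawm)), 1e-10)
})

test_that("repeated harmonization is a fixed point", {
  feats <- c("alps_cnawm", "alps_ipsi", "fw_cnawm")
  coh <- plant_site_effects(quick_cohort(seed = 40, n = 150), feats,
                            shift = 0.2, scale = 1.3)
  # exact fixed point for the pure location/scale adjustment: once site
  # effects are removed, refitting finds none
  m1 <- combat_fit(coh, features = feats, covariates = character(0),
                   parametric = FALSE)
  h1 <- combat_apply(m1, coh)
  m2 <- combat_fit(h1, features = feats, covariates = character(0),
                   parametric = FALSE)
  h2 <- combat_apply(m2, h1)
  expect_lt(max(abs(as.matrix(h2[, feats]) - as.matrix(h1[, feats]))), 1e-8)

  # with covariate re-standardization the fixed point is approximate: the
  # per-site scale correction rescales within-site covariate slopes
  m1c <- combat_fit(coh, features = feats)
  h1c <- combat_apply(m1c, coh)
  h2c <- combat_apply(combat_fit(h1c, features = feats), h1c)
  expect_lt(max(abs(as.matrix(h2c[, feats]) - as.matrix(h1c[, feats]))), 5e-3)
})

test_that("null site effects: moments preserved, perturbation shrinks with n", {
  set.seed(55)
  feats <- c("alps_cnawm", "alps_ipsi", "fw_cnawm")
  devs <- sapply(c(100, 400), function(n) {
    coh <- quick_cohort(seed = n, n = n)
    m <- combat_fit(coh, features = feats)
    h <- combat_apply(m, coh)
    mean(abs(h$alps_cnawm - coh$alps_cnawm))
  })
  expect_lt(devs[2], devs[1]) # shrinks with n
  expect_lt(devs[2], 0.02)

  coh <- quick_cohort(seed = 56, n = 300)
  h <- combat_apply(combat_fit(coh, features = feats), coh)
  expect_equal(mean(h$alps_cnawm), mean(coh$alps_cnawm), tolerance = 0.02)
  expect_equal(var(h$alps_cnawm) / var(coh$alps_cnawm), 1, tolerance = 0.02)
})

test_that("the implementation matches sva::ComBat on shared ground", {
  skip_if_not_installed("sva")
  feats <- c("alps_cnawm", "alps_ipsi", "fw_cnawm")
  coh <- plant_site_effects(quick_cohort(seed = 60, n = 120), feats,
                            shift = 0.25, scale = 1.4)
  m <- combat_fit(coh, features = feats)
  h <- combat_apply(m, coh)
  ref <- suppressMessages(sva::ComBat(
    dat = t(as.matrix(coh[, feats])),
    batch = coh$site,
    mod = stats::model.matrix(~ age + sex, data = coh)
  ))
  # agreement up to the per-site variance divisor convention (sva uses the
  # n - 1 sample variance; this implementation uses the population variance
  # so the no-op and idempotence limits are exact) -- an O(1/n) difference
  expect_lt(max(abs(t(ref) - as.matrix(h[, feats]))), 5e-3)
  # locations agree tightly; scale ratio differs only by ~n/(n-1)
  expect_equal(unname(diff(m$gamma_hat[, "alps_cnawm"])),
               unname(diff(m$gamma_star[, "alps_cnawm"])), tolerance = 0.05)
})

test_that("degenerate inputs are rejected", {
  coh <- quick_cohort(seed = 70, n = 50)
  expect_error(combat_fit(coh[coh$site == "A", ], features = "alps_cnawm"),
               "2 sites")
  bad <- coh
  bad$alps_cnawm[bad$site == "A"] <- 1.4 # constant within a site
  expect_error(combat_fit(bad, features = "alps_cnawm"), "constant")
  na <- coh
  na$alps_cnawm[1] <- NA
  expect_error(combat_fit(na, features = "alps_cnawm"), "missing")

  m <- combat_fit(coh, features = "alps_cnawm")
  unseen <- dplyr::mutate(coh, site = "C")
  expect_error(combat_apply(m, unseen), "unseen")
})
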