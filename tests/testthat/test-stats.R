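test_that("ANOVA with Tukey behaves at its analytic anchor points", {
  # identical group distributions: F = 0, p = 1
  d <- data.frame(v = rep(c(1, 2, 3, 4), 3),
                  g = rep(c("a", "b", "c"), each = 4))
  res <- anova_tukey(d, "v", "g")
  expect_lt(res$f_statistic, 1e-12)
  expect_equal(res$p_value, 1)

  # two groups: Tukey p equals the pooled-variance two-sample t-test p
  set.seed(14)
  d2 <- data.frame(v = c(rnorm(20), rnorm(20, 0.8)),
                   g = rep(c("a", "b"), each = 20))
  res2 <- anova_tukey(d2, "v", "g")
  tt <- t.test(v ~ g, data = d2, var.equal = TRUE)
  expect_equal(res2$pairwise$p_adj, tt$p.value, tolerance = 1e-6)

  # power: the 1-SD shifted group's pairwise contrasts are flagged in
  # nearly all replicates
  hits <- 0
  total <- 0
  reps <- 100
  set.seed(15)
  for (r in seq_len(reps)) {
    dd <- data.frame(
      v = c(rnorm(50), rnorm(50), rnorm(50), rnorm(50, 1)),
      g = rep(c("a", "b", "c", "d"), each = 50)
    )
    pw <- anova_tukey(dd, "v", "g")$pairwise
    pd <- pw$p_adj[grepl("d", pw$contrast)]
    hits <- hits + sum(pd < 0.01)
    total <- total + length(pd)
  }
  expect_gte(hits / total, 0.95)

  expect_error(anova_tukey(data.frame(v = 1:3, g = c("a", "a", "b")),
                           "v", "g"), "at least 2")
})

test_that("median dichotomization follows the ties-to-low rule", {
  g <- dichotomize_median(1:5)
  expect_equal(as.character(g), c("low", "low", "low", "high", "high"))

  set.seed(16)
  v <- rnorm(40)
  expect_equal(as.integer(table(dichotomize_median(v))), c(20L, 20L))

  # heavy ties at the median: brute-force rule application
  vt <- c(1, 2, 2, 2, 2, 3, 4)
  gt <- dichotomize_median(vt)
  oracle <- ifelse(vt > median(vt), "high", "low")
  expect_equal(as.character(gt), oracle)

  expect_error(dichotomize_median(rep(3, 5)), "identical")
})

test_that("Kaplan-Meier matches hand product-limit computation", {
  # no censoring: steps 0.75/0.5/0.25/0 and the flat-at-0.5 median convention
  km <- km_estimate(data.frame(os_days = 1:4, event = 1))
  expect_equal(km$curve$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$medians$median_days, 2.5)
  expect_equal(km$medians$median_months, 2.5 / 30.44)

  # all censored: flat curve, undefined median
  km_c <- km_estimate(data.frame(os_days = c(5, 8, 12), event = 0))
  expect_true(all(km_c$curve$surv == 1))
  expect_true(is.na(km_c$medians$median_days))

  # mixed toy set against the hand-rolled product-limit oracle
  time <- c(3, 5, 5, 7, 9, 11, 11, 14)
  event <- c(1, 1, 0, 1, 0, 1, 1, 0)
  km_m <- km_estimate(data.frame(os_days = time, event = event))
  orc <- km_oracle(time, event)
  got <- km_m$curve[km_m$curve$n_event > 0, c("time", "surv")]
  expect_equal(got$time, orc$time)
  expect_equal(got$surv, orc$surv, tolerance = 1e-12)

  # no censoring: KM equals the empirical survival function
  set.seed(17)
  t2 <- sample(1:50, 30, replace = TRUE)
  km2 <- km_estimate(data.frame(os_days = t2, event = 1))
  emp <- sapply(km2$curve$time, function(u) mean(t2 > u))
  expect_equal(km2$curve$surv, emp, tolerance = 1e-12)
})

test_that("log-rank matches the hand-computed O-E statistic", {
  d <- data.frame(
    os_days = c(3, 6, 8, 12, 4, 7, 10, 15),
    event = c(1, 1, 0, 1, 1, 1, 1, 0),
    grp = rep(c("x", "y"), each = 4)
  )
  lr <- logrank_test(d, group = "grp")
  chi2_oracle <- logrank_oracle(d$os_days, d$event, d$grp)
  expect_equal(lr$chi2, chi2_oracle, tolerance = 1e-9)
  expect_equal(lr$p, pchisq(chi2_oracle, 1, lower.tail = FALSE))

  # identical groups: statistic 0, p 1
  same <- data.frame(os_days = rep(c(2, 5, 9), 2), event = 1,
                     grp = rep(c("x", "y"), each = 3))
  lr0 <- logrank_test(same, group = "grp")
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  # relabeling invariance
  flip <- d
  flip$grp <- ifelse(d$grp == "x", "y", "x")
  expect_equal(logrank_test(flip, group = "grp")$chi2, lr$chi2,
               tolerance = 1e-12)

  expect_error(
    logrank_test(data.frame(os_days = 1:4, event = 0,
                            grp = rep(c("x", "y"), 2)), group = "grp"),
    "no events"
  )
})

test_that("Cox fits recover planted effects and agree with the log-rank score", {
  # two-group indicator: Cox score test ~ log-rank chi-square, no ties
  set.seed(18)
  n <- 200
  d <- data.frame(
    os_days = rexp(n) * 100 + cumsum(rep(1e-4, n)), # jitter kills ties
    event = 1L,
    grp = rep(c(0, 1), each = n / 2)
  )
  lr <- logrank_test(dplyr::mutate(d, g = factor(grp)), group = "g")
  cx <- cox_fit(d, covariates = "grp", standardize = FALSE)
  sc <- summary(cx$fit)$sctest[["test"]]
  expect_lt(abs(sc - lr$chi2) / lr$chi2, 0.01)

  # per-SD parameter recovery on the cohort generator's own scale
  coh <- simulate_cohort(
    cohort_spec(n_per_site = c(A = 300, B = 300), censor_rate = 0.3),
    seed = 19
  )
  cx2 <- cox_fit(coh, covariates = c("alps_cnawm_true", "fw_cnawm_true",
                                     "age", "sex"))
  res <- tidy(cx2)
  expect_lt(abs(res$beta[res$term == "alps_cnawm_true"] - (-0.3)),
            2 * res$se[res$term == "alps_cnawm_true"])
  expect_lt(abs(res$beta[res$term == "fw_cnawm_true"] - 0.3),
            2 * res$se[res$term == "fw_cnawm_true"])
  expect_true(all(res$hr > 0))
  expect_true(all(res$ci_lo < res$hr & res$hr < res$ci_hi))

  # Efron and Breslow agree exactly without tied event times
  cxe <- cox_fit(d, covariates = "grp", ties = "efron", standardize = FALSE)
  cxb <- cox_fit(d, covariates = "grp", ties = "breslow", standardize = FALSE)
  expect_equal(tidy(cxe)$beta, tidy(cxb)$beta, tolerance = 1e-10)

  # degenerate designs error out
  expect_error(cox_fit(d, covariates = c("grp", "grp2")), "")
  dc <- d
  dc$const <- 1
  expect_error(cox_fit(dc, covariates = "const"), "constant")
})
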