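# shared fixture builders; everything is generated in code at test time

# whole-grid single-fiber phantom (every voxel anisotropic tissue)
fiber_phantom <- function(shape = c(12, 12, 12), diag = c(0.3e-3, 0.3e-3, 1.4e-3),
                          fw = 0) {
  spec <- list(list(
    name = "fiber", label = "projection", diag = diag,
    bounds = list(x = c(1, shape[1]), y = c(1, shape[2]), z = c(1, shape[3]))
  ))
  make_phantom(shape, region_spec = spec, fw_field = fw)
}

# independently coded closed-form FA from an eigenvalue triple (oracle)
fa_closed_form <- function(l) {
  sqrt(0.5 * ((l[1] - l[2])^2 + (l[2] - l[3])^2 + (l[3] - l[1])^2) /
         sum(l^2))
}

# hand-rolled product-limit estimator (oracle for KM)
km_oracle <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  data.frame(time = ut, surv = out)
}

# hand-rolled two-group log-rank chi-square (oracle)
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group)) # 1/2
  ut <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ut) {
    n1 <- sum(time >= t & g == 1)
    n2 <- sum(time >= t & g == 2)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    n <- n1 + n2
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}

# uniform planted site-B distortion across a feature set (explicit ground
# truth for harmonization tests)
plant_site_effects <- function(coh, feats, shift = 0.3, scale = 1.5) {
  rows <- coh$site == "B"
  for (f in feats) {
    y <- coh[[f]][rows] + shift
    m <- mean(y)
    coh[[f]][rows] <- m + scale * (y - m)
  }
  coh
}

# small two-site cohort used in several table-level tests
quick_cohort <- function(seed = 123, n = 150, shift_b = 0, scale_b = 1,
                         censor_rate = 0.3, ...) {
  spec <- cohort_spec(
    n_per_site = c(A = n, B = n),
    site_effects = list(A = list(shift = 0, scale = 1),
                        B = list(shift = shift_b, scale = scale_b)),
    censor_rate = censor_rate, ...
  )
  simulate_cohort(spec, seed = seed)
}
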