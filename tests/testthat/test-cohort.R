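test_that("generation is bit-reproducible given the seed", {
  a <- generate_cohort(cohort_config(n_patients = 4, seed = 77))
  b <- generate_cohort(cohort_config(n_patients = 4, seed = 77))
  expect_identical(a$activity, b$activity)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(cohort_config(n_patients = 4, seed = 78))
  expect_false(identical(a$activity, c2$activity))
})

test_that("invalid configuration fields raise named validation errors", {
  cfg <- cohort_config()
  cfg$n_patients <- 0
  expect_error(generate_cohort(cfg), "invalid config field: n_patients")
  cfg2 <- cohort_config()
  cfg2$dropout_prob <- 2
  expect_error(generate_cohort(cfg2), "invalid config field: dropout_prob")
  expect_error(cohort_config(injected_gbq_mean = -1), "injected_gbq")
})

test_that("generated tables respect their structural invariants", {
  coh <- generate_cohort(cohort_config(n_patients = 6, seed = 21))
  expect_true(all(coh$activity$conc >= 0))
  expect_true(all(coh$activity$time_h > 0))
  cumok <- tapply(coh$cycles$cumulative_gbq, coh$cycles$patient_id,
                  function(v) all(diff(v) > 0))
  expect_true(all(cumok))
  # every followed cycle has all five organ truths and a cumulative dose
  expect_true(all(table(coh$truth$patient_id, coh$truth$cycle) %in% c(0, 5)))
  expect_true(all(coh$truth$cum_dose_gy >= coh$truth$dose_gy - 1e-12))
  # per-patient cycle counts fall in 4..6 under dropout
  ncy <- tapply(coh$cycles$cycle, coh$cycles$patient_id, max)
  expect_true(all(ncy >= 4 & ncy <= 6))
  # baseline row present for every patient
  expect_true(all(table(coh$outcomes$patient_id[coh$outcomes$cycle == 0]) == 1))
})

test_that("scan eligibility reproduces the organ-wise window tension", {
  cfg <- cohort_config()
  # tumor population half-life ~45 h: day-1 scans fall below the window,
  # day-2/3 scans inside; marrow (~30 h) accepts day-1 scans
  expect_false(window_filter(24, cfg$teff_mean_h[["tumor"]]))
  expect_true(all(window_filter(c(48, 72), cfg$teff_mean_h[["tumor"]])))
  expect_true(window_filter(24, cfg$teff_mean_h[["bone_marrow"]]))
  sc <- small_cohort()
  st_times <- sc$doses$scan_time_h[sc$doses$method == "STPD" &
                                     sc$doses$organ == "tumor"]
  expect_true(all(st_times > 33))   # no day-1 tumor STPD survives the filter
})

test_that("the configured negative dose-PSA link dominates across replicate seeds", {
  neg <- logical(20)
  for (s in seq_len(20)) {
    coh <- generate_cohort(cohort_config(n_patients = 12, seed = 1000 + s))
    tum <- coh$truth[coh$truth$organ == "tumor", ]
    out <- coh$outcomes
    base <- out[out$cycle == 0, c("patient_id", "psa")]
    fup <- merge(out[out$cycle > 0, ], base, by = "patient_id",
                 suffixes = c("", "_baseline"))
    m <- merge(fup, tum[, c("patient_id", "cycle", "cum_dose_gy")],
               by = c("patient_id", "cycle"))
    rho <- spearman_test(m$cum_dose_gy,
                         psa_decline_rate(m$psa_baseline, m$psa))$rho
    neg[s] <- rho < 0
  }
  expect_gte(mean(neg), 0.95)
})

test_that("null cohorts carry no dose-outcome association", {
  rhos <- hrs <- numeric(12)
  for (s in seq_len(12)) {
    coh <- generate_null_cohort(cohort_config(n_patients = 16, seed = 3000 + s))
    tum <- coh$truth[coh$truth$organ == "tumor", ]
    out <- coh$outcomes
    base <- out[out$cycle == 0, c("patient_id", "psa")]
    fup <- merge(out[out$cycle > 0, ], base, by = "patient_id",
                 suffixes = c("", "_baseline"))
    m <- merge(fup, tum[, c("patient_id", "cycle", "cum_dose_gy")],
               by = c("patient_id", "cycle"))
    rhos[s] <- spearman_test(m$cum_dose_gy,
                             psa_decline_rate(m$psa_baseline, m$psa))$rho
    tot <- tapply(tum$dose_gy, tum$patient_id, sum)
    pt <- unique(out[, c("patient_id", "os_days", "os_event")])
    pt$logdose <- log(tot[pt$patient_id])
    hrs[s] <- cox_univariate(pt$os_days, pt$os_event, pt$logdose)$hr
  }
  expect_lt(median(abs(rhos)), 0.15)
  expect_gt(median(hrs), 0.7)
  expect_lt(median(hrs), 1.4)
})

test_that("the generator is centered on the configured population half-lives", {
  # ~200 curves per organ: the draw median settles within 5% of the target
  cfg <- cohort_config(n_patients = 35, noise_cv = 0)
  coh <- generate_cohort(cfg)
  for (og in organ_levels()) {
    med <- median(coh$truth$teff_h[coh$truth$organ == og])
    expect_equal(med / cfg$teff_mean_h[[og]], 1, tolerance = 0.05)
  }
})

test_that("mean first-cycle dose per unit activity tracks the calibration targets", {
  sc <- small_cohort()
  coh <- generate_cohort(cohort_config(n_patients = 20, seed = 4))
  tr1 <- coh$truth[coh$truth$cycle == 1, ]
  inj1 <- coh$cycles[coh$cycles$cycle == 1, c("patient_id", "injected_gbq")]
  m <- merge(tr1, inj1, by = "patient_id")
  targets <- cohort_config()$gy_per_gbq_cycle1
  for (og in c("kidneys", "tumor", "bone_marrow")) {
    gy_gbq <- mean(m$dose_gy[m$organ == og] / m$injected_gbq[m$organ == og])
    expect_equal(gy_gbq / targets[[og]], 1, tolerance = 0.35)
  }
})
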