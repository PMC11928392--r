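test_that("noiseless mono-exponential samples return the generating parameters", {
  lam <- log(2) / 45.05
  d <- mono_samples(5, lam, c(4, 24, 48, 72))
  fit <- fit_kinetics(d, model_kind = "mono")
  expect_equal(fit$rates[1], lam, tolerance = 1e-6)
  expect_equal(fit$amplitudes[1], 5, tolerance = 1e-6)
  expect_equal(fit$Teff_h, 45.05, tolerance = 1e-6)
  expect_identical(fit$model_kind, "mono")
})

test_that("noiseless bi-exponential samples return the generating half-life", {
  d <- biexp_samples(10, 0.0154, 10, 0.15, c(2, 6, 24, 48, 72))
  fit <- fit_kinetics(d, model_kind = "biexp")
  expect_identical(fit$model_kind, "biexp")
  expect_equal(fit$Teff_h, log(2) / 0.0154, tolerance = 1e-4)
  expect_equal(fit$rates, c(0.0154, 0.15), tolerance = 1e-4)
})

test_that("degenerate and invalid inputs are rejected with named errors", {
  expect_error(fit_kinetics(data.frame(time_h = c(4, 24, 48), conc = c(0, 0, 0))),
               "empty curve")
  expect_error(fit_kinetics(mono_samples(5, 0.02, 24), model_kind = "mono"),
               "insufficient time points")
  expect_error(fit_kinetics(biexp_samples(10, 0.015, 10, 0.2, c(3, 24)),
                            model_kind = "biexp"),
               "insufficient time points")
  expect_error(fit_kinetics(data.frame(time_h = c(4, 4, 24), conc = c(1, 1, 0.5))),
               "duplicate")
  expect_error(fit_kinetics(data.frame(time_h = c(-1, 24), conc = c(1, 0.5)),
                            model_kind = "mono"),
               "positive")
})

test_that("biexp request on mono-shaped data falls back to mono", {
  d <- mono_samples(4, 0.02, c(4, 24, 48, 72))
  fit <- fit_kinetics(d, model_kind = "biexp")
  expect_identical(fit$model_kind, "mono")
  expect_equal(fit$Teff_h, log(2) / 0.02, tolerance = 1e-4)
})

test_that("self-inverse recovery holds over random admissible parameter sets", {
  set.seed(42)
  lam_phys <- nuclide_lu177()$lambda_phys
  for (r in 1:20) {
    A <- runif(1, 0.5, 20)
    lam <- runif(1, lam_phys * 1.5, 0.1)
    d <- mono_samples(A, lam, c(3, 20, 45, 70, 96))
    fit <- fit_kinetics(d, model_kind = "mono")
    expect_equal(fit$rates[1], lam, tolerance = 1e-4)
    expect_equal(fit$amplitudes[1], A, tolerance = 1e-4)
  }
})

test_that("Teff is invariant to uniform concentration rescaling and rates respect physical decay", {
  set.seed(7)
  lam_phys <- nuclide_lu177()$lambda_phys
  d <- biexp_samples(8, 0.018, 8, 0.5, c(3, 24, 48, 72))
  f1 <- fit_kinetics(d)
  d2 <- transform(d, conc = conc * 137.5)
  f2 <- fit_kinetics(d2)
  expect_equal(f1$Teff_h, f2$Teff_h, tolerance = 1e-6)
  expect_true(all(f1$rates >= lam_phys))
  # noisy fits stay bounded below by the physical decay constant too
  for (r in 1:10) {
    dn <- transform(d, conc = conc * exp(rnorm(4, 0, 0.3)))
    fn <- fit_kinetics(dn)
    expect_true(all(fn$rates >= lam_phys))
  }
})

test_that("curve_integral matches closed forms", {
  f_mono <- fit_kinetics(mono_samples(2, 0.1, c(5, 15, 30)), model_kind = "mono")
  expect_equal(curve_integral(f_mono), 20, tolerance = 1e-6)
  f_t <- fit_kinetics(mono_samples(1, log(2) / 45.05, c(5, 30, 60)), model_kind = "mono")
  expect_equal(curve_integral(f_t), 45.05 / log(2), tolerance = 1e-6)
  f_bi <- fit_kinetics(biexp_samples(10, 0.05, 10, 0.5, c(1, 3, 8, 20, 40)))
  expect_equal(curve_integral(f_bi), 10 / 0.05 - 10 / 0.5, tolerance = 1e-4)
  bad <- f_mono; bad$rates <- -0.1
  expect_error(curve_integral(bad), "non-integrable")
})

test_that("numeric and analytic integrals agree", {
  # dense noiseless mono sampling: within 0.5% of the closed form
  d <- mono_samples(1, 0.1, seq(1, 200, by = 1))
  fit <- fit_kinetics(d, model_kind = "mono")
  expect_equal(numeric_integral(d, fit), 10, tolerance = 0.005)
  # two samples on a mono curve: exponential segments plus the analytic
  # tail A exp(-lambda t_last)/lambda recover the closed form exactly
  d2 <- mono_samples(3, 0.05, c(10, 40))
  fit2 <- fit_kinetics(d2, model_kind = "mono")
  expect_equal(numeric_integral(d2, fit2), 3 / 0.05, tolerance = 1e-8)
  expect_error(numeric_integral(d2[0, ], fit2), "empty")
  # >= 6 points over >= 3 half-lives: agreement within 1%
  set.seed(3)
  for (r in 1:10) {
    lam <- runif(1, 0.02, 0.2)
    tt <- seq(2, 3.5 * log(2) / lam, length.out = sample(6:12, 1))
    d3 <- mono_samples(runif(1, 1, 10), lam, tt)
    f3 <- fit_kinetics(d3, model_kind = "mono")
    expect_equal(numeric_integral(d3, f3) / curve_integral(f3), 1, tolerance = 0.01)
  }
})

test_that("population_teff summarises organ half-lives", {
  fits <- lapply(c(40, 45.05, 50), function(te) {
    fit_kinetics(mono_samples(1, log(2) / te, c(10, 40, 80)), model_kind = "mono")
  })
  expect_equal(population_teff(fits), 45.05, tolerance = 1e-6)
  expect_equal(population_teff(fits[2]), 45.05, tolerance = 1e-6)
  expect_error(population_teff(list()), "no fits")
  tab <- data.frame(organ = c("tumor", "tumor", "kidneys"), teff_h = c(44, 46, 35))
  expect_equal(population_teff(tab, "tumor"), 45)
})

test_that("area-equivalent Teff equals terminal Teff for mono curves", {
  d <- mono_samples(2, 0.02, c(5, 25, 60))
  f_term <- fit_kinetics(d, model_kind = "mono", teff_method = "terminal")
  f_area <- fit_kinetics(d, model_kind = "mono", teff_method = "area")
  expect_equal(f_area$Teff_h, f_term$Teff_h, tolerance = 1e-6)
})
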