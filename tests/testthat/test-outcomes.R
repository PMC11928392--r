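test_that("PSA decline rate and response classification follow the definitions", {
  expect_equal(psa_decline_rate(10, 4), -0.6)
  expect_equal(psa_decline_rate(8, 8), 0)
  expect_equal(psa_decline_rate(8, 12), 0.5)
  expect_error(psa_decline_rate(0, 5), "invalid baseline")
  expect_equal(as.character(classify_response(c(-0.6, -0.5, -0.49, 0.2))),
               c("good", "good", "poor", "poor"))
})

test_that("anemia grading maps hemoglobin bands to CTCAE grades", {
  expect_equal(anemia_grade(9.0, 13.0), 2L)
  expect_equal(anemia_grade(14.0, 13.0), 0L)
  expect_equal(anemia_grade(7.5), 3L)
  expect_equal(anemia_grade(c(13.0, 12.9, 10.0, 9.9, 8.0, 7.9)),
               c(0L, 1L, 1L, 2L, 2L, 3L))
  expect_equal(anemia_grade(7.5, clinical_grade = 4L), 4L)
  expect_error(anemia_grade(0), "invalid measurement")
})

test_that("spearman correlation matches hand ranks and is rank-invariant", {
  s <- spearman_test(c(1, 2, 3, 4), c(10, 20, 30, 40))
  expect_equal(s$rho, 1)
  # hand computation: x = 1,2,3 ; y = 3,1,2 ; sum d^2 = 6 -> rho = -0.5
  expect_equal(cor(c(1, 2, 3), c(3, 1, 2), method = "spearman"), -0.5)
  set.seed(10)
  x <- rnorm(30); y <- rnorm(30)
  a <- spearman_test(x, y)
  b <- spearman_test(y, x)
  expect_equal(a$rho, b$rho)
  # strictly monotone transforms leave rho unchanged
  m <- spearman_test(exp(x), y^3 + 5 * y)
  expect_equal(m$rho, spearman_test(x, y^3 + 5 * y)$rho)
  # p agrees with the classical t-approximation in cor.test
  ct <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(a$rho, unname(ct$estimate))
  expect_error(spearman_test(rep(1, 10), rnorm(10)), "undefined correlation")
})

test_that("Fisher Z comparison reproduces the closed form and its symmetries", {
  eq <- fisher_z_compare(0.4, 50, 0.4, 50)
  expect_equal(eq$z_stat, 0)
  expect_equal(eq$p_value, 1)
  cmp <- fisher_z_compare(-0.39, 95, -0.46, 95)
  expect_equal(cmp$z_stat,
               (atanh(-0.39) - atanh(-0.46)) / sqrt(2 / 92), tolerance = 1e-12)
  expect_equal(cmp$z_stat, 0.58, tolerance = 0.005)
  expect_equal(cmp$p_value, 0.562, tolerance = 1e-3)
  # swapping the correlations negates the statistic
  swp <- fisher_z_compare(-0.46, 95, -0.39, 95)
  expect_equal(swp$z_stat, -cmp$z_stat, tolerance = 1e-12)
  expect_equal(swp$p_value, cmp$p_value, tolerance = 1e-12)
  expect_error(fisher_z_compare(1, 50, 0.2, 50), "infinite transform")
  # dependent-correlation variant: equal correlations still give Z = 0
  st <- fisher_z_compare(0.5, 80, 0.5, 80, method = "steiger", rho12 = 0.7)
  expect_equal(st$z_stat, 0)
})

test_that("normal CDF and atanh satisfy their analytic identities to 1e-10", {
  for (x in c(-3, -1, -0.2, 0, 0.4, 1.7, 3.5)) {
    expect_equal(pnorm(x) + pnorm(-x), 1, tolerance = 1e-12)
    expect_equal(pnorm(x), 0.5 * (1 + pracma::erf(x / sqrt(2))), tolerance = 1e-10)
  }
  for (r in c(-0.95, -0.5, 0, 0.3, 0.8)) {
    expect_equal(atanh(r), 0.5 * log((1 + r) / (1 - r)), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney U equals the pairwise-win count", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$U, 0)
  expect_equal(mann_whitney_u(c(1, 3), c(2, 4))$U, 1)
  g <- c(2, 5, 9)
  expect_equal(mann_whitney_u(g, g)$U, length(g)^2 / 2)
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty group")
  set.seed(12)
  for (r in 1:30) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- sample(1:10, na, replace = TRUE)  # ties allowed
    b <- sample(1:10, nb, replace = TRUE)
    expect_equal(mann_whitney_u(a, b)$U, enumerate_u(a, b))
  }
})

test_that("Cox estimates maximise the Breslow partial likelihood", {
  # 4-subject toy with interleaved covariate (finite maximiser exists)
  toy <- cox_univariate(c(1, 2, 3, 4), c(1, 1, 1, 1), c(1, 0, 1, 0))
  expect_equal(toy$beta, grid_search_beta(c(1, 2, 3, 4), c(1, 1, 1, 1), c(1, 0, 1, 0)),
               tolerance = 1e-4)
  expect_equal(toy$hr, exp(toy$beta), tolerance = 1e-12)
  set.seed(13)
  for (r in 1:25) {
    n <- sample(4:6, 1)
    tm <- sample(1:8, n, replace = TRUE)
    ev <- rbinom(n, 1, 0.8); if (sum(ev) == 0) ev[1] <- 1
    x <- round(rnorm(n), 2); if (sd(x) == 0) next
    fit <- tryCatch(cox_univariate(tm, ev, x), error = function(e) NULL)
    if (is.null(fit) || fit$flagged || abs(fit$beta) > 6) next
    expect_equal(fit$beta, grid_search_beta(tm, ev, x), tolerance = 1e-4)
  }
  expect_error(cox_univariate(1:4, rep(0, 4), rnorm(4)), "no events")
})

test_that("Kaplan-Meier reproduces the product-limit formula", {
  km <- kaplan_meier(c(2, 5, 7, 9), c(1, 1, 1, 1))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  flat <- kaplan_meier(c(3, 6, 8), c(0, 0, 0))
  expect_true(all(flat$surv == 1))
  set.seed(14)
  for (r in 1:20) {
    n <- sample(5:15, 1)
    tm <- sample(1:12, n, replace = TRUE)
    ev <- rbinom(n, 1, 0.6)
    if (sum(ev) == 0) next
    km2 <- kaplan_meier(tm, ev)
    oracle <- brute_km(tm, ev)
    got <- km2[km2$n_event > 0, c("time", "surv")]
    expect_equal(got$time, oracle$time)
    expect_equal(got$surv, oracle$surv, tolerance = 1e-12)
  }
})

test_that("the joint analysis links doses to outcomes with the expected signs", {
  sc <- small_cohort()
  rep <- run_comparison_analysis(sc$doses, sc$cohort$outcomes)
  expect_s3_class(rep, "dosimetry_outcome_report")
  # negative dose->PSA link configured: both methods' correlations negative
  expect_lt(rep$psa$by_method$MTPD$rho, 0)
  expect_lt(rep$psa$by_method$STPD$rho, 0)
  expect_false(is.null(rep$psa$comparison))
  # marrow dose increases anemia grade
  expect_gt(rep$anemia$by_method$MTPD$rho, 0)
  # single-method input: comparison skipped with warning
  w <- capture_warnings(
    rep1 <- run_comparison_analysis(sc$doses[sc$doses$method == "MTPD", ],
                                    sc$cohort$outcomes))
  expect_match(w, "single-method", all = TRUE)
  expect_null(rep1$psa$comparison)
})

test_that("shuffled outcomes break the dose-outcome correlation", {
  sc <- small_cohort()
  out <- sc$cohort$outcomes
  set.seed(15)
  # permute patient labels among patients (keeps each trajectory intact)
  ids <- unique(out$patient_id)
  relab <- setNames(sample(ids), ids)
  out$patient_id <- unname(relab[out$patient_id])
  rep <- run_comparison_analysis(sc$doses, out)
  expect_lt(abs(rep$psa$by_method$MTPD$rho), 0.45)
})
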