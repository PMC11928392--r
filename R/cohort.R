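#' Configuration for the synthetic treatment cohort
#'
#' Default values emulate a multi-cycle Lu-177-PSMA-617 cohort: ~7.2 GBq
#' per cycle over up to 6 cycles, organ-wise population effective
#' half-lives (tumor 45.05 h, bone marrow 29.86 h, kidneys 35.11 h, liver
#' 38.40 h, spleen 34.02 h), per-organ uptake scaled so the expected
#' first-cycle dose per unit activity matches typical values (kidneys 0.36,
#' liver 0.12, spleen 0.09, bone marrow 0.45, tumor 2.02 Gy/GBq), SPECT
#' sampling at ~3 h and days 1-3 with +/-2 h jitter, and 10% multiplicative
#' (lognormal) measurement noise. Outcome links: per-cycle PSA decline rate
#' is linear in cumulative true tumor dose (negative slope), hemoglobin
#' declines with cumulative marrow dose, and survival is exponential with a
#' log-hazard proportional to the log total tumor dose. Inter-patient
#' spreads (20% CV on half-lives, 50% CV on uptake) are assumptions, not
#' measured quantities.
#'
#' @param n_patients Number of patients.
#' @param n_cycles Maximum number of cycles (patients may stop after 4-6,
#'   see `dropout_prob`).
#' @param injected_gbq_mean,injected_gbq_sd Per-cycle administered activity
#'   distribution, GBq.
#' @param teff_mean_h Named vector of organ population effective
#'   half-lives, hours.
#' @param teff_cv Inter-patient coefficient of variation of the half-life.
#' @param gy_per_gbq_cycle1 Named vector of expected first-cycle dose per
#'   unit activity per organ, Gy/GBq (calibrates uptake amplitudes).
#' @param uptake_cv Inter-patient lognormal CV of organ uptake.
#' @param cycle_uptake_cv Small per-cycle lognormal jitter on uptake.
#' @param scan_times_h Nominal scan grid, hours post-injection.
#' @param scan_jitter_h Uniform jitter half-width on each scan time, hours.
#' @param noise_cv Multiplicative lognormal measurement noise CV (0 =
#'   noiseless).
#' @param lambda_fast_range Range the uptake-phase rate is drawn from
#'   (per hour); places the concentration peak at roughly 2-8 h.
#' @param psa_slope Decline-rate change per Gy cumulative tumor dose
#'   (negative links higher dose to deeper PSA decline).
#' @param psa_noise_sd Gaussian noise SD on the decline rate (truncated so
#'   the rate stays >= -1).
#' @param psa_baseline_meanlog,psa_baseline_sdlog Lognormal baseline PSA
#'   (ng/mL).
#' @param hgb_baseline_mean,hgb_baseline_sd Baseline hemoglobin, g/dL.
#' @param hgb_slope Hemoglobin change per Gy cumulative marrow dose.
#' @param hgb_noise_sd Gaussian noise SD on per-cycle hemoglobin.
#' @param hgb_lln Lower limit of normal for anemia grading, g/dL.
#' @param os_log_hr Log hazard ratio per unit log(total tumor dose in Gy).
#' @param os_median_days Baseline median overall survival, days.
#' @param censor_range_days Administrative censoring window (uniform),
#'   days.
#' @param dropout_prob Probability a patient stops after 4-6 cycles
#'   (uniform over 4:min(6, n_cycles)) instead of completing `n_cycles`.
#' @param n_phantoms Number of small random voxel phantoms to emit.
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 20,
                          n_cycles = 6,
                          injected_gbq_mean = 7.2,
                          injected_gbq_sd = 0.3,
                          teff_mean_h = c(tumor = 45.05, bone_marrow = 29.86,
                                          kidneys = 35.11, liver = 38.40,
                                          spleen = 34.02),
                          teff_cv = 0.2,
                          gy_per_gbq_cycle1 = c(kidneys = 0.36, liver = 0.12,
                                                spleen = 0.09, bone_marrow = 0.45,
                                                tumor = 2.02),
                          uptake_cv = 0.5,
                          cycle_uptake_cv = 0.1,
                          scan_times_h = c(3, 24, 48, 72),
                          scan_jitter_h = 2,
                          noise_cv = 0.1,
                          lambda_fast_range = c(0.4, 1.0),
                          psa_slope = -0.004,
                          psa_noise_sd = 0.25,
                          psa_baseline_meanlog = log(50),
                          psa_baseline_sdlog = 0.8,
                          hgb_baseline_mean = 13.5,
                          hgb_baseline_sd = 1.0,
                          hgb_slope = -0.15,
                          hgb_noise_sd = 0.5,
                          hgb_lln = 13.0,
                          os_log_hr = log(3.41),
                          os_median_days = 450,
                          censor_range_days = c(400, 1100),
                          dropout_prob = 0.5,
                          n_phantoms = 2,
                          seed = 20201) {
  cfg <- as.list(environment())
  .validate_config(cfg)
  structure(cfg, class = "cohort_config")
}

.validate_config <- function(cfg) {
  organs <- organ_levels()
  chk <- function(ok, field) if (!ok) stop(sprintf("invalid config field: %s", field), call. = FALSE)
  chk(cfg$n_patients >= 1, "n_patients")
  chk(cfg$n_cycles >= 1 && cfg$n_cycles <= 12, "n_cycles")
  chk(cfg$injected_gbq_mean > 0 && cfg$injected_gbq_sd >= 0, "injected_gbq")
  chk(all(organs %in% names(cfg$teff_mean_h)) && all(cfg$teff_mean_h > 0), "teff_mean_h")
  chk(all(organs %in% names(cfg$gy_per_gbq_cycle1)) && all(cfg$gy_per_gbq_cycle1 > 0),
      "gy_per_gbq_cycle1")
  chk(cfg$teff_cv >= 0 && cfg$uptake_cv >= 0 && cfg$noise_cv >= 0, "cv fields")
  chk(all(cfg$scan_times_h > 0), "scan_times_h")
  chk(length(cfg$lambda_fast_range) == 2 && all(cfg$lambda_fast_range > 0) &&
        diff(cfg$lambda_fast_range) >= 0, "lambda_fast_range")
  chk(cfg$psa_noise_sd >= 0 && cfg$hgb_noise_sd >= 0, "noise sd fields")
  chk(cfg$os_median_days > 0 && all(cfg$censor_range_days > 0), "survival fields")
  chk(cfg$dropout_prob >= 0 && cfg$dropout_prob <= 1, "dropout_prob")
  invisible(TRUE)
}

.lognorm_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Generate a synthetic treatment cohort
#'
#' Draws per-patient organ kinetics (bi-exponential uptake-washout truth),
#' samples the scan grid with multiplicative noise, and generates clinical
#' outcomes stochastically linked to the true cumulative doses. The
#' uptake amplitude of each organ is calibrated so that the expected
#' first-cycle MTPD per unit activity equals the configured Gy/GBq target,
#' then perturbed by the patient- and cycle-level lognormal factors.
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort` list:
#' \describe{
#'   \item{activity}{long table `patient_id`, `cycle`, `organ`, `time_h`,
#'     `conc` (MBq/g).}
#'   \item{cycles}{`patient_id`, `cycle`, `injected_gbq`, `cumulative_gbq`.}
#'   \item{outcomes}{long table `patient_id`, `cycle` (0 = baseline),
#'     `psa` (ng/mL), `hgb` (g/dL), `os_days`, `os_event`.}
#'   \item{truth}{ground-truth `patient_id`, `cycle`, `organ`, `teff_h`,
#'     `a_mbq_g`, `lambda_slow`, `lambda_fast`, `integral_mbqh_g`,
#'     `dose_gy`, `cum_dose_gy`.}
#'   \item{phantoms}{list of [voxel_phantom()] objects.}
#'   \item{config}{the configuration used.}
#' }
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config") || is.list(config))
  .validate_config(config)
  set.seed(config$seed)
  organs <- organ_levels()
  nuc <- nuclide_lu177()
  K <- dose_conversion_factor(nuc)
  lam_phys <- nuc$lambda_phys

  act <- list(); cyc <- list(); tru <- list()
  patients <- sprintf("P%02d", seq_len(config$n_patients))

  # patient-level draws
  for (p in seq_along(patients)) {
    pid <- patients[p]
    ncy <- if (stats::runif(1) < config$dropout_prob)
      sample(4:min(6, max(4, config$n_cycles)), 1) else config$n_cycles
    ncy <- min(ncy, config$n_cycles)
    inj <- pmax(stats::rnorm(ncy, config$injected_gbq_mean, config$injected_gbq_sd), 0.5)
    cyc[[pid]] <- data.frame(patient_id = pid, cycle = seq_len(ncy),
                             injected_gbq = inj, cumulative_gbq = cumsum(inj),
                             stringsAsFactors = FALSE)
    for (og in organs) {
      m_pat <- .lognorm_mult(1, config$uptake_cv)
      for (ci in seq_len(ncy)) {
        # clearance is drawn afresh each cycle (fits are per patient-cycle)
        teff <- config$teff_mean_h[[og]] *
          max(stats::rnorm(1, 1, config$teff_cv), 0.3)
        teff <- min(teff, 0.95 * nuc$physical_half_life_h)  # effective rate >= physical
        l1 <- max(log(2) / teff, lam_phys * 1.0001)
        l2 <- stats::runif(1, config$lambda_fast_range[1], config$lambda_fast_range[2])
        # amplitude per GBq calibrated so E[dose/GBq] hits the organ target
        u <- config$gy_per_gbq_cycle1[[og]] / (K * (1 / l1 - 1 / l2))
        A <- u * m_pat * .lognorm_mult(1, config$cycle_uptake_cv) * inj[ci]
        times <- config$scan_times_h +
          stats::runif(length(config$scan_times_h), -config$scan_jitter_h,
                       config$scan_jitter_h)
        times <- pmax(times, 0.5)
        conc_true <- A * (exp(-l1 * times) - exp(-l2 * times))
        conc <- conc_true * .lognorm_mult(length(times), config$noise_cv)
        act[[length(act) + 1L]] <- data.frame(
          patient_id = pid, cycle = ci, organ = og, time_h = times,
          conc = conc, stringsAsFactors = FALSE)
        integ <- A * (1 / l1 - 1 / l2)
        tru[[length(tru) + 1L]] <- data.frame(
          patient_id = pid, cycle = ci, organ = og, teff_h = teff,
          a_mbq_g = A, lambda_slow = l1, lambda_fast = l2,
          integral_mbqh_g = integ, dose_gy = integ * K,
          stringsAsFactors = FALSE)
      }
    }
  }
  activity <- do.call(rbind, c(act, list(make.row.names = FALSE)))
  cycles <- do.call(rbind, c(cyc, list(make.row.names = FALSE)))
  truth <- do.call(rbind, c(tru, list(make.row.names = FALSE)))
  truth <- truth[order(truth$patient_id, truth$organ, truth$cycle), ]
  truth$cum_dose_gy <- stats::ave(truth$dose_gy,
                                  interaction(truth$patient_id, truth$organ, drop = TRUE),
                                  FUN = cumsum)
  rownames(truth) <- NULL

  outcomes <- .generate_outcomes(patients, cycles, truth, config)
  phantoms <- replicate(config$n_phantoms, .random_phantom(), simplify = FALSE)

  structure(list(activity = activity, cycles = cycles, outcomes = outcomes,
                 truth = truth, phantoms = phantoms, config = config),
            class = "synthetic_cohort")
}

.generate_outcomes <- function(patients, cycles, truth, config) {
  # total true tumor dose drives the survival hazard; cumulative doses
  # drive the per-cycle PSA and hemoglobin trajectories
  tum <- truth[truth$organ == "tumor", ]
  mar <- truth[truth$organ == "bone_marrow", ]
  total_tumor <- tapply(tum$dose_gy, tum$patient_id, sum)[patients]
  logd <- log(pmax(total_tumor, 1e-6))
  h0 <- log(2) / config$os_median_days
  haz <- h0 * exp(config$os_log_hr * (logd - mean(logd)))
  t_death <- stats::rexp(length(patients), rate = haz)
  t_cens <- stats::runif(length(patients), config$censor_range_days[1],
                         config$censor_range_days[2])
  os_days <- pmax(round(pmin(t_death, t_cens)), 1)
  os_event <- as.integer(t_death <= t_cens)

  psa0 <- stats::rlnorm(length(patients), config$psa_baseline_meanlog,
                        config$psa_baseline_sdlog)
  hgb0 <- stats::rnorm(length(patients), config$hgb_baseline_mean,
                       config$hgb_baseline_sd)
  rows <- list()
  for (p in seq_along(patients)) {
    pid <- patients[p]
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = pid, cycle = 0L, psa = psa0[p], hgb = hgb0[p],
      os_days = os_days[p], os_event = os_event[p], stringsAsFactors = FALSE)
    pcy <- cycles[cycles$patient_id == pid, ]
    for (ci in pcy$cycle) {
      cumt <- tum$cum_dose_gy[tum$patient_id == pid & tum$cycle == ci]
      cumm <- mar$cum_dose_gy[mar$patient_id == pid & mar$cycle == ci]
      rate <- config$psa_slope * cumt + stats::rnorm(1, 0, config$psa_noise_sd)
      rate <- max(rate, -1)
      hgb <- hgb0[p] + config$hgb_slope * cumm + stats::rnorm(1, 0, config$hgb_noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, cycle = ci,
        psa = max(psa0[p] * (1 + rate), 0.01),
        hgb = max(hgb, 4),
        os_days = os_days[p], os_event = os_event[p], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

.random_phantom <- function(shape = c(4, 8, 8)) {
  n <- prod(shape)
  bone <- array(stats::rbinom(n, 1, 0.4), dim = shape)
  suv <- array(stats::rgamma(n, shape = 2, scale = 1.5), dim = shape)
  voxel_phantom(bone, suv, voxel_volume_ml = 0.5)
}

#' Generate a null cohort (no dose-outcome links)
#'
#' Identical to [generate_cohort()] but with the PSA, hemoglobin and
#' survival link coefficients set to zero; used for type-I-error
#' calibration.
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort` (see [generate_cohort()]).
#' @export
generate_null_cohort <- function(config = cohort_config()) {
  config$psa_slope <- 0
  config$hgb_slope <- 0
  config$os_log_hr <- 0
  generate_cohort(config)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d activity samples, %d cycles, seed %d\n",
              length(unique(x$cycles$patient_id)), nrow(x$activity),
              nrow(x$cycles), x$config$seed))
  invisible(x)
}
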