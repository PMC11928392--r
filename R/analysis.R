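#' Dose-outcome comparison analysis
#'
#' The full statistical battery linking absorbed doses to clinical
#' endpoints, run for both dosimetry methods and compared:
#' \itemize{
#'   \item cycle-level cumulative tumor dose vs that cycle's PSA decline
#'     rate — Spearman rho for MTPD and STPD, plus the Fisher Z comparison
#'     of the two correlations;
#'   \item cycle-level cumulative bone-marrow dose vs the anemia grade from
#'     that cycle's hemoglobin — the same Spearman pair and Fisher
#'     comparison;
#'   \item Mann-Whitney U test of tumor doses split by biochemical
#'     response (PSA decline >= 50% vs < 50%);
#'   \item univariate Cox regression of overall survival on the per-patient
#'     total tumor dose (raw and log-transformed), restricted to patients
#'     with more than `min_cycles_for_cox` cycles;
#'   \item Kaplan-Meier curves overall and split at the median MTPD total.
#' }
#'
#' @param doses Dose table from [compute_doses()] (needs `cumulative_gy`).
#' @param outcomes Long outcome table with columns `patient_id`, `cycle`
#'   (0 = baseline), `psa`, `hgb`, `os_days`, `os_event`.
#' @param hgb_lln Lower limit of normal for anemia grading, g/dL.
#' @param min_cycles_for_cox Patients with strictly more cycles than this
#'   enter the Cox models (default 4, i.e. >= 5 cycles).
#' @param fisher_method Passed to [fisher_z_compare()].
#' @return An object of class `dosimetry_outcome_report`: list with
#'   `psa` (per-method Spearman + `comparison`), `anemia` (same),
#'   `u_test` (per method), `cox` (list of [cox_result] by label),
#'   `km` (overall and by median split), `n_obs`, and `joined` (the
#'   analysis table).
#' @export
run_comparison_analysis <- function(doses, outcomes, hgb_lln = 13.0,
                                    min_cycles_for_cox = 4,
                                    fisher_method = "independent") {
  stopifnot(all(c("patient_id", "cycle", "organ", "method", "cumulative_gy") %in% names(doses)),
            all(c("patient_id", "cycle", "psa", "hgb", "os_days", "os_event") %in% names(outcomes)))
  base <- outcomes[outcomes$cycle == 0, c("patient_id", "psa", "hgb")]
  names(base) <- c("patient_id", "psa_baseline", "hgb_baseline")
  fup <- outcomes[outcomes$cycle > 0, , drop = FALSE]
  fup <- merge(fup, base, by = "patient_id")
  missing_base <- setdiff(unique(outcomes$patient_id[outcomes$cycle > 0]),
                          base$patient_id)
  if (length(missing_base) > 0)
    warning("patients without baseline row dropped: ",
            paste(missing_base, collapse = ", "))
  fup$decline_rate <- psa_decline_rate(fup$psa_baseline, fup$psa)
  fup$anemia_grade <- anemia_grade(fup$hgb, hgb_lln)
  fup$response <- classify_response(fup$decline_rate)

  methods <- intersect(c("MTPD", "STPD"), unique(doses$method))
  join_organ <- function(og) {
    d <- doses[doses$organ == og, c("patient_id", "cycle", "method", "cumulative_gy")]
    merge(fup, d, by = c("patient_id", "cycle"))
  }
  tum <- join_organ("tumor")
  mar <- join_organ("bone_marrow")

  corr_block <- function(dat, yvar) {
    res <- lapply(methods, function(m) {
      sub <- dat[dat$method == m, ]
      spearman_test(sub$cumulative_gy, sub[[yvar]])
    })
    names(res) <- methods
    cmp <- if (length(methods) == 2) {
      fisher_z_compare(res$MTPD$rho, res$MTPD$n, res$STPD$rho, res$STPD$n,
                       method = fisher_method)
    } else {
      warning("single-method input: correlation comparison skipped")
      NULL
    }
    list(by_method = res, comparison = cmp)
  }
  psa_block <- corr_block(tum, "decline_rate")
  anemia_block <- corr_block(mar, "anemia_grade")

  u_test <- lapply(methods, function(m) {
    sub <- tum[tum$method == m, ]
    g <- sub$cumulative_gy[sub$response == "good"]
    p <- sub$cumulative_gy[sub$response == "poor"]
    if (length(g) == 0 || length(p) == 0) return(NULL)
    mann_whitney_u(g, p)
  })
  names(u_test) <- methods

  # per-patient totals for survival analyses
  tot <- total_doses(doses[doses$organ == "tumor", ])
  surv_tab <- merge(tot, unique(outcomes[, c("patient_id", "os_days", "os_event")]),
                    by = "patient_id")
  surv_tab <- surv_tab[surv_tab$n_cycles > min_cycles_for_cox, , drop = FALSE]
  cox <- list()
  for (m in methods) {
    st <- surv_tab[surv_tab$method == m, ]
    if (nrow(st) >= 2 && sum(st$os_event) >= 1 && stats::sd(st$total_gy) > 0) {
      lbl <- paste0(m, "_total")
      cox[[lbl]] <- tryCatch(
        cox_univariate(st$os_days, st$os_event, st$total_gy, lbl),
        error = function(e) NULL)
      pos <- st[st$total_gy > 0, ]
      if (nrow(pos) < nrow(st)) warning("zero total doses excluded from log Cox")
      lbl2 <- paste0("log_", m, "_total")
      cox[[lbl2]] <- tryCatch(
        cox_univariate(pos$os_days, pos$os_event, log(pos$total_gy), lbl2),
        error = function(e) NULL)
    }
  }

  km <- list()
  pt <- unique(merge(unique(outcomes[, c("patient_id", "os_days", "os_event")]),
                     tot[tot$method == methods[1], c("patient_id", "total_gy")],
                     by = "patient_id"))
  if (nrow(pt) >= 2) {
    km$overall <- kaplan_meier(pt$os_days, pt$os_event)
    hi <- pt$total_gy > stats::median(pt$total_gy)
    if (any(hi) && any(!hi)) {
      km$high_dose <- kaplan_meier(pt$os_days[hi], pt$os_event[hi])
      km$low_dose <- kaplan_meier(pt$os_days[!hi], pt$os_event[!hi])
    }
  }

  structure(list(psa = psa_block, anemia = anemia_block, u_test = u_test,
                 cox = cox, km = km,
                 n_obs = c(tumor = nrow(tum) / max(length(methods), 1),
                           marrow = nrow(mar) / max(length(methods), 1)),
                 joined = list(tumor = tum, marrow = mar)),
            class = "dosimetry_outcome_report")
}

#' @export
print.dosimetry_outcome_report <- function(x, ...) {
  cat("<dosimetry_outcome_report>\n")
  fmt_corr <- function(blk, what) {
    for (m in names(blk$by_method)) {
      r <- blk$by_method[[m]]
      cat(sprintf("  %s ~ %s: rho = %.3f, p = %.3g (n = %d)\n",
                  what, m, r$rho, r$p_value, r$n))
    }
    if (!is.null(blk$comparison))
      cat(sprintf("    Fisher Z = %.2f, p = %.2f\n",
                  blk$comparison$z_stat, blk$comparison$p_value))
  }
  fmt_corr(x$psa, "PSA decline")
  fmt_corr(x$anemia, "anemia grade")
  for (m in names(x$u_test)) {
    u <- x$u_test[[m]]
    if (!is.null(u))
      cat(sprintf("  U-test (%s by response): U = %.1f, p = %.3g\n", m, u$U, u$p_value))
  }
  for (nm in names(x$cox)) {
    cr <- x$cox[[nm]]
    if (!is.null(cr))
      cat(sprintf("  Cox %s: HR = %.3f, p = %.3g\n", nm, cr$hr, cr$p_value))
  }
  invisible(x)
}
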