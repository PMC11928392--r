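#' PSA decline rate
#'
#' Fractional change of serum PSA relative to baseline,
#' `(psa_t - psa_baseline) / psa_baseline`; negative values are declines,
#' -1 is complete biochemical response.
#'
#' @param psa_baseline Baseline PSA, ng/mL (> 0).
#' @param psa_t PSA at the evaluation time, ng/mL (>= 0).
#' @return Decline rate (fraction; vectorized).
#' @examples
#' psa_decline_rate(10, 4)  # -0.6
#' @export
psa_decline_rate <- function(psa_baseline, psa_t) {
  if (any(!is.finite(psa_baseline)) || any(psa_baseline <= 0))
    stop("invalid baseline", call. = FALSE)
  if (any(psa_t < 0)) stop("negative PSA", call. = FALSE)
  (psa_t - psa_baseline) / psa_baseline
}

#' Biochemical response classification
#'
#' A good response is a confirmed PSA decrease of at least 50% from
#' baseline, i.e. decline rate <= -0.5 (the boundary counts as good).
#'
#' @param decline_rate Decline rate(s) from [psa_decline_rate()].
#' @return Factor with levels `good`, `poor`.
#' @export
classify_response <- function(decline_rate) {
  if (any(!is.finite(decline_rate))) stop("non-finite decline rate", call. = FALSE)
  factor(ifelse(decline_rate <= -0.5, "good", "poor"), levels = c("good", "poor"))
}

#' CTCAE v5.0 anemia grade from hemoglobin
#'
#' Grades anemia from a hemoglobin value against the lower limit of normal
#' (LLN): grade 0 for Hgb >= LLN; grade 1 for 10.0 <= Hgb < LLN; grade 2
#' for 8.0 <= Hgb < 10.0; grade 3 for Hgb < 8.0 g/dL. Grades 4-5 denote
#' life-threatening consequences/death and cannot be derived from
#' hemoglobin alone; supply `clinical_grade` to override upward.
#'
#' @param hgb_g_dl Hemoglobin, g/dL (> 0; vectorized).
#' @param lln_g_dl Lower limit of normal, g/dL. Default 13.0 (adult men).
#' @param clinical_grade Optional integer vector of clinically assigned
#'   grades (e.g. 4-5); the returned grade is the elementwise maximum.
#' @return Integer grade(s) 0-5.
#' @examples
#' anemia_grade(c(14, 12, 9, 7.5))  # 0 1 2 3
#' @export
anemia_grade <- function(hgb_g_dl, lln_g_dl = 13.0, clinical_grade = NULL) {
  if (any(!is.finite(hgb_g_dl)) || any(hgb_g_dl <= 0))
    stop("invalid measurement", call. = FALSE)
  g <- ifelse(hgb_g_dl >= lln_g_dl, 0L,
              ifelse(hgb_g_dl >= 10.0, 1L,
                     ifelse(hgb_g_dl >= 8.0, 2L, 3L)))
  if (!is.null(clinical_grade)) g <- pmax(g, as.integer(clinical_grade))
  as.integer(g)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation with average ranks for ties; the two-sided p-value uses
#' the t approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on n - 2
#' degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, n >= 4.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("unpaired input", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation", call. = FALSE)
  rho <- stats::cor(x, y, method = "spearman")
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Fisher Z-transformed comparison of two correlations
#'
#' Tests whether two correlation coefficients differ. The default
#' independent-samples form transforms each coefficient with
#' \eqn{z = \mathrm{atanh}(\rho)} and compares
#' \deqn{Z = \frac{z_1 - z_2}{\sqrt{1/(n_1-3) + 1/(n_2-3)}}}
#' against the standard normal (two-sided). When the two correlations share
#' an outcome variable measured on the same observations (as when two dose
#' methods are each correlated with the same clinical endpoint),
#' `method = "steiger"` applies Steiger's dependent-correlation modification,
#' which requires the correlation `rho12` between the two predictor
#' variables and a single `n`.
#'
#' @param rho1,rho2 Correlation coefficients, |rho| < 1.
#' @param n1,n2 Sample sizes (>= 4).
#' @param method `"independent"` (default) or `"steiger"`.
#' @param rho12 Correlation between the two correlated predictors
#'   (Steiger only).
#' @return An object of class `correlation_comparison`: list with `rho1`,
#'   `rho2`, `n1`, `n2`, `z_stat`, `p_value`, `method`.
#' @examples
#' fisher_z_compare(-0.39, 95, -0.46, 95)
#' @export
fisher_z_compare <- function(rho1, n1, rho2, n2, method = c("independent", "steiger"),
                             rho12 = NULL) {
  method <- match.arg(method)
  for (r in c(rho1, rho2)) {
    if (!is.finite(r) || abs(r) >= 1) stop("infinite transform", call. = FALSE)
  }
  if (n1 < 4L || n2 < 4L) stop("need n >= 4 in each sample", call. = FALSE)
  z1 <- atanh(rho1); z2 <- atanh(rho2)
  if (method == "independent") {
    zs <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  } else {
    if (is.null(rho12) || !is.finite(rho12) || abs(rho12) >= 1)
      stop("steiger method needs rho12 with |rho12| < 1", call. = FALSE)
    if (n1 != n2) stop("steiger method assumes one sample (n1 == n2)", call. = FALSE)
    n <- n1
    rm2 <- (rho1^2 + rho2^2) / 2
    f <- min((1 - rho12) / (2 * (1 - rm2)), 1)
    h <- (1 - f * rm2) / (1 - rm2)
    zs <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - rho12) * h))
  }
  p <- 2 * (1 - stats::pnorm(abs(zs)))
  structure(list(rho1 = rho1, rho2 = rho2, n1 = n1, n2 = n2,
                 z_stat = zs, p_value = p, method = method),
            class = "correlation_comparison")
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat(sprintf("<correlation_comparison> rho1 = %.3f (n=%d) vs rho2 = %.3f (n=%d): Z = %.2f, p = %.3f [%s]\n",
              x$rho1, x$n1, x$rho2, x$n2, x$z_stat, x$p_value, x$method))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two groups. The U statistic counts, over all
#' cross-group pairs, the wins of group A (ties count 1/2). The p-value
#' comes from [stats::wilcox.test()] (exact for small tie-free samples,
#' normal approximation with continuity and tie correction otherwise).
#'
#' @param group_a,group_b Nonempty numeric vectors.
#' @return List with `U` (for `group_a`), `p_value`, `n_a`, `n_b`.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("empty group", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       n_a = length(group_a), n_b = length(group_b))
}

#' Univariate Cox proportional-hazards regression
#'
#' Maximum partial-likelihood fit of a single covariate with Breslow tie
#' handling; the Wald test provides the p-value. Monotone likelihood
#' (perfect separation) is reported via the `flagged` field.
#'
#' @param times Survival/censoring times (> 0).
#' @param events Event indicators (1 = death observed, 0 = censored).
#' @param covariate Numeric covariate, same length.
#' @param label Covariate label carried into the result.
#' @return An object of class `cox_result`: list with `beta`, `hr`, `se`,
#'   `p_value`, `n`, `n_event`, `covariate_label`, `flagged`.
#' @export
cox_univariate <- function(times, events, covariate, label = "dose") {
  n <- length(times)
  stopifnot(length(events) == n, length(covariate) == n)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (sum(events) < 1) stop("no events", call. = FALSE)
  if (stats::sd(covariate) == 0) stop("constant covariate", call. = FALSE)
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ covariate,
                    ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite", conditionMessage(w)))
        flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  beta <- unname(stats::coef(fit))
  structure(list(beta = beta, hr = exp(beta),
                 se = unname(sqrt(stats::vcov(fit)[1, 1])),
                 p_value = unname(sm$coefficients[1, "Pr(>|z|)"]),
                 n = n, n_event = sum(events),
                 covariate_label = label, flagged = flagged),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> %s: HR = %.3f (beta = %.3f, se = %.3f), p = %.4f, %d/%d events%s\n",
              x$covariate_label, x$hr, x$beta, x$se, x$p_value, x$n_event, x$n,
              if (x$flagged) " [monotone likelihood flagged]" else ""))
  invisible(x)
}

#' Kaplan-Meier product-limit estimate
#'
#' Right-censoring-aware survival curve via [survival::survfit()].
#'
#' @param times Survival/censoring times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return Data frame `time`, `n_risk`, `n_event`, `surv`; the underlying
#'   `survfit` object is attached as the `survfit` attribute.
#' @export
kaplan_meier <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) >= 1L)
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, surv = sf$surv)
  attr(out, "survfit") <- sf
  out
}
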