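#' Fit an organ time-activity curve
#'
#' Least-squares fit of the activity-concentration curve of one organ in one
#' therapy cycle. Two model families are supported:
#' \describe{
#'   \item{mono}{\eqn{c(t) = A e^{-\lambda t}} — pure washout.}
#'   \item{biexp}{\eqn{c(t) = A_1 e^{-\lambda_1 t} - A_2 e^{-\lambda_2 t}}
#'     with \eqn{\lambda_2 > \lambda_1} — an uptake phase followed by
#'     washout, the usual shape of post-injection organ kinetics.}
#' }
#' Concentrations are taken as physically decaying (what a quantitative
#' SPECT measures), so every fitted rate is bounded below by the nuclide's
#' physical decay constant. The effective half-life reported is that of the
#' terminal (slow) phase, \eqn{T_{eff} = \ln 2 / \lambda_1}, the quantity
#' that governs late washout and hence the single-time-point scan window.
#'
#' A requested bi-exponential fit falls back to mono-exponential when it is
#' degenerate: the optimizer fails, the two rates collapse
#' (\eqn{\lambda_2 \le 1.01 \lambda_1}), an amplitude is inadmissible, or
#' the residual sum of squares improves on the mono fit by less than 1%.
#' The fallback mono fit uses the samples from the observed concentration
#' peak onward, because a mono-exponential cannot represent the uptake limb.
#'
#' @param samples Data frame with columns `time_h` (hours post-injection,
#'   > 0) and `conc` (MBq per g, >= 0), one organ/cycle. Rows need not be
#'   sorted; duplicate times are an error.
#' @param nuclide A [nuclide_spec()]; defaults to Lu-177.
#' @param model_kind `"biexp"` (default) or `"mono"`.
#' @param teff_method `"terminal"` (default; `Teff = ln2 / slow rate`) or
#'   `"area"` (area-equivalent: `Teff = ln2 * integral / c_max`, the
#'   half-life of the mono-exponential with the same peak and area).
#'
#' @return An object of class `kinetic_fit`: list with `model_kind`,
#'   `amplitudes` (MBq/g), `rates` (per hour, slow first), `Teff_h`, `rss`,
#'   `n_points`, `teff_method`, and the `nuclide` used.
#' @examples
#' t <- c(4, 24, 48, 72)
#' d <- data.frame(time_h = t, conc = 5 * exp(-log(2) / 45.05 * t))
#' fit <- fit_kinetics(d, model_kind = "mono")
#' fit$Teff_h
#' @export
fit_kinetics <- function(samples, nuclide = nuclide_lu177(),
                         model_kind = c("biexp", "mono"),
                         teff_method = c("terminal", "area")) {
  model_kind <- match.arg(model_kind)
  teff_method <- match.arg(teff_method)
  stopifnot(is.data.frame(samples), all(c("time_h", "conc") %in% names(samples)))
  t <- as.numeric(samples$time_h)
  y <- as.numeric(samples$conc)
  if (any(!is.finite(t)) || any(t <= 0)) stop("sample times must be positive and finite", call. = FALSE)
  if (any(!is.finite(y)) || any(y < 0)) stop("concentrations must be nonnegative and finite", call. = FALSE)
  if (anyDuplicated(t)) stop("duplicate time points", call. = FALSE)
  o <- order(t); t <- t[o]; y <- y[o]
  n <- length(t)
  if (all(y == 0)) stop("empty curve", call. = FALSE)
  n_min <- if (model_kind == "mono") 2L else 3L
  if (n < n_min) stop("insufficient time points", call. = FALSE)

  lam_min <- nuclide$lambda_phys
  lam_max <- 10

  if (model_kind == "mono") {
    fit <- .fit_mono(t, y, lam_min, lam_max)
  } else {
    mono_fb <- .fit_mono_postpeak(t, y, lam_min, lam_max)
    fit <- tryCatch(.fit_biexp(t, y, lam_min, lam_max), error = function(e) NULL)
    degenerate <- is.null(fit) ||
      fit$rates[2] <= 1.01 * fit$rates[1] ||
      any(fit$amplitudes <= 0) ||
      fit$amplitudes[1] / fit$rates[1] - fit$amplitudes[2] / fit$rates[2] <= 0 ||
      (is.finite(mono_fb$rss) && fit$rss > 0.99 * mono_fb$rss && mono_fb$rss > 0) ||
      (mono_fb$rss == 0 && fit$rss > 1e-12 * sum(y^2))
    if (degenerate) fit <- mono_fb
  }

  Teff <- if (teff_method == "terminal") {
    log(2) / fit$rates[1]
  } else {
    integ <- sum(c(1, -1)[seq_along(fit$amplitudes)] * fit$amplitudes / fit$rates)
    cmax <- .curve_peak(fit)
    log(2) * integ / cmax
  }

  structure(
    list(model_kind = fit$model_kind,
         amplitudes = fit$amplitudes,
         rates = fit$rates,
         Teff_h = Teff,
         rss = fit$rss,
         n_points = n,
         teff_method = teff_method,
         nuclide = nuclide),
    class = "kinetic_fit"
  )
}

# mono fit on all points; seeded by log-linear regression on positive concs
.fit_mono <- function(t, y, lam_min, lam_max) {
  pos <- y > 0
  if (sum(pos) >= 2) {
    cf <- stats::lm.fit(cbind(1, t[pos]), log(y[pos]))$coefficients
    lam0 <- unname(min(max(-cf[2], lam_min), lam_max))
    A0 <- unname(exp(cf[1]))
  } else {
    lam0 <- max(log(2) / max(t), lam_min)
    A0 <- max(y)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-lam * t),
                      start = list(A = A0, lam = lam0),
                      lower = c(0, lam_min), upper = c(Inf, lam_max),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # bounded log-linear solution as last resort
    list(model_kind = "mono", amplitudes = A0, rates = lam0,
         rss = sum((y - A0 * exp(-lam0 * t))^2))
  } else {
    p <- stats::coef(fit)
    list(model_kind = "mono", amplitudes = unname(p["A"]), rates = unname(p["lam"]),
         rss = sum(stats::resid(fit)^2))
  }
}

# mono fit restricted to the washout limb (peak onward); rss reported on
# the restricted points only, for the degeneracy comparison
.fit_mono_postpeak <- function(t, y, lam_min, lam_max) {
  i0 <- which.max(y)
  if (length(t) - i0 + 1L < 2L) i0 <- max(1L, length(t) - 1L)
  idx <- seq(i0, length(t))
  .fit_mono(t[idx], y[idx], lam_min, lam_max)
}

# With n <= 4 samples the 4-parameter model would interpolate measurement
# noise exactly (zero residual df), which badly distorts the terminal
# slope; the fit is then constrained to A2 = A1 (c(0) = 0, the physical
# boundary condition at injection), leaving at least one residual df.
.fit_biexp <- function(t, y, lam_min, lam_max) {
  constrained <- length(t) <= 4L
  # seed slow rate from the last two positive points
  pos <- which(y > 0)
  tail2 <- utils::tail(pos, 2)
  lam1_0 <- if (length(tail2) == 2 && diff(t[tail2]) > 0 && y[tail2[1]] > y[tail2[2]]) {
    log(y[tail2[1]] / y[tail2[2]]) / diff(t[tail2])
  } else {
    log(2) / max(t)
  }
  lam1_0 <- unname(min(max(lam1_0, lam_min * 1.001), lam_max / 20))
  A1_0 <- unname(max(y[tail2[length(tail2)]] * exp(lam1_0 * t[tail2[length(tail2)]]), max(y)))
  # multistart over fast-rate seeds: 5x slow, and the inverse of the first
  # scan time (uptake roughly complete by the first scan)
  lam2_seeds <- unique(pmin(pmax(c(5 * lam1_0, 1 / min(t), 0.3, 0.8), lam_min * 1.1), lam_max))
  best <- NULL
  for (lam2_0 in lam2_seeds) {
    fit <- tryCatch({
      if (constrained) {
        minpack.lm::nlsLM(
          y ~ A1 * (exp(-l1 * t) - exp(-l2 * t)),
          start = list(A1 = A1_0, l1 = lam1_0, l2 = lam2_0),
          lower = c(0, lam_min, lam_min), upper = c(Inf, lam_max, lam_max),
          control = minpack.lm::nls.lm.control(maxiter = 500))
      } else {
        minpack.lm::nlsLM(
          y ~ A1 * exp(-l1 * t) - A2 * exp(-l2 * t),
          start = list(A1 = A1_0, A2 = A1_0, l1 = lam1_0, l2 = lam2_0),
          lower = c(0, 0, lam_min, lam_min), upper = c(Inf, Inf, lam_max, lam_max),
          control = minpack.lm::nls.lm.control(maxiter = 500))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("biexp fit failed", call. = FALSE)
  p <- stats::coef(best$fit)
  l <- unname(p[c("l1", "l2")])
  A <- if (constrained) rep(unname(p["A1"]), 2) else unname(p[c("A1", "A2")])
  if (l[1] > l[2]) { l <- rev(l); A <- rev(A) }  # slow phase first
  list(model_kind = "biexp", amplitudes = A, rates = l, rss = best$rss)
}

.curve_peak <- function(fit) {
  if (fit$model_kind == "mono") return(fit$amplitudes[1])
  A <- fit$amplitudes; l <- fit$rates
  tpk <- log((A[2] * l[2]) / (A[1] * l[1])) / (l[2] - l[1])
  tpk <- max(tpk, 0)
  A[1] * exp(-l[1] * tpk) - A[2] * exp(-l[2] * tpk)
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> %s, Teff = %.2f h (%s), %d points, rss = %.3g\n",
              x$model_kind, x$Teff_h, x$teff_method, x$n_points, x$rss))
  cat("  amplitudes (MBq/g):", paste(signif(x$amplitudes, 5), collapse = ", "), "\n")
  cat("  rates (/h):       ", paste(signif(x$rates, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a fitted curve
#'
#' @param fit A `kinetic_fit`.
#' @param time_h Times in hours.
#' @return Concentrations (MBq/g) at `time_h`.
#' @export
predict_conc <- function(fit, time_h) {
  stopifnot(inherits(fit, "kinetic_fit"))
  if (fit$model_kind == "mono") {
    fit$amplitudes[1] * exp(-fit$rates[1] * time_h)
  } else {
    fit$amplitudes[1] * exp(-fit$rates[1] * time_h) -
      fit$amplitudes[2] * exp(-fit$rates[2] * time_h)
  }
}

#' Closed-form time integral of a fitted curve
#'
#' The time-integrated activity concentration ("cumulated concentration")
#' \eqn{\int_0^\infty c(t)\,dt = \sum_i \pm A_i/\lambda_i}, in MBq h per g.
#' This is the quantity the multi-time-point dose is proportional to.
#'
#' @param fit A `kinetic_fit`.
#' @return Integral in MBq h / g (strictly positive).
#' @examples
#' f <- structure(list(model_kind = "mono", amplitudes = 2, rates = 0.1),
#'                class = "kinetic_fit")
#' curve_integral(f)  # 20
#' @export
curve_integral <- function(fit) {
  stopifnot(inherits(fit, "kinetic_fit"))
  if (any(!is.finite(fit$rates)) || any(fit$rates <= 0))
    stop("non-integrable curve", call. = FALSE)
  signs <- if (fit$model_kind == "mono") 1 else c(1, -1)
  val <- sum(signs * fit$amplitudes / fit$rates)
  if (!is.finite(val) || val < 0) stop("non-integrable curve", call. = FALSE)
  val
}

#' Piecewise numeric integral of observed samples
#'
#' Numerical cross-check of [curve_integral()]. Segments between
#' consecutive samples are integrated with the exponential-trapezoid rule
#' (log-linear interpolation, exact for exponential washout between two
#' positive values), falling back to the linear trapezoid when a segment
#' touches zero; the segment from t = 0 to the first sample is closed
#' using the fitted model's value at t = 0, and the analytic tail beyond
#' the last sample is `c(t_last) / lambda_slow` with the fitted terminal
#' rate.
#'
#' @param samples Data frame with `time_h`, `conc` (sorted or sortable,
#'   nonempty).
#' @param fit The `kinetic_fit` for the same curve (supplies the t = 0
#'   extrapolation and the terminal rate).
#' @return Integral in MBq h / g.
#' @export
numeric_integral <- function(samples, fit) {
  stopifnot(is.data.frame(samples), inherits(fit, "kinetic_fit"))
  if (nrow(samples) < 1L) stop("empty sample list", call. = FALSE)
  t <- as.numeric(samples$time_h); y <- as.numeric(samples$conc)
  if (is.unsorted(t, strictly = TRUE)) {
    if (anyDuplicated(t)) stop("unsorted samples", call. = FALSE)
    o <- order(t); t <- t[o]; y <- y[o]
  }
  if (nrow(samples) < 2L) stop("need at least 2 samples", call. = FALSE)
  c0 <- max(predict_conc(fit, 0), 0)
  tt <- c(0, t); yy <- c(c0, y)
  seg <- function(t1, t2, y1, y2) {
    if (y1 > 0 && y2 > 0 && y1 != y2) {
      (y1 - y2) * (t2 - t1) / log(y1 / y2)   # exponential trapezoid
    } else {
      (t2 - t1) * (y1 + y2) / 2
    }
  }
  trap <- sum(vapply(seq_len(length(tt) - 1L), function(i)
    seg(tt[i], tt[i + 1L], yy[i], yy[i + 1L]), numeric(1)))
  lam_slow <- fit$rates[1]
  if (lam_slow <= 0) stop("non-integrable curve", call. = FALSE)
  trap + y[length(y)] / lam_slow
}

#' Population effective half-life for an organ
#'
#' Summarises per-patient/per-cycle fitted effective half-lives into one
#' organ-wise population value (median by default), the quantity used to
#' define the single-time-point scan-eligibility window.
#'
#' @param fits A list of `kinetic_fit` objects, or a data.frame of fit
#'   results (as produced by [fit_cohort_kinetics()]) with columns `organ`
#'   and `teff_h`.
#' @param organ Organ label to subset on when `fits` is a data.frame with
#'   several organs; ignored for a plain list.
#' @param summary `"median"` (default) or `"mean"`.
#' @return Population effective half-life in hours.
#' @export
population_teff <- function(fits, organ = NULL, summary = c("median", "mean")) {
  summary <- match.arg(summary)
  if (is.data.frame(fits)) {
    stopifnot("teff_h" %in% names(fits))
    if (!is.null(organ)) fits <- fits[fits$organ == organ, , drop = FALSE]
    vals <- fits$teff_h
  } else {
    stopifnot(is.list(fits))
    vals <- vapply(fits, function(f) {
      stopifnot(inherits(f, "kinetic_fit")); f$Teff_h
    }, numeric(1))
  }
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) stop("no fits", call. = FALSE)
  if (summary == "median") stats::median(vals) else mean(vals)
}

#' Fit every organ/cycle curve in a cohort activity table
#'
#' Applies [fit_kinetics()] per (patient, cycle, organ) group of a long
#' activity table, the per-patient-per-cycle convention.
#'
#' @param activity Data frame with columns `patient_id`, `cycle`, `organ`,
#'   `time_h`, `conc`.
#' @param nuclide A [nuclide_spec()].
#' @param model_kind Passed to [fit_kinetics()].
#' @param min_points Groups with fewer samples are skipped (with a count
#'   reported in the `skipped` attribute).
#' @return Data frame with one row per fitted curve: `patient_id`, `cycle`,
#'   `organ`, `model_kind`, `a1`, `a2`, `lambda1`, `lambda2`, `teff_h`,
#'   `integral_mbqh_g`, `rss`, `n_points`. The full `kinetic_fit` objects
#'   are attached as the `fits` attribute (named `patient/cycle/organ`).
#' @export
fit_cohort_kinetics <- function(activity, nuclide = nuclide_lu177(),
                                model_kind = "biexp", min_points = 3L) {
  stopifnot(all(c("patient_id", "cycle", "organ", "time_h", "conc") %in% names(activity)))
  key <- interaction(activity$patient_id, activity$cycle, activity$organ, drop = TRUE)
  groups <- split(activity, key)
  rows <- list(); fits <- list(); skipped <- 0L
  for (g in groups) {
    if (nrow(g) < min_points || all(g$conc == 0)) { skipped <- skipped + 1L; next }
    f <- tryCatch(fit_kinetics(g[, c("time_h", "conc")], nuclide, model_kind),
                  error = function(e) NULL)
    if (is.null(f)) { skipped <- skipped + 1L; next }
    id <- paste(g$patient_id[1], g$cycle[1], g$organ[1], sep = "/")
    fits[[id]] <- f
    rows[[id]] <- data.frame(
      patient_id = g$patient_id[1], cycle = g$cycle[1], organ = g$organ[1],
      model_kind = f$model_kind,
      a1 = f$amplitudes[1], a2 = if (length(f$amplitudes) > 1) f$amplitudes[2] else NA_real_,
      lambda1 = f$rates[1], lambda2 = if (length(f$rates) > 1) f$rates[2] else NA_real_,
      teff_h = f$Teff_h, integral_mbqh_g = curve_integral(f),
      rss = f$rss, n_points = f$n_points,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE))) else data.frame()
  attr(out, "fits") <- fits
  attr(out, "skipped") <- skipped
  out
}
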