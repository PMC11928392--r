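#' Error metrics between single- and multi-time-point doses
#'
#' Paired discrepancy metrics between STPD and MTPD dose vectors, reported
#' the way dosimetry comparison tables print them:
#' \describe{
#'   \item{RMSE}{\eqn{\sqrt{\frac1n\sum_i (S_i - M_i)^2}} in Gy.}
#'   \item{MPE}{mean percentage error
#'     \eqn{\frac1n\sum_i \frac{S_i - M_i}{M_i}\times 100}.}
#'   \item{RPD}{relative percentage difference per pair
#'     \eqn{\frac{S_i - M_i}{(S_i + M_i)/2}\times 100}; the tabulated
#'     aggregate is the arithmetic mean over pairs.}
#' }
#'
#' @param stpd,mtpd Equal-length numeric vectors of paired doses (Gy).
#' @return `dose_rmse`/`dose_mpe`: a scalar. `dose_rpd`: the per-pair
#'   vector; use `mean()` for the tabulated aggregate.
#' @examples
#' dose_rmse(c(1, 2, 3), c(2, 2, 3))  # sqrt(1/3)
#' dose_mpe(c(1, 2, 3), c(2, 2, 3))   # -16.67
#' dose_rpd(1, 2)                     # -66.67
#' @name dose_metrics
NULL

.check_paired <- function(stpd, mtpd) {
  if (length(stpd) != length(mtpd)) stop("unpaired input", call. = FALSE)
  if (length(stpd) < 1L) stop("empty input", call. = FALSE)
  if (any(!is.finite(stpd)) || any(!is.finite(mtpd)))
    stop("non-finite dose", call. = FALSE)
}

#' @rdname dose_metrics
#' @export
dose_rmse <- function(stpd, mtpd) {
  .check_paired(stpd, mtpd)
  sqrt(mean((stpd - mtpd)^2))
}

#' @rdname dose_metrics
#' @export
dose_mpe <- function(stpd, mtpd) {
  .check_paired(stpd, mtpd)
  if (any(mtpd == 0)) stop("undefined relative error", call. = FALSE)
  mean((stpd - mtpd) / mtpd * 100)
}

#' @rdname dose_metrics
#' @export
dose_rpd <- function(stpd, mtpd) {
  .check_paired(stpd, mtpd)
  if (any(stpd + mtpd == 0)) stop("undefined RPD", call. = FALSE)
  (stpd - mtpd) / ((stpd + mtpd) / 2) * 100
}

#' Organ x cycle comparison table of STPD versus MTPD
#'
#' Pairs the two methods' doses per (patient, cycle, organ), computes
#' RMSE/MPE/mean RPD per organ and cycle, and reports the per-cycle
#' percentage-difference (PD) distributions used for error-bar plots.
#' Pairs with no STPD (window-filtered out) are dropped and counted.
#'
#' @param doses Long dose table as produced by [compute_doses()] (columns
#'   `patient_id`, `cycle`, `organ`, `method`, `dose_gy`, `cumulative_gy`).
#' @param on `"cumulative"` (default) compares cumulative doses at each
#'   cycle; `"per_cycle"` compares per-cycle doses.
#' @return An object of class `dose_comparison_report`: list with
#'   `metrics` (organ, cycle, n, rmse, mpe, rpd), `pd` (per-pair
#'   percentage differences with organ/cycle labels), and `attrition`
#'   (unpaired MTPD rows per organ x cycle).
#' @export
compare_methods <- function(doses, on = c("cumulative", "per_cycle")) {
  on <- match.arg(on)
  val <- if (on == "cumulative") doses$cumulative_gy else doses$dose_gy
  d <- data.frame(patient_id = doses$patient_id, cycle = doses$cycle,
                  organ = doses$organ, method = doses$method, value = val,
                  stringsAsFactors = FALSE)
  wide <- merge(d[d$method == "MTPD", c("patient_id", "cycle", "organ", "value")],
                d[d$method == "STPD", c("patient_id", "cycle", "organ", "value")],
                by = c("patient_id", "cycle", "organ"),
                suffixes = c("_mtpd", "_stpd"), all.x = TRUE)
  unpaired <- is.na(wide$value_stpd)
  attr_tab <- if (any(unpaired)) {
    stats::aggregate(cbind(n_dropped = patient_id) ~ organ + cycle,
                     data = wide[unpaired, ], FUN = length)
  } else {
    data.frame(organ = character(0), cycle = integer(0), n_dropped = integer(0))
  }
  wide <- wide[!unpaired, , drop = FALSE]
  metrics <- list(); pd <- list()
  for (grp in split(wide, interaction(wide$organ, wide$cycle, drop = TRUE))) {
    if (nrow(grp) == 0L) next
    S <- grp$value_stpd; M <- grp$value_mtpd
    metrics[[length(metrics) + 1L]] <- data.frame(
      organ = grp$organ[1], cycle = grp$cycle[1], n = nrow(grp),
      rmse = dose_rmse(S, M),
      mpe = if (all(M != 0)) dose_mpe(S, M) else NA_real_,
      rpd = if (all(S + M != 0)) mean(dose_rpd(S, M)) else NA_real_,
      stringsAsFactors = FALSE)
    pd[[length(pd) + 1L]] <- data.frame(
      organ = grp$organ[1], cycle = grp$cycle[1],
      patient_id = grp$patient_id,
      pd = if (all(M != 0)) (S - M) / M * 100 else NA_real_,
      stringsAsFactors = FALSE)
  }
  metrics <- do.call(rbind, c(metrics, list(make.row.names = FALSE)))
  metrics <- metrics[order(metrics$organ, metrics$cycle), , drop = FALSE]
  rownames(metrics) <- NULL
  structure(list(metrics = metrics,
                 pd = do.call(rbind, c(pd, list(make.row.names = FALSE))),
                 attrition = attr_tab, on = on),
            class = "dose_comparison_report")
}

#' @export
print.dose_comparison_report <- function(x, ...) {
  cat(sprintf("<dose_comparison_report> STPD vs MTPD on %s doses\n", x$on))
  print(transform(x$metrics, rmse = round(rmse, 2), mpe = round(mpe, 2),
                  rpd = round(rpd, 2)), row.names = FALSE)
  if (nrow(x$attrition) > 0)
    cat(sprintf("%d organ/cycle cells had window-filtered (unpaired) doses\n",
                nrow(x$attrition)))
  invisible(x)
}

#' Per-cycle percentage-difference series
#'
#' Convenience accessor: per-cycle summaries (mean, SD, n) of the
#' percentage differences (STPD - MTPD)/MTPD x 100 for one organ or all.
#'
#' @param report A [compare_methods()] result.
#' @param organ Optional organ label to subset on.
#' @return Data frame `organ`, `cycle`, `n`, `mean_pd`, `sd_pd`.
#' @export
pd_series <- function(report, organ = NULL) {
  stopifnot(inherits(report, "dose_comparison_report"))
  pd <- report$pd
  if (!is.null(organ)) pd <- pd[pd$organ == organ, , drop = FALSE]
  if (nrow(pd) == 0L)
    return(data.frame(organ = character(0), cycle = integer(0), n = integer(0),
                      mean_pd = numeric(0), sd_pd = numeric(0)))
  out <- do.call(rbind, lapply(split(pd, interaction(pd$organ, pd$cycle, drop = TRUE)),
                               function(g) data.frame(
                                 organ = g$organ[1], cycle = g$cycle[1],
                                 n = nrow(g), mean_pd = mean(g$pd),
                                 sd_pd = stats::sd(g$pd),
                                 stringsAsFactors = FALSE)))
  out <- out[order(out$organ, out$cycle), , drop = FALSE]
  rownames(out) <- NULL
  out
}
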