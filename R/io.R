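#' Readers and writers for the pipeline's CSV schemas
#'
#' All files are comma-separated UTF-8 with a mandatory header row and '.'
#' decimal separator. Validation errors name the offending column (and file).
#'
#' Schemas:
#' \describe{
#'   \item{activity}{`patient_id`, `cycle`, `organ`, `time_h`,
#'     `conc_mbq_per_g`.}
#'   \item{cycles}{`patient_id`, `cycle`, `injected_gbq`,
#'     `cumulative_gbq`.}
#'   \item{outcomes}{`patient_id`, `cycle` (0 = baseline), `psa`, `hgb`,
#'     `os_days`, `os_event`.}
#'   \item{fits}{as written by [write_fits_csv()].}
#'   \item{doses}{as written by [write_doses_csv()].}
#' }
#'
#' @param path File path.
#' @name pipeline_io
NULL

.read_checked <- function(path, required, label) {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", label, path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    stop(sprintf("%s schema error in %s: missing column(s) %s",
                 label, path, paste(miss, collapse = ", ")), call. = FALSE)
  df
}

#' @rdname pipeline_io
#' @export
read_activity_csv <- function(path) {
  df <- .read_checked(path, c("patient_id", "cycle", "organ", "time_h",
                              "conc_mbq_per_g"), "activity")
  bad <- !df$organ %in% organ_levels()
  if (any(bad))
    stop(sprintf("activity schema error: unknown organ '%s' at row %d",
                 df$organ[which(bad)[1]], which(bad)[1]), call. = FALSE)
  if (any(!is.finite(df$time_h)) || any(df$time_h <= 0))
    stop("activity schema error: time_h must be positive", call. = FALSE)
  if (any(!is.finite(df$conc_mbq_per_g)) || any(df$conc_mbq_per_g < 0))
    stop("activity schema error: conc_mbq_per_g must be nonnegative", call. = FALSE)
  key <- interaction(df$patient_id, df$cycle, df$organ, df$time_h, drop = TRUE)
  if (anyDuplicated(key))
    stop("activity schema error: duplicate (patient, cycle, organ, time_h)", call. = FALSE)
  data.frame(patient_id = df$patient_id, cycle = as.integer(df$cycle),
             organ = df$organ, time_h = df$time_h, conc = df$conc_mbq_per_g,
             stringsAsFactors = FALSE)
}

#' @rdname pipeline_io
#' @param activity Activity table with column `conc` (written as
#'   `conc_mbq_per_g`).
#' @export
write_activity_csv <- function(activity, path) {
  out <- data.frame(patient_id = activity$patient_id, cycle = activity$cycle,
                    organ = activity$organ, time_h = activity$time_h,
                    conc_mbq_per_g = activity$conc)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_cycles_csv <- function(path) {
  df <- .read_checked(path, c("patient_id", "cycle", "injected_gbq"), "cycles")
  if (any(!is.finite(df$injected_gbq)) || any(df$injected_gbq <= 0))
    stop("cycles schema error: injected_gbq must be positive", call. = FALSE)
  df$cycle <- as.integer(df$cycle)
  if (!"cumulative_gbq" %in% names(df)) {
    df <- df[order(df$patient_id, df$cycle), ]
    df$cumulative_gbq <- stats::ave(df$injected_gbq, df$patient_id, FUN = cumsum)
  }
  df
}

#' @rdname pipeline_io
#' @param cycles Cycle table.
#' @export
write_cycles_csv <- function(cycles, path) {
  utils::write.csv(cycles, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_outcomes_csv <- function(path) {
  df <- .read_checked(path, c("patient_id", "cycle", "psa", "hgb",
                              "os_days", "os_event"), "outcomes")
  df$cycle <- as.integer(df$cycle)
  if (any(!is.finite(df$os_days)) || any(df$os_days <= 0))
    stop("outcomes schema error: os_days must be positive", call. = FALSE)
  if (!all(df$os_event %in% c(0, 1)))
    stop("outcomes schema error: os_event must be 0/1", call. = FALSE)
  df
}

#' @rdname pipeline_io
#' @param outcomes Outcome table.
#' @export
write_outcomes_csv <- function(outcomes, path) {
  utils::write.csv(outcomes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @param fit_table Result of [fit_cohort_kinetics()].
#' @export
write_fits_csv <- function(fit_table, path) {
  utils::write.csv(as.data.frame(fit_table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_fits_csv <- function(path) {
  .read_checked(path, c("patient_id", "cycle", "organ", "model_kind",
                        "a1", "lambda1", "teff_h", "integral_mbqh_g",
                        "rss", "n_points"), "fits")
}

#' @rdname pipeline_io
#' @param doses Dose table from [compute_doses()], optionally merged with
#'   cycle activities.
#' @export
write_doses_csv <- function(doses, path) {
  utils::write.csv(as.data.frame(doses), path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_doses_csv <- function(path) {
  df <- .read_checked(path, c("patient_id", "cycle", "organ", "method",
                              "dose_gy", "cumulative_gy"), "doses")
  df$cycle <- as.integer(df$cycle)
  df
}
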