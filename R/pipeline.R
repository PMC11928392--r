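#' File-level pipeline stages
#'
#' Thin orchestration wrappers that read the CSV schemas of
#' [pipeline_io], run the corresponding package stage, and write the
#' stage outputs plus a JSON run manifest (`manifest_<stage>.json` with the
#' input digests, seed, package version and timing). Each stage's outputs
#' are valid inputs to the next. These functions back the `inst/cli`
#' script; in R they can be called directly.
#'
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the files written.
#' @name pipeline
NULL

.write_manifest <- function(stage, inputs, out_dir, seed = NA, t0 = NULL) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  man <- list(stage = stage, inputs = digests, seed = seed,
              package_version = as.character(utils::packageVersion("ludosim")),
              elapsed_s = if (is.null(t0)) NA else
                as.numeric(proc.time()["elapsed"] - t0))
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  writeLines(jsonlite::toJSON(man, auto_unbox = TRUE, pretty = TRUE, digits = NA), path)
  path
}

#' @rdname pipeline
#' @param config A [cohort_config()], or the path of a flat key-value YAML
#'   file overriding its defaults.
#' @param seed Optional seed overriding the config's.
#' @export
cmd_simulate <- function(config = cohort_config(), out_dir, seed = NULL) {
  if (is.character(config)) {
    vals <- yaml::read_yaml(config)
    base <- cohort_config()
    unknown <- setdiff(names(vals), names(base))
    if (length(unknown) > 0)
      stop("invalid config field: ", paste(unknown, collapse = ", "), call. = FALSE)
    for (nm in names(vals)) {
      v <- vals[[nm]]
      if (!is.null(names(base[[nm]])) && is.list(v)) v <- unlist(v)
      base[[nm]] <- v
    }
    config <- base
  }
  if (!is.null(seed)) config$seed <- as.integer(seed)
  .validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()["elapsed"]
  coh <- generate_cohort(config)
  files <- c(activity = file.path(out_dir, "activity.csv"),
             cycles = file.path(out_dir, "cycles.csv"),
             outcomes = file.path(out_dir, "outcomes.csv"),
             ground_truth = file.path(out_dir, "ground_truth.csv"))
  write_activity_csv(coh$activity, files["activity"])
  write_cycles_csv(coh$cycles, files["cycles"])
  write_outcomes_csv(coh$outcomes, files["outcomes"])
  utils::write.csv(coh$truth, files["ground_truth"], row.names = FALSE)
  .write_manifest("simulate", character(0), out_dir, config$seed, t0)
  message(sprintf("simulate: %d patients, %d activity rows -> %s",
                  config$n_patients, nrow(coh$activity), out_dir))
  invisible(files)
}

#' @rdname pipeline
#' @param activity_csv Activity samples file.
#' @export
cmd_fit <- function(activity_csv, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()["elapsed"]
  activity <- read_activity_csv(activity_csv)
  fits <- fit_cohort_kinetics(activity)
  out <- file.path(out_dir, "fits.csv")
  write_fits_csv(fits, out)
  .write_manifest("fit", activity_csv, out_dir, t0 = t0)
  message(sprintf("fit: %d curves fitted, %d skipped -> %s",
                  nrow(fits), attr(fits, "skipped"), out))
  invisible(c(fits = out))
}

#' @rdname pipeline
#' @param fits_csv Kinetic-fit table file.
#' @param cycles_csv Injected-activity file.
#' @export
cmd_dose <- function(fits_csv, activity_csv, cycles_csv, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()["elapsed"]
  fits <- read_fits_csv(fits_csv)
  activity <- read_activity_csv(activity_csv)
  cycles <- read_cycles_csv(cycles_csv)
  doses <- compute_doses(fits, activity)
  n_rejected <- attr(doses, "attrition")
  doses <- merge(doses, cycles[, c("patient_id", "cycle", "injected_gbq", "cumulative_gbq")],
                 by = c("patient_id", "cycle"), all.x = TRUE)
  doses$gy_per_gbq <- ifelse(is.finite(doses$injected_gbq) & doses$injected_gbq > 0,
                             doses$dose_gy / doses$injected_gbq, NA_real_)
  out <- file.path(out_dir, "doses.csv")
  write_doses_csv(doses, out)
  .write_manifest("dose", c(fits_csv, activity_csv, cycles_csv), out_dir, t0 = t0)
  message(sprintf("dose: %d dose rows (%d STPD scans rejected by window) -> %s",
                  nrow(doses), n_rejected %||% NA_integer_, out))
  invisible(c(doses = out))
}

#' @rdname pipeline
#' @param doses_csv Dose table file.
#' @export
cmd_compare <- function(doses_csv, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()["elapsed"]
  doses <- read_doses_csv(doses_csv)
  rep <- compare_methods(doses)
  f1 <- file.path(out_dir, "metrics.csv")
  f2 <- file.path(out_dir, "pd_series.csv")
  utils::write.csv(rep$metrics, f1, row.names = FALSE)
  utils::write.csv(pd_series(rep), f2, row.names = FALSE)
  .write_manifest("compare", doses_csv, out_dir, t0 = t0)
  message(sprintf("compare: %d organ/cycle cells -> %s", nrow(rep$metrics), f1))
  invisible(c(metrics = f1, pd_series = f2))
}

#' @rdname pipeline
#' @param outcomes_csv Outcome table file.
#' @export
cmd_correlate <- function(doses_csv, outcomes_csv, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()["elapsed"]
  doses <- read_doses_csv(doses_csv)
  outcomes <- read_outcomes_csv(outcomes_csv)
  rep <- run_comparison_analysis(doses, outcomes)
  rows <- list()
  for (blk_name in c("psa", "anemia")) {
    blk <- rep[[blk_name]]
    for (m in names(blk$by_method)) {
      r <- blk$by_method[[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        analysis = blk_name, method = m, statistic = "spearman_rho",
        value = r$rho, p_value = r$p_value, n = r$n)
    }
    if (!is.null(blk$comparison))
      rows[[length(rows) + 1L]] <- data.frame(
        analysis = blk_name, method = "MTPD_vs_STPD", statistic = "fisher_z",
        value = blk$comparison$z_stat, p_value = blk$comparison$p_value,
        n = blk$comparison$n1 + blk$comparison$n2)
  }
  for (m in names(rep$u_test)) {
    u <- rep$u_test[[m]]
    if (!is.null(u))
      rows[[length(rows) + 1L]] <- data.frame(
        analysis = "response_split", method = m, statistic = "mann_whitney_U",
        value = u$U, p_value = u$p_value, n = u$n_a + u$n_b)
  }
  for (nm in names(rep$cox)) {
    cr <- rep$cox[[nm]]
    if (!is.null(cr))
      rows[[length(rows) + 1L]] <- data.frame(
        analysis = "survival", method = nm, statistic = "cox_hr",
        value = cr$hr, p_value = cr$p_value, n = cr$n)
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  f1 <- file.path(out_dir, "correlations.csv")
  utils::write.csv(tab, f1, row.names = FALSE)
  f2 <- file.path(out_dir, "summary.txt")
  con <- file(f2, open = "wt"); sink(con); print(rep); sink(); close(con)
  .write_manifest("correlate", c(doses_csv, outcomes_csv), out_dir, t0 = t0)
  message(sprintf("correlate: %d statistics -> %s", nrow(tab), f1))
  invisible(c(correlations = f1, summary = f2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
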