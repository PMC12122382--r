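# End-to-end pipeline: simulate -> filter -> fit -> analyse -> associate,
# with CSV outputs and a JSON manifest. The R functions here back the
# command-line interface in inst/cli/tsb_pipeline.R.

# tiny polynomial rolling hash so the manifest can fingerprint the
# configuration without an external digest dependency
.config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.write_manifest <- function(out_dir, stage_files, config, seed) {
  counts <- lapply(stage_files, function(f) {
    if (file.exists(f)) length(readLines(f)) - 1L else NA_integer_
  })
  manifest <- list(
    tool = "tsbdecay",
    version = as.character(packageVersion("tsbdecay")),
    config_hash = .config_hash(unclass(config)),
    seed = seed,
    files = lapply(seq_along(stage_files), function(i) {
      list(path = basename(stage_files[[i]]),
           rows = counts[[i]])
    }),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE))
  names(manifest$files) <- names(stage_files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Simulate a synthetic cohort and write it to disk
#'
#' @param n number of patients
#' @param seed master seed
#' @param out_dir output directory (created if needed)
#' @param config a [load_config] list; `n` and `seed` override its values
#' @return invisibly, the list of files written (cohort CSVs, `truth.csv`,
#'   `manifest.json`)
#' @export
run_simulate <- function(n, seed, out_dir, config = load_config()) {
  settings <- generator_settings(config, n_patients = as.integer(n),
                                 seed = as.integer(seed))
  gen <- generate_cohort(settings)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- write_cohort(gen$cohort, out_dir, config)
  truth_path <- file.path(out_dir, "truth.csv")
  .write_csv(gen$truth, truth_path)
  files <- c(as.list(paths), list(truth = truth_path))
  .write_manifest(out_dir, files, settings, seed)
  message(sprintf("simulated %d patients (%d TSB measurements) into %s",
                  length(gen$cohort), nrow(gen$cohort$measurements), out_dir))
  invisible(files)
}

#' Run the analysis pipeline on a cohort
#'
#' Applies the inclusion filter, fits the patient-specific decay model to
#' every included infant, summarises the parameters, builds the median model
#' with its four sensitivity sweeps, and tabulates the RMSE-vs-elevated-CRP
#' association. Writes `filter_report.csv`, `fits.csv`, `summary.csv`,
#' `median_model.csv`, `sensitivity_<param>.csv`, `associations.csv` and
#' `manifest.json` into `out_dir`.
#'
#' @param cohort a `tsb_cohort`, or a directory containing the cohort CSVs
#' @param out_dir output directory (created if needed)
#' @param config a [load_config] list
#' @param seed seed recorded in the manifest (fitting itself is
#'   deterministic)
#' @return invisibly, a list with the intermediate objects (`outcomes`,
#'   `fits`, `summary`, `median_model`, `associations`) and `files`
#' @export
run_pipeline <- function(cohort, out_dir, config = load_config(),
                         seed = config$seed) {
  if (is.character(cohort)) {
    dirpath <- cohort
    opt <- function(f) {
      p <- file.path(dirpath, f)
      if (file.exists(p)) p else NULL
    }
    cohort <- read_cohort(
      file.path(dirpath, "measurements.csv"),
      file.path(dirpath, "patients.csv"),
      treatments_path = opt("treatments.csv"),
      crp_path = opt("crp.csv"), events_path = opt("events.csv"),
      config = .config_with(config, validate_ga = FALSE))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  outcomes <- apply_inclusion_pipeline(cohort, config)
  report <- as.data.frame(outcomes)
  .write_csv(report, file.path(out_dir, "filter_report.csv"))
  n_included <- sum(report$status == "included")
  if (n_included == 0) stop("0 patients included after filtering")
  sub <- retained_cohort(cohort, outcomes, config)

  fits <- fit_cohort(sub, fit_settings(config))
  fits_df <- as.data.frame(fits)
  .write_csv(fits_df, file.path(out_dir, "fits.csv"))

  summ <- summarize_parameters(fits_df)
  .write_csv(as.data.frame(summ), file.path(out_dir, "summary.csv"))
  med <- build_median_model(fits_df)
  .write_csv(data.frame(A = med$A, B = med$B, C = med$C, Tc = med$Tc,
                        ga_days = med$ga_days),
             file.path(out_dir, "median_model.csv"))
  for (par in c("A", "B", "C", "Tc")) {
    sw <- sensitivity_sweep(med, par, config = config)
    mat <- cbind(grid_value = sw$grid, as.data.frame(sw$curves))
    names(mat)[-1] <- sprintf("pna_%g", sw$pna_grid)
    .write_csv(mat, file.path(out_dir, sprintf("sensitivity_%s.csv", par)))
  }

  assoc <- rmse_crp_table(fits, sub, config$crp_threshold_mg_l)
  .write_csv(assoc, file.path(out_dir, "associations.csv"))

  files <- list(
    filter_report = file.path(out_dir, "filter_report.csv"),
    fits = file.path(out_dir, "fits.csv"),
    summary = file.path(out_dir, "summary.csv"),
    median_model = file.path(out_dir, "median_model.csv"),
    associations = file.path(out_dir, "associations.csv"))
  .write_manifest(out_dir, files, config, seed)
  message(sprintf(
    "pipeline: %d/%d patients included, %d fitted, outputs in %s",
    n_included, length(outcomes), nrow(fits_df), out_dir))
  invisible(list(outcomes = outcomes, fits = fits, summary = summ,
                 median_model = med, associations = assoc, files = files))
}
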