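# Central registry of every tunable used across the pipeline. Each key has a
# documented default; load_config() rejects unknown keys and type mismatches.

.tsb_defaults <- function() {
  list(
    ## reproducibility
    seed = 1L,

    ## cohort validation
    ga_min_days = 168,            # 24 completed weeks
    ga_max_days = 224,            # below 32 completed weeks
    validate_ga = TRUE,
    validate_tsb_nonnegative = TRUE,

    ## inclusion filtering
    min_samples = 4,              # "fewer than 4" excludes counts <= 3
    max_gap_days = 10,            # gaps strictly greater than this exclude
    gap_check_stage = "pre_strip",  # or "post_strip"

    ## synthetic cohort: parameter distributions
    n_patients = 72L,
    a_mean = 120.9, a_sd = 27.54,             # truncated to fitting bounds
    b_median = 0.11,
    b_sdlog = log(0.21 / 0.06) / 1.349,       # lognormal sigma matching IQR
    c_zero_fraction = 0.75,                   # point mass of C at 0
    c_exp_mean = 35, c_gen_max = 175,         # truncated exponential tail
    delta_sd = 10,                            # SD of GA + Tc offset, days
    noise_rmse_mean = 10.62, noise_rmse_sd = 7.69,  # gamma-matched noise SD
    noise_sd_fixed = NA_real_,                # override: constant noise SD
    clip_negative = TRUE,

    ## synthetic cohort: sampling schedule
    n_samples_min = 4L, n_samples_max = 20L,
    count_weights_456 = c(0.30, 0.34, 0.16),  # P(n = 4, 5, 6)
    count_tail_ratio = 0.65,                  # geometric tail over 7..20
    first_pna_median = 4.3, first_pna_sdlog = log(7.0 / 2.0) / 1.349,
    first_pna_min = 3.0,                      # inclusion starts at PNA > 72 h
    gap_median_days = 2.0, gap_sdlog = 0.6,
    gap_min_days = 0.25,
    schedule_max_gap_days = 10,               # raise to emit filter violators
    n_fixed = NA_integer_,                    # degenerate: fixed sample count
    first_pna_fixed = NA_real_,               # degenerate: fixed first PNA
    gap_fixed = NA_real_,                     # degenerate: fixed gaps

    ## synthetic cohort: events and treatments
    event_fraction = 1 / 6,
    event_amp_min = 40, event_amp_max = 120,      # umol/L
    event_center_min = 10, event_center_max = 30, # days
    event_width_min = 1.5, event_width_max = 4,   # days
    event_crp_min = 20, event_crp_max = 300,      # mg/L
    baseline_crp_rate = 2,                        # Poisson mean of routine draws
    baseline_crp_max = 4.5,                       # routine CRP stays below 5
    pt_fraction = 0.15,
    pt_start_min = 3, pt_start_max = 8, pt_duration_days = 2,

    ## fitting
    fit_a_lower = 0, fit_a_upper = 200,
    fit_b_lower = 0, fit_b_upper = 1.5,
    fit_c_lower = 0, fit_c_upper = 500,       # finite box for C in [0, inf)
    fit_delta_halfwidth = 100,                # Tc in -ga_days +/- this
    fit_b_starts = c(0.05, 0.11, 0.3),
    fit_delta_starts = c(0, -20, 20),
    fit_scale_factors = c(0.5, 1, 2, 4),      # x MAD of initial residuals
    fit_maxit = 500L,
    fit_factr = 10,                           # L-BFGS-B relative tolerance
    fit_pgtol = 1e-12,

    ## sensitivity analysis
    sweep_range_A = c(0, 400),
    sweep_range_B = c(0, 0.3),
    sweep_range_C = c(-100, 200),
    sweep_range_Tc = c(-215, -150),
    sweep_n_grid = 9L,
    sweep_pna_max = 60, sweep_pna_step = 0.25,

    ## event association
    crp_threshold_mg_l = 5,
    alert_k_sigma = 2,
    alert_abs_floor = 10,

    ## statistics
    base_alpha = 0.05,

    ## output
    write_empty_crp = TRUE                    # header-only crp.csv vs omit
  )
}

#' Load a run configuration
#'
#' Reads a flat `key: value` (YAML) file of overrides on top of the documented
#' defaults. Every tunable of the pipeline lives here: filter thresholds,
#' generator distribution parameters, fitting bounds and grids, sweep ranges,
#' alert thresholds. Unknown keys and type mismatches are errors.
#'
#' @param path optional path to a YAML config file; `NULL` means all defaults
#' @param quiet suppress the effective-configuration echo
#' @return a named list of class `tsb_config`
#' @export
#' @examples
#' cfg <- load_config()
#' cfg$min_samples
load_config <- function(path = NULL, quiet = TRUE) {
  cfg <- .tsb_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    over <- yaml::read_yaml(path)
    if (length(over)) {
      unknown <- setdiff(names(over), names(cfg))
      if (length(unknown)) {
        stop("unknown config key(s): ", paste(unknown, collapse = ", "),
             "\nvalid keys: ", paste(sort(names(cfg)), collapse = ", "))
      }
      for (k in names(over)) {
        v <- over[[k]]
        if (is.character(cfg[[k]]) && !is.character(v)) {
          stop("config key '", k, "' must be character")
        }
        if (is.numeric(cfg[[k]]) && !is.numeric(v) && !all(is.na(v))) {
          stop("config key '", k, "' must be numeric")
        }
        if (is.logical(cfg[[k]]) && !is.logical(v)) {
          stop("config key '", k, "' must be logical")
        }
        cfg[[k]] <- v
      }
    }
  }
  if (!cfg$gap_check_stage %in% c("pre_strip", "post_strip")) {
    stop("gap_check_stage must be 'pre_strip' or 'post_strip'")
  }
  cfg <- structure(cfg, class = "tsb_config")
  if (!quiet) {
    message("effective configuration:")
    for (k in names(cfg)) {
      message("  ", k, ": ", paste(format(cfg[[k]]), collapse = ", "))
    }
  }
  cfg
}

# merge ad-hoc overrides (name = value ...) onto a config, with key checking
.config_with <- function(cfg = load_config(), ...) {
  over <- list(...)
  if (!length(over)) return(cfg)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  structure(modifyList(unclass(cfg), over), class = "tsb_config")
}
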