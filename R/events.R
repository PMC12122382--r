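# Association of model misfit with clinical events: elevated-CRP counting in
# the post-phototherapy window, the RMSE-vs-CRP association table with a rank
# correlation, and a residual-based deviation alert for newly drawn TSB
# levels.

#' Count elevated CRP in a patient's observation window
#'
#' The window runs from the end of the last phototherapy interval (exclusive)
#' to the last retained TSB measurement (inclusive); patients without
#' phototherapy use the full retained TSB span (both ends inclusive). CRP is
#' elevated when strictly greater than the threshold (5 mg/L by default, so a
#' value of exactly 5.0 does not count).
#'
#' @param patient a [patient_record]
#' @param threshold_mg_l elevation threshold, mg/L
#' @return list with `patient_id`, `window_start_pna`, `window_end_pna`,
#'   `n_elevated`, `max_crp` (max CRP of any record in the window; 0 if none)
#' @export
crp_window <- function(patient, threshold_mg_l = 5) {
  meas <- patient$measurements
  stopifnot(nrow(meas) >= 1)
  last_tsb <- max(meas$pna_days)
  pt <- patient$treatments[patient$treatments$kind == "PT", , drop = FALSE]
  if (nrow(pt)) {
    start <- max(pt$end_pna_days)
    in_window <- function(t) t > start & t <= last_tsb
  } else {
    start <- min(meas$pna_days)
    in_window <- function(t) t >= start & t <= last_tsb
  }
  crp <- patient$crp[in_window(patient$crp$pna_days), , drop = FALSE]
  list(patient_id = patient$patient_id,
       window_start_pna = start, window_end_pna = last_tsb,
       n_elevated = sum(crp$crp_mg_l > threshold_mg_l),
       max_crp = if (nrow(crp)) max(crp$crp_mg_l) else 0)
}

#' RMSE versus elevated-CRP association table
#'
#' One row per fitted patient with the model RMSE and the elevated-CRP
#' statistics of [crp_window], sorted by RMSE ascending. The Spearman rank
#' correlation between RMSE and the elevated-CRP count is attached as
#' attributes `spearman` and `spearman_defined` (undefined when either
#' column is constant).
#'
#' @param fits a `tsb_fits` list
#' @param cohort the `tsb_cohort` the fits came from
#' @param threshold_mg_l CRP elevation threshold, mg/L
#' @return data frame `patient_id, rmse, n_elevated, max_crp` (the
#'   `associations.csv` schema)
#' @export
rmse_crp_table <- function(fits, cohort, threshold_mg_l = 5) {
  fit_ids <- vapply(fits, `[[`, character(1), "patient_id")
  missing_ids <- setdiff(fit_ids, cohort$patients$patient_id)
  if (length(missing_ids)) {
    stop("fitted patients absent from cohort: ",
         paste(missing_ids, collapse = ", "))
  }
  rows <- lapply(fits, function(f) {
    w <- crp_window(patient_record(cohort, f$patient_id), threshold_mg_l)
    data.frame(patient_id = f$patient_id, rmse = f$rmse,
               n_elevated = w$n_elevated, max_crp = w$max_crp)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$rmse), , drop = FALSE]
  rownames(tab) <- NULL
  defined <- nrow(tab) >= 3 && sd(tab$n_elevated) > 0 && sd(tab$rmse) > 0
  attr(tab, "spearman") <- if (defined) {
    cor(tab$rmse, tab$n_elevated, method = "spearman")
  } else NA_real_
  attr(tab, "spearman_defined") <- defined
  tab
}

#' Residual-based deviation alert for a new TSB measurement
#'
#' Compares a newly drawn TSB level against the patient's fitted decay curve;
#' an absolute residual beyond `max(k_sigma * rmse, abs_floor)` raises the
#' alert. The threshold rule is this package's operationalisation of
#' deviation-based monitoring: the floor keeps near-perfect fits (rmse ~ 0)
#' from alerting on clinically trivial deviations.
#'
#' @param fit a converged `tsb_fit`
#' @param new_measurement list or one-row data frame with `pna_days` and
#'   `tsb_umol_l`
#' @param k_sigma multiple of the fit RMSE (default 2)
#' @param abs_floor minimum alert threshold, umol/L (default 10)
#' @return list with `patient_id, pna_days, observed_tsb, predicted_tsb,
#'   residual, threshold_used, alert`
#' @export
deviation_alert <- function(fit, new_measurement, k_sigma = 2,
                            abs_floor = 10) {
  if (!isTRUE(fit$converged)) {
    stop("deviation_alert needs a converged fit; refit patient ",
         fit$patient_id)
  }
  pna <- new_measurement$pna_days
  stopifnot(pna >= 0)
  observed <- new_measurement$tsb_umol_l
  predicted <- eval_patient_specific(fit$params, pna)
  threshold <- max(k_sigma * fit$rmse, abs_floor)
  residual <- observed - predicted
  list(patient_id = fit$patient_id, pna_days = pna,
       observed_tsb = observed, predicted_tsb = predicted,
       residual = residual, threshold_used = threshold,
       alert = abs(residual) > threshold)
}
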