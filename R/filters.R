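# Inclusion cascade selecting the modelled subgroup:
#   1. at least `min_samples` TSB measurements ("fewer than 4" excludes <= 3);
#   2. no two adjacent measurements more than `max_gap_days` apart
#      (infrequent monitoring; gaps of exactly the limit pass);
#   3. samples drawn during phototherapy or exchange transfusion are removed
#      (closed intervals [start, end]), then the minimum-sample rule is
#      re-checked on what remains.
# Rules are applied in this order and the first failing rule is recorded as
# the primary exclusion reason.

#' Minimum-sample inclusion check
#'
#' @param patient a [patient_record]
#' @param min_samples inclusion threshold (default 4; "fewer than 4" excludes
#'   counts of 3 or less)
#' @return TRUE if the patient has at least `min_samples` measurements
#' @export
check_min_samples <- function(patient, min_samples = 4) {
  nrow(patient$measurements) >= min_samples
}

#' Monitoring-frequency inclusion check
#'
#' Fails when any two adjacent (PNA-sorted) TSB measurements are strictly
#' more than `max_gap_days` apart; a gap of exactly the limit passes.
#'
#' @param patient a [patient_record] with at least 2 measurements
#' @param max_gap_days monitoring gap limit, days (default 10)
#' @return TRUE if every consecutive gap is within the limit
#' @export
check_monitoring_gap <- function(patient, max_gap_days = 10) {
  pna <- sort(patient$measurements$pna_days)
  if (length(pna) < 2) {
    stop("check_monitoring_gap needs >= 2 measurements; ",
         "apply the minimum-sample rule first")
  }
  all(diff(pna) <= max_gap_days)
}

#' Remove samples drawn during treatment
#'
#' A measurement is removed when it falls inside any phototherapy or exchange
#' transfusion interval of the patient, boundaries included
#' (start <= pna <= end): a sample drawn at treatment cessation still
#' reflects the treatment effect.
#'
#' @param patient a [patient_record]
#' @return list with `retained` and `removed` measurement data frames;
#'   `removed` gains a `removal_cause` column naming the treatment kind
#' @export
strip_treatment_samples <- function(patient) {
  meas <- patient$measurements
  trt <- patient$treatments
  if (!nrow(trt) || !nrow(meas)) {
    removed <- meas[0, , drop = FALSE]
    removed$removal_cause <- character(0)
    return(list(retained = meas, removed = removed))
  }
  cause <- rep(NA_character_, nrow(meas))
  for (j in seq_len(nrow(trt))) {
    hit <- meas$pna_days >= trt$start_pna_days[j] &
      meas$pna_days <= trt$end_pna_days[j]
    cause[hit & is.na(cause)] <- trt$kind[j]
  }
  removed <- meas[!is.na(cause), , drop = FALSE]
  removed$removal_cause <- cause[!is.na(cause)]
  list(retained = meas[is.na(cause), , drop = FALSE], removed = removed)
}

#' Apply the full inclusion cascade to a cohort
#'
#' @param cohort a `tsb_cohort`
#' @param config a [load_config] list (`min_samples`, `max_gap_days`,
#'   `gap_check_stage`)
#' @return list of per-patient outcomes (class `tsb_filter_outcomes`), each
#'   with `patient_id`, `status` ("included"/"excluded"), `primary_reason`
#'   ("too_few_samples", "infrequent_monitoring",
#'   "too_few_after_treatment_removal" or "none"), `retained_measurements`
#'   and `removed_measurements`
#' @export
apply_inclusion_pipeline <- function(cohort, config = load_config()) {
  out <- lapply(cohort$patients$patient_id, function(id) {
    p <- patient_record(cohort, id)
    meas <- p$measurements
    no_removed <- {
      r <- meas[0, , drop = FALSE]
      r$removal_cause <- character(0)
      r
    }
    res <- list(patient_id = id, status = "excluded",
                primary_reason = "none",
                retained_measurements = meas,
                removed_measurements = no_removed,
                n_total = nrow(meas))

    # retained/removed always partition the input measurements, whatever the
    # inclusion status; excluded patients simply are not modelled
    if (!check_min_samples(p, config$min_samples)) {
      res$primary_reason <- "too_few_samples"
      return(res)
    }
    gap_patient <- p
    stripped <- strip_treatment_samples(p)
    if (identical(config$gap_check_stage, "post_strip")) {
      gap_patient <- p
      gap_patient$measurements <- stripped$retained
    }
    if (nrow(gap_patient$measurements) >= 2 &&
        !check_monitoring_gap(gap_patient, config$max_gap_days)) {
      res$primary_reason <- "infrequent_monitoring"
      return(res)
    }
    if (nrow(stripped$retained) < config$min_samples) {
      res$primary_reason <- "too_few_after_treatment_removal"
      res$retained_measurements <- stripped$retained
      res$removed_measurements <- stripped$removed
      return(res)
    }
    res$status <- "included"
    res$retained_measurements <- stripped$retained
    res$removed_measurements <- stripped$removed
    res
  })
  names(out) <- cohort$patients$patient_id
  n_inc <- sum(vapply(out, function(o) o$status == "included", logical(1)))
  message(sprintf("inclusion pipeline: %d of %d patients included",
                  n_inc, length(out)))
  structure(out, class = "tsb_filter_outcomes")
}

#' Tabulate filter outcomes
#'
#' @param x a `tsb_filter_outcomes` list
#' @param ... unused
#' @return data frame `patient_id, status, primary_reason, n_total,
#'   n_retained` (the `filter_report.csv` schema)
#' @export
as.data.frame.tsb_filter_outcomes <- function(x, ...) {
  do.call(rbind, lapply(x, function(o) data.frame(
    patient_id = o$patient_id, status = o$status,
    primary_reason = o$primary_reason, n_total = o$n_total,
    n_retained = nrow(o$retained_measurements))))
}

#' Build the included sub-cohort from filter outcomes
#'
#' Keeps only included patients with their retained measurements; treatment
#' intervals are dropped (their samples have already been removed).
#'
#' @param cohort the original `tsb_cohort`
#' @param outcomes result of [apply_inclusion_pipeline]
#' @param config a [load_config] list
#' @return a `tsb_cohort` of included patients
#' @export
retained_cohort <- function(cohort, outcomes, config = load_config()) {
  inc <- Filter(function(o) o$status == "included", outcomes)
  if (!length(inc)) stop("0 patients included after filtering")
  ids <- vapply(inc, `[[`, character(1), "patient_id")
  meas <- do.call(rbind, lapply(inc, function(o) {
    m <- o$retained_measurements
    m[, c("patient_id", "pna_days", "tsb_umol_l"), drop = FALSE]
  }))
  tsb_cohort(
    patients = cohort$patients[cohort$patients$patient_id %in% ids, ,
                               drop = FALSE],
    measurements = meas,
    treatments = NULL,
    crp = cohort$crp[cohort$crp$patient_id %in% ids, , drop = FALSE],
    events = cohort$events[cohort$events$patient_id %in% ids, , drop = FALSE],
    config = .config_with(config, validate_ga = FALSE))
}
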