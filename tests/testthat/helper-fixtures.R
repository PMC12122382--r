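# Shared fixture builders. Everything is constructed in code; no data files.

# a bare patient record, bypassing cohort assembly, for unit-level functions
make_patient <- function(id = "T1", ga_days = 196, pna = c(4, 6, 8, 10),
                         tsb = NULL, treatments = NULL, crp = NULL) {
  if (is.null(tsb)) tsb <- 150 * exp(-0.1 * pna) + 20
  empty_trt <- data.frame(patient_id = character(0), kind = character(0),
                          start_pna_days = numeric(0),
                          end_pna_days = numeric(0))
  empty_crp <- data.frame(patient_id = character(0), pna_days = numeric(0),
                          crp_mg_l = numeric(0))
  list(patient_id = id, ga_days = ga_days, birth_weight_g = NA, sex = NA,
       measurements = data.frame(patient_id = id, pna_days = pna,
                                 tsb_umol_l = tsb),
       treatments = if (is.null(treatments)) empty_trt else
         cbind(patient_id = id, treatments),
       crp = if (is.null(crp)) empty_crp else cbind(patient_id = id, crp),
       events = data.frame(patient_id = character(0), event = character(0),
                           pna_days = numeric(0)))
}

# assemble a small cohort from a list of per-patient specs
make_cohort <- function(specs, config = load_config()) {
  patients <- do.call(rbind, lapply(specs, function(s) data.frame(
    patient_id = s$id, ga_days = if (is.null(s$ga_days)) 196 else s$ga_days,
    birth_weight_g = NA_real_, sex = NA_character_)))
  measurements <- do.call(rbind, lapply(specs, function(s) data.frame(
    patient_id = s$id, pna_days = s$pna,
    tsb_umol_l = if (is.null(s$tsb)) 150 * exp(-0.1 * s$pna) + 20 else s$tsb)))
  trts <- Filter(Negate(is.null), lapply(specs, function(s) {
    if (is.null(s$treatments)) return(NULL)
    cbind(patient_id = s$id, s$treatments)
  }))
  crps <- Filter(Negate(is.null), lapply(specs, function(s) {
    if (is.null(s$crp)) return(NULL)
    cbind(patient_id = s$id, s$crp)
  }))
  tsb_cohort(patients, measurements,
             treatments = if (length(trts)) do.call(rbind, trts) else NULL,
             crp = if (length(crps)) do.call(rbind, crps) else NULL,
             config = config)
}

# generator settings for controlled experiments, silencing progress messages
gen_quiet <- function(...) {
  suppressMessages(generate_cohort(generator_settings(load_config(), ...)))
}

# fit every patient of a cohort, silencing messages
fit_all <- function(cohort, ...) {
  suppressMessages(fit_cohort(cohort, fit_settings(load_config(), ...)))
}

# composite amplitude of a truth table row
truth_composite <- function(tr) {
  to_composite(decay_parameters(tr$A, tr$B, tr$C, tr$Tc, tr$ga_days))
}
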