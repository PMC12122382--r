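# Data model: a cohort is a set of data frames keyed by patient_id.
#   patients:     patient_id, ga_days, birth_weight_g, sex
#   measurements: patient_id, pna_days, tsb_umol_l   (TSB draws)
#   treatments:   patient_id, kind (PT/ET), start_pna_days, end_pna_days
#   crp:          patient_id, pna_days, crp_mg_l
#   events:       patient_id, event, pna_days        (clinical outcomes)
# PNA is postnatal age in days (0 at birth, fractional allowed); GA is stored
# in days so the model's time shift p + GA + Tc works in a single unit.

#' Convert a clinical gestational age to days
#'
#' Clinical notation gives GA as completed weeks plus days (e.g. 27+3); the
#' model uses days throughout.
#'
#' @param weeks completed weeks
#' @param days extra days (default 0)
#' @return gestational age in days
#' @export
ga_weeks_to_days <- function(weeks, days = 0) weeks * 7 + days

#' Assemble and validate a cohort
#'
#' @param patients data frame with `patient_id`, `ga_days` (or `ga_weeks` and
#'   optionally `ga_extra_days`), optional `birth_weight_g`, `sex`
#' @param measurements data frame with `patient_id`, `pna_days`, `tsb_umol_l`
#' @param treatments,crp,events optional data frames (see schemas above);
#'   `NULL` becomes an empty table
#' @param config a [load_config] list; controls GA-range validation
#' @return a `tsb_cohort` object (list of the five tables, measurements
#'   sorted by patient then PNA, input order preserved among PNA ties)
#' @export
tsb_cohort <- function(patients, measurements, treatments = NULL, crp = NULL,
                       events = NULL, config = load_config()) {
  patients <- as.data.frame(patients)
  if (!"ga_days" %in% names(patients) && "ga_weeks" %in% names(patients)) {
    extra <- if ("ga_extra_days" %in% names(patients)) {
      patients$ga_extra_days
    } else 0
    patients$ga_days <- ga_weeks_to_days(patients$ga_weeks, extra)
  }
  .require_cols(patients, c("patient_id", "ga_days"), "patients")
  for (opt in c("birth_weight_g", "sex")) {
    if (!opt %in% names(patients)) patients[[opt]] <- NA
  }
  patients <- patients[, c("patient_id", "ga_days", "birth_weight_g", "sex")]
  patients$patient_id <- as.character(patients$patient_id)
  if (anyDuplicated(patients$patient_id)) {
    stop("duplicated patient_id in patients table")
  }
  if (isTRUE(config$validate_ga) && nrow(patients)) {
    bad <- patients$ga_days < config$ga_min_days |
      patients$ga_days >= config$ga_max_days
    if (any(bad)) {
      stop("gestational age outside [", config$ga_min_days, ", ",
           config$ga_max_days, ") days for patient(s): ",
           paste(patients$patient_id[bad], collapse = ", "),
           " (set validate_ga = FALSE to override)")
    }
  }

  measurements <- .empty_if_null(
    measurements, c("patient_id", "pna_days", "tsb_umol_l"))
  treatments <- .empty_if_null(
    treatments, c("patient_id", "kind", "start_pna_days", "end_pna_days"))
  crp <- .empty_if_null(crp, c("patient_id", "pna_days", "crp_mg_l"))
  events <- .empty_if_null(events, c("patient_id", "event", "pna_days"))

  for (tab in list(measurements, treatments, crp, events)) {
    orphan <- setdiff(unique(tab$patient_id), patients$patient_id)
    if (length(orphan)) {
      stop("orphan patient_id not present in patients table: ",
           paste(orphan, collapse = ", "))
    }
  }
  if (nrow(measurements)) {
    if (any(measurements$pna_days < 0)) {
      stop("negative pna_days in measurements")
    }
    if (isTRUE(config$validate_tsb_nonnegative) &&
        any(measurements$tsb_umol_l < 0)) {
      stop("negative tsb_umol_l in measurements")
    }
  }
  if (nrow(treatments)) {
    if (!all(treatments$kind %in% c("PT", "ET"))) {
      stop("treatment kind must be PT or ET")
    }
    if (any(treatments$start_pna_days < 0 |
            treatments$start_pna_days > treatments$end_pna_days)) {
      stop("treatment intervals need 0 <= start_pna_days <= end_pna_days")
    }
  }
  if (nrow(crp) && any(crp$crp_mg_l < 0 | crp$pna_days < 0)) {
    stop("negative value in crp table")
  }

  measurements <- .sort_by_patient_pna(measurements)
  crp <- .sort_by_patient_pna(crp)

  structure(
    list(patients = patients, measurements = measurements,
         treatments = treatments, crp = crp, events = events),
    class = "tsb_cohort")
}

#' @export
print.tsb_cohort <- function(x, ...) {
  cat(sprintf(
    "<tsb_cohort> %d patients, %d TSB measurements, %d treatment intervals, %d CRP records\n",
    nrow(x$patients), nrow(x$measurements), nrow(x$treatments), nrow(x$crp)))
  invisible(x)
}

#' Number of patients in a cohort
#' @param x a `tsb_cohort`
#' @param ... unused
#' @export
length.tsb_cohort <- function(x, ...) nrow(x$patients)

#' Extract one patient's record from a cohort
#'
#' @param cohort a `tsb_cohort`
#' @param patient_id identifier present in the patients table
#' @return list with scalar metadata plus this patient's `measurements`,
#'   `treatments`, `crp` and `events` tables
#' @export
patient_record <- function(cohort, patient_id) {
  i <- match(patient_id, cohort$patients$patient_id)
  if (is.na(i)) stop("unknown patient_id: ", patient_id)
  pick <- function(tab) tab[tab$patient_id == patient_id, , drop = FALSE]
  list(patient_id = patient_id,
       ga_days = cohort$patients$ga_days[i],
       birth_weight_g = cohort$patients$birth_weight_g[i],
       sex = cohort$patients$sex[i],
       measurements = pick(cohort$measurements),
       treatments = pick(cohort$treatments),
       crp = pick(cohort$crp),
       events = pick(cohort$events))
}

#' Read a cohort from CSV files
#'
#' Files are comma-separated UTF-8 with a header row and "." decimal
#' separator. Missing optional files yield empty tables: the model core needs
#' only measurements and gestational age.
#'
#' @param measurements_path CSV `patient_id,pna_days,tsb_umol_l`
#' @param patients_path CSV `patient_id,ga_days,birth_weight_g,sex`
#' @param treatments_path optional CSV
#'   `patient_id,kind,start_pna_days,end_pna_days` with kind in {PT, ET}
#' @param crp_path optional CSV `patient_id,pna_days,crp_mg_l`
#' @param events_path optional CSV `patient_id,event,pna_days`
#' @param config a [load_config] list
#' @return a `tsb_cohort`
#' @export
read_cohort <- function(measurements_path, patients_path,
                        treatments_path = NULL, crp_path = NULL,
                        events_path = NULL, config = load_config()) {
  patients <- .read_table(
    patients_path, required = c("patient_id", "ga_days"),
    numeric_cols = c("ga_days", "birth_weight_g"))
  measurements <- .read_table(
    measurements_path,
    required = c("patient_id", "pna_days", "tsb_umol_l"),
    numeric_cols = c("pna_days", "tsb_umol_l"), nonnegative = TRUE)
  treatments <- .read_optional(
    treatments_path,
    required = c("patient_id", "kind", "start_pna_days", "end_pna_days"),
    numeric_cols = c("start_pna_days", "end_pna_days"), nonnegative = TRUE)
  crp <- .read_optional(
    crp_path, required = c("patient_id", "pna_days", "crp_mg_l"),
    numeric_cols = c("pna_days", "crp_mg_l"), nonnegative = TRUE)
  events <- .read_optional(
    events_path, required = c("patient_id", "event", "pna_days"),
    numeric_cols = "pna_days", nonnegative = TRUE)
  tsb_cohort(patients, measurements, treatments, crp, events, config = config)
}

#' Write a cohort to CSV files
#'
#' Emits the same schemas [read_cohort] accepts, with deterministic row order
#' (patient_id, then pna_days), so identical cohorts produce byte-identical
#' files.
#'
#' @param cohort a `tsb_cohort`
#' @param out_dir output directory (created if needed)
#' @param config a [load_config] list; `write_empty_crp = FALSE` omits
#'   `crp.csv` when there are no CRP records
#' @return invisibly, the named vector of file paths written
#' @export
write_cohort <- function(cohort, out_dir, config = load_config()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  ord_pat <- order(cohort$patients$patient_id)
  paths <- c(
    patients = file.path(out_dir, "patients.csv"),
    measurements = file.path(out_dir, "measurements.csv"),
    treatments = file.path(out_dir, "treatments.csv"),
    crp = file.path(out_dir, "crp.csv"),
    events = file.path(out_dir, "events.csv"))
  .write_csv(cohort$patients[ord_pat, , drop = FALSE], paths["patients"])
  .write_csv(.sort_by_patient_pna(cohort$measurements), paths["measurements"])
  trt <- cohort$treatments
  .write_csv(trt[order(trt$patient_id, trt$start_pna_days), , drop = FALSE],
             paths["treatments"])
  if (nrow(cohort$crp) || isTRUE(config$write_empty_crp)) {
    .write_csv(.sort_by_patient_pna(cohort$crp), paths["crp"])
  } else {
    paths <- paths[names(paths) != "crp"]
  }
  ev <- cohort$events
  .write_csv(ev[order(ev$patient_id, ev$pna_days), , drop = FALSE],
             paths["events"])
  invisible(paths)
}

## ---- internal helpers -------------------------------------------------

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop("missing required column(s) in ", what, ": ",
         paste(miss, collapse = ", "))
  }
}

.empty_if_null <- function(df, cols) {
  if (is.null(df)) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    num <- setdiff(cols, c("patient_id", "kind", "event", "sex"))
    for (cc in num) df[[cc]] <- numeric(0)
    return(df)
  }
  df <- as.data.frame(df)
  .require_cols(df, cols, deparse(substitute(df)))
  df <- df[, cols, drop = FALSE]
  df$patient_id <- as.character(df$patient_id)
  df
}

# stable sort: ties in pna_days keep input order
.sort_by_patient_pna <- function(df) {
  if (!nrow(df)) return(df)
  ord <- order(df$patient_id, df$pna_days)
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.read_table <- function(path, required, numeric_cols = character(0),
                        nonnegative = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 fileEncoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  for (col in intersect(numeric_cols, names(df))) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(val))
    if (length(bad)) {
      stop("validation error in ", basename(path), " line ", bad[1] + 1L,
           ": non-numeric value '", raw[bad[1]], "' in column ", col)
    }
    if (nonnegative) {
      neg <- which(!is.na(val) & val < 0)
      if (length(neg)) {
        stop("validation error in ", basename(path), " line ", neg[1] + 1L,
             ": negative value ", val[neg[1]], " in column ", col)
      }
    }
    df[[col]] <- val
  }
  df
}

.read_optional <- function(path, required, numeric_cols, nonnegative = FALSE) {
  if (is.null(path)) return(NULL)
  .read_table(path, required, numeric_cols, nonnegative)
}

.write_csv <- function(df, path) {
  rownames(df) <- NULL
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "",
            fileEncoding = "UTF-8")
}
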