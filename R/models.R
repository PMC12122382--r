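#' Construct a patient-specific decay parameter set
#'
#' Holds the four fitted parameters of the patient-specific exponential decay
#' model together with the gestational age that anchors its time axis:
#' TSB(p) = A * exp(-B * (p + ga_days + Tc)) + C, with p the postnatal age in
#' days and TSB in umol/L.
#'
#' @param A amplitude, umol/L (fitting bounds `[0, 200]`)
#' @param B decay rate, per day (fitting bounds `[0, 1.5]`)
#' @param C baseline asymptote, umol/L (non-negative under fitting bounds)
#' @param Tc time-correction term, days; typically close to `-ga_days` so the
#'   combined shift `ga_days + Tc` is small
#' @param ga_days gestational age at birth, days
#' @return an object of class `decay_parameters`
#' @export
#' @examples
#' pars <- decay_parameters(A = 120, B = 0.1, C = 10, Tc = -195, ga_days = 195)
#' eval_patient_specific(pars, p = c(0, 10))
decay_parameters <- function(A, B, C, Tc, ga_days) {
  vals <- c(A = A, B = B, C = C, Tc = Tc, ga_days = ga_days)
  if (any(!is.finite(vals))) {
    stop("decay parameters must be finite; got ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  }
  structure(as.list(vals), class = "decay_parameters")
}

#' @export
print.decay_parameters <- function(x, ...) {
  cat(sprintf(
    "<decay_parameters> A=%.4g B=%.4g C=%.4g Tc=%.4g ga_days=%.4g\n",
    x$A, x$B, x$C, x$Tc, x$ga_days))
  invisible(x)
}

#' Evaluate the population linear decay model
#'
#' TSB(t) = intercept + slope * t. Used as the simplest population-level
#' description of TSB against postnatal age.
#'
#' @param params list with elements `intercept_A` (umol/L) and `slope_B`
#'   (umol/L per day)
#' @param t postnatal age, days (vectorised)
#' @return TSB in umol/L
#' @export
eval_linear <- function(params, t) {
  stopifnot(is.numeric(t))
  params$intercept_A + params$slope_B * t
}

#' Evaluate the general exponential decay model
#'
#' TSB(t) = A * exp(-B * t) + C: decay at a rate proportional to the current
#' level above the asymptote C. This is the population-level exponential
#' model, without patient-specific time shifting.
#'
#' @param params list with elements `A` (umol/L), `B` (per day, >= 0 at fit
#'   time), `C` (umol/L)
#' @param t postnatal age, days (vectorised)
#' @return TSB in umol/L
#' @export
eval_general_exponential <- function(params, t) {
  stopifnot(is.numeric(t))
  params$A * exp(-params$B * t) + params$C
}

#' Evaluate the patient-specific decay model
#'
#' TSB(p) = A * exp(-B * (p + ga_days + Tc)) + C. The gestational age and the
#' correction factor Tc act jointly as a time shift that personalises the
#' curve; the exponent is computed on the raw sum, without pre-reducing to
#' the composite form, so fitted A and Tc round-trip exactly.
#'
#' @param params a [decay_parameters] object (or list with A, B, C, Tc,
#'   ga_days)
#' @param p postnatal age, days (vectorised)
#' @return TSB in umol/L
#' @export
eval_patient_specific <- function(params, p) {
  stopifnot(is.numeric(p))
  params$A * exp(-params$B * (p + params$ga_days + params$Tc)) + params$C
}

#' Reduce a parameter set to its identifiable composite form
#'
#' A and Tc enter the patient-specific model only through the composite
#' amplitude `Atilde = A * exp(-B * (ga_days + Tc))`; the mean curve equals
#' `Atilde * exp(-B * p) + C` for all p. Raw A and Tc are therefore not
#' separately identifiable from data, and recovery claims are made on
#' `(Atilde, B, C)` only.
#'
#' @param params a [decay_parameters] object
#' @return list with `amplitude_tilde` (umol/L), `B` (per day), `C` (umol/L),
#'   of class `composite_parameters`
#' @export
to_composite <- function(params) {
  expo <- -params$B * (params$ga_days + params$Tc)
  if (expo > 700) {
    stop("composite amplitude overflows: -B*(ga_days+Tc) = ",
         format(expo), " exceeds exp() range")
  }
  structure(
    list(amplitude_tilde = params$A * exp(expo), B = params$B, C = params$C),
    class = "composite_parameters")
}

#' Root-mean-square error between observed and predicted TSB
#'
#' @param observed numeric vector, umol/L
#' @param predicted numeric vector of equal length, umol/L
#' @return RMSE in umol/L
#' @export
#' @examples
#' rmse(c(10, 20), c(13, 16)) # sqrt((9 + 16) / 2)
rmse <- function(observed, predicted) {
  if (length(observed) == 0L) stop("rmse: empty input")
  if (length(observed) != length(predicted)) {
    stop("rmse: length mismatch (", length(observed), " vs ",
         length(predicted), ")")
  }
  sqrt(mean((observed - predicted)^2))
}
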