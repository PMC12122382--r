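# Fitting machinery.
#
# The patient-specific model is fitted by bounded nonlinear least squares
# over a candidate grid: {plain least squares, smooth-L1 robust loss at four
# scales} x a deterministic multi-start set. The smooth-L1 (soft-L1) loss
# rho(z) = 2(sqrt(1+z)-1) applied to squared scaled residuals is a smooth
# approximation to absolute-error regression; its scales are multiples of
# the MAD of residuals from an initial plain fit (the adaptive robustness
# strategy). Every candidate solution is scored by its plain (unweighted)
# sum of squared residuals on all samples and the lowest-SSR candidate wins;
# ties break by candidate enumeration order. Optimisation works on the
# conditioned variable delta = ga_days + Tc (raw Tc ~ -200 d is reported).

#' Build fit settings
#'
#' @param config a [load_config] list
#' @param ... named overrides of config keys (e.g. `fit_c_upper = 1000`)
#' @return a `tsb_config` with overrides applied
#' @export
fit_settings <- function(config = load_config(), ...) {
  .config_with(config, ...)
}

# one bounded L-BFGS-B run on theta = (A, B, C, delta); returns par + value
.one_optim <- function(start, lower, upper, p, y, loss, scale, s) {
  fn <- function(th) decay_cost(th, p, y, loss, scale)
  gr <- function(th) decay_grad(th, p, y, loss, scale)
  res <- try(optim(start, fn, gr, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = s$fit_maxit, factr = s$fit_factr,
                                  pgtol = s$fit_pgtol)),
             silent = TRUE)
  if (inherits(res, "try-error")) return(NULL)
  res
}

# deterministic multi-start set for one patient
.start_grid <- function(y, s) {
  a_starts <- unique(c(min(max(y), s$fit_a_upper), 120))
  c_starts <- unique(c(0, min(y)))
  starts <- expand.grid(A = a_starts, B = s$fit_b_starts, C = c_starts,
                        delta = s$fit_delta_starts, KEEP.OUT.ATTRS = FALSE)
  as.matrix(starts)
}

#' Fit the patient-specific decay model for one infant
#'
#' Bounded robust nonlinear least squares on (A, B, C, Tc) with multi-start
#' and an adaptive robustness strategy; see the package vignette for the
#' candidate-grid construction. Bounds default to A in `[0, 200]`, B in
#' `[0, 1.5]`, C in `[0, 500]`, Tc within `ga_days +/- 100` of `-ga_days`.
#'
#' @param patient a [patient_record] (uses `measurements` and `ga_days`);
#'   at least 4 retained measurements are required -- fewer signals that the
#'   inclusion filter was not applied
#' @param settings a [fit_settings] list
#' @param return_candidates attach the per-candidate solutions (for
#'   diagnostics and robustness checks)
#' @return a `tsb_fit` object: `params` ([decay_parameters]), `composite`
#'   ([to_composite]), `fitted`, `residuals`, `rmse`, `ssr`, `n_samples`,
#'   `converged`, `loss_config_used`
#' @export
fit_patient <- function(patient, settings = fit_settings(),
                        return_candidates = FALSE) {
  s <- settings
  meas <- patient$measurements
  if (nrow(meas) < 4) {
    stop("fit_patient needs >= 4 measurements (got ", nrow(meas),
         "); apply the inclusion filter first")
  }
  ga <- patient$ga_days
  stopifnot(is.finite(ga))
  p <- meas$pna_days
  y <- meas$tsb_umol_l
  lower <- c(s$fit_a_lower, s$fit_b_lower, s$fit_c_lower,
             -s$fit_delta_halfwidth)
  upper <- c(s$fit_a_upper, s$fit_b_upper, s$fit_c_upper,
             s$fit_delta_halfwidth)
  starts <- .start_grid(y, s)

  candidates <- list()
  add_candidate <- function(res, label) {
    if (is.null(res)) return(invisible(NULL))
    candidates[[length(candidates) + 1L]] <<- list(
      par = res$par, ssr = decay_ssr(res$par, p, y),
      converged = res$convergence == 0L, label = label)
  }

  # stage 1: plain least squares from every start
  for (k in seq_len(nrow(starts))) {
    add_candidate(.one_optim(starts[k, ], lower, upper, p, y, 0L, 1, s),
                  sprintf("plain/start%02d", k))
  }
  plain_ssr <- vapply(candidates, `[[`, numeric(1), "ssr")
  if (!length(candidates)) {
    stop("all plain least-squares candidates failed for patient ",
         patient$patient_id)
  }
  best_plain <- candidates[[which.min(plain_ssr)]]

  # stage 2: smooth-L1 at scales adapted to the initial residual spread
  resid0 <- y - .eval_theta(best_plain$par, p)
  mad0 <- mad(resid0)
  if (mad0 > 0 && is.finite(mad0)) {
    for (f in s$fit_scale_factors) {
      scale <- f * mad0
      for (k in seq_len(nrow(starts))) {
        add_candidate(
          .one_optim(starts[k, ], lower, upper, p, y, 1L, scale, s),
          sprintf("soft_l1/s=%.4g/start%02d", scale, k))
      }
    }
  }

  ssr <- vapply(candidates, `[[`, numeric(1), "ssr")
  best <- candidates[[which.min(ssr)]]  # which.min: first minimum wins ties

  # final polish: plain refinement from the winner (never raises the SSR)
  pol <- .one_optim(best$par, lower, upper, p, y, 0L, 1, s)
  if (!is.null(pol) && decay_ssr(pol$par, p, y) <= best$ssr) {
    best <- list(par = pol$par, ssr = decay_ssr(pol$par, p, y),
                 converged = pol$convergence == 0L, label = best$label)
  }

  th <- best$par
  converged <- best$converged || .stationary(th, p, y, lower, upper)
  params <- decay_parameters(A = th[1], B = th[2], C = th[3],
                             Tc = th[4] - ga, ga_days = ga)
  fitted <- eval_patient_specific(params, p)
  out <- structure(list(
    patient_id = patient$patient_id,
    params = params,
    composite = to_composite(params),
    fitted = fitted,
    residuals = y - fitted,
    rmse = sqrt(best$ssr / length(y)),
    ssr = best$ssr,
    n_samples = length(y),
    converged = converged,
    loss_config_used = best$label), class = "tsb_fit")
  if (return_candidates) {
    out$candidates <- lapply(candidates, function(cc) {
      list(params = decay_parameters(A = cc$par[1], B = cc$par[2],
                                     C = cc$par[3], Tc = cc$par[4] - ga,
                                     ga_days = ga),
           ssr = cc$ssr, label = cc$label)
    })
  }
  out
}

# evaluate theta = (A, B, C, delta) at postnatal ages p
.eval_theta <- function(th, p) th[1] * exp(-th[2] * (p + th[4])) + th[3]

# first-order optimality at theta under box constraints: the bound-projected
# gradient of the plain SSR vanishes relative to the cost scale. L-BFGS-B's
# exit code alone is too pessimistic at tight tolerances (its line search can
# stop one ulp short of a solution that is already stationary).
.stationary <- function(th, p, y, lower, upper, tol = 1e-3) {
  g <- decay_grad(th, p, y, 0L, 1)
  at_lo <- th <= lower + 1e-10
  at_hi <- th >= upper - 1e-10
  g[at_lo] <- pmin(g[at_lo], 0)
  g[at_hi] <- pmax(g[at_hi], 0)
  max(abs(g)) <= tol * (1 + decay_ssr(th, p, y))
}

#' @export
print.tsb_fit <- function(x, ...) {
  cat(sprintf(
    "<tsb_fit> %s: A=%.3g B=%.3g C=%.3g Tc=%.4g (Atilde=%.4g) rmse=%.3g [%s]\n",
    x$patient_id, x$params$A, x$params$B, x$params$C, x$params$Tc,
    x$composite$amplitude_tilde, x$rmse, x$loss_config_used))
  invisible(x)
}

#' Fit the patient-specific model for every patient of a cohort
#'
#' @param cohort a `tsb_cohort` (normally the output of [retained_cohort])
#' @param settings a [fit_settings] list
#' @return list of `tsb_fit` objects (class `tsb_fits`), one per patient;
#'   per-patient failures are collected as `converged = FALSE` stubs rather
#'   than aborting the cohort
#' @export
fit_cohort <- function(cohort, settings = fit_settings()) {
  fits <- lapply(cohort$patients$patient_id, function(id) {
    tryCatch(fit_patient(patient_record(cohort, id), settings),
             error = function(e) {
               warning("fit failed for ", id, ": ", conditionMessage(e),
                       call. = FALSE)
               structure(list(patient_id = id, params = NULL,
                              composite = NULL, fitted = NULL,
                              residuals = NULL, rmse = NA_real_,
                              ssr = NA_real_, n_samples = NA_integer_,
                              converged = FALSE,
                              loss_config_used = "failed"),
                         class = "tsb_fit")
             })
  })
  names(fits) <- cohort$patients$patient_id
  structure(fits, class = "tsb_fits")
}

#' Tabulate cohort fits
#'
#' @param x a `tsb_fits` list
#' @param ... unused
#' @return data frame in the `fits.csv` schema: `patient_id, A, B, C, Tc,
#'   ga_days, amplitude_tilde, rmse, ssr, n_samples, converged,
#'   loss_config_used`
#' @export
as.data.frame.tsb_fits <- function(x, ...) {
  do.call(rbind, lapply(x, function(f) {
    if (is.null(f$params)) {
      return(data.frame(
        patient_id = f$patient_id, A = NA_real_, B = NA_real_, C = NA_real_,
        Tc = NA_real_, ga_days = NA_real_, amplitude_tilde = NA_real_,
        rmse = NA_real_, ssr = NA_real_, n_samples = NA_integer_,
        converged = FALSE, loss_config_used = f$loss_config_used))
    }
    data.frame(
      patient_id = f$patient_id, A = f$params$A, B = f$params$B,
      C = f$params$C, Tc = f$params$Tc, ga_days = f$params$ga_days,
      amplitude_tilde = f$composite$amplitude_tilde, rmse = f$rmse,
      ssr = f$ssr, n_samples = f$n_samples, converged = f$converged,
      loss_config_used = f$loss_config_used)
  }))
}

#' Fit the population-level linear decay model
#'
#' Ordinary least squares of TSB on postnatal age over pooled samples.
#'
#' @param samples data frame with `pna_days` and `tsb_umol_l`
#' @return list with `params` (`intercept_A`, `slope_B`), `fitted`,
#'   `residuals`, `rmse`, `ssr`, `n_samples`
#' @export
fit_linear_population <- function(samples) {
  stopifnot(nrow(samples) >= 2)
  if (length(unique(samples$pna_days)) < 2) {
    stop("rank-deficient design: all postnatal ages identical")
  }
  fit <- lm(tsb_umol_l ~ pna_days, data = samples)
  res <- unname(residuals(fit))
  list(params = list(intercept_A = unname(coef(fit)[1]),
                     slope_B = unname(coef(fit)[2])),
       fitted = unname(fitted(fit)), residuals = res,
       rmse = sqrt(mean(res^2)), ssr = sum(res^2),
       n_samples = nrow(samples))
}

#' Fit the population-level general exponential decay model
#'
#' Nonlinear least squares of `A * exp(-B * t) + C` with `B >= 0`, by
#' bounded multi-start optimisation.
#'
#' @param samples data frame with `pna_days` and `tsb_umol_l`
#' @param settings a [fit_settings] list
#' @param a_upper,c_upper finite optimisation boxes for A and C, umol/L
#' @return list with `params` (`A`, `B`, `C`), `fitted`, `residuals`,
#'   `rmse`, `ssr`, `n_samples`, `converged`
#' @export
fit_exponential_population <- function(samples, settings = fit_settings(),
                                       a_upper = 1000, c_upper = 1000) {
  s <- settings
  stopifnot(nrow(samples) >= 4)
  p <- samples$pna_days
  y <- samples$tsb_umol_l
  lower <- c(0, 0, 0, 0)
  upper <- c(a_upper, 5, c_upper, 0)  # delta pinned at 0 reduces to Eq. 2
  a_starts <- unique(c(max(y) - min(y), max(y)))
  starts <- as.matrix(expand.grid(A = a_starts,
                                  B = unique(c(0.01, s$fit_b_starts)),
                                  C = unique(c(0, min(y))),
                                  delta = 0, KEEP.OUT.ATTRS = FALSE))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    res <- .one_optim(starts[k, ], lower, upper, p, y, 0L, 1, s)
    if (is.null(res)) next
    ssr_k <- decay_ssr(res$par, p, y)
    if (is.null(best) || ssr_k < best$ssr) {
      best <- list(par = res$par, ssr = ssr_k,
                   converged = res$convergence == 0L)
    }
  }
  if (is.null(best)) {
    return(list(params = list(A = NA_real_, B = NA_real_, C = NA_real_),
                fitted = NULL, residuals = NULL, rmse = NA_real_,
                ssr = NA_real_, n_samples = length(y), converged = FALSE))
  }
  fitted <- .eval_theta(best$par, p)
  list(params = list(A = unname(best$par[1]), B = unname(best$par[2]),
                     C = unname(best$par[3])),
       fitted = fitted, residuals = y - fitted,
       rmse = sqrt(best$ssr / length(y)), ssr = best$ssr,
       n_samples = length(y), converged = best$converged)
}

#' Brute-force SSR lower bound over a parameter grid
#'
#' Independent check of fit quality: evaluates the plain SSR of the
#' patient-specific model over a dense regular grid spanning the fitting
#' bounds and returns the minimum. Uses the closed form
#' SSR(A, C | B, delta) over precomputed exponential sums so an 11^4 grid is
#' cheap.
#'
#' @param patient a [patient_record]
#' @param settings a [fit_settings] list (for the bounds)
#' @param n_grid points per parameter axis
#' @return minimum SSR over the grid, umol/L^2
#' @export
grid_ssr_oracle <- function(patient, settings = fit_settings(), n_grid = 11) {
  s <- settings
  p <- patient$measurements$pna_days
  y <- patient$measurements$tsb_umol_l
  a_grid <- seq(s$fit_a_lower, s$fit_a_upper, length.out = n_grid)
  b_grid <- seq(s$fit_b_lower, s$fit_b_upper, length.out = n_grid)
  c_grid <- seq(s$fit_c_lower, s$fit_c_upper, length.out = n_grid)
  d_grid <- seq(-s$fit_delta_halfwidth, s$fit_delta_halfwidth,
                length.out = n_grid)
  sy2 <- sum(y^2); sy <- sum(y); n <- length(y)
  best <- Inf
  for (b in b_grid) for (d in d_grid) {
    e <- exp(-b * (p + d))
    se2 <- sum(e^2); se <- sum(e); sye <- sum(y * e)
    for (a in a_grid) {
      # SSR = sy2 - 2a*sye - 2C*sy + a^2*se2 + 2aC*se + n*C^2, min over grid C
      ssr_c <- sy2 - 2 * a * sye + a^2 * se2 +
        c_grid * (2 * a * se - 2 * sy) + n * c_grid^2
      m <- min(ssr_c)
      if (m < best) best <- m
    }
  }
  best
}
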