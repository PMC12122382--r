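# Population-level analysis of the fitted cohort: parameter summaries and
# histograms, the median model, local one-at-a-time sensitivity sweeps, and
# the descriptive/comparison statistics (Pearson correlation, chi-square,
# Mann-Whitney U with Bonferroni correction).

#' Summarise fitted parameters across a cohort
#'
#' Mean, SD, median, quartiles (linear interpolation, type 7), range and a
#' Freedman-Diaconis histogram per quantity (A, B, C, Tc, rmse).
#'
#' @param fits a `tsb_fits` list or a data frame in the `fits.csv` schema
#' @return list of per-parameter summaries (class `parameter_summary`); each
#'   has `mean, sd, median, q1, q3, min, max, n, breaks, counts` and a
#'   `sd_undefined` flag for single-fit input
#' @export
summarize_parameters <- function(fits) {
  df <- if (is.data.frame(fits)) fits else as.data.frame(fits)
  df <- df[!is.na(df$rmse), , drop = FALSE]
  if (!nrow(df)) stop("no converged fits to summarise")
  out <- lapply(c("A", "B", "C", "Tc", "rmse"), function(v) {
    x <- df[[v]]
    h <- if (length(unique(x)) < 2) {
      # degenerate: a single bin around the common value
      list(breaks = c(x[1] - 0.5, x[1] + 0.5), counts = length(x))
    } else {
      graphics::hist(x, breaks = "FD", plot = FALSE)
    }
    qs <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
    list(parameter = v, n = length(x), mean = mean(x),
         sd = if (length(x) > 1) sd(x) else 0,
         sd_undefined = length(x) <= 1,
         median = qs[2], q1 = qs[1], q3 = qs[3],
         min = min(x), max = max(x),
         breaks = h$breaks, counts = h$counts)
  })
  names(out) <- c("A", "B", "C", "Tc", "rmse")
  structure(out, class = "parameter_summary")
}

#' Tabulate a parameter summary
#'
#' @param x a `parameter_summary`
#' @param ... unused
#' @return data frame (the `summary.csv` schema)
#' @export
as.data.frame.parameter_summary <- function(x, ...) {
  do.call(rbind, lapply(x, function(s) data.frame(
    parameter = s$parameter, n = s$n, mean = s$mean, sd = s$sd,
    median = s$median, q1 = s$q1, q3 = s$q3, min = s$min, max = s$max)))
}

#' Build the median model
#'
#' The across-patient medians of A, B, C and Tc define a single decay curve
#' summarising the cohort; its gestational age is the median `ga_days` of the
#' fitted patients (configurable by passing `ga_days`).
#'
#' @param fits a `tsb_fits` list or `fits.csv`-schema data frame
#' @param ga_days optional gestational age for the median curve, days
#' @return a [decay_parameters] object
#' @export
build_median_model <- function(fits, ga_days = NULL) {
  df <- if (is.data.frame(fits)) fits else as.data.frame(fits)
  df <- df[!is.na(df$A), , drop = FALSE]
  if (!nrow(df)) stop("no fits to build a median model from")
  if (is.null(ga_days)) ga_days <- median(df$ga_days)
  decay_parameters(A = median(df$A), B = median(df$B), C = median(df$C),
                   Tc = median(df$Tc), ga_days = ga_days)
}

#' Local one-at-a-time sensitivity sweep
#'
#' Varies one parameter of the median model over its sweep range while the
#' others stay fixed, and evaluates each curve on a regular postnatal-age
#' grid. Sweep ranges may exceed the fitting bounds (A up to 400, C down to
#' -100) -- the model is simply evaluated there, without clipping.
#'
#' @param median_params a [decay_parameters] (normally [build_median_model])
#' @param parameter one of "A", "B", "C", "Tc"
#' @param range length-2 numeric; defaults: A `[0, 400]`, B `[0, 0.3]`,
#'   C `[-100, 200]`, Tc `[-215, -150]`
#' @param n_grid number of sweep values
#' @param pna_grid postnatal-age grid, days (default 0 to 60 by 0.25)
#' @param config a [load_config] list supplying the defaults
#' @return list (class `sensitivity_sweep`) with `parameter`, `grid`,
#'   `pna_grid` and `curves` (matrix, one row per grid value)
#' @export
sensitivity_sweep <- function(median_params, parameter, range = NULL,
                              n_grid = NULL, pna_grid = NULL,
                              config = load_config()) {
  if (!parameter %in% c("A", "B", "C", "Tc")) {
    stop("unknown parameter '", parameter, "': must be one of A, B, C, Tc")
  }
  if (is.null(range)) range <- config[[paste0("sweep_range_", parameter)]]
  if (is.null(n_grid)) n_grid <- config$sweep_n_grid
  if (is.null(pna_grid)) {
    pna_grid <- seq(0, config$sweep_pna_max, by = config$sweep_pna_step)
  }
  grid <- seq(range[1], range[2], length.out = n_grid)
  curves <- t(vapply(grid, function(v) {
    pars <- median_params
    pars[[parameter]] <- v
    eval_patient_specific(pars, pna_grid)
  }, numeric(length(pna_grid))))
  stopifnot(all(is.finite(curves)))
  structure(list(parameter = parameter, grid = grid, pna_grid = pna_grid,
                 curves = curves), class = "sensitivity_sweep")
}

#' Pearson correlation between TSB and postnatal age
#'
#' @param samples data frame with `pna_days` and `tsb_umol_l` (>= 3 rows,
#'   both coordinates non-constant)
#' @return Pearson r
#' @export
pearson_tsb_pna <- function(samples) {
  stopifnot(nrow(samples) >= 3)
  if (sd(samples$pna_days) == 0 || sd(samples$tsb_umol_l) == 0) {
    stop("zero variance: Pearson correlation undefined")
  }
  cor(samples$pna_days, samples$tsb_umol_l)
}

#' Compare two patient groups variable by variable
#'
#' Categorical variables by chi-square on the group-by-value contingency
#' table (Yates continuity correction for 2x2); continuous variables by the
#' two-sided Mann-Whitney U test (exact when the smaller group has at most 8
#' observations and there are no ties, normal approximation with continuity
#' and tie correction otherwise). Significance at the Bonferroni-adjusted level
#' `base_alpha / n_comparisons`.
#'
#' @param group_a,group_b data frames of per-patient variables
#' @param variables named character vector: names are columns, values are
#'   "categorical" or "continuous"
#' @param n_comparisons total number of comparisons for the Bonferroni
#'   adjustment (an explicit argument: it depends on the full comparison
#'   table, not on the subset passed here)
#' @param base_alpha unadjusted significance level
#' @return data frame `variable, type, test, statistic, p_value,
#'   adjusted_alpha, significant, flag`
#' @export
compare_groups <- function(group_a, group_b, variables, n_comparisons,
                           base_alpha = 0.05) {
  stopifnot(n_comparisons >= 1)
  alpha_adj <- base_alpha / n_comparisons
  rows <- lapply(names(variables), function(v) {
    type <- match.arg(variables[[v]], c("categorical", "continuous"))
    if (!v %in% names(group_a) || !v %in% names(group_b)) {
      stop("variable '", v, "' missing from one of the groups")
    }
    xa <- group_a[[v]][!is.na(group_a[[v]])]
    xb <- group_b[[v]][!is.na(group_b[[v]])]
    flag <- ""
    if (type == "categorical") {
      tab <- table(group = rep(c("a", "b"), c(length(xa), length(xb))),
                   value = c(as.character(xa), as.character(xb)))
      if (ncol(tab) < 2) stop("variable '", v, "' has a single level")
      ht <- suppressWarnings(
        chisq.test(tab, correct = all(dim(tab) == c(2, 2))))
      stat <- unname(ht$statistic); pv <- ht$p.value; test <- "chi_square"
    } else {
      if (length(unique(c(xa, xb))) == 1) {
        stat <- NA_real_; pv <- 1; test <- "mann_whitney"
        flag <- "all_tied"
      } else {
        exact <- min(length(xa), length(xb)) <= 8 &&
          !anyDuplicated(c(xa, xb))
        ht <- suppressWarnings(
          wilcox.test(xa, xb, exact = exact, correct = TRUE))
        stat <- unname(ht$statistic); pv <- ht$p.value
        test <- "mann_whitney"
      }
    }
    data.frame(variable = v, type = type, test = test, statistic = stat,
               p_value = pv, adjusted_alpha = alpha_adj,
               significant = pv < alpha_adj, flag = flag)
  })
  do.call(rbind, rows)
}
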