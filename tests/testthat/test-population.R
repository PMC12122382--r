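# minimal fits table for summary/median tests
fits_df <- function(A, B = 0.1, C = 0, Tc = -195, ga = 196) {
  n <- length(A)
  data.frame(patient_id = sprintf("P%d", seq_len(n)), A = A,
             B = rep_len(B, n), C = rep_len(C, n), Tc = rep_len(Tc, n),
             ga_days = rep_len(ga, n), amplitude_tilde = rep_len(NA_real_, n),
             rmse = rep_len(5, n), ssr = rep_len(100, n),
             n_samples = rep_len(4L, n), converged = rep_len(TRUE, n),
             loss_config_used = rep_len("plain/start01", n))
}

test_that("parameter summaries compute the descriptive statistics", {
  s <- summarize_parameters(fits_df(A = c(100, 120, 140)))
  expect_equal(s$A$mean, 120)
  expect_equal(s$A$median, 120)
  expect_equal(s$A$q1, 110)
  expect_equal(s$A$q3, 130)
  expect_equal(sum(s$A$counts), 3)
  expect_false(s$A$sd_undefined)

  one <- summarize_parameters(fits_df(A = 100))
  expect_equal(one$A$sd, 0)
  expect_true(one$A$sd_undefined)
  expect_error(summarize_parameters(fits_df(A = numeric(0))), "no converged")
})

test_that("summary statistics recover a known generating distribution", {
  set.seed(31)
  n <- 10000
  a <- rnorm(n, 120.9, 27.54)
  s <- summarize_parameters(fits_df(A = a))
  expect_lt(abs(s$A$mean - 120.9), 3 * 27.54 / sqrt(n))
  expect_equal(s$A$sd, sd(a))
  expect_equal(s$A$q1, unname(quantile(a, 0.25, type = 7)))
})

test_that("median model takes coordinate-wise medians", {
  df <- fits_df(A = c(100, 120, 140), B = 0.1, C = c(0, 0, 30),
                Tc = c(-190, -195, -200), ga = c(190, 196, 200))
  med <- build_median_model(df)
  expect_equal(med$A, 120)
  expect_equal(med$B, 0.1)
  expect_equal(med$C, 0)
  expect_equal(med$Tc, -195)
  expect_equal(med$ga_days, 196)

  single <- build_median_model(fits_df(A = 111, B = 0.2, C = 3, Tc = -180))
  expect_equal(single$A, 111)
  expect_equal(single$B, 0.2)

  # the median model is itself a valid decaying curve
  curve <- eval_patient_specific(med, seq(0, 60, 0.25))
  expect_true(all(is.finite(curve)))
  expect_true(all(diff(curve) < 0))
})

test_that("sensitivity sweeps reproduce the analytic parameter effects", {
  med <- decay_parameters(A = 120, B = 0.11, C = 5, Tc = -193, ga_days = 196)
  pna <- seq(0, 60, 0.25)

  swC <- sensitivity_sweep(med, "C", range = c(0, 50), n_grid = 2,
                           pna_grid = pna)
  expect_equal(swC$curves[2, ] - swC$curves[1, ], rep(50, length(pna)))

  # Tc shift identity: curve(Tc - d) at p equals curve(Tc) at p - d
  d <- 5
  swT <- sensitivity_sweep(med, "Tc", range = c(med$Tc - d, med$Tc),
                           n_grid = 2, pna_grid = pna)
  keep <- pna >= d
  ref <- sensitivity_sweep(med, "Tc", range = c(med$Tc, med$Tc), n_grid = 2,
                           pna_grid = pna - d)
  expect_equal(swT$curves[1, keep], ref$curves[1, keep], tolerance = 1e-9)

  # larger B lowers the curve wherever p + ga + Tc > 0
  swB <- sensitivity_sweep(med, "B", range = c(0.05, 0.3), n_grid = 4,
                           pna_grid = pna)
  pos <- pna + med$ga_days + med$Tc > 0
  for (k in 2:4) {
    expect_true(all(swB$curves[k, pos] < swB$curves[k - 1, pos]))
  }

  # larger A raises the curve pointwise
  swA <- sensitivity_sweep(med, "A", range = c(0, 400), n_grid = 5,
                           pna_grid = pna)
  expect_true(all(diff(swA$curves[, 10]) > 0))

  # defaults come from the configuration; unknown parameters error
  swdef <- sensitivity_sweep(med, "B")
  expect_equal(range(swdef$grid), c(0, 0.3))
  expect_error(sensitivity_sweep(med, "GA"), "unknown parameter")
})

test_that("Pearson correlation matches its closed form", {
  expect_equal(pearson_tsb_pna(
    data.frame(pna_days = 0:10, tsb_umol_l = 200 - 4 * (0:10))), -1)
  expect_equal(pearson_tsb_pna(
    data.frame(pna_days = 0:10, tsb_umol_l = 5 * (0:10))), 1)
  r <- pearson_tsb_pna(
    data.frame(pna_days = 0:3, tsb_umol_l = c(0, 1, 0, 1)))
  expect_equal(r, 1 / sqrt(5))
  expect_error(pearson_tsb_pna(
    data.frame(pna_days = 1:3, tsb_umol_l = rep(7, 3))), "zero variance")
})

test_that("group comparisons run the declared tests with Bonferroni control", {
  a <- data.frame(sex = rep(c("F", "M"), each = 10), weight = 1:20)
  b <- data.frame(sex = rep(c("F", "M"), each = 10), weight = 1:20 + 0.5)
  out <- compare_groups(a, b, c(sex = "categorical", weight = "continuous"),
                        n_comparisons = 20)
  expect_equal(out$adjusted_alpha, rep(0.05 / 20, 2))
  # balanced 2x2 table: no association
  chi <- out[out$variable == "sex", ]
  expect_equal(chi$statistic, 0)
  expect_equal(chi$p_value, 1)

  # exact Mann-Whitney on fully separated small groups
  mw <- compare_groups(data.frame(x = c(1, 2, 3)),
                       data.frame(x = c(4, 5, 6)),
                       c(x = "continuous"), n_comparisons = 1)
  expect_equal(mw$p_value, 0.1)
  expect_equal(mw$test, "mann_whitney")

  # a cohort compared with itself is never significant
  self <- compare_groups(a, a, c(sex = "categorical", weight = "continuous"),
                         n_comparisons = 2)
  expect_true(all(self$p_value >= 0.99))

  tied <- compare_groups(data.frame(x = rep(1, 5)),
                         data.frame(x = rep(1, 6)),
                         c(x = "continuous"), n_comparisons = 1)
  expect_equal(tied$p_value, 1)
  expect_equal(tied$flag, "all_tied")

  expect_error(compare_groups(a, b, c(ga = "continuous"), 1), "missing")
})
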