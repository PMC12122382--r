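test_that("minimum-sample rule uses the 'fewer than' boundary", {
  expect_false(check_min_samples(make_patient(pna = c(4, 6, 8)), 4))
  expect_true(check_min_samples(make_patient(pna = c(4, 6, 8, 10)), 4))
  expect_true(check_min_samples(make_patient(pna = seq(4, 42, 2)), 4))
})

test_that("monitoring-gap rule fails only on gaps strictly over the limit", {
  expect_false(check_monitoring_gap(make_patient(pna = c(4, 5, 6, 20)), 10))
  expect_true(check_monitoring_gap(make_patient(pna = c(4, 14, 24, 34)), 10))
  expect_true(check_monitoring_gap(make_patient(pna = c(4, 4.5, 5, 6)), 10))
  expect_error(check_monitoring_gap(make_patient(pna = 4), 10),
               "minimum-sample")
})

test_that("treatment stripping removes samples in closed intervals", {
  p <- make_patient(pna = c(1, 3, 4, 8, 10, 12),
                    treatments = data.frame(kind = "PT", start_pna_days = 2,
                                            end_pna_days = 5))
  st <- strip_treatment_samples(p)
  expect_equal(st$removed$pna_days, c(3, 4))
  expect_equal(st$retained$pna_days, c(1, 8, 10, 12))
  expect_equal(unique(st$removed$removal_cause), "PT")

  # boundary: a sample exactly at the interval end is removed
  p2 <- make_patient(pna = c(2, 5, 8, 11),
                     treatments = data.frame(kind = "ET", start_pna_days = 3,
                                             end_pna_days = 5))
  expect_equal(strip_treatment_samples(p2)$removed$pna_days, 5)

  # no treatments: nothing removed
  st3 <- strip_treatment_samples(make_patient())
  expect_equal(nrow(st3$removed), 0)
})

# hand-evaluated five-patient fixture covering each exclusion reason, a clean
# inclusion and a boundary phototherapy case keeping exactly 4 samples
filter_fixture <- function() {
  make_cohort(list(
    list(id = "F1", pna = c(4, 6, 8)),                       # too few
    list(id = "F2", pna = c(4, 5, 6, 20, 22)),               # gap 14 > 10
    list(id = "F3", pna = c(4, 5, 6, 7, 8),                  # 2 left post-strip
         treatments = data.frame(kind = "PT", start_pna_days = 4.5,
                                 end_pna_days = 7.5)),
    list(id = "F4", pna = c(4, 6, 8, 10, 12, 14)),           # clean
    list(id = "F5", pna = c(4, 5, 6, 8, 10, 12),             # exactly 4 left
         treatments = data.frame(kind = "PT", start_pna_days = 4.5,
                                 end_pna_days = 6))))
}

test_that("inclusion cascade matches the hand-evaluated fixture", {
  out <- suppressMessages(apply_inclusion_pipeline(filter_fixture()))
  rep <- as.data.frame(out)
  expect_equal(rep$status,
               c("excluded", "excluded", "excluded", "included", "included"))
  expect_equal(rep$primary_reason,
               c("too_few_samples", "infrequent_monitoring",
                 "too_few_after_treatment_removal", "none", "none"))
  # retained counts surviving sample-level removal, whatever the status
  expect_equal(rep$n_retained, c(3, 5, 2, 6, 4))
  expect_equal(out$F3$retained_measurements$pna_days, c(4, 8))
  expect_equal(out$F5$retained_measurements$pna_days, c(4, 8, 10, 12))
  expect_equal(out$F5$removed_measurements$pna_days, c(5, 6))
})

test_that("every measurement lands in retained or removed exactly once", {
  co <- filter_fixture()
  out <- suppressMessages(apply_inclusion_pipeline(co))
  for (id in paste0("F", 1:5)) {
    o <- out[[id]]
    total <- sort(c(o$retained_measurements$pna_days,
                    o$removed_measurements$pna_days))
    orig <- sort(co$measurements$pna_days[co$measurements$patient_id == id])
    expect_equal(total, orig)
  }
  rep <- as.data.frame(out)
  expect_equal(sum(rep$status == "included") + sum(rep$status == "excluded"),
               length(co))
})

test_that("pipeline is idempotent on the retained cohort", {
  co <- filter_fixture()
  out <- suppressMessages(apply_inclusion_pipeline(co))
  sub <- retained_cohort(co, out)
  out2 <- suppressMessages(apply_inclusion_pipeline(sub))
  rep2 <- as.data.frame(out2)
  expect_true(all(rep2$status == "included"))
  expect_identical(sub$measurements,
                   retained_cohort(sub, out2)$measurements)
})

test_that("tightening the gap limit never admits more patients", {
  gen <- gen_quiet(n_patients = 20L, seed = 55L, schedule_max_gap_days = 14,
                   pt_fraction = 0.3)
  counts <- vapply(c(14, 10, 6, 3), function(g) {
    cfg <- load_config(); cfg$max_gap_days <- g
    rep <- as.data.frame(
      suppressMessages(apply_inclusion_pipeline(gen$cohort, cfg)))
    sum(rep$status == "included")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("edge cohorts pass through the filter cleanly", {
  empty <- gen_quiet(n_patients = 0L, seed = 1L)
  expect_length(suppressMessages(apply_inclusion_pipeline(empty$cohort)), 0)
  dense <- make_cohort(list(list(id = "D1", pna = c(4, 6, 8, 10)),
                            list(id = "D2", pna = c(5, 7, 9, 11))))
  rep <- as.data.frame(suppressMessages(apply_inclusion_pipeline(dense)))
  expect_true(all(rep$status == "included"))
})

test_that("gap check honours the configured stage", {
  # gap appears only after stripping: pre-strip passes, post-strip fails
  co <- make_cohort(list(list(
    id = "G1", pna = c(4, 10, 16, 18, 20, 22),
    treatments = data.frame(kind = "PT", start_pna_days = 9,
                            end_pna_days = 11))))
  pre <- as.data.frame(suppressMessages(apply_inclusion_pipeline(co)))
  expect_equal(pre$status, "included")
  cfg <- load_config(); cfg$gap_check_stage <- "post_strip"
  post <- as.data.frame(suppressMessages(apply_inclusion_pipeline(co, cfg)))
  expect_equal(post$primary_reason, "infrequent_monitoring")
})
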