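iv_fixture <- function(..., landmark = as.Date("2009-09-15"),
                       patient_id = "P1") {
  entries <- list(...)
  base <- list(
    second_surgery = list(present = FALSE, evidence_date = NULL,
                          evidence_window = NULL),
    second_radiation = list(present = FALSE, evidence_date = NULL,
                            evidence_window = NULL),
    second_chemo = list(present = FALSE, evidence_date = NULL,
                        evidence_window = NULL),
    re_imaging = list(present = FALSE, evidence_date = NULL,
                      evidence_window = NULL),
    re_biopsy = list(present = FALSE, evidence_date = NULL,
                     evidence_window = NULL),
    visit_cluster = list(present = FALSE, evidence_date = NULL,
                         evidence_window = NULL),
    died = list(present = FALSE, evidence_date = NULL,
                evidence_window = NULL, undated = TRUE),
    died_of_breast_cancer = list(present = FALSE, evidence_date = NULL,
                                 evidence_window = NULL, undated = TRUE),
    stage_III = list(present = FALSE, evidence_date = NULL,
                     evidence_window = NULL, undated = TRUE))
  base[names(entries)] <- entries
  structure(c(list(patient_id = patient_id, landmark_date = landmark), base),
            class = "indicator_vector")
}

test_that("dated and window triggers produce the stated dates", {
  b <- make_baseline()
  iv <- iv_fixture(second_surgery = list(
    present = TRUE, evidence_date = as.Date("2010-05-01"),
    evidence_window = NULL))
  expect_equal(assign_recurrence_date("second_surgery", iv, b),
               as.Date("2010-05-01"))

  # window midpoint: start + floor((end - start)/2)
  iv <- iv_fixture(visit_cluster = list(
    present = TRUE, evidence_date = NULL,
    evidence_window = as.Date(c("2010-01-01", "2010-03-01"))))
  expect_equal(assign_recurrence_date("visit_cluster", iv, b),
               as.Date("2010-01-30"))

  # degenerate single-day window
  iv <- iv_fixture(visit_cluster = list(
    present = TRUE, evidence_date = NULL,
    evidence_window = as.Date(c("2010-02-02", "2010-02-02"))))
  expect_equal(assign_recurrence_date("visit_cluster", iv, b),
               as.Date("2010-02-02"))

  expect_error(assign_recurrence_date("second_chemo", iv, b), "not present")
})

test_that("undated triggers fall back to dated evidence, death, then midpoint", {
  b <- make_baseline(death_date = as.Date("2012-06-01"),
                     last_contact_date = as.Date("2012-06-01"),
                     death_cause = "breast_cancer")
  # earliest dated evidence wins
  iv <- iv_fixture(
    died_of_breast_cancer = list(present = TRUE,
                                 evidence_date = as.Date("2012-06-01"),
                                 evidence_window = NULL, undated = TRUE),
    re_imaging = list(present = TRUE, evidence_date = as.Date("2011-02-01"),
                      evidence_window = NULL),
    second_chemo = list(present = TRUE, evidence_date = as.Date("2011-04-01"),
                        evidence_window = NULL))
  expect_equal(assign_recurrence_date("died_of_breast_cancer", iv, b),
               as.Date("2011-02-01"))
  # no dated evidence: death date
  iv <- iv_fixture(died = list(present = TRUE,
                               evidence_date = as.Date("2012-06-01"),
                               evidence_window = NULL, undated = TRUE))
  expect_equal(assign_recurrence_date("died", iv, b), as.Date("2012-06-01"))
  # neither: midpoint of [landmark, last_contact]
  b2 <- make_baseline(stage = "III")
  iv <- iv_fixture(stage_III = list(present = TRUE, evidence_date = NULL,
                                    evidence_window = NULL, undated = TRUE))
  lm <- as.Date("2009-09-15")
  expected <- lm + floor(as.numeric(b2$last_contact_date - lm) / 2)
  expect_equal(assign_recurrence_date("stage_III", iv, b2), expected)
  # no usable window at all: dating error
  b3 <- make_baseline(stage = "III", last_contact_date = as.Date("2008-06-01"))
  expect_error(assign_recurrence_date("stage_III", iv, b3), "cannot date")
})

test_that("survival records count calendar days from the correct origin", {
  b <- make_baseline(surgery_date = as.Date("2008-01-01"))
  r <- build_survival_record(b, list(predicted_recurred = TRUE,
                                     estimated_recurrence_date = as.Date("2009-01-01")))
  expect_equal(r$time_days, 366)  # 2008 is a leap year
  expect_true(r$event)
  expect_equal(r$origin, "surgery")

  b <- make_baseline(surgery_date = as.Date("2008-01-01"),
                     last_contact_date = as.Date("2012-01-01"))
  r <- build_survival_record(b, list(predicted_recurred = FALSE,
                                     estimated_recurrence_date = as.Date(NA)))
  expect_equal(r$time_days, 1461)
  expect_false(r$event)

  # no surgery: diagnosis-date origin
  b <- make_baseline(surgery_date = as.Date(NA), surgery_type = "none",
                     diagnosis_date = as.Date("2008-02-01"))
  r <- build_survival_record(b, list(predicted_recurred = TRUE,
                                     estimated_recurrence_date = as.Date("2008-12-01")))
  expect_equal(r$origin, "diagnosis")
  expect_equal(r$time_days, 304)

  expect_error(
    build_survival_record(b, list(predicted_recurred = TRUE,
                                  estimated_recurrence_date = as.Date("2007-01-01"))),
    "precedes")
})

test_that("cohort-level calls are total, dated, and landmark-consistent", {
  co <- sim_small(150, seed = 6)
  im <- build_indicator_matrix(co)
  tree <- fit_tree(im$matrix, labels_for_matrix(co, im), tree_config())
  res <- call_cohort(co, tree)
  expect_equal(nrow(res$calls), 150)
  expect_equal(nrow(res$survival), 150)
  expect_equal(res$n_flagged, sum(res$calls$predicted_recurred))

  # every recurrent call has a date (dating totality)
  rec <- res$calls[res$calls$predicted_recurred, ]
  expect_false(any(is.na(rec$estimated_recurrence_date)))
  # and the RFS of surgery-origin recurrent calls respects the 180-day floor
  surv <- res$survival
  rec_surg <- surv$event & surv$origin == "surgery"
  expect_true(all(surv$time_days[rec_surg] >= 180))
  expect_true(all(surv$time_days >= 0))
  # event flag mirrors the call
  expect_equal(surv$event,
               res$calls$predicted_recurred[match(surv$patient_id,
                                                  res$calls$patient_id)])

  # permuting event rows leaves every estimated date unchanged
  co2 <- co
  set.seed(99)
  co2$events <- co2$events[sample(nrow(co2$events)), ]
  res2 <- call_cohort(co2, tree)
  expect_equal(res2$calls, res$calls)
})

test_that("gold survival mirrors chart-review labels", {
  co <- sim_small(80, seed = 14)
  gs <- gold_survival(co)
  l <- co$labels[match(gs$patient_id, co$labels$patient_id), ]
  expect_equal(gs$event, l$recurred)
  b <- co$baselines[match(gs$patient_id, co$baselines$patient_id), ]
  i <- which(l$recurred)[1]
  expect_equal(gs$time_days[i],
               as.numeric(l$recurrence_date[i] - b$surgery_date[i]))
})
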