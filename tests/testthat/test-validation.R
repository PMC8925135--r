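calls_df <- function(ids, flagged, dates = as.Date(NA)) {
  data.frame(patient_id = ids, predicted_recurred = flagged,
             estimated_recurrence_date = dates,
             triggering_indicator = NA_character_, stringsAsFactors = FALSE)
}

test_that("confusion metrics follow their defining identities", {
  ids <- sprintf("P%03d", 1:100)
  gold <- make_labels(ids, c(rep(TRUE, 30), rep(FALSE, 70)))
  # perfect calls
  cm <- confusion_metrics(calls_df(ids, gold$recurred), gold)
  expect_equal(cm$sensitivity, 100.0)
  expect_equal(cm$specificity, 100.0)
  expect_equal(cm$accuracy, 100.0)
  # shuffled patient order must not matter
  perm <- sample(100)
  cm2 <- confusion_metrics(calls_df(ids, gold$recurred)[perm, ], gold)
  expect_equal(cm2$tp, cm$tp)

  # constructed mixed calls checked against hand counts
  flagged <- c(rep(TRUE, 24), rep(FALSE, 6), rep(TRUE, 10), rep(FALSE, 60))
  cm <- confusion_metrics(calls_df(ids, flagged), gold)
  expect_equal(c(cm$tp, cm$fn, cm$fp, cm$tn), c(24, 6, 10, 60))
  expect_equal(cm$sensitivity, 80.0)
  expect_equal(cm$ppv, round(100 * 24 / 34, 1))
  expect_equal(cm$n_flagged + cm$n_censored, 100)

  expect_error(confusion_metrics(calls_df(ids[-1], flagged[-1]), gold),
               "same patients")
})

test_that("reconstructed confusion matrices round-trip printed metrics", {
  # metrics derived from the reconstructed integers agree with the inputs
  set.seed(5)
  for (i in 1:40) {
    n_pos <- sample(50:300, 1); n_neg <- sample(100:600, 1)
    tp <- sample(0:n_pos, 1); tn <- sample(0:n_neg, 1)
    sens <- round(100 * tp / n_pos, 1); spec <- round(100 * tn / n_neg, 1)
    cm <- reconstruct_confusion(sens, spec, n_pos, n_neg)
    expect_equal(cm$sensitivity, sens, tolerance = 0.051)
    expect_equal(cm$specificity, spec, tolerance = 0.051)
    expect_equal(cm$tp + cm$fn, n_pos)
    expect_equal(cm$tn + cm$fp, n_neg)
  }
  cm <- reconstruct_confusion(100, 100, 25, 75)
  expect_equal(c(cm$tp, cm$tn, cm$fp, cm$fn), c(25, 75, 0, 0))
  expect_equal(cm$accuracy, 100.0)
})

test_that("timing agreement bins differences and absorbs missed patients", {
  ids <- sprintf("P%02d", 1:10)
  gold_dates <- as.Date("2010-01-01") + (0:9) * 30
  gold <- make_labels(ids, rep(TRUE, 10), gold_dates)
  # exact dates: everything in the <=1 bin
  tab <- timing_agreement(calls_df(ids, TRUE, gold_dates), gold)
  expect_equal(tab$n, c(10, 0, 0, 0, 0))
  expect_equal(tab$cum_pct[1], 100.0)

  # constructed offsets land in known bins; one missed patient goes to >6
  offs <- c(10, 20, 40, 50, 70, 100, 150, 200, 300, 0)
  calls <- calls_df(ids, c(rep(TRUE, 9), FALSE), gold_dates + offs)
  tab <- timing_agreement(calls, gold)
  # 30.4375-day months: 10,20 <=1; 40,50 in (1,2]; 70 in (2,3]; 100,150 in
  # (3,6]; 200,300 > 6; plus the missed patient
  expect_equal(tab$n, c(2, 2, 1, 2, 3))
  expect_equal(tab$cum_n, cumsum(tab$n))
  expect_equal(tab$cum_n[5], attr(tab, "n_total"))
  expect_true(all(diff(tab$cum_n) >= 0))
  expect_equal(tab$cum_pct[5], 100.0)
})

test_that("rank-sum comparison matches exact permutation enumeration", {
  expect_gte(compare_rfs_lengths(c(3, 1, 4, 1, 5), c(3, 1, 4, 1, 5)), 0.99)
  # strongly shifted samples
  set.seed(11)
  a <- rnorm(50, 0); b <- rnorm(50, 30)
  expect_lt(compare_rfs_lengths(a, b), 0.001)
  # n=8 vs n=8 against full enumeration
  for (i in 1:5) {
    x <- round(rexp(8, 1 / 400)); y <- round(rexp(8, 1 / 600))
    if (anyDuplicated(c(x, y))) next
    expect_equal(compare_rfs_lengths(x, y), oracle_ranksum_exact_p(x, y),
                 tolerance = 0.01)
  }
  expect_error(compare_rfs_lengths(numeric(0), 1:3), "non-empty")
})

test_that("Kaplan-Meier estimates match hand-computed product limits", {
  # no censoring: the empirical survivor function
  rec <- data.frame(time_days = c(100, 200, 300, 400), event = TRUE)
  km <- km_curve(rec)
  expect_equal(km$steps$surv, c(0.75, 0.5, 0.25, 0))
  # all censored: flat at 1
  rec <- data.frame(time_days = c(100, 200), event = FALSE)
  expect_true(all(km_curve(rec)$steps$surv == 1))
  # mixed 6-record fixture, hand-computed product-limit values
  rec <- data.frame(time_days = c(2, 4, 6, 8, 10, 12),
                    event = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  km <- km_curve(rec)
  ev <- km$steps[km$steps$n_event > 0, ]
  expect_equal(ev$time, c(2, 6, 8, 12))
  expect_equal(ev$surv, c(5/6, 5/6 * 3/4, 5/6 * 3/4 * 2/3,
                          5/6 * 3/4 * 2/3 * 0), tolerance = 1e-12)
  expect_error(km_curve(data.frame(time_days = -1, event = TRUE)), "negative")
})

test_that("log-rank test matches the textbook O-E/V statistic", {
  a <- data.frame(time_days = c(10, 25, 40, 70, 90), event = c(1, 1, 0, 1, 0) == 1)
  b <- data.frame(time_days = c(15, 30, 55, 80, 95), event = c(1, 0, 1, 1, 1) == 1)
  lr <- logrank(a, b)
  want <- oracle_logrank_chisq(a$time_days, a$event, b$time_days, b$event)
  expect_equal(lr$chisq, want, tolerance = 1e-8)
  expect_equal(lr$p, pchisq(want, 1, lower.tail = FALSE))
  # identical groups: p near 1
  expect_gte(logrank(a, a)$p, 0.99)
  # strongly separated exponentials
  set.seed(21)
  g1 <- data.frame(time_days = rexp(100, 1), event = TRUE)
  g2 <- data.frame(time_days = rexp(100, 4), event = TRUE)
  expect_lt(logrank(g1, g2)$p, 0.001)
  # invariance to patient ordering
  expect_equal(logrank(a[c(3, 1, 5, 2, 4), ], b)$chisq, lr$chisq)
})

test_that("Cox concordance recovers planted effects and degenerate identity", {
  # identical datasets: perfect concordance
  co <- sim_small(150, seed = 17)
  gs <- gold_survival(co)
  covs <- baseline_covariates(co)
  # small cohort: some coefficients are expected to diverge and be excluded
  cc <- suppressWarnings(cox_concordance(gs, gs, covs))
  expect_equal(cc$direction_match_fraction, 1)
  expect_equal(cc$significance_match_fraction, 1)

  # single binary covariate with planted log-hazard 0.7 at n=1000
  set.seed(31)
  n <- 1000
  x <- runif(n) < 0.5
  t <- rexp(n, rate = 0.001 * exp(0.7 * x))
  cens <- runif(n, 0, 2000)
  dat <- data.frame(patient_id = as.character(1:n),
                    time_days = pmin(t, cens), event = t <= cens)
  cv <- data.frame(patient_id = as.character(1:n),
                   exposure = factor(ifelse(x, "yes", "no"), c("no", "yes")))
  fit <- recurfs:::fit_cox_summary(dat, cv)
  expect_equal(fit$hr, exp(0.7), tolerance = 0.2)
})

test_that("characteristic comparisons pick the right test", {
  d <- data.frame(g = rep(c("a", "b"), each = 100),
                  cat = c(rep(c("x", "y"), c(20, 80)), rep(c("x", "y"), c(50, 50))),
                  cont = c(rnorm(100, 5), rnorm(100, 5)))
  out <- compare_characteristics(d, "g", c(cat = "categorical"))
  expect_equal(out$test, "chisq")
  expect_lt(out$p, 0.001)
  # identical categorical distributions: p = 1
  d2 <- data.frame(g = rep(c("a", "b"), each = 40),
                   cat = rep(rep(c("x", "y"), each = 20), 2))
  expect_equal(compare_characteristics(d2, "g", c(cat = "categorical"))$p, 1)
  # sparse table switches to Fisher
  d3 <- data.frame(g = rep(c("a", "b"), each = 8),
                   cat = c(rep("x", 7), "y", rep("y", 7), "x"))
  expect_equal(compare_characteristics(d3, "g", c(cat = "categorical"))$test,
               "fisher")
  expect_error(compare_characteristics(d, "g", c(nope = "categorical")),
               "not found")
})

test_that("the validation report bundles every section per operating point", {
  co <- sim_small(200, seed = 23)
  im <- build_indicator_matrix(co)
  trees <- fit_operating_points(im$matrix, labels_for_matrix(co, im))
  rep <- validation_report(co, trees)
  for (op in names(trees)) {
    sec <- rep[[op]]
    expect_s3_class(sec$confusion, "confusion_metrics")
    expect_s3_class(sec$agreement, "agreement_table")
    expect_true(is.numeric(sec$rfs_wilcoxon_p))
    expect_true(is.list(sec$km_algorithm) && is.list(sec$km_gold))
    expect_true(is.numeric(sec$logrank$p))
    expect_s3_class(sec$cox, "concordance_report")
    expect_true(is.data.frame(sec$characteristics))
    # censored count identity
    expect_equal(sec$n_censored, nrow(co$baselines) - sec$n_flagged)
    # metrics equal independent recomputation from the calls table
    g <- co$labels$recurred[match(sec$calls$patient_id, co$labels$patient_id)]
    p <- sec$calls$predicted_recurred
    expect_equal(sec$confusion$tp, sum(p & g))
    expect_equal(sec$confusion$tn, sum(!p & !g))
  }
  dir <- withr::local_tempdir()
  write_validation_report(rep, dir)
  expect_true(all(file.exists(file.path(dir,
    c("metrics.csv", "agreement.csv", "concordance.csv",
      "characteristics.csv", "km_curves.csv", "summary.txt")))))

  co$labels <- NULL
  expect_error(validation_report(co, trees), "labels")
})
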