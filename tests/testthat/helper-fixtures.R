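# Shared fixtures and independent oracles. Oracles are deliberately naive
# (exhaustive scans, first-principles arithmetic) and never call the
# implementation they check.

make_baseline <- function(patient_id = "P1",
                          diagnosis_date = as.Date("2008-01-10"),
                          surgery_date = as.Date("2008-03-15"),
                          surgery_type = "mastectomy",
                          stage = "II", grade = 2L,
                          er = "pos", pr = "pos", her2 = "neg",
                          age_at_diagnosis = 45,
                          last_contact_date = as.Date("2013-03-15"),
                          death_date = as.Date(NA),
                          death_cause = NA_character_) {
  data.frame(patient_id = patient_id, diagnosis_date = diagnosis_date,
             surgery_date = surgery_date, surgery_type = surgery_type,
             stage = stage, grade = grade, er = er, pr = pr, her2 = her2,
             age_at_diagnosis = age_at_diagnosis,
             last_contact_date = last_contact_date, death_date = death_date,
             death_cause = death_cause, stringsAsFactors = FALSE)
}

make_events <- function(patient_id, event_type, event_date,
                        detail = NA_character_) {
  data.frame(patient_id = patient_id, event_type = event_type,
             event_date = event_date, detail = detail,
             stringsAsFactors = FALSE)
}

make_labels <- function(patient_id, recurred, recurrence_date = as.Date(NA)) {
  data.frame(patient_id = patient_id, recurred = recurred,
             recurrence_date = recurrence_date, stringsAsFactors = FALSE)
}

tiny_cohort <- function() {
  b <- rbind(
    make_baseline("P1"),
    make_baseline("P2", surgery_date = as.Date(NA), surgery_type = "none",
                  stage = "0_I", grade = 1L),
    make_baseline("P3", stage = "III", grade = 3L, er = "neg",
                  death_date = as.Date("2012-06-01"),
                  last_contact_date = as.Date("2012-06-01"),
                  death_cause = "breast_cancer"))
  e <- rbind(
    make_events("P1", "surgery", as.Date("2008-03-15"), "mastectomy"),
    make_events("P1", "oncology_visit", as.Date("2008-01-10")),
    make_events("P2", "imaging", as.Date("2008-01-20")),
    make_events("P3", "surgery", as.Date("2008-03-15"), "BCS"),
    make_events("P3", "chemo_admin", as.Date("2010-05-01")),
    make_events("P3", "death", as.Date("2012-06-01"), "breast_cancer"))
  l <- rbind(make_labels("P1", FALSE),
             make_labels("P2", FALSE),
             make_labels("P3", TRUE, as.Date("2010-04-20")))
  recurfs:::new_cohort(b, e, l)
}

# exhaustive all-windows visit-cluster scan
oracle_cluster <- function(visit_dates, landmark, min_count, window_days) {
  v <- sort(visit_dates[visit_dates >= landmark])
  n <- length(v)
  if (n < min_count) return(NULL)
  for (i in seq_len(n)) {
    inwin <- v[as.numeric(v - v[i]) >= 0 & as.numeric(v - v[i]) < window_days]
    if (length(inwin) >= min_count) return(c(v[i], max(inwin)))
  }
  NULL
}

# first-principles weighted Gini and split gain
oracle_gini <- function(counts) {
  stopifnot(sum(counts) > 0)
  1 - sum((counts / sum(counts))^2)
}
oracle_split_gain <- function(column, labels, weights) {
  wc <- function(sel) c(sum(weights[sel & labels]), sum(weights[sel & !labels]))
  tot <- sum(weights)
  parent <- oracle_gini(wc(rep(TRUE, length(labels))))
  wy <- sum(weights[column]); wn <- tot - wy
  if (wy == 0 || wn == 0) return(0)
  parent - wy / tot * oracle_gini(wc(column)) - wn / tot * oracle_gini(wc(!column))
}

# exact two-sided rank-sum p-value by full enumeration of group assignments
oracle_ranksum_exact_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  stats <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# textbook two-group log-rank: sum(O - E) over event times, variance V
oracle_logrank_chisq <- function(t1, e1, t2, e2) {
  times <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
  OE <- 0; V <- 0
  for (tt in times) {
    n1 <- sum(t1 >= tt); n2 <- sum(t2 >= tt); n <- n1 + n2
    d1 <- sum(t1 == tt & e1 == 1); d2 <- sum(t2 == tt & e2 == 1); d <- d1 + d2
    OE <- OE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  OE^2 / V
}

sim_small <- function(n = 120, seed = 7) {
  p <- default_sim_params()
  p$n_patients <- n
  simulate_cohort(p, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

labels_for_matrix <- function(cohort, im) {
  cohort$labels$recurred[match(rownames(im$matrix), cohort$labels$patient_id)]
}
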