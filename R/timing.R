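# Recurrence dating and recurrence-free survival construction.
#
# A flagged patient's recurrence date comes from the triggering indicator:
# dated indicators contribute their evidence date directly; the visit
# cluster contributes the midpoint of its time window. When the trigger is
# undated (vital status, cause of death, stage III) the date falls back to
# the earliest evidence date among the patient's present dated indicators,
# then to the death date, then to the midpoint of the landmark-to-last-
# contact window; fallback dates are clamped to the landmark. RFS runs
# from definitive surgery (diagnosis when there was no surgery) to the
# estimated recurrence date, censored at last contact for non-recurrent
# calls (death without recurrence is censoring, not an event).

UNDATED_INDICATORS <- c("died", "died_of_breast_cancer", "stage_III")

window_midpoint <- function(win) win[1] + floor(days_between(win[2], win[1]) / 2)

#' Estimate the recurrence date for a flagged patient
#'
#' @param triggering_indicator name of the indicator the patient met.
#' @param indicator_vector the patient's [extract_indicators()] result.
#' @param baseline the patient's baseline row (needed for the undated
#'   fallback chain).
#' @return the estimated recurrence `Date` (never before the landmark).
#' @export
assign_recurrence_date <- function(triggering_indicator, indicator_vector,
                                   baseline) {
  stopifnot(inherits(indicator_vector, "indicator_vector"))
  lm <- indicator_vector$landmark_date
  # NA trigger (a recurrent leaf reached without meeting any indicator)
  # uses the same fallback chain as an undated trigger
  if (!is.na(triggering_indicator)) {
    entry <- indicator_vector[[triggering_indicator]]
    if (is.null(entry))
      stop(sprintf("unknown triggering indicator '%s'", triggering_indicator),
           call. = FALSE)
    if (!entry$present)
      stop(sprintf("triggering indicator '%s' is not present for patient %s",
                   triggering_indicator, indicator_vector$patient_id),
           call. = FALSE)
  }
  if (!is.na(triggering_indicator) &&
      !triggering_indicator %in% UNDATED_INDICATORS) {
    entry <- indicator_vector[[triggering_indicator]]
    if (!is.null(entry$evidence_date)) return(entry$evidence_date)
    if (!is.null(entry$evidence_window))
      return(window_midpoint(entry$evidence_window))
  }
  # undated trigger: earliest dated evidence, else death date, else the
  # midpoint of the remaining follow-up window
  dated <- setdiff(names(indicator_vector),
                   c("patient_id", "landmark_date", UNDATED_INDICATORS))
  cand <- as.Date(character())
  for (nm in dated) {
    e <- indicator_vector[[nm]]
    if (e$present && !is.null(e$evidence_date)) cand <- c(cand, e$evidence_date)
    if (e$present && !is.null(e$evidence_window))
      cand <- c(cand, window_midpoint(e$evidence_window))
  }
  if (length(cand)) return(max(min(cand), lm))
  if (!is.na(baseline$death_date)) return(max(baseline$death_date, lm))
  if (baseline$last_contact_date >= lm)
    return(window_midpoint(c(lm, baseline$last_contact_date)))
  stop(sprintf("cannot date recurrence for patient %s: no evidence and no follow-up beyond the landmark",
               indicator_vector$patient_id), call. = FALSE)
}

#' Build one recurrence-free survival record
#'
#' Time origin is the definitive surgery date, or the diagnosis date for
#' patients with no surgery. Flagged patients contribute
#' `estimated date - origin` days with an event; everyone else contributes
#' `last contact - origin` days censored.
#'
#' @param baseline the patient's baseline row.
#' @param call a recurrence call: list/row with `predicted_recurred` and
#'   `estimated_recurrence_date`.
#' @return `list(patient_id, time_days, event, origin)`.
#' @export
build_survival_record <- function(baseline, call) {
  origin_name <- if (!is.na(baseline$surgery_date)) "surgery" else "diagnosis"
  origin <- if (origin_name == "surgery") baseline$surgery_date
            else baseline$diagnosis_date
  if (isTRUE(call$predicted_recurred)) {
    if (is.na(call$estimated_recurrence_date))
      stop("recurrent call without an estimated recurrence date", call. = FALSE)
    t <- days_between(call$estimated_recurrence_date, origin)
    if (t < 0)
      stop(sprintf("estimated recurrence date precedes %s date for patient %s",
                   origin_name, baseline$patient_id), call. = FALSE)
    ev <- TRUE
  } else {
    t <- days_between(baseline$last_contact_date, origin)
    ev <- FALSE
  }
  list(patient_id = baseline$patient_id, time_days = t, event = ev,
       origin = origin_name)
}

#' Apply a fitted tree to a whole cohort
#'
#' Extracts indicators, predicts each patient's status, dates every flagged
#' recurrence from its triggering indicator and assembles the survival
#' records.
#'
#' @param cohort a `cohort`.
#' @param tree a `recurrence_tree`.
#' @param config the [indicator_config()] used for extraction (must match
#'   the indicators the tree was fitted on).
#' @return list with data frames `calls` (`patient_id, predicted_recurred,
#'   estimated_recurrence_date, triggering_indicator`) and `survival`
#'   (`patient_id, time_days, event, origin`), plus `n_flagged`.
#' @export
call_cohort <- function(cohort, tree, config = indicator_config()) {
  stopifnot(inherits(cohort, "cohort"), inherits(tree, "recurrence_tree"))
  im <- build_indicator_matrix(cohort, config)
  b <- cohort$baselines
  n <- nrow(b)
  calls <- data.frame(
    patient_id = b$patient_id,
    predicted_recurred = logical(n),
    estimated_recurrence_date = as.Date(rep(NA_real_, n), origin = "1970-01-01"),
    triggering_indicator = NA_character_,
    stringsAsFactors = FALSE)
  surv <- vector("list", n)
  for (i in seq_len(n)) {
    iv <- im$evidence[[b$patient_id[i]]]
    pred <- predict(tree, iv)
    if (pred$label == "recurrent") {
      calls$predicted_recurred[i] <- TRUE
      calls$triggering_indicator[i] <- pred$triggering_indicator
      calls$estimated_recurrence_date[i] <-
        assign_recurrence_date(pred$triggering_indicator, iv, b[i, ])
    }
    surv[[i]] <- as.data.frame(build_survival_record(b[i, ], calls[i, ]),
                               stringsAsFactors = FALSE)
  }
  list(calls = calls, survival = do.call(rbind, surv),
       n_flagged = sum(calls$predicted_recurred))
}

#' Gold-standard survival records from chart-review labels
#'
#' The chart-review counterpart of [call_cohort()]: labelled recurrences
#' contribute events at their recorded date, everyone else is censored at
#' last contact.
#'
#' @param cohort a `cohort` with labels.
#' @return a survival data frame (`patient_id, time_days, event, origin`).
#' @export
gold_survival <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(cohort$labels))
    stop("cohort has no gold labels", call. = FALSE)
  b <- cohort$baselines
  l <- cohort$labels[match(b$patient_id, cohort$labels$patient_id), ]
  out <- vector("list", nrow(b))
  for (i in seq_len(nrow(b))) {
    call <- list(predicted_recurred = isTRUE(l$recurred[i]),
                 estimated_recurrence_date = l$recurrence_date[i])
    out[[i]] <- as.data.frame(build_survival_record(b[i, ], call),
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
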