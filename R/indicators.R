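# Recurrence indicators.
#
# Each patient's event stream is reduced to binary indicators of possible
# recurrence, all restricted to events on or after a landmark date
# (definitive surgery plus 6, 12 or 18 calendar months; diagnosis is the
# anchor for the few patients without surgery). Dated indicators carry the
# evidence date later used to estimate the recurrence date; the visit
# cluster carries a time window whose midpoint is used instead. Undated
# indicators (vital status, cause of death, stage III) carry no date.

# Fixed indicator column order; CART gain ties break on this order.
INDICATOR_ORDER <- c("second_surgery", "second_radiation", "second_chemo",
                     "re_imaging", "re_biopsy", "visit_cluster",
                     "died", "died_of_breast_cancer", "stage_III")

#' Indicator extraction configuration
#'
#' @param landmark_months months added to the definitive surgery date
#'   (diagnosis date when no surgery) before events may count as recurrence
#'   evidence; one of 6, 12, 18.
#' @param visit_cluster_min_count minimum number of oncology visits that
#'   must fall inside one window to flag a visit cluster.
#' @param visit_cluster_window_days length of the visit-cluster window.
#' @param second_chemo_min_cycles chemotherapy administrations on/after the
#'   landmark needed to flag a new chemotherapy episode ("more than two
#'   cycles" = 3).
#' @param include_hormone also extract a `re_hormone` indicator (earliest
#'   hormone dispense on/after the landmark). Off by default.
#' @return an `indicator_config` list.
#' @export
indicator_config <- function(landmark_months = 6,
                             visit_cluster_min_count = 3,
                             visit_cluster_window_days = 90,
                             second_chemo_min_cycles = 3,
                             include_hormone = FALSE) {
  if (!landmark_months %in% c(6, 12, 18))
    stop("landmark_months must be one of 6, 12, 18", call. = FALSE)
  stopifnot(visit_cluster_min_count >= 1, second_chemo_min_cycles >= 1,
            visit_cluster_window_days > 0)
  structure(list(landmark_months = as.integer(landmark_months),
                 visit_cluster_min_count = as.integer(visit_cluster_min_count),
                 visit_cluster_window_days = as.integer(visit_cluster_window_days),
                 second_chemo_min_cycles = as.integer(second_chemo_min_cycles),
                 include_hormone = isTRUE(include_hormone)),
            class = "indicator_config")
}

indicator_names <- function(config) {
  if (config$include_hormone) c(INDICATOR_ORDER, "re_hormone") else INDICATOR_ORDER
}

#' Landmark date for a patient
#'
#' Definitive surgery date plus `landmark_months` calendar months
#' (month-end clamped); for patients with no surgery the diagnosis date is
#' the anchor.
#'
#' @param baseline one baseline row (list or 1-row data frame).
#' @param config an [indicator_config()].
#' @return a `Date`.
#' @export
landmark_date <- function(baseline, config = indicator_config()) {
  anchor <- baseline$surgery_date
  if (is.null(anchor) || is.na(anchor)) anchor <- baseline$diagnosis_date
  add_months(anchor, config$landmark_months)
}

#' Find the earliest post-landmark visit cluster
#'
#' Scans the sorted visit dates for the earliest window starting at a visit
#' on/after the landmark in which at least `visit_cluster_min_count` visits
#' fall within `visit_cluster_window_days` (a visit at day `d` belongs to
#' the window opened at `d0` when `d - d0 < window`). The returned evidence
#' window spans from the opening visit to the last visit inside the window.
#'
#' @param visit_dates `Date` vector, sorted ascending.
#' @param landmark the landmark `Date`.
#' @param config an [indicator_config()].
#' @return a `Date` vector `c(start, end)`, or `NULL` when no window
#'   qualifies.
#' @export
detect_visit_cluster <- function(visit_dates, landmark,
                                 config = indicator_config()) {
  v <- visit_dates[visit_dates >= landmark]
  k <- config$visit_cluster_min_count
  w <- config$visit_cluster_window_days
  n <- length(v)
  if (n < k) return(NULL)
  for (i in seq_len(n - k + 1L)) {
    inwin <- which(days_between(v, v[i]) >= 0 & days_between(v, v[i]) < w)
    if (length(inwin) >= k) return(c(v[i], max(v[inwin])))
  }
  NULL
}

#' Detect a second round of a treatment or diagnostic procedure
#'
#' For surgery, radiation, imaging and biopsy the evidence is the earliest
#' event of that type on/after the landmark. For chemotherapy the indicator
#' is present only when at least `min_count` administrations fall on/after
#' the landmark, and the evidence date is the first of them.
#'
#' @param events one patient's event data frame.
#' @param event_type one of the event-type enum values.
#' @param landmark the landmark `Date`.
#' @param min_count minimum number of qualifying events (1 for everything
#'   but chemotherapy).
#' @return the evidence `Date`, or `NULL` when the indicator is absent.
#' @export
detect_second_treatment <- function(events, event_type, landmark,
                                    min_count = 1) {
  d <- sort(events$event_date[events$event_type == event_type &
                                events$event_date >= landmark])
  if (length(d) < min_count) return(NULL)
  d[1]
}

#' Extract the indicator vector for one patient
#'
#' Applies every detector to one patient's events: second surgery / second
#' radiation / re-imaging / re-biopsy (earliest post-landmark event), a new
#' chemotherapy episode (at least `second_chemo_min_cycles` administrations
#' post landmark), the visit cluster, plus the undated indicators `died`,
#' `died_of_breast_cancer` (from the baseline vital-status fields) and
#' `stage_III`.
#'
#' @param baseline one baseline row.
#' @param events that patient's events.
#' @param config an [indicator_config()].
#' @return an `indicator_vector`: list with `patient_id`, `landmark_date`,
#'   and one entry per indicator, each
#'   `list(present, evidence_date, evidence_window)`.
#' @export
extract_indicators <- function(baseline, events,
                               config = indicator_config()) {
  lm <- landmark_date(baseline, config)
  ev <- events[events$patient_id == baseline$patient_id, , drop = FALSE]

  dated <- function(date) {
    if (is.null(date)) list(present = FALSE, evidence_date = NULL,
                            evidence_window = NULL)
    else list(present = TRUE, evidence_date = date, evidence_window = NULL)
  }
  ind <- list(
    second_surgery = dated(detect_second_treatment(ev, "surgery", lm)),
    second_radiation = dated(detect_second_treatment(ev, "radiation_fraction", lm)),
    second_chemo = dated(detect_second_treatment(ev, "chemo_admin", lm,
                                                 config$second_chemo_min_cycles)),
    re_imaging = dated(detect_second_treatment(ev, "imaging", lm)),
    re_biopsy = dated(detect_second_treatment(ev, "biopsy", lm))
  )
  visits <- sort(ev$event_date[ev$event_type == "oncology_visit"])
  win <- detect_visit_cluster(visits, lm, config)
  ind$visit_cluster <- if (is.null(win))
    list(present = FALSE, evidence_date = NULL, evidence_window = NULL)
  else list(present = TRUE, evidence_date = NULL, evidence_window = win)

  died <- !is.na(baseline$death_date)
  ind$died <- list(present = died,
                   evidence_date = if (died) baseline$death_date else NULL,
                   evidence_window = NULL, undated = TRUE)
  bc <- died && !is.na(baseline$death_cause) &&
    baseline$death_cause == "breast_cancer"
  ind$died_of_breast_cancer <- list(
    present = bc, evidence_date = if (bc) baseline$death_date else NULL,
    evidence_window = NULL, undated = TRUE)
  ind$stage_III <- list(present = identical(baseline$stage, "III"),
                        evidence_date = NULL, evidence_window = NULL,
                        undated = TRUE)
  if (config$include_hormone)
    ind$re_hormone <- dated(detect_second_treatment(ev, "hormone_dispense", lm))

  structure(c(list(patient_id = baseline$patient_id, landmark_date = lm), ind),
            class = "indicator_vector")
}

#' Build the cohort indicator matrix
#'
#' One row per patient (baseline order), one logical column per indicator in
#' the fixed order `second_surgery, second_radiation, second_chemo,
#' re_imaging, re_biopsy, visit_cluster, died, died_of_breast_cancer,
#' stage_III` (plus `re_hormone` when configured). Equal-gain ties during
#' tree induction break on this column order. The evidence map retains each
#' patient's full [extract_indicators()] result for recurrence dating.
#'
#' @param cohort a `cohort`.
#' @param config an [indicator_config()].
#' @return a list: `matrix` (logical, patients x indicators, rownames =
#'   patient ids) and `evidence` (named list of `indicator_vector`s).
#' @export
build_indicator_matrix <- function(cohort, config = indicator_config()) {
  stopifnot(inherits(cohort, "cohort"))
  b <- cohort$baselines
  cols <- indicator_names(config)
  ev_split <- split(cohort$events, cohort$events$patient_id)
  vectors <- lapply(seq_len(nrow(b)), function(i) {
    pe <- ev_split[[b$patient_id[i]]] %||% empty_events()
    extract_indicators(b[i, ], pe, config)
  })
  names(vectors) <- b$patient_id
  m <- matrix(FALSE, nrow = nrow(b), ncol = length(cols),
              dimnames = list(b$patient_id, cols))
  for (i in seq_along(vectors))
    m[i, ] <- vapply(cols, function(cn) vectors[[i]][[cn]]$present, logical(1))
  list(matrix = m, evidence = vectors)
}
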