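# Cohort container and delimited-text I/O.
#
# A cohort bundles three tables:
#   baselines — one row per patient: index dates, tumor/treatment covariates,
#               vital status;
#   events    — one row per dated clinical event (long format);
#   labels    — optional chart-review gold standard: recurrence status and
#               date.
# All dates are ISO-8601 calendar dates and all arithmetic is in integer
# days. Files are comma-separated UTF-8 with a header row; blank cells are
# absent optional values and booleans are coded "yes"/"no".

EVENT_TYPES <- c("oncology_visit", "imaging", "biopsy", "surgery",
                 "chemo_admin", "radiation_fraction", "hormone_dispense",
                 "death")
SURGERY_TYPES <- c("none", "BCS", "mastectomy")
STAGES <- c("0_I", "II", "III")
MARKER_LEVELS <- c("pos", "neg")
DEATH_CAUSES <- c("breast_cancer", "other")

EVENTS_COLS <- c("patient_id", "event_type", "event_date", "detail")
PATIENTS_COLS <- c("patient_id", "diagnosis_date", "surgery_date",
                   "surgery_type", "stage", "grade", "er", "pr", "her2",
                   "age_at_diagnosis", "last_contact_date", "death_date",
                   "death_cause")
LABELS_COLS <- c("patient_id", "recurred", "recurrence_date")

new_cohort <- function(baselines, events, labels = NULL) {
  structure(list(baselines = baselines, events = events, labels = labels),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients, %d events%s\n",
              nrow(x$baselines), nrow(x$events),
              if (is.null(x$labels)) ", no gold labels"
              else sprintf(", %d gold labels (%d recurred)",
                           nrow(x$labels), sum(x$labels$recurred))))
  invisible(x)
}

read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = character(), encoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s",
                 basename(path), paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  df
}

parse_enum <- function(x, levels, what, file, required = TRUE) {
  v <- trimws(x)
  blank <- !nzchar(v)
  if (required && any(blank)) {
    stop(sprintf("%s: column '%s' has a blank value (data row %d)",
                 file, what, which(blank)[1]), call. = FALSE)
  }
  bad <- !blank & !v %in% levels
  if (any(bad)) {
    stop(sprintf("%s: invalid value '%s' in column '%s' (data row %d); allowed: %s",
                 file, v[which(bad)[1]], what, which(bad)[1],
                 paste(levels, collapse = ", ")), call. = FALSE)
  }
  v[blank] <- NA_character_
  v
}

#' Read a cohort from delimited text files
#'
#' Reads `events.csv`, `patients.csv` and (optionally) `labels.csv` into a
#' `cohort` object, parsing ISO-8601 dates and `"yes"`/`"no"` booleans and
#' checking the schema: a missing required column, an unparseable date or an
#' event whose `patient_id` does not appear in the patient table is an error.
#'
#' @param events_path path to the event table
#'   (`patient_id,event_type,event_date,detail`).
#' @param patients_path path to the patient baseline table.
#' @param labels_path optional path to the chart-review label table
#'   (`patient_id,recurred,recurrence_date`).
#' @return a `cohort`: list with `baselines`, `events` and (possibly `NULL`)
#'   `labels` data frames.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(events_path, patients_path, labels_path = NULL) {
  pf <- basename(patients_path)
  p <- read_table_checked(patients_path, PATIENTS_COLS)
  baselines <- data.frame(
    patient_id = trimws(p$patient_id),
    diagnosis_date = parse_iso_date(p$diagnosis_date, "diagnosis_date", pf),
    surgery_date = parse_iso_date(p$surgery_date, "surgery_date", pf),
    surgery_type = parse_enum(p$surgery_type, SURGERY_TYPES, "surgery_type", pf),
    stage = parse_enum(p$stage, STAGES, "stage", pf),
    grade = as.integer(parse_enum(p$grade, c("1", "2", "3"), "grade", pf)),
    er = parse_enum(p$er, MARKER_LEVELS, "er", pf),
    pr = parse_enum(p$pr, MARKER_LEVELS, "pr", pf),
    her2 = parse_enum(p$her2, MARKER_LEVELS, "her2", pf),
    age_at_diagnosis = as.numeric(p$age_at_diagnosis),
    last_contact_date = parse_iso_date(p$last_contact_date, "last_contact_date", pf),
    death_date = parse_iso_date(p$death_date, "death_date", pf),
    death_cause = parse_enum(p$death_cause, DEATH_CAUSES, "death_cause", pf,
                             required = FALSE),
    stringsAsFactors = FALSE
  )
  if (any(is.na(baselines$diagnosis_date)))
    stop(sprintf("%s: diagnosis_date is required (data row %d)", pf,
                 which(is.na(baselines$diagnosis_date))[1]), call. = FALSE)
  if (any(is.na(baselines$last_contact_date)))
    stop(sprintf("%s: last_contact_date is required (data row %d)", pf,
                 which(is.na(baselines$last_contact_date))[1]), call. = FALSE)

  ef <- basename(events_path)
  e <- read_table_checked(events_path, EVENTS_COLS)
  events <- data.frame(
    patient_id = trimws(e$patient_id),
    event_type = parse_enum(e$event_type, EVENT_TYPES, "event_type", ef),
    event_date = parse_iso_date(e$event_date, "event_date", ef),
    detail = ifelse(nzchar(trimws(e$detail)), trimws(e$detail), NA_character_),
    stringsAsFactors = FALSE
  )
  if (any(is.na(events$event_date)))
    stop(sprintf("%s: event_date is required (data row %d)", ef,
                 which(is.na(events$event_date))[1]), call. = FALSE)
  orphan <- !events$patient_id %in% baselines$patient_id
  if (any(orphan)) {
    stop(sprintf("%s: event patient_id '%s' not present in patient table (data row %d)",
                 ef, events$patient_id[which(orphan)[1]], which(orphan)[1]),
         call. = FALSE)
  }

  labels <- NULL
  if (!is.null(labels_path)) {
    lf <- basename(labels_path)
    l <- read_table_checked(labels_path, LABELS_COLS)
    labels <- data.frame(
      patient_id = trimws(l$patient_id),
      recurred = parse_yesno(l$recurred, "recurred", lf),
      recurrence_date = parse_iso_date(l$recurrence_date, "recurrence_date", lf),
      stringsAsFactors = FALSE
    )
    orphan <- !labels$patient_id %in% baselines$patient_id
    if (any(orphan))
      stop(sprintf("%s: label patient_id '%s' not present in patient table",
                   lf, labels$patient_id[which(orphan)[1]]), call. = FALSE)
  }
  new_cohort(baselines, events, labels)
}

#' Write a cohort to delimited text files
#'
#' Writes `events.csv`, `patients.csv` and (when labels are present)
#' `labels.csv` under `dir_path`. Reading the written files back with
#' [read_cohort()] reproduces the cohort field for field; absent optional
#' values are blank cells.
#'
#' @param cohort a `cohort` object.
#' @param dir_path output directory (created if needed).
#' @return invisibly, a named character vector of written paths.
#' @export
write_cohort <- function(cohort, dir_path) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir_path))
    stop(sprintf("cannot create output directory: %s", dir_path), call. = FALSE)

  b <- cohort$baselines
  pb <- data.frame(
    patient_id = b$patient_id,
    diagnosis_date = format_date_col(b$diagnosis_date),
    surgery_date = format_date_col(b$surgery_date),
    surgery_type = ifelse(is.na(b$surgery_type), "", b$surgery_type),
    stage = b$stage,
    grade = b$grade,
    er = b$er, pr = b$pr, her2 = b$her2,
    age_at_diagnosis = b$age_at_diagnosis,
    last_contact_date = format_date_col(b$last_contact_date),
    death_date = format_date_col(b$death_date),
    death_cause = ifelse(is.na(b$death_cause), "", b$death_cause),
    stringsAsFactors = FALSE
  )
  e <- cohort$events
  pe <- data.frame(
    patient_id = e$patient_id,
    event_type = e$event_type,
    event_date = format_date_col(e$event_date),
    detail = ifelse(is.na(e$detail), "", e$detail),
    stringsAsFactors = FALSE
  )
  paths <- c(events = file.path(dir_path, "events.csv"),
             patients = file.path(dir_path, "patients.csv"))
  utils::write.csv(pe, paths[["events"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(pb, paths[["patients"]], row.names = FALSE, quote = FALSE)
  if (!is.null(cohort$labels)) {
    l <- cohort$labels
    pl <- data.frame(
      patient_id = l$patient_id,
      recurred = format_yesno(l$recurred),
      recurrence_date = format_date_col(l$recurrence_date),
      stringsAsFactors = FALSE
    )
    paths <- c(paths, labels = file.path(dir_path, "labels.csv"))
    utils::write.csv(pl, paths[["labels"]], row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

violation <- function(patient_id, rule, message) {
  data.frame(patient_id = patient_id, rule = rule, message = message,
             stringsAsFactors = FALSE)
}

#' Check a cohort against its structural invariants
#'
#' Reports, rather than raises, every violated invariant: duplicate patient
#' ids, orphan events, events outside the diagnosis/last-contact window,
#' more than one death event per patient, death-event/baseline date
#' disagreement, surgery before diagnosis, last contact before the index
#' dates, death date not equal to last contact, labelled recurrences dated
#' less than 180 days after definitive surgery, and recurrence dates missing
#' or spurious relative to the recurred flag.
#'
#' @param cohort a `cohort`.
#' @return a data frame with columns `patient_id`, `rule`, `message`; zero
#'   rows iff every invariant holds.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  b <- cohort$baselines; e <- cohort$events; l <- cohort$labels
  out <- list()
  add <- function(v) out[[length(out) + 1L]] <<- v

  dup <- b$patient_id[duplicated(b$patient_id)]
  for (id in unique(dup))
    add(violation(id, "unique_patient", "duplicate patient_id in baselines"))

  orphan <- unique(e$patient_id[!e$patient_id %in% b$patient_id])
  for (id in orphan)
    add(violation(id, "event_linkage", "event patient_id absent from baselines"))

  idx <- match(e$patient_id, b$patient_id)
  known <- !is.na(idx)
  late <- known & e$event_date > b$last_contact_date[idx]
  for (i in which(late))
    add(violation(e$patient_id[i], "event_window",
                  sprintf("%s on %s postdates last_contact_date",
                          e$event_type[i], e$event_date[i])))
  early <- known & e$event_date < b$diagnosis_date[idx]
  for (i in which(early))
    add(violation(e$patient_id[i], "event_window",
                  sprintf("%s on %s predates diagnosis_date",
                          e$event_type[i], e$event_date[i])))

  deaths <- e[e$event_type == "death", , drop = FALSE]
  ndeath <- table(deaths$patient_id)
  for (id in names(ndeath)[ndeath > 1])
    add(violation(id, "single_death", "more than one death event"))
  di <- match(deaths$patient_id, b$patient_id)
  mism <- !is.na(di) & !is.na(b$death_date[di]) &
    deaths$event_date != b$death_date[di]
  for (i in which(mism))
    add(violation(deaths$patient_id[i], "death_date_match",
                  "death event date differs from baseline death_date"))

  bad <- !is.na(b$surgery_date) & b$surgery_date < b$diagnosis_date
  for (i in which(bad))
    add(violation(b$patient_id[i], "surgery_after_diagnosis",
                  "surgery_date precedes diagnosis_date"))
  origin <- pmax(b$diagnosis_date,
                 as.Date(ifelse(is.na(b$surgery_date), b$diagnosis_date,
                                b$surgery_date), origin = "1970-01-01"))
  bad <- b$last_contact_date < origin
  for (i in which(bad))
    add(violation(b$patient_id[i], "followup_window",
                  "last_contact_date precedes diagnosis/surgery"))
  bad <- !is.na(b$death_date) & b$death_date != b$last_contact_date
  for (i in which(bad))
    add(violation(b$patient_id[i], "death_is_last_contact",
                  "death_date differs from last_contact_date"))

  if (!is.null(l)) {
    dupl <- l$patient_id[duplicated(l$patient_id)]
    for (id in unique(dupl))
      add(violation(id, "unique_patient", "duplicate patient_id in labels"))
    bad <- l$recurred & is.na(l$recurrence_date)
    for (i in which(bad))
      add(violation(l$patient_id[i], "label_date_required",
                    "recurred=yes without a recurrence_date"))
    bad <- !l$recurred & !is.na(l$recurrence_date)
    for (i in which(bad))
      add(violation(l$patient_id[i], "label_date_spurious",
                    "recurred=no with a recurrence_date"))
    li <- match(l$patient_id, b$patient_id)
    sd <- b$surgery_date[li]
    bad <- !is.na(li) & l$recurred & !is.na(l$recurrence_date) & !is.na(sd) &
      days_between(l$recurrence_date, sd) < 180
    for (i in which(bad))
      add(violation(l$patient_id[i], "recurrence_after_180d",
                    sprintf("recurrence_date %d days after surgery (< 180)",
                            days_between(l$recurrence_date[i], sd[i]))))
  }

  if (!length(out))
    return(data.frame(patient_id = character(), rule = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
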