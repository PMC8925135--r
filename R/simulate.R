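# Synthetic cohort simulator.
#
# Generates administrative event streams with the structure the recurrence
# method assumes: a primary-treatment phase (diagnostic workup, surgery,
# chemotherapy, radiation, hormone dispenses) followed, for recurrent
# patients, by a second cluster of oncology visits, diagnostics and
# treatments starting shortly after the true (latent) recurrence date.
# Ground-truth recurrence status and date are emitted as gold labels, so
# indicator extraction, tree induction, dating and the validation battery
# are all testable against a known truth.

#' Default simulation parameters
#'
#' The defaults emulate a chart-reviewed cohort of 598 stage 0--III breast
#' cancer patients with a 20.2\% recurrence fraction over a median 4-year
#' (IQR 3--5) follow-up: covariate marginals (stage, grade, ER/PR/HER2,
#' surgery type) match that cohort's entire-cohort column, 0.8\% of patients
#' receive no surgery, and recurrence latency is 180 days plus a
#' Weibull(shape 1.3) draw scaled so about 80\% of recurrences fall within
#' five years of surgery.
#'
#' @return an object of class `sim_params` (a named list; see fields).
#' @export
default_sim_params <- function() {
  p <- list(
    n_patients = 598L,
    recurrence_prob = 0.202,
    # follow-up from diagnosis, years: gamma calibrated to median 4, IQR 3-5
    followup_shape = 7.6,
    followup_scale_years = 0.546,
    # latent recurrence: latency_min_days + Weibull(shape, scale) days
    latency_min_days = 180,
    latency_weibull_shape = 1.3,
    latency_weibull_scale_days = 1141,
    # post-recurrence administrative signal lag, uniform on [0, max] days
    indicator_lag_max_days = 60,
    # primary phase
    neoadjuvant_prob = 0.528,
    chemo_prob = 0.915,
    chemo_cycles_range = c(4L, 8L),
    chemo_cycle_interval_days = 21,
    radiation_prob = 0.65,
    radiation_fractions_range = c(16L, 25L),
    hormone_prob_er_pos = 0.8,
    # scheduled follow-up visits: successive gaps uniform on this range,
    # so visits come ~twice a year without spurious 3-in-90-day bursts
    surveillance_gap_days_range = c(120, 240),
    # sporadic diagnostics outside recurrence (benign workups)
    background_imaging_rate_per_year = 0.15,
    background_biopsy_prob = 0.25,
    # false administrative signals unrelated to recurrence: a short visit
    # burst (e.g. wound complication, lymphedema) and benign/reconstructive
    # second surgery
    complication_prob = 0.05,
    benign_second_surgery_prob = 0.03,
    # recurrence phase
    recur_visit_rate_per_year = 12,
    recur_burst_duration_days = 180,
    reimaging_prob = 0.95,
    rebiopsy_prob = 0.7,
    second_surgery_prob = 0.35,
    second_chemo_prob = 0.6,
    second_chemo_cycles_range = c(3L, 6L),
    second_radiation_prob = 0.3,
    # death
    post_recurrence_death_median_years = 3,
    other_cause_rate_per_year = 0.005,
    # covariate marginals (entire-cohort column)
    surgery_type_probs = c(none = 0.008, BCS = 0.266, mastectomy = 0.726),
    stage_probs = c("0_I" = 0.159, "II" = 0.520, "III" = 0.321),
    grade_probs = c("1" = 0.075, "2" = 0.353, "3" = 0.572),
    er_pos_prob = 0.734,
    pr_pos_prob = 0.627,
    her2_pos_prob = 0.269,
    young_cohort_prob = 0.472,
    diagnosis_start = as.Date("2007-01-01"),
    diagnosis_end = as.Date("2014-12-31"),
    rng_seed = 1L
  )
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  probs <- c("recurrence_prob", "neoadjuvant_prob", "chemo_prob",
             "radiation_prob", "hormone_prob_er_pos", "reimaging_prob",
             "rebiopsy_prob", "second_surgery_prob", "second_chemo_prob",
             "second_radiation_prob", "er_pos_prob", "pr_pos_prob",
             "her2_pos_prob", "young_cohort_prob", "background_biopsy_prob",
             "complication_prob", "benign_second_surgery_prob")
  for (f in probs) {
    v <- p[[f]]
    if (is.null(v) || !is.numeric(v) || v < 0 || v > 1)
      stop(sprintf("invalid sim_params field '%s': must be a probability in [0,1]", f),
           call. = FALSE)
  }
  for (f in c("surgery_type_probs", "stage_probs", "grade_probs")) {
    v <- p[[f]]
    if (any(v < 0) || any(v > 1))
      stop(sprintf("invalid sim_params field '%s': probabilities in [0,1]", f),
           call. = FALSE)
  }
  rates <- c("followup_shape", "followup_scale_years",
             "latency_weibull_shape", "latency_weibull_scale_days",
             "indicator_lag_max_days", "surveillance_gap_days_range",
             "recur_visit_rate_per_year", "recur_burst_duration_days",
             "background_imaging_rate_per_year",
             "post_recurrence_death_median_years", "other_cause_rate_per_year")
  for (f in rates) {
    v <- p[[f]]
    if (is.null(v) || !is.numeric(v) || any(v < 0))
      stop(sprintf("invalid sim_params field '%s': must be a non-negative rate", f),
           call. = FALSE)
  }
  if (p$latency_min_days < 180)
    stop("invalid sim_params field 'latency_min_days': minimum is 180 days",
         call. = FALSE)
  if (p$n_patients < 0)
    stop("invalid sim_params field 'n_patients': must be non-negative",
         call. = FALSE)
  invisible(p)
}

# Poisson-process event dates on [from, to], rate per year.
rpois_dates <- function(from, to, rate_per_year) {
  span <- days_between(to, from)
  if (span <= 0 || rate_per_year <= 0) return(as.Date(character()))
  n <- stats::rpois(1, rate_per_year * span / 365.25)
  if (n == 0) return(as.Date(character()))
  sort(from + sample.int(span + 1L, n, replace = TRUE) - 1L)
}

runif_days <- function(lo, hi) lo + floor(stats::runif(1) * (hi - lo + 1))

#' Simulate a synthetic cohort with known recurrence ground truth
#'
#' Draws baselines, event streams and gold labels under `params`. Each
#' patient gets a primary phase (workup visits and imaging/biopsy at
#' diagnosis, surgery unless exempt, chemotherapy before or after surgery,
#' radiation, hormone dispenses for ER-positive patients, sparse
#' surveillance visits). Recurrent patients additionally get, after a
#' latency of at least 180 days post surgery and a uniform administrative
#' lag, a burst of oncology visits plus re-imaging, re-biopsy, second
#' surgery, second chemotherapy and second radiation per the configured
#' probabilities. Deaths truncate the event stream and set the last contact
#' date. The same `params` and `seed` always reproduce the same cohort.
#'
#' @param params a `sim_params` list, e.g. [default_sim_params()].
#' @param seed integer RNG seed; defaults to `params$rng_seed`.
#' @return a `cohort` with `labels` populated.
#' @export
simulate_cohort <- function(params = default_sim_params(),
                            seed = params$rng_seed) {
  validate_sim_params(params)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  p <- params
  n <- as.integer(p$n_patients)

  bl <- vector("list", n); evl <- vector("list", n); lbl <- vector("list", n)
  dx_span <- days_between(p$diagnosis_end, p$diagnosis_start)

  for (i in seq_len(n)) {
    id <- sprintf("P%04d", i)
    stage <- sample(names(p$stage_probs), 1, prob = p$stage_probs)
    grade <- as.integer(sample(names(p$grade_probs), 1, prob = p$grade_probs))
    er <- if (stats::runif(1) < p$er_pos_prob) "pos" else "neg"
    pr <- if (stats::runif(1) < p$pr_pos_prob) "pos" else "neg"
    her2 <- if (stats::runif(1) < p$her2_pos_prob) "pos" else "neg"
    age <- if (stats::runif(1) < p$young_cohort_prob)
      stats::runif(1, 23, 40) else stats::runif(1, 30, 70)
    age <- round(age)
    dx <- p$diagnosis_start + floor(stats::runif(1) * (dx_span + 1))

    surg_type <- sample(names(p$surgery_type_probs), 1,
                        prob = p$surgery_type_probs)
    neoadj <- stats::runif(1) < p$neoadjuvant_prob
    chemo <- stats::runif(1) < p$chemo_prob
    n_cycles <- runif_days(p$chemo_cycles_range[1], p$chemo_cycles_range[2])
    chemo_dates <- as.Date(character())
    if (chemo && neoadj)
      chemo_dates <- dx + 14 + (seq_len(n_cycles) - 1L) * p$chemo_cycle_interval_days

    if (surg_type != "none") {
      surg <- if (chemo && neoadj) max(chemo_dates) + runif_days(28, 56)
              else dx + runif_days(21, 56)
    } else surg <- as.Date(NA)
    anchor <- if (is.na(surg)) dx else surg
    if (chemo && !neoadj)
      chemo_dates <- anchor + 28 + (seq_len(n_cycles) - 1L) * p$chemo_cycle_interval_days

    fup_days <- round(stats::rgamma(1, p$followup_shape,
                                    scale = p$followup_scale_years) * 365.25)
    last_contact <- dx + max(fup_days, days_between(anchor, dx) + 60)

    # latent recurrence, conditioned to be observable inside follow-up
    recurred <- stats::runif(1) < p$recurrence_prob
    rec_date <- as.Date(NA)
    if (recurred) {
      margin <- p$indicator_lag_max_days + 180  # room for the signal cluster
      avail <- days_between(last_contact, anchor) - p$latency_min_days - margin
      if (avail < 30) {
        last_contact <- anchor + p$latency_min_days + 30 + margin
        avail <- 30
      }
      sh <- p$latency_weibull_shape; sc <- p$latency_weibull_scale_days
      u <- stats::runif(1) * stats::pweibull(avail, sh, sc)
      w <- stats::qweibull(u, sh, sc)
      rec_date <- anchor + p$latency_min_days + round(w)
    }

    # death: breast-cancer death after recurrence, other-cause any time
    death <- as.Date(NA); cause <- NA_character_
    t_other <- stats::rexp(1, p$other_cause_rate_per_year / 365.25)
    if (dx + round(t_other) < last_contact) {
      death <- dx + round(t_other); cause <- "other"
    }
    if (recurred) {
      rate <- log(2) / (p$post_recurrence_death_median_years * 365.25)
      t_bc <- rec_date + round(stats::rexp(1, rate))
      # leave the signal cluster at least partly observable
      t_bc <- max(t_bc, rec_date + 90)
      if (t_bc < last_contact && (is.na(death) || t_bc < death)) {
        death <- t_bc; cause <- "breast_cancer"
      }
    }
    if (!is.na(death) && (!recurred || death > rec_date)) {
      last_contact <- death
    } else if (!is.na(death)) {
      death <- as.Date(NA); cause <- NA_character_  # pre-recurrence draw discarded
    }

    # --- events ---
    ev_type <- character(); ev_date <- as.Date(character()); ev_det <- character()
    emit <- function(type, dates, detail = NA_character_) {
      k <- length(dates)
      if (!k) return()
      ev_type <<- c(ev_type, rep(type, k))
      ev_date <<- c(ev_date, dates)
      ev_det <<- c(ev_det, rep(detail, k))
    }
    emit("oncology_visit", dx + c(0, runif_days(5, 10)))
    emit("imaging", dx + runif_days(0, 3))
    emit("biopsy", dx + runif_days(3, 10))
    if (!is.na(surg)) emit("surgery", surg, surg_type)
    emit("chemo_admin", chemo_dates)
    if (stats::runif(1) < p$radiation_prob && !is.na(surg)) {
      rstart <- surg + runif_days(49, 84)
      emit("radiation_fraction",
           rstart + seq_len(runif_days(p$radiation_fractions_range[1],
                                       p$radiation_fractions_range[2])) - 1L)
    }
    if (er == "pos" && stats::runif(1) < p$hormone_prob_er_pos) {
      hstart <- anchor + 90
      hend <- min(last_contact, anchor + round(5 * 365.25))
      if (hend > hstart)
        emit("hormone_dispense", seq(hstart, hend, by = 90))
    }
    sv <- anchor + 30
    repeat {
      sv <- sv + runif_days(p$surveillance_gap_days_range[1],
                            p$surveillance_gap_days_range[2])
      if (sv > last_contact) break
      emit("oncology_visit", sv)
    }
    bg_img <- rpois_dates(anchor + 30, last_contact,
                          p$background_imaging_rate_per_year)
    emit("imaging", bg_img)
    for (d in as.list(bg_img))
      if (stats::runif(1) < p$background_biopsy_prob)
        emit("biopsy", d + runif_days(5, 20))
    # recurrence-unrelated signal noise
    noise_span <- days_between(last_contact, anchor) - 240
    if (stats::runif(1) < p$complication_prob && noise_span > 0) {
      cstart <- anchor + 180 + floor(stats::runif(1) * noise_span)
      emit("oncology_visit",
           cstart + sort(sample.int(60, runif_days(3, 5), replace = TRUE)))
    }
    if (stats::runif(1) < p$benign_second_surgery_prob && noise_span > 0)
      emit("surgery", anchor + 180 + floor(stats::runif(1) * noise_span), "BCS")

    if (recurred) {
      lag <- runif_days(0, p$indicator_lag_max_days)
      sig <- rec_date + lag
      bend <- min(last_contact, sig + p$recur_burst_duration_days)
      emit("oncology_visit", rpois_dates(sig, bend, p$recur_visit_rate_per_year))
      if (stats::runif(1) < p$reimaging_prob)
        emit("imaging", sig + runif_days(0, 14))
      if (stats::runif(1) < p$rebiopsy_prob)
        emit("biopsy", sig + runif_days(7, 28))
      if (stats::runif(1) < p$second_surgery_prob)
        emit("surgery", sig + runif_days(21, 75), "mastectomy")
      if (stats::runif(1) < p$second_chemo_prob) {
        k <- runif_days(p$second_chemo_cycles_range[1],
                        p$second_chemo_cycles_range[2])
        emit("chemo_admin",
             sig + runif_days(14, 45) + (seq_len(k) - 1L) * p$chemo_cycle_interval_days)
      }
      if (stats::runif(1) < p$second_radiation_prob) {
        rs <- sig + runif_days(45, 100)
        emit("radiation_fraction", rs + seq_len(runif_days(10, 15)) - 1L)
      }
    }
    if (!is.na(death)) emit("death", death, cause)

    keep <- ev_date >= dx & ev_date <= last_contact
    ord <- order(ev_date[keep], ev_type[keep])
    evl[[i]] <- data.frame(
      patient_id = id, event_type = ev_type[keep][ord],
      event_date = ev_date[keep][ord], detail = ev_det[keep][ord],
      stringsAsFactors = FALSE)

    bl[[i]] <- data.frame(
      patient_id = id, diagnosis_date = dx, surgery_date = surg,
      surgery_type = surg_type, stage = stage, grade = grade,
      er = er, pr = pr, her2 = her2, age_at_diagnosis = age,
      last_contact_date = last_contact, death_date = death,
      death_cause = cause, stringsAsFactors = FALSE)
    lbl[[i]] <- data.frame(
      patient_id = id, recurred = recurred, recurrence_date = rec_date,
      stringsAsFactors = FALSE)
  }

  new_cohort(do.call(rbind, bl) %||% empty_baselines(),
             do.call(rbind, evl) %||% empty_events(),
             do.call(rbind, lbl) %||% empty_labels())
}

empty_baselines <- function() {
  data.frame(patient_id = character(), diagnosis_date = as.Date(character()),
             surgery_date = as.Date(character()), surgery_type = character(),
             stage = character(), grade = integer(), er = character(),
             pr = character(), her2 = character(), age_at_diagnosis = numeric(),
             last_contact_date = as.Date(character()),
             death_date = as.Date(character()), death_cause = character(),
             stringsAsFactors = FALSE)
}
empty_events <- function() {
  data.frame(patient_id = character(), event_type = character(),
             event_date = as.Date(character()), detail = character(),
             stringsAsFactors = FALSE)
}
empty_labels <- function() {
  data.frame(patient_id = character(), recurred = logical(),
             recurrence_date = as.Date(character()), stringsAsFactors = FALSE)
}

#' Tabulate cohort characteristics
#'
#' Counts and percentages by stage, grade, hormone-receptor and HER2 status,
#' surgery type and treatment receipt (any chemotherapy / radiation /
#' hormone dispense in the event stream), plus the recurrence count and the
#' median (IQR) follow-up in years from diagnosis to last contact.
#'
#' @param cohort a `cohort`.
#' @return a list with `counts` (data frame: variable, level, n, pct),
#'   `recurrence` (n, pct; `NA` without labels) and `followup_years`
#'   (median, q25, q75).
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  b <- cohort$baselines
  n <- nrow(b)
  received <- function(type)
    b$patient_id %in% cohort$events$patient_id[cohort$events$event_type == type]
  vars <- list(
    stage = factor(b$stage, STAGES),
    grade = factor(b$grade, 1:3),
    er = factor(b$er, MARKER_LEVELS),
    pr = factor(b$pr, MARKER_LEVELS),
    her2 = factor(b$her2, MARKER_LEVELS),
    surgery_type = factor(b$surgery_type, SURGERY_TYPES),
    chemotherapy = factor(ifelse(received("chemo_admin"), "yes", "no"), c("no", "yes")),
    radiotherapy = factor(ifelse(received("radiation_fraction"), "yes", "no"), c("no", "yes")),
    hormone_therapy = factor(ifelse(received("hormone_dispense"), "yes", "no"), c("no", "yes"))
  )
  counts <- do.call(rbind, lapply(names(vars), function(v) {
    tab <- table(vars[[v]])
    data.frame(variable = v, level = names(tab), n = as.integer(tab),
               pct = vapply(as.integer(tab), pct1, numeric(1), den = n),
               stringsAsFactors = FALSE)
  }))
  rec <- if (!is.null(cohort$labels)) {
    k <- sum(cohort$labels$recurred)
    list(n = k, pct = pct1(k, n))
  } else list(n = NA_integer_, pct = NA_real_)
  fy <- days_between(b$last_contact_date, b$diagnosis_date) / 365.25
  q <- if (n) stats::quantile(fy, c(0.25, 0.5, 0.75), names = FALSE)
       else rep(NA_real_, 3)
  list(counts = counts,
       recurrence = rec,
       followup_years = list(median = q[2], q25 = q[1], q75 = q[3]))
}
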