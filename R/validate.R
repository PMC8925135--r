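# Validation battery against chart-review gold labels.
#
# Everything the method's users need to judge an algorithm against chart
# review: confusion metrics (1-decimal percentages), the month-binned
# timing-agreement table, rank-sum comparison of RFS lengths, Kaplan-Meier
# curves with a log-rank comparison, per-covariate Cox hazard-ratio and
# p-value concordance, and Table-1-style cohort characteristic comparisons.
# Standard estimators are delegated to the survival package and stats;
# the metric arithmetic and binning conventions live here.

#' Confusion metrics of algorithm calls against gold labels
#'
#' @param calls data frame with `patient_id` and logical
#'   `predicted_recurred` (the `calls` element of [call_cohort()]).
#' @param gold data frame with `patient_id` and logical `recurred`.
#' @return a `confusion_metrics` list: counts `tp, fp, tn, fn` and
#'   percentages `sensitivity, specificity, ppv, npv, accuracy`, each
#'   rounded to one decimal (half away from zero).
#' @export
confusion_metrics <- function(calls, gold) {
  if (!setequal(calls$patient_id, gold$patient_id) ||
      anyDuplicated(calls$patient_id) || anyDuplicated(gold$patient_id))
    stop("calls and gold must cover the same patients exactly once",
         call. = FALSE)
  g <- gold$recurred[match(calls$patient_id, gold$patient_id)]
  p <- calls$predicted_recurred
  counts_to_metrics(tp = sum(p & g), fp = sum(p & !g),
                    tn = sum(!p & !g), fn = sum(!p & g))
}

counts_to_metrics <- function(tp, fp, tn, fn) {
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = pct1(tp, tp + fn),
                 specificity = pct1(tn, tn + fp),
                 ppv = pct1(tp, tp + fp),
                 npv = pct1(tn, tn + fn),
                 accuracy = pct1(tp + tn, tp + fp + tn + fn),
                 n_flagged = tp + fp,
                 n_censored = tn + fn),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("tp=%d fp=%d tn=%d fn=%d | sens %.1f%% spec %.1f%% PPV %.1f%% NPV %.1f%% acc %.1f%%\n",
              x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$specificity, x$ppv,
              x$npv, x$accuracy))
  invisible(x)
}

#' Reconstruct a confusion matrix from printed sensitivity and specificity
#'
#' With the class sizes known, a reported sensitivity/specificity pair
#' pins down the integer confusion matrix: `tp = round(sens * n_pos /
#' 100)`, `tn = round(spec * n_neg / 100)` (half away from zero), and all
#' other metrics follow from those integers. Useful for checking that a
#' set of published metrics is mutually consistent.
#'
#' @param sensitivity_pct,specificity_pct percentages in `[0, 100]`.
#' @param n_pos,n_neg gold positive / negative class sizes.
#' @return a `confusion_metrics`.
#' @export
reconstruct_confusion <- function(sensitivity_pct, specificity_pct,
                                  n_pos, n_neg) {
  stopifnot(sensitivity_pct >= 0, sensitivity_pct <= 100,
            specificity_pct >= 0, specificity_pct <= 100,
            n_pos >= 0, n_neg >= 0)
  tp <- as.integer(round_half_up(sensitivity_pct * n_pos / 100))
  tn <- as.integer(round_half_up(specificity_pct * n_neg / 100))
  counts_to_metrics(tp = tp, fp = n_neg - tn, tn = tn, fn = n_pos - tp)
}

AGREEMENT_BINS <- c("<=1", ">1,<=2", ">2,<=3", ">3,<=6", ">6")

#' Month-binned agreement between estimated and gold recurrence dates
#'
#' For every gold-recurrent patient the absolute difference between the
#' algorithm-estimated and chart-review recurrence date, in months of
#' `month_len_days`, is binned into (<=1, >1-<=2, >2-<=3, >3-<=6, >6).
#' Gold-recurrent patients the algorithm called non-recurrent have no
#' estimated date and enter the >6 bin, so every gold-recurrent patient is
#' counted and the cumulative column ends at their total.
#'
#' @param calls the `calls` data frame of [call_cohort()].
#' @param gold gold labels (`patient_id, recurred, recurrence_date`).
#' @param month_len_days days per month for binning (default 30.4375).
#' @return an `agreement_table` data frame: `bin, n, pct, cum_n, cum_pct`
#'   with an `n_total` attribute.
#' @export
timing_agreement <- function(calls, gold, month_len_days = DAYS_PER_MONTH) {
  g <- gold[gold$recurred, , drop = FALSE]
  n_total <- nrow(g)
  idx <- match(g$patient_id, calls$patient_id)
  if (any(is.na(idx)))
    stop("calls are missing gold-recurrent patients", call. = FALSE)
  est <- calls$estimated_recurrence_date[idx]
  flagged <- calls$predicted_recurred[idx]
  diff_months <- ifelse(flagged,
                        abs(days_between(est, g$recurrence_date)) / month_len_days,
                        Inf)
  bin <- cut(diff_months, breaks = c(-Inf, 1, 2, 3, 6, Inf),
             labels = AGREEMENT_BINS)
  n <- as.integer(table(bin))
  cum <- cumsum(n)
  out <- data.frame(bin = AGREEMENT_BINS, n = n,
                    pct = vapply(n, pct1, numeric(1), den = n_total),
                    cum_n = cum,
                    cum_pct = vapply(cum, pct1, numeric(1), den = n_total),
                    stringsAsFactors = FALSE)
  attr(out, "n_total") <- n_total
  class(out) <- c("agreement_table", class(out))
  out
}

#' Compare two RFS-length samples with the rank-sum test
#'
#' Two-sided Wilcoxon rank-sum. An exact permutation p-value is used when
#' both samples have fewer than 20 observations and no ties; otherwise the
#' normal approximation with tie correction.
#'
#' @param times_a,times_b numeric RFS times (days).
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact computation;
#'   `NULL` (default) applies the size rule.
#' @param paired use the signed-rank (paired) variant; requires equal
#'   lengths in matching order. Default is the unpaired rank-sum.
#' @return the two-sided p-value.
#' @export
compare_rfs_lengths <- function(times_a, times_b, exact = NULL,
                                paired = FALSE) {
  if (!length(times_a) || !length(times_b))
    stop("both samples must be non-empty", call. = FALSE)
  if (is.null(exact))
    exact <- length(times_a) < 20 && length(times_b) < 20 &&
      !anyDuplicated(c(times_a, times_b))
  suppressWarnings(
    stats::wilcox.test(times_a, times_b, exact = exact, correct = FALSE,
                       paired = paired)$p.value)
}

#' Kaplan-Meier curve of RFS records
#'
#' Product-limit estimator via [survival::survfit()], returned as a step
#' table plus median and quartile survival times.
#'
#' @param records survival data frame (`time_days`, logical `event`).
#' @return a `km_curve` list: `steps` (data frame `time, n_risk, n_event,
#'   surv`), `median`, `q25`, `q75`.
#' @export
km_curve <- function(records) {
  if (!nrow(records)) stop("no survival records", call. = FALSE)
  if (any(records$time_days < 0)) stop("negative survival time", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time_days, event) ~ 1,
                           data = records)
  q <- stats::quantile(fit, probs = c(0.25, 0.5, 0.75))$quantile
  list(steps = data.frame(time = fit$time, n_risk = fit$n.risk,
                          n_event = fit$n.event, surv = fit$surv),
       q25 = unname(q[1]), median = unname(q[2]), q75 = unname(q[3]))
}

#' Two-group log-rank test
#'
#' @param records_a,records_b survival data frames (`time_days`, `event`).
#' @return list with `chisq`, `df` and the p-value `p`.
#' @export
logrank <- function(records_a, records_b) {
  if (!nrow(records_a) || !nrow(records_b))
    stop("both groups must be non-empty", call. = FALSE)
  dat <- rbind(data.frame(time = records_a$time_days, event = records_a$event,
                          group = "a"),
               data.frame(time = records_b$time_days, event = records_b$event,
                          group = "b"))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  df <- length(sd$n) - 1
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Default Cox covariate table for a cohort
#'
#' Age group (<=35, 36-40, 41-55, >=56), stage, grade, ER/PR/HER2 status,
#' treatment receipt flags read off the event stream, and diagnosis-year
#' tertile group.
#'
#' @param cohort a `cohort`.
#' @return data frame keyed by `patient_id`, one factor column per
#'   covariate.
#' @export
baseline_covariates <- function(cohort) {
  b <- cohort$baselines
  received <- function(type)
    b$patient_id %in% cohort$events$patient_id[cohort$events$event_type == type]
  yr <- as.integer(format(b$diagnosis_date, "%Y"))
  brk <- unique(stats::quantile(yr, c(0, 1/3, 2/3, 1), names = FALSE))
  yr_group <- if (length(brk) > 1)
    cut(yr, breaks = brk, include.lowest = TRUE) else factor(rep("all", nrow(b)))
  data.frame(
    patient_id = b$patient_id,
    age_group = cut(b$age_at_diagnosis, c(-Inf, 35, 40, 55, Inf),
                    labels = c("<=35", "36-40", "41-55", ">=56")),
    stage = factor(b$stage, STAGES),
    grade = factor(b$grade, 1:3),
    er = factor(b$er, c("neg", "pos")),
    pr = factor(b$pr, c("neg", "pos")),
    her2 = factor(b$her2, c("neg", "pos")),
    chemotherapy = factor(ifelse(received("chemo_admin"), "yes", "no"),
                          c("no", "yes")),
    radiotherapy = factor(ifelse(received("radiation_fraction"), "yes", "no"),
                          c("no", "yes")),
    hormone_therapy = factor(ifelse(received("hormone_dispense"), "yes", "no"),
                             c("no", "yes")),
    dx_year_group = yr_group,
    stringsAsFactors = FALSE)
}

fit_cox_summary <- function(records, covariates) {
  dat <- merge(records, covariates, by = "patient_id")
  vars <- setdiff(names(covariates), "patient_id")
  vars <- vars[vapply(vars, function(v) length(unique(dat[[v]])) > 1, logical(1))]
  fml <- stats::as.formula(paste("survival::Surv(time_days, event) ~",
                                 paste(vars, collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  s <- summary(fit)$coefficients
  data.frame(term = rownames(s), hr = s[, "exp(coef)"],
             p = s[, "Pr(>|z|)"], stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Per-covariate Cox concordance between two survival datasets
#'
#' Fits one proportional-hazards model (Efron ties) per dataset over the
#' shared covariate table and reports, for every coefficient, whether the
#' hazard-ratio direction (>1 vs <1) and the Wald significance at the 5\%
#' two-sided level agree between the two fits. Coefficients that fail to
#' estimate in either fit are flagged and excluded from the match
#' fractions.
#'
#' @param survival_a,survival_b survival data frames (`patient_id,
#'   time_days, event`), e.g. gold vs algorithm-estimated.
#' @param covariates covariate table from [baseline_covariates()] or
#'   user-supplied, keyed by `patient_id`.
#' @return a `concordance_report` list: `table` (per-term HRs, p-values and
#'   match flags), `direction_match_fraction`, `significance_match_fraction`,
#'   `n_terms`, `n_unstable`.
#' @export
cox_concordance <- function(survival_a, survival_b, covariates) {
  a <- fit_cox_summary(survival_a, covariates)
  b <- fit_cox_summary(survival_b, covariates)
  tab <- merge(a, b, by = "term", suffixes = c("_a", "_b"))
  unstable <- !is.finite(tab$hr_a) | !is.finite(tab$hr_b) |
    is.na(tab$p_a) | is.na(tab$p_b) |
    tab$hr_a <= 0 | tab$hr_b <= 0 | tab$hr_a > 1e3 | tab$hr_b > 1e3
  tab$direction_match <- ifelse(unstable, NA, (tab$hr_a > 1) == (tab$hr_b > 1))
  tab$significance_match <- ifelse(unstable, NA,
                                   (tab$p_a < 0.05) == (tab$p_b < 0.05))
  ok <- !unstable
  structure(list(
    table = tab,
    direction_match_fraction = mean(tab$direction_match[ok]),
    significance_match_fraction = mean(tab$significance_match[ok]),
    n_terms = nrow(tab), n_unstable = sum(unstable)),
    class = "concordance_report")
}

#' Compare cohort characteristics between groups
#'
#' Table-1-style comparison: categorical variables are tabulated
#' (count/percent per group) and tested by chi-square, replaced by
#' Fisher's exact test when any expected cell is below 5; continuous
#' variables are summarized as median (IQR) and tested by the t-test, or
#' the rank-sum test when either group fails a Shapiro normality check.
#'
#' @param data data frame with one row per patient.
#' @param group name of the (two-level or more) grouping column.
#' @param variables named character vector: variable name -> `"categorical"`
#'   or `"continuous"`.
#' @return data frame with one row per variable: the test used and its
#'   p-value.
#' @export
compare_characteristics <- function(data, group, variables) {
  if (!group %in% names(data))
    stop(sprintf("grouping variable '%s' not found", group), call. = FALSE)
  g <- factor(data[[group]])
  rows <- lapply(names(variables), function(v) {
    if (!v %in% names(data))
      stop(sprintf("variable '%s' not found", v), call. = FALSE)
    x <- data[[v]]
    if (variables[[v]] == "categorical") {
      tab <- table(factor(x), g)
      exp <- suppressWarnings(stats::chisq.test(tab)$expected)
      if (any(exp < 5)) {
        p <- stats::fisher.test(tab, simulate.p.value = nrow(tab) * ncol(tab) > 10,
                                B = 10000)$p.value
        test <- "fisher"
      } else {
        p <- stats::chisq.test(tab, correct = FALSE)$p.value
        test <- "chisq"
      }
      summary_txt <- paste(apply(tab, 2, function(cl)
        paste(sprintf("%s:%d", rownames(tab), cl), collapse = ",")),
        collapse = " | ")
    } else {
      sets <- split(as.numeric(x), g)
      normal <- all(vapply(sets, function(s) {
        s <- s[!is.na(s)]
        if (length(s) < 3 || length(unique(s)) < 3) return(FALSE)
        stats::shapiro.test(s[seq_len(min(length(s), 5000))])$p.value >= 0.05
      }, logical(1)))
      if (normal && length(sets) == 2) {
        p <- stats::t.test(sets[[1]], sets[[2]])$p.value
        test <- "t"
      } else {
        p <- if (length(sets) == 2)
          suppressWarnings(stats::wilcox.test(sets[[1]], sets[[2]])$p.value)
        else stats::kruskal.test(as.numeric(x), g)$p.value
        test <- if (length(sets) == 2) "wilcoxon" else "kruskal"
      }
      summary_txt <- paste(vapply(sets, function(s)
        sprintf("%.1f (%.1f-%.1f)",
                stats::median(s, na.rm = TRUE),
                stats::quantile(s, 0.25, na.rm = TRUE),
                stats::quantile(s, 0.75, na.rm = TRUE)), character(1)),
        collapse = " | ")
    }
    data.frame(variable = v, type = variables[[v]], test = test,
               summary = summary_txt, p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full validation battery on a labelled cohort
#'
#' For each operating-point tree: applies it with [call_cohort()], then
#' computes confusion metrics, flagged/censored counts, the
#' timing-agreement table, the rank-sum comparison of estimated vs gold
#' RFS lengths, Kaplan-Meier curves for both datasets with the log-rank
#' comparison, Cox hazard-ratio concordance, and a characteristics
#' comparison of the flagged vs gold-recurrent groups.
#'
#' @param cohort a labelled `cohort`.
#' @param trees named list of `recurrence_tree`s (e.g. from
#'   [fit_operating_points()]).
#' @param config the [indicator_config()] the trees were fitted with.
#' @return a `validation_report`: named list per operating point with
#'   elements `confusion`, `n_flagged`, `n_censored`, `agreement`,
#'   `rfs_wilcoxon_p`, `km_algorithm`, `km_gold`, `logrank`, `cox`,
#'   `characteristics`, plus shared element `gold_survival`.
#' @export
validation_report <- function(cohort, trees, config = indicator_config()) {
  if (is.null(cohort$labels))
    stop("cannot validate: cohort has no gold labels", call. = FALSE)
  gsurv <- gold_survival(cohort)
  covs <- baseline_covariates(cohort)
  gold <- cohort$labels
  per_op <- lapply(trees, function(tree) {
    res <- call_cohort(cohort, tree, config)
    cm <- confusion_metrics(res$calls, gold)
    agr <- timing_agreement(res$calls, gold)
    wp <- compare_rfs_lengths(res$survival$time_days, gsurv$time_days)
    lr <- logrank(res$survival, gsurv)
    cc <- cox_concordance(gsurv, res$survival, covs)
    chars <- characteristics_vs_gold(cohort, res$calls, covs)
    list(calls = res$calls, survival = res$survival,
         confusion = cm, n_flagged = cm$n_flagged, n_censored = cm$n_censored,
         agreement = agr, rfs_wilcoxon_p = wp,
         km_algorithm = km_curve(res$survival), km_gold = km_curve(gsurv),
         logrank = lr, cox = cc, characteristics = chars)
  })
  structure(c(per_op, list(gold_survival = gsurv)),
            class = "validation_report")
}

# Characteristics of the algorithm-flagged group vs the chart-review
# recurrent group (categorical covariates only).
characteristics_vs_gold <- function(cohort, calls, covs) {
  gold_ids <- cohort$labels$patient_id[cohort$labels$recurred]
  alg_ids <- calls$patient_id[calls$predicted_recurred]
  dat <- rbind(
    cbind(covs[covs$patient_id %in% gold_ids, , drop = FALSE],
          group = "chart_review"),
    cbind(covs[covs$patient_id %in% alg_ids, , drop = FALSE],
          group = "algorithm"))
  vars <- setdiff(names(covs), "patient_id")
  compare_characteristics(dat, "group",
                          stats::setNames(rep("categorical", length(vars)), vars))
}

#' Write a validation report to delimited files
#'
#' Writes `metrics.csv`, `agreement.csv`, `concordance.csv`,
#' `characteristics.csv`, `km_curves.csv` and a human-readable
#' `summary.txt` under `dir_path`.
#'
#' @param report a [validation_report()].
#' @param dir_path output directory.
#' @return invisibly, the directory path.
#' @export
write_validation_report <- function(report, dir_path) {
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  ops <- setdiff(names(report), "gold_survival")
  metrics <- do.call(rbind, lapply(ops, function(op) {
    cm <- report[[op]]$confusion
    data.frame(operating_point = op, tp = cm$tp, fp = cm$fp, tn = cm$tn,
               fn = cm$fn, sensitivity = cm$sensitivity,
               specificity = cm$specificity, ppv = cm$ppv, npv = cm$npv,
               accuracy = cm$accuracy, n_flagged = cm$n_flagged,
               n_censored = cm$n_censored,
               rfs_wilcoxon_p = report[[op]]$rfs_wilcoxon_p,
               logrank_p = report[[op]]$logrank$p,
               cox_direction_match = report[[op]]$cox$direction_match_fraction,
               cox_significance_match = report[[op]]$cox$significance_match_fraction,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(metrics, file.path(dir_path, "metrics.csv"),
                   row.names = FALSE)
  agreement <- do.call(rbind, lapply(ops, function(op)
    cbind(operating_point = op, as.data.frame(report[[op]]$agreement))))
  utils::write.csv(agreement, file.path(dir_path, "agreement.csv"),
                   row.names = FALSE)
  concord <- do.call(rbind, lapply(ops, function(op)
    cbind(operating_point = op, report[[op]]$cox$table)))
  utils::write.csv(concord, file.path(dir_path, "concordance.csv"),
                   row.names = FALSE)
  chars <- do.call(rbind, lapply(ops, function(op)
    cbind(operating_point = op, report[[op]]$characteristics)))
  utils::write.csv(chars, file.path(dir_path, "characteristics.csv"),
                   row.names = FALSE)
  km <- do.call(rbind, lapply(ops, function(op)
    rbind(cbind(operating_point = op, curve = "algorithm",
                report[[op]]$km_algorithm$steps),
          cbind(operating_point = op, curve = "chart_review",
                report[[op]]$km_gold$steps))))
  utils::write.csv(km, file.path(dir_path, "km_curves.csv"),
                   row.names = FALSE)

  lines <- c("Recurrence algorithm validation against chart review", "")
  for (op in ops) {
    cm <- report[[op]]$confusion
    lines <- c(lines, sprintf("== %s ==", op),
      sprintf("  sensitivity %.1f%%, specificity %.1f%%, PPV %.1f%%, NPV %.1f%%, accuracy %.1f%%",
              cm$sensitivity, cm$specificity, cm$ppv, cm$npv, cm$accuracy),
      sprintf("  flagged %d, censored %d", cm$n_flagged, cm$n_censored),
      sprintf("  cumulative timing agreement <=3 months: %.1f%% of gold-recurrent",
              report[[op]]$agreement$cum_pct[3]),
      sprintf("  RFS rank-sum p = %.3f; log-rank p = %.3f (same patients in both curves; p is descriptive)",
              report[[op]]$rfs_wilcoxon_p, report[[op]]$logrank$p),
      sprintf("  Cox concordance: direction %.0f%%, significance %.0f%% (%d terms, %d unstable)",
              100 * report[[op]]$cox$direction_match_fraction,
              100 * report[[op]]$cox$significance_match_fraction,
              report[[op]]$cox$n_terms, report[[op]]$cox$n_unstable),
      "")
  }
  writeLines(lines, file.path(dir_path, "summary.txt"))
  invisible(dir_path)
}
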