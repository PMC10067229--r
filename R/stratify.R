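# NOD/SOD/POD stratification from the daily clinical course.
#
# Progressive organ dysfunction (POD): de novo kidney, liver or respiratory
# dysfunction (an organ system not dysfunctional at the admission-day
# assessment becoming dysfunctional within the horizon), or ICU admission or
# death within 72 h of ED admission. Stable organ dysfunction (SOD):
# dysfunction present on the admission day with no de novo organ and no
# ICU/death trigger. No organ dysfunction (NOD): neither.

#' Construct a patient clinical record
#'
#' @param days Data frame of daily assessments with columns `day` (0 =
#'   admission day), `creatinine` (umol/L), `bilirubin` (umol/L),
#'   `alp_uln`, `asat_uln`, `alat_uln` (multiples of the upper limit of
#'   normal), `pao2_kpa`, `paco2_kpa` (daily worst), `spo2` (%, daily
#'   worst), `o2_lmin` (concurrent oxygen supply, L/min), `ventilated`
#'   (logical). Missing values are allowed.
#' @param baseline_creatinine Baseline creatinine (umol/L), the earliest
#'   value available at or before admission.
#' @param icu_admission_h,death_h Hours from ED admission (NA if none).
#' @param rr,sbp,gcs Admission respiratory rate (/min), systolic blood
#'   pressure (mmHg) and Glasgow Coma Scale, for the qSOFA comparator.
#' @param sepsis_severity Externally supplied comparator score value.
#' @param patient_id Identifier.
#' @return A `patient_record` list.
#' @export
patient_record <- function(days, baseline_creatinine,
                           icu_admission_h = NA_real_, death_h = NA_real_,
                           rr = NA_real_, sbp = NA_real_, gcs = NA_real_,
                           sepsis_severity = NA_real_,
                           patient_id = "patient") {
  stopifnot(is.data.frame(days), "day" %in% names(days))
  need <- c("creatinine", "bilirubin", "alp_uln", "asat_uln", "alat_uln",
            "pao2_kpa", "paco2_kpa", "spo2", "o2_lmin", "ventilated")
  for (col in need) if (!col %in% names(days)) days[[col]] <- NA
  if (!is.na(baseline_creatinine) && baseline_creatinine <= 0)
    stop("baseline creatinine must be positive")
  sp <- days$spo2[!is.na(days$spo2)]
  if (any(sp < 0 | sp > 100)) stop("SpO2 must lie in [0, 100]")
  structure(list(days = days[order(days$day), , drop = FALSE],
                 baseline_creatinine = baseline_creatinine,
                 icu_admission_h = icu_admission_h, death_h = death_h,
                 rr = rr, sbp = sbp, gcs = gcs,
                 sepsis_severity = sepsis_severity,
                 patient_id = patient_id),
            class = "patient_record")
}

day_row <- function(record, day) {
  i <- match(day, record$days$day)
  if (is.na(i)) NULL else record$days[i, , drop = FALSE]
}

#' Assess acute kidney injury on a given day
#'
#' KDIGO-style creatinine criterion as used in the study: a rise of at least
#' 25.6 umol/L above baseline, or a value of at least 150% of baseline.
#'
#' @param record A [patient_record()].
#' @param day Day index (0 = admission day).
#' @param rise_threshold Absolute rise threshold (umol/L). The study prints
#'   25.6; set `use_canonical_kdigo = TRUE` for the canonical 26.5.
#' @param use_canonical_kdigo Use the canonical KDIGO absolute rise (26.5).
#' @return TRUE/FALSE (FALSE when the day's creatinine is missing).
#' @export
assess_aki <- function(record, day, rise_threshold = 25.6,
                       use_canonical_kdigo = FALSE) {
  if (use_canonical_kdigo) rise_threshold <- 26.5
  if (is.na(record$baseline_creatinine)) stop("baseline creatinine required")
  r <- day_row(record, day)
  if (is.null(r) || is.na(r$creatinine)) return(FALSE)
  (r$creatinine - record$baseline_creatinine >= rise_threshold) ||
    (r$creatinine >= 1.5 * record$baseline_creatinine)
}

#' Assess liver dysfunction on a given day
#'
#' Bilirubin above 35.2 umol/L AND at least one of ALP, ASAT, ALAT above
#' twice the upper limit of normal. Missing values count as not exceeding.
#'
#' @inheritParams assess_aki
#' @return TRUE/FALSE.
#' @export
assess_liver <- function(record, day) {
  r <- day_row(record, day)
  if (is.null(r)) return(FALSE)
  bili <- !is.na(r$bilirubin) && r$bilirubin > 35.2
  enz <- isTRUE(r$alp_uln > 2) || isTRUE(r$asat_uln > 2) || isTRUE(r$alat_uln > 2)
  bili && enz
}

#' Assess respiratory dysfunction on a given day
#'
#' Mechanical ventilation, or any of: worst PaO2 below 8.0 kPa, worst PaCO2
#' above 6.5 kPa, worst SpO2 below 90% on ambient air, or worst SpO2 below
#' 95% with at least 2 L/min oxygen supply. Evaluated on the measurements
#' present that day.
#'
#' @inheritParams assess_aki
#' @return TRUE/FALSE.
#' @export
assess_respiratory <- function(record, day) {
  r <- day_row(record, day)
  if (is.null(r)) return(FALSE)
  if (isTRUE(r$ventilated)) return(TRUE)
  if (isTRUE(r$pao2_kpa < 8.0)) return(TRUE)
  if (isTRUE(r$paco2_kpa > 6.5)) return(TRUE)
  if (!is.na(r$spo2)) {
    o2 <- if (is.na(r$o2_lmin)) 0 else r$o2_lmin
    if (o2 >= 2 && r$spo2 < 95) return(TRUE)
    if (o2 < 2 && r$spo2 < 90) return(TRUE)
  }
  FALSE
}

#' Classify a patient into NOD, SOD or POD
#'
#' @param record A [patient_record()].
#' @param horizon_h Horizon (h) for the ICU-admission and death triggers
#'   (fixed at 72 in the study) and, by default, for de novo organ
#'   dysfunction as well.
#' @param organ_horizon_h Horizon (h) for de novo organ dysfunction; daily
#'   assessments up to `floor(organ_horizon_h / 24)` days are examined.
#' @param ... Passed to [assess_aki()].
#' @return A `group_label` list: `label` ("NOD"/"SOD"/"POD"), `trigger`
#'   (which criterion fired) and `trigger_day` (day or hour of the trigger).
#' @export
classify_outcome <- function(record, horizon_h = 72,
                             organ_horizon_h = horizon_h, ...) {
  if (nrow(record$days) == 0 && is.na(record$icu_admission_h) &&
      is.na(record$death_h))
    stop("no clinical data available for ", record$patient_id)
  assess <- function(day) c(aki = assess_aki(record, day, ...),
                            liver = assess_liver(record, day),
                            resp = assess_respiratory(record, day))
  base <- assess(0)
  label <- NULL; trigger <- NA_character_; trigger_day <- NA_real_
  if (!is.na(record$death_h) && record$death_h <= horizon_h) {
    label <- "POD"; trigger <- "death"; trigger_day <- record$death_h / 24
  } else if (!is.na(record$icu_admission_h) &&
             record$icu_admission_h <= horizon_h) {
    label <- "POD"; trigger <- "icu_admission"
    trigger_day <- record$icu_admission_h / 24
  } else {
    max_day <- floor(organ_horizon_h / 24)
    days <- record$days$day
    for (d in sort(days[days > 0 & days <= max_day])) {
      st <- assess(d)
      novo <- names(st)[st & !base]
      if (length(novo)) {
        label <- "POD"; trigger <- paste0("de_novo_", novo[1])
        trigger_day <- d
        break
      }
    }
  }
  if (is.null(label)) {
    if (any(base)) {
      label <- "SOD"; trigger <- paste0("admission_", names(base)[base][1])
      trigger_day <- 0
    } else {
      label <- "NOD"
    }
  }
  structure(list(label = label, trigger = trigger, trigger_day = trigger_day,
                 patient_id = record$patient_id),
            class = "group_label")
}

#' @export
print.group_label <- function(x, ...) {
  cat(sprintf("%s: %s%s\n", x$patient_id, x$label,
              if (!is.na(x$trigger)) paste0(" (", x$trigger, ")") else ""))
  invisible(x)
}

#' Stratify a whole cohort
#'
#' @param records List of [patient_record()]s (or a `cohort`).
#' @param ... Passed to [classify_outcome()].
#' @return Data frame with `patient_id`, `label`, `trigger`, `trigger_day`.
#' @export
stratify_cohort <- function(records, ...) {
  if (inherits(records, "cohort"))
    records <- lapply(records$patients, `[[`, "record")
  out <- lapply(records, function(r) {
    g <- classify_outcome(r, ...)
    data.frame(patient_id = r$patient_id, label = g$label,
               trigger = g$trigger, trigger_day = g$trigger_day,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
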