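# Synthetic clinical courses. Each course is built so that classify_outcome()
# deterministically returns the intended group: lab values are drawn with
# safe margins on either side of the stratification thresholds.

normal_day <- function(day, cr0) {
  data.frame(day = day,
             creatinine = cr0 + runif(1, -8, 8),
             bilirubin = runif(1, 5, 25),
             alp_uln = runif(1, 0.3, 1.5),
             asat_uln = runif(1, 0.3, 1.5),
             alat_uln = runif(1, 0.3, 1.5),
             pao2_kpa = runif(1, 9.5, 13),
             paco2_kpa = runif(1, 4.5, 6.0),
             spo2 = runif(1, 94, 99),
             o2_lmin = 0,
             ventilated = FALSE)
}

dysfunction_day <- function(row, organ) {
  if (organ == "aki") {
    # handled at the creatinine level by the caller
  } else if (organ == "liver") {
    row$bilirubin <- runif(1, 45, 90)
    row$alat_uln <- runif(1, 2.5, 4)
  } else if (organ == "resp") {
    mode <- sample(c("spo2_air", "spo2_o2", "pao2", "paco2", "vent"), 1)
    if (mode == "spo2_air") { row$spo2 <- runif(1, 84, 88); row$o2_lmin <- 0 }
    if (mode == "spo2_o2")  { row$spo2 <- runif(1, 88, 93); row$o2_lmin <- runif(1, 2, 5) }
    if (mode == "pao2")     row$pao2_kpa <- runif(1, 6, 7.5)
    if (mode == "paco2")    row$paco2_kpa <- runif(1, 6.8, 8)
    if (mode == "vent")     row$ventilated <- TRUE
  }
  row
}

comparator_inputs <- function(group) {
  mu <- switch(group,
               NOD = c(rr = 20, sbp = 129, sev = 4.0, p15 = 0.90),
               SOD = c(rr = 23, sbp = 118, sev = 5.5, p15 = 0.80),
               POD = c(rr = 26, sbp = 108, sev = 7.0, p15 = 0.55))
  rr <- max(8, rnorm(1, mu[["rr"]], 3))
  sbp <- min(220, max(60, rnorm(1, mu[["sbp"]], 12)))
  gcs <- if (runif(1) < mu[["p15"]]) 15 else sample(12:14, 1)
  sev <- max(0, rnorm(1, mu[["sev"]], 1.5))
  list(rr = rr, sbp = sbp, gcs = gcs, sepsis_severity = sev)
}

#' Simulate a clinical course for an intended outcome group
#'
#' Draws daily labs, blood gases and oxygenation so that the stratification
#' criteria classify the course into `intended_group`. POD courses realise
#' exactly one randomly chosen trigger (de novo kidney/liver/respiratory
#' dysfunction, ICU admission, or death within 72 h); SOD courses carry one
#' dysfunction from day 0 onward with no de novo organ and no ICU/death;
#' NOD courses stay inside normal thresholds throughout.
#'
#' @param intended_group "NOD", "SOD" or "POD".
#' @param seed Integer seed.
#' @param n_days Number of daily assessments after admission (default 3,
#'   covering the 72 h horizon).
#' @param patient_id Identifier.
#' @return A [patient_record()].
#' @export
simulate_patient_course <- function(intended_group = c("NOD", "SOD", "POD"),
                                    seed = 1L, n_days = 3,
                                    patient_id = "synthetic") {
  intended_group <- match.arg(intended_group)
  set.seed(as.integer(seed))
  cr0 <- runif(1, 60, 100)
  days <- 0:n_days
  tab <- do.call(rbind, lapply(days, normal_day, cr0 = cr0))
  icu_h <- NA_real_; death_h <- NA_real_

  if (intended_group == "SOD") {
    organ <- sample(c("aki", "liver", "resp"), 1)
    if (organ == "aki") {
      tab$creatinine <- cr0 + runif(nrow(tab), 35, 80)
    } else {
      for (i in seq_len(nrow(tab))) tab[i, ] <- dysfunction_day(tab[i, ], organ)
    }
  } else if (intended_group == "POD") {
    trigger <- sample(c("aki", "liver", "resp", "icu", "death"), 1)
    if (trigger == "icu") {
      icu_h <- runif(1, 4, 70)
    } else if (trigger == "death") {
      death_h <- runif(1, 12, 70)
      tab <- tab[tab$day <= floor(death_h / 24), , drop = FALSE]
    } else {
      onset <- sample(seq_len(min(3, n_days)), 1)
      for (i in which(tab$day >= onset)) {
        if (trigger == "aki") {
          tab$creatinine[i] <- cr0 + runif(1, 35, 80)
        } else {
          tab[i, ] <- dysfunction_day(tab[i, ], trigger)
        }
      }
    }
  }
  cmp <- comparator_inputs(intended_group)
  patient_record(tab, baseline_creatinine = cr0,
                 icu_admission_h = icu_h, death_h = death_h,
                 rr = cmp$rr, sbp = cmp$sbp, gcs = cmp$gcs,
                 sepsis_severity = cmp$sepsis_severity,
                 patient_id = patient_id)
}
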