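# Synthetic-cohort generator: IPFM-style tachograms, rendered ECG waveforms,
# clinical-lab courses that classify deterministically into NOD/SOD/POD, and
# a dropout process shaped like the study's attrition.

#' Simulation configuration
#'
#' Parameters of the synthetic cohort. Beat times follow an integral-pulse-
#' frequency-modulation scheme: the instantaneous NN interval is `mean_nn`
#' plus one sinusoidal (or band-limited-noise) modulation per spectral band.
#' Group effects act multiplicatively on the mean NN interval and on the
#' modulation amplitudes, emulating the shorter NN intervals and reduced
#' low-frequency power seen in deteriorating patients.
#'
#' @param mean_nn Mean NN interval (ms). Default 600 ms, i.e. a heart rate of
#'   100 bpm, typical of septic tachycardia at triage.
#' @param band_amp Named modulation amplitudes (ms) for ULF, VLF, LF, HF.
#' @param band_freq Named modulation centre frequencies (Hz); each must lie
#'   inside its band.
#' @param modulation `"sine"` (default) for a single sinusoid per band, or
#'   `"noise"` for band-limited noise (a superposition of random-phase
#'   sinusoids spread over the band).
#' @param ectopic_rate Probability per beat of an ectopic displacement (one
#'   shortened interval followed by a compensatory lengthened one).
#' @param missed_beat_rate Probability per beat of a missed detection (two
#'   intervals merged into one).
#' @param record_duration Record length (s). Default 48 h, the study horizon.
#' @param sampling_rate ECG sampling rate (Hz). Default 500.
#' @param ecg_noise_sd Gaussian noise on the rendered ECG (mV).
#' @param baseline_amp,baseline_freq Sinusoidal baseline wander (mV, Hz).
#' @param group_sizes Named counts for NOD, SOD, POD. Defaults 119/38/11.
#' @param group_effects List per group of `nn` and `amp` multiplicative
#'   shifts applied to `mean_nn` and `band_amp`.
#' @param between_sd Lognormal between-patient standard deviation on the
#'   patient-level mean NN multiplier.
#' @param amp_between_sd Lognormal between-patient standard deviation on
#'   the modulation-amplitude multiplier; HRV power varies far more across
#'   patients than mean heart rate does, hence the larger default.
#' @param dropout_times Optional explicit per-patient censoring times (h).
#'   When `NULL`, times are drawn from a segment schedule calibrated so
#'   expected cohort counts at 0/12/24/48 h are 168/105/69/25.
#' @param ectopic_shift Fraction of the local NN interval by which an
#'   ectopic beat arrives early.
#' @param min_nn Floor (ms) for the instantaneous interval.
#' @param seed Root seed; per-patient streams are derived from it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(mean_nn = 600,
                       band_amp = c(ULF = 30, VLF = 25, LF = 15, HF = 10),
                       band_freq = c(ULF = 0.002, VLF = 0.01, LF = 0.1, HF = 0.25),
                       modulation = c("sine", "noise"),
                       ectopic_rate = 0.01,
                       missed_beat_rate = 0.005,
                       record_duration = 48 * 3600,
                       sampling_rate = 500,
                       ecg_noise_sd = 0.02,
                       baseline_amp = 0.05,
                       baseline_freq = 0.25,
                       group_sizes = c(NOD = 119, SOD = 38, POD = 11),
                       group_effects = list(
                         NOD = c(nn = 1.00, amp = 1.00),
                         SOD = c(nn = 0.96, amp = 0.85),
                         POD = c(nn = 0.85, amp = 0.50)),
                       between_sd = 0.10,
                       amp_between_sd = 0.40,
                       dropout_times = NULL,
                       ectopic_shift = 0.4,
                       min_nn = 250,
                       seed = 1L) {
  modulation <- match.arg(modulation)
  # tolerate YAML-style nested lists for the named numeric fields
  if (is.list(band_amp)) band_amp <- unlist(band_amp)
  if (is.list(band_freq)) band_freq <- unlist(band_freq)
  if (is.list(group_sizes)) group_sizes <- unlist(group_sizes)
  group_effects <- lapply(group_effects,
                          function(e) if (is.list(e)) unlist(e) else e)
  cfg <- list(mean_nn = mean_nn, band_amp = band_amp, band_freq = band_freq,
              modulation = modulation, ectopic_rate = ectopic_rate,
              missed_beat_rate = missed_beat_rate,
              record_duration = record_duration,
              sampling_rate = sampling_rate, ecg_noise_sd = ecg_noise_sd,
              baseline_amp = baseline_amp, baseline_freq = baseline_freq,
              group_sizes = group_sizes, group_effects = group_effects,
              between_sd = between_sd, amp_between_sd = amp_between_sd,
              dropout_times = dropout_times,
              ectopic_shift = ectopic_shift, min_nn = min_nn,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$mean_nn), length(cfg$mean_nn) == 1)
  if (cfg$mean_nn <= 0) stop("mean_nn must be positive")
  if (cfg$record_duration <= 0) stop("record_duration must be positive")
  rates <- c(cfg$ectopic_rate, cfg$missed_beat_rate)
  if (any(rates < 0 | rates > 1)) stop("beat artifact rates must lie in [0, 1]")
  if (any(cfg$group_sizes < 0)) stop("group_sizes must be nonnegative")
  bands <- spectral_bands()
  for (b in names(cfg$band_freq)) {
    f <- cfg$band_freq[[b]]
    if (f < bands$lower[[b]] || f >= bands$upper[[b]])
      stop("band centre frequency for ", b, " lies outside its band")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  mean NN %.0f ms, %s modulation, record %.1f h\n",
              x$mean_nn, x$modulation, x$record_duration / 3600))
  cat(sprintf("  groups: %s\n",
              paste(names(x$group_sizes), x$group_sizes, sep = "=",
                    collapse = ", ")))
  invisible(x)
}

# Expand per-band modulation into the (amp, freq, phase) triples given to the
# beat generator. "noise" spreads each band's amplitude over 8 random-phase
# sinusoids across the band, giving a rough band-limited process with the
# same total power as the single sinusoid.
modulation_components <- function(cfg, amp_scale = 1) {
  bands <- spectral_bands()
  amp <- numeric(0); freq <- numeric(0); phase <- numeric(0)
  for (b in names(cfg$band_amp)) {
    a <- cfg$band_amp[[b]] * amp_scale
    if (a <= 0) next
    if (cfg$modulation == "sine") {
      amp <- c(amp, a)
      freq <- c(freq, cfg$band_freq[[b]])
      phase <- c(phase, runif(1, 0, 2 * pi))
    } else {
      k <- 8L
      lo <- max(bands$lower[[b]], 1e-4)
      amp <- c(amp, rep(a / sqrt(k), k))
      freq <- c(freq, runif(k, lo, bands$upper[[b]]))
      phase <- c(phase, runif(k, 0, 2 * pi))
    }
  }
  list(amp = amp, freq = freq, phase = phase)
}

#' Simulate an NN-interval series with ground truth
#'
#' Generates beat times by integral pulse frequency modulation (instantaneous
#' interval = `mean_nn` plus the per-band modulations), then injects ectopic
#' and missed-beat artifacts at the configured per-beat rates. Ectopic beats
#' are displaced early, producing a shortened interval followed by a
#' compensatory lengthened one; missed beats merge two intervals into one.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for this series; identical seed and config give
#'   identical output.
#' @param amp_scale,nn_scale Extra multiplicative shifts (used for group
#'   effects and between-patient variation).
#' @return List with `nn` (an `nn_series` data frame: `time_s`, `nn_ms`,
#'   `flagged`) and `truth` (true peak times, true NN intervals, indices of
#'   artifact-corrupted intervals, generative parameters).
#' @export
simulate_nn_series <- function(config = sim_config(), seed = config$seed,
                               amp_scale = 1, nn_scale = 1) {
  validate_sim_config(config)
  set.seed(as.integer(seed))
  comp <- modulation_components(config, amp_scale)
  mean_nn <- config$mean_nn * nn_scale
  beats <- cpp_ipfm_beats(config$record_duration, mean_nn,
                          comp$amp, comp$freq, comp$phase,
                          numeric(0), 1, config$min_nn)
  true_beats <- beats
  n <- length(beats)
  flag_end <- rep(FALSE, n)   # does the interval ENDING at this beat carry an artifact?
  ect <- integer(0); mis <- integer(0)
  if (n > 6 && (config$ectopic_rate > 0 || config$missed_beat_rate > 0)) {
    eligible <- 3:(n - 2)
    u <- runif(length(eligible))
    pick <- eligible[u < config$ectopic_rate + config$missed_beat_rate]
    is_ect <- runif(length(pick)) <
      config$ectopic_rate / (config$ectopic_rate + config$missed_beat_rate)
    # keep picks at least 3 beats apart so artifact effects do not overlap
    if (length(pick)) {
      keep <- c(TRUE, diff(pick) > 2)
      pick <- pick[keep]; is_ect <- is_ect[keep]
    }
    ect <- pick[is_ect]; mis <- pick[!is_ect]
    if (length(ect)) {
      beats[ect] <- beats[ect] -
        config$ectopic_shift * (beats[ect] - beats[ect - 1])
      flag_end[ect] <- TRUE       # shortened interval ends at the displaced beat
      flag_end[ect + 1] <- TRUE   # compensatory interval ends at the next beat
    }
    if (length(mis)) flag_end[mis + 1] <- TRUE  # merged interval ends one beat on
  }
  keep <- if (length(mis)) setdiff(seq_len(n), mis) else seq_len(n)
  t2 <- beats[keep]; f2 <- flag_end[keep]
  nn <- data.frame(time_s = t2[-1], nn_ms = diff(t2) * 1000,
                   flagged = FALSE)
  class(nn) <- c("nn_series", "data.frame")
  truth <- list(true_peak_times = true_beats,
                true_nn = diff(true_beats) * 1000,
                injected_artifact_indices = which(f2[-1]),
                n_ectopic = length(ect), n_missed = length(mis),
                mean_nn = mean_nn, amp_scale = amp_scale)
  list(nn = nn, truth = truth)
}

#' Render a synthetic ECG waveform from beat times
#'
#' Places a QRS-like biphasic template (dominant R deflection flanked by
#' small Q and S dips) at each peak time, with optional P and T bumps,
#' Gaussian measurement noise and sinusoidal baseline wander.
#'
#' @param peak_times Strictly increasing beat times (s).
#' @param config A [sim_config()]; supplies sampling rate, noise, wander.
#' @param duration Record length (s); defaults to `config$record_duration`.
#' @param include_pt Add P and T waves (default TRUE).
#' @param t0 Admission offset (s) of the first sample.
#' @param patient_id Identifier carried on the record.
#' @return An `ecg_record`: list with `samples` (mV), `fs`, `t0`,
#'   `patient_id`, and `true_peak_times`.
#' @export
render_ecg <- function(peak_times, config = sim_config(),
                       duration = config$record_duration,
                       include_pt = TRUE, t0 = 0, patient_id = "synthetic") {
  if (length(peak_times) > 1 && any(diff(peak_times) <= 0))
    stop("peak times must be strictly increasing")
  fs <- config$sampling_rate
  n <- round(duration * fs)
  tt <- t0 + (seq_len(n) - 1) / fs
  samples <- numeric(n)
  gauss <- function(center, sigma, amp) {
    # add a Gaussian bump at each center; support trimmed to 4 sigma
    for (p in center) {
      i0 <- max(1L, floor((p - 4 * sigma - t0) * fs) + 1L)
      i1 <- min(n, ceiling((p + 4 * sigma - t0) * fs) + 1L)
      if (i1 < i0) next
      idx <- i0:i1
      samples[idx] <<- samples[idx] + amp * exp(-((tt[idx] - p)^2) / (2 * sigma^2))
    }
  }
  if (length(peak_times)) {
    gauss(peak_times, 0.008, 1.0)            # R
    gauss(peak_times - 0.025, 0.008, -0.15)  # Q
    gauss(peak_times + 0.025, 0.008, -0.20)  # S
    if (include_pt) {
      gauss(peak_times - 0.18, 0.03, 0.10)   # P
      gauss(peak_times + 0.30, 0.05, 0.20)   # T
    }
  }
  if (config$baseline_amp > 0)
    samples <- samples +
      config$baseline_amp * sin(2 * pi * config$baseline_freq * tt)
  if (config$ecg_noise_sd > 0)
    samples <- samples + rnorm(n, 0, config$ecg_noise_sd)
  structure(list(samples = samples, fs = fs, t0 = t0,
                 patient_id = patient_id,
                 true_peak_times = peak_times),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ECG record '%s': %d samples @ %g Hz (%.1f min), t0 = %g s\n",
              x$patient_id, length(x$samples), x$fs,
              length(x$samples) / x$fs / 60, x$t0))
  invisible(x)
}

# Draw a censoring time (h) from the attrition schedule: segment
# probabilities chosen so expected cohort counts at 0/12/24/48 h match
# 168/105/69/25; uniform within segments, floored at 1 h.
draw_dropout_time <- function(n = 1) {
  p <- c(63, 36, 44, 25) / 168
  seg <- sample.int(4, n, replace = TRUE, prob = p)
  lo <- c(1, 12, 24, 48)[seg]
  hi <- c(12, 24, 48, 48)[seg]
  ifelse(seg == 4, 48, runif(n, lo, hi))
}

#' Simulate a full synthetic cohort
#'
#' One NN series (optionally a rendered ECG) plus one clinical course per
#' patient. Group effects multiply the patient's mean NN and modulation
#' amplitudes; each record is truncated at the patient's dropout time.
#'
#' @param config A [sim_config()].
#' @param render Render ECG waveforms as well (slow for long records).
#' @return A `cohort` object: list with `patients` (per-patient list of
#'   `nn`, `truth`, `record` (clinical course), `group`, `dropout_h`,
#'   optionally `ecg`) and the `config`.
#' @export
simulate_cohort <- function(config = sim_config(), render = FALSE) {
  validate_sim_config(config)
  if (sum(config$group_sizes) == 0) stop("cohort must contain at least one patient")
  groups <- rep(names(config$group_sizes), config$group_sizes)
  n <- length(groups)
  set.seed(config$seed)
  dropout <- config$dropout_times %||% draw_dropout_time(n)
  dropout <- rep_len(dropout, n)
  pat_seeds <- sample.int(.Machine$integer.max - n, 1L) + seq_len(n)
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    g <- groups[i]
    eff <- config$group_effects[[g]]
    set.seed(pat_seeds[i])
    nn_mult <- eff[["nn"]] * exp(rnorm(1, 0, config$between_sd))
    amp_mult <- eff[["amp"]] * exp(rnorm(1, 0, config$amp_between_sd))
    dur <- min(config$record_duration, dropout[i] * 3600)
    cfg_i <- config
    cfg_i$record_duration <- dur
    sim <- simulate_nn_series(cfg_i, seed = pat_seeds[i],
                              amp_scale = amp_mult, nn_scale = nn_mult)
    rec <- simulate_patient_course(g, seed = pat_seeds[i] + 1L,
                                   patient_id = sprintf("P%03d", i))
    ecg <- NULL
    if (render) {
      set.seed(pat_seeds[i] + 2L)
      ecg <- render_ecg(sim$truth$true_peak_times, cfg_i, duration = dur,
                        patient_id = sprintf("P%03d", i))
    }
    patients[[i]] <- list(patient_id = sprintf("P%03d", i), group = g,
                          dropout_h = dropout[i] , nn = sim$nn,
                          truth = sim$truth, record = rec, ecg = ecg)
  }
  structure(list(patients = patients, config = config), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  g <- table(vapply(x$patients, `[[`, "", "group"))
  cat(sprintf("Synthetic cohort: %d patients (%s)\n", length(x$patients),
              paste(names(g), g, sep = "=", collapse = ", ")))
  invisible(x)
}
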