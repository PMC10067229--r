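# Per-window HRV features: time-domain statistics, Poincare axes, sample
# entropy, and Lomb-Scargle band powers of the unevenly sampled tachogram.

#' Time-domain HRV features
#'
#' AVNN = mean; SDNN = sample standard deviation (n-1 denominator);
#' RMSSD = root mean square of successive differences; NN50 = count of
#' successive differences strictly greater than 50 ms in magnitude;
#' pNN50 = 100 * NN50 / (n - 1); CV = SDNN / AVNN.
#'
#' @param nn_ms Numeric vector of NN intervals (ms); at least 2 values.
#' @return Named list with AVNN, SDNN, RMSSD, NN50, pNN50, CV.
#' @export
time_domain_features <- function(nn_ms) {
  n <- length(nn_ms)
  if (n < 2)
    return(list(AVNN = NA_real_, SDNN = NA_real_, RMSSD = NA_real_,
                NN50 = NA_real_, pNN50 = NA_real_, CV = NA_real_))
  d <- diff(nn_ms)
  avnn <- mean(nn_ms)
  sdnn <- stats::sd(nn_ms)
  nn50 <- sum(abs(d) > 50)
  list(AVNN = avnn, SDNN = sdnn,
       RMSSD = sqrt(mean(d^2)),
       NN50 = nn50, pNN50 = 100 * nn50 / (n - 1),
       CV = sdnn / avnn)
}

#' Poincare-plot axes SD1 and SD2
#'
#' SD1 = SDSD / sqrt(2) with SDSD the sample standard deviation of
#' successive differences; SD2 = sqrt(2 * SDNN^2 - SD1^2), floored at 0.
#'
#' @param nn_ms Numeric vector of NN intervals (ms); at least 3 values.
#' @return Named list with SD1, SD2.
#' @export
poincare_features <- function(nn_ms) {
  if (length(nn_ms) < 3) return(list(SD1 = NA_real_, SD2 = NA_real_))
  sd1 <- stats::sd(diff(nn_ms)) / sqrt(2)
  sd2sq <- 2 * stats::sd(nn_ms)^2 - sd1^2
  list(SD1 = sd1, SD2 = sqrt(max(0, sd2sq)))
}

#' Sample entropy
#'
#' SampEn = -ln(A/B), where B counts pairs of m-length templates within
#' Chebyshev tolerance r and A counts pairs of (m+1)-length templates;
#' self-matches excluded (Richman-Moorman convention with N - m templates
#' for both lengths).
#'
#' @param x Numeric sequence of length at least m + 2.
#' @param m Embedding length (default 2).
#' @param r Tolerance; default 0.2 times the sample standard deviation of
#'   `x`.
#' @return SampEn value, or NA (with a warning) when A or B is zero.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  if (length(x) <= m + 1) return(NA_real_)
  if (is.na(r) || r < 0) return(NA_real_)
  cnt <- cpp_sampen_counts(as.numeric(x), as.integer(m), r)
  if (cnt[1] == 0 || cnt[2] == 0) {
    warning("sample entropy undefined: no template matches within tolerance")
    return(NA_real_)
  }
  -log(cnt[2] / cnt[1])
}

#' Lomb-Scargle power spectral estimate of a tachogram
#'
#' Classic tau-offset Lomb-Scargle periodogram on the unevenly timed
#' intervals, evaluated on a uniform frequency grid from `1/(ofac * span)`
#' up to `fmax`. Powers are scaled so that a sinusoidal modulation of
#' amplitude A concentrates approximately A^2/2 (ms^2) in its band.
#'
#' @param time_s Interval end-times (s).
#' @param nn_ms Interval values (ms).
#' @param fmax Upper frequency (Hz), default 0.4 (HF upper edge).
#' @param ofac Oversampling factor for the frequency grid.
#' @param span Nominal record span (s) fixing the grid spacing; default
#'   300 s, the window length.
#' @return List with `freq` (Hz) and `power` (ms^2 per grid bin, i.e. band
#'   power = sum over the band's bins).
#' @export
lomb_psd <- function(time_s, nn_ms, fmax = 0.4, ofac = 4, span = 300) {
  n <- length(nn_ms)
  df <- 1 / (ofac * span)
  nf <- floor(fmax / df)
  p <- cpp_lomb(as.numeric(time_s), as.numeric(nn_ms), df, df, nf)
  freq <- df * seq_len(nf)
  list(freq = freq, power = p * 2 / (n * ofac))
}

#' Welch estimate on a resampled tachogram (cross-check option)
#'
#' Cubic-interpolates the tachogram onto a uniform 4 Hz grid and computes a
#' plain FFT periodogram (single segment, no taper). Provided as an
#' independent route to the spectral band powers.
#'
#' @inheritParams lomb_psd
#' @param resample_hz Resampling rate (Hz).
#' @return List with `freq` and `power` on the same scale as [lomb_psd()].
#' @export
welch_psd <- function(time_s, nn_ms, fmax = 0.4, resample_hz = 4) {
  tt <- seq(min(time_s), max(time_s), by = 1 / resample_hz)
  y <- stats::spline(time_s, nn_ms, xout = tt)$y
  y <- y - mean(y)
  n <- length(y)
  sp <- Mod(stats::fft(y))^2 / n
  freq <- (seq_len(n) - 1) / n * resample_hz
  sel <- freq > 0 & freq <= fmax
  # one-sided: double everything below Nyquist
  list(freq = freq[sel], power = 2 * sp[sel] / n)
}

#' Spectral band powers of one window
#'
#' Integrates the PSD over the ULF, VLF, LF and HF bands. TotalPower is the
#' sum of LF and HF (the study's definition); the conventional full-band
#' integral up to 0.4 Hz is additionally reported as `FullBandPower`.
#' LFnorm = LF/(LF+HF), HFnorm = HF/(LF+HF), LFHFratio = LF/HF; all three
#' are missing when LF + HF = 0. `ULF_unresolved`/`VLF_unresolved` flag
#' bands whose lower edge lies below the window's resolvable frequency
#' (1/300 Hz for 5-minute windows).
#'
#' @param time_s,nn_ms Interval end-times (s) and values (ms).
#' @param method `"lomb"` (default) or `"welch"`.
#' @param bands Band edges, see [spectral_bands()].
#' @param span Nominal window length (s).
#' @param ... Passed to the estimator.
#' @return Named list with ULF, VLF, LF, HF, TotalPower, LFnorm, HFnorm,
#'   LFHFratio, FullBandPower, ULF_unresolved, VLF_unresolved.
#' @export
spectral_features <- function(time_s, nn_ms, method = c("lomb", "welch"),
                              bands = spectral_bands(), span = 300, ...) {
  method <- match.arg(method)
  empty <- list(ULF = NA_real_, VLF = NA_real_, LF = NA_real_, HF = NA_real_,
                TotalPower = NA_real_, LFnorm = NA_real_, HFnorm = NA_real_,
                LFHFratio = NA_real_, FullBandPower = NA_real_,
                ULF_unresolved = NA, VLF_unresolved = NA)
  if (length(nn_ms) < 4) {
    warning("too few intervals for a spectral estimate")
    return(empty)
  }
  psd <- if (method == "lomb") lomb_psd(time_s, nn_ms, span = span, ...)
         else welch_psd(time_s, nn_ms, ...)
  bp <- function(b) sum(psd$power[psd$freq >= bands$lower[[b]] &
                                  psd$freq < bands$upper[[b]]])
  ulf <- bp("ULF"); vlf <- bp("VLF"); lf <- bp("LF"); hf <- bp("HF")
  tot <- lf + hf
  res <- 1 / span
  list(ULF = ulf, VLF = vlf, LF = lf, HF = hf,
       TotalPower = tot,
       LFnorm = if (tot > 0) lf / tot else NA_real_,
       HFnorm = if (tot > 0) hf / tot else NA_real_,
       LFHFratio = if (hf > 0) lf / hf else NA_real_,
       FullBandPower = sum(psd$power[psd$freq <= bands$upper[["HF"]]]),
       ULF_unresolved = bands$lower[["ULF"]] < res,
       VLF_unresolved = bands$lower[["VLF"]] < res)
}

#' Assemble the full 17-feature vector for one window
#'
#' @param nn_win Data frame with `time_s` and `nn_ms` (the unflagged member
#'   intervals of one retained window), as from [window_intervals()].
#' @param sampen_m,sampen_r_factor Sample-entropy embedding length and
#'   tolerance factor (r = factor * window SDNN).
#' @param spectral_method `"lomb"` or `"welch"`.
#' @param span Window length (s).
#' @return Named list of the 17 features plus `FullBandPower`,
#'   `ULF_unresolved`, `VLF_unresolved` and `n_beats`. Missing components
#'   propagate as NA, never as zero.
#' @export
feature_vector <- function(nn_win, sampen_m = 2, sampen_r_factor = 0.2,
                           spectral_method = "lomb", span = 300) {
  v <- nn_win$nn_ms
  td <- time_domain_features(v)
  pc <- poincare_features(v)
  se <- if (length(v) > sampen_m + 1 && !is.na(td$SDNN))
    suppressWarnings(sample_entropy(v, m = sampen_m,
                                    r = sampen_r_factor * td$SDNN))
  else NA_real_
  sp <- suppressWarnings(
    spectral_features(nn_win$time_s, v, method = spectral_method, span = span))
  c(td, list(SampEn = se), pc, sp[c("ULF", "VLF", "LF", "HF", "TotalPower",
                                    "LFnorm", "HFnorm", "LFHFratio")],
    list(FullBandPower = sp$FullBandPower,
         ULF_unresolved = sp$ULF_unresolved,
         VLF_unresolved = sp$VLF_unresolved,
         n_beats = length(v)))
}

#' Compute the feature table for all retained windows of one record
#'
#' @param nn An artifact-corrected `nn_series`.
#' @param windows The [segment_windows()] table.
#' @param patient_id Identifier carried on each row.
#' @param ... Passed to [feature_vector()].
#' @return Data frame, one row per retained window: `patient_id`,
#'   `window_start` (s), the 17 features, `FullBandPower`, resolution
#'   flags and `n_beats`.
#' @export
hrv_features <- function(nn, windows, patient_id = "patient", ...) {
  ret <- windows[windows$retained, , drop = FALSE]
  num_cols <- c(hrv_feature_names(), "FullBandPower")
  if (!nrow(ret)) {
    out <- data.frame(patient_id = character(0), window_start = numeric(0))
    for (f in num_cols) out[[f]] <- numeric(0)
    out$ULF_unresolved <- logical(0); out$VLF_unresolved <- logical(0)
    out$n_beats <- integer(0)
    return(out)
  }
  width <- ret$end[1] - ret$start[1]
  good <- !nn$flagged
  widx <- floor(nn$time_s[good] / width)
  tg <- nn$time_s[good]; vg <- nn$nn_ms[good]
  by_win <- split(seq_along(widx), widx)
  vals <- matrix(NA_real_, nrow(ret), length(num_cols),
                 dimnames = list(NULL, num_cols))
  flags <- matrix(NA, nrow(ret), 2,
                  dimnames = list(NULL, c("ULF_unresolved", "VLF_unresolved")))
  nb <- integer(nrow(ret))
  for (i in seq_len(nrow(ret))) {
    sel <- by_win[[as.character(ret$window_index[i])]]
    wi <- data.frame(time_s = tg[sel], nn_ms = vg[sel])
    fv <- feature_vector(wi, ...)
    vals[i, ] <- unlist(fv[num_cols], use.names = FALSE)
    flags[i, ] <- c(fv$ULF_unresolved, fv$VLF_unresolved)
    nb[i] <- fv$n_beats
  }
  out <- data.frame(patient_id = patient_id, window_start = ret$start)
  for (f in num_cols) out[[f]] <- vals[, f]
  out$ULF_unresolved <- flags[, 1]; out$VLF_unresolved <- flags[, 2]
  out$n_beats <- nb
  out
}
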