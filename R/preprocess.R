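# Raw ECG -> R peaks -> NN intervals -> artifact flags -> 5-minute windows.

#' Construct an ECG record from samples
#'
#' @param samples Voltage samples (mV).
#' @param fs Sampling rate (Hz), must be positive.
#' @param t0 Time of the first sample relative to ED admission (s).
#' @param patient_id Identifier.
#' @return An `ecg_record`.
#' @export
ecg_record <- function(samples, fs, t0 = 0, patient_id = "patient") {
  if (fs <= 0) stop("sampling rate must be positive")
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0,
                 patient_id = patient_id),
            class = "ecg_record")
}

#' Detect R peaks with a Pan-Tompkins detector
#'
#' Canonical stages: 5-15 Hz band-pass (zero-phase Butterworth), five-point
#' derivative, squaring, 150 ms centred moving-window integration, then dual
#' adaptive thresholds with a 200 ms refractory period, a T-wave veto and
#' search-back at the halved threshold. Accepted detections are refined to
#' the local maximum of the band-passed signal and interpolated
#' parabolically to sub-sample precision.
#'
#' @param ecg An `ecg_record` with sampling rate of at least 100 Hz.
#' @param bandpass Band-pass edges (Hz).
#' @param integration_s Moving-window integration length (s).
#' @param refractory_s Refractory period (s).
#' @param refine_s Half-width (s) of the search for the local R maximum.
#' @return An `rpeak_series`: list with `peak_times` (admission-aligned, s)
#'   and `fs`.
#' @export
detect_r_peaks <- function(ecg, bandpass = c(5, 15), integration_s = 0.150,
                           refractory_s = 0.200, refine_s = 0.075) {
  if (ecg$fs < 100) stop("sampling rate must be at least 100 Hz")
  x <- ecg$samples
  if (length(x) == 0) stop("empty ECG record")
  if (diff(range(x)) == 0) {
    warning("constant ECG signal: no peaks detected")
    return(structure(list(peak_times = numeric(0), fs = ecg$fs),
                     class = "rpeak_series"))
  }
  fs <- ecg$fs
  bf <- signal::butter(3, bandpass / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  # five-point derivative (Pan-Tompkins), zero-lag alignment via centring
  d <- stats::filter(xf, c(2, 1, 0, -1, -2) / 8, sides = 2)
  d[is.na(d)] <- 0
  sq <- as.numeric(d)^2
  w <- max(1L, round(integration_s * fs))
  mwi <- stats::filter(sq, rep(1 / w, w), sides = 2)
  mwi[is.na(mwi)] <- 0
  idx <- cpp_pt_scan(as.numeric(mwi), xf, fs, refractory_s) + 1L
  if (length(idx) == 0) {
    warning("no QRS complexes detected")
    return(structure(list(peak_times = numeric(0), fs = ecg$fs),
                     class = "rpeak_series"))
  }
  # refine to the local maximum of the band-passed signal, then parabolic
  # interpolation on the three samples around the maximum
  half <- max(1L, round(refine_s * fs))
  n <- length(xf)
  refined <- vapply(idx, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    j <- lo + which.max(xf[lo:hi]) - 1L
    if (j > 1 && j < n) {
      y1 <- xf[j - 1]; y2 <- xf[j]; y3 <- xf[j + 1]
      den <- y1 - 2 * y2 + y3
      delta <- if (abs(den) > 1e-12) 0.5 * (y1 - y3) / den else 0
      delta <- max(-0.5, min(0.5, delta))
      (j - 1 + delta) / fs
    } else (j - 1) / fs
  }, numeric(1))
  refined <- sort(unique(refined))
  # enforce the refractory period after refinement
  keep <- c(TRUE, diff(refined) >= refractory_s)
  while (!all(keep)) {
    refined <- refined[keep]
    keep <- c(TRUE, diff(refined) >= refractory_s)
  }
  structure(list(peak_times = ecg$t0 + refined, fs = fs),
            class = "rpeak_series")
}

#' @export
print.rpeak_series <- function(x, ...) {
  cat(sprintf("R-peak series: %d peaks", length(x$peak_times)))
  if (length(x$peak_times) > 1)
    cat(sprintf(", mean rate %.1f bpm",
                60 * (length(x$peak_times) - 1) / diff(range(x$peak_times))))
  cat("\n")
  invisible(x)
}

#' Compute NN intervals from R peaks
#'
#' Interval i spans peaks i and i+1; its value is the gap in ms and its
#' timestamp is the time of the closing peak.
#'
#' @param peaks An `rpeak_series` or a numeric vector of peak times (s).
#' @return An `nn_series` data frame (`time_s`, `nn_ms`, `flagged`), empty
#'   when fewer than two peaks are available.
#' @export
compute_nn_intervals <- function(peaks) {
  pt <- if (inherits(peaks, "rpeak_series")) peaks$peak_times else as.numeric(peaks)
  if (length(pt) < 2) {
    nn <- data.frame(time_s = numeric(0), nn_ms = numeric(0), flagged = logical(0))
  } else {
    nn <- data.frame(time_s = pt[-1], nn_ms = diff(pt) * 1000, flagged = FALSE)
  }
  class(nn) <- c("nn_series", "data.frame")
  nn
}

#' Flag RR-interval artifacts by adjacent-difference (ADARRI) thresholding
#'
#' Computes the absolute difference of each interval against the last
#' retained (non-flagged) interval and flags the interval when that
#' difference exceeds the decision threshold. The threshold is the larger of
#' a robust limit derived from the record's own adjacent-difference
#' distribution (median + k * MAD, 50% breakdown) and an absolute floor.
#' Flagged intervals are excluded from feature computation, not
#' interpolated.
#'
#' @param nn An `nn_series`.
#' @param k Multiplier on the MAD of the adjacent-difference distribution.
#' @param floor_ms Absolute lower bound on the threshold (ms).
#' @return The series with `flagged` set; attributes `n_flagged` and
#'   `threshold_ms` report the decision.
#' @export
correct_artifacts <- function(nn, k = 5, floor_ms = 200) {
  if (nrow(nn) == 0) stop("empty NN series")
  v <- nn$nn_ms
  if (length(v) < 2) {
    attr(nn, "n_flagged") <- 0L
    attr(nn, "threshold_ms") <- NA_real_
    return(nn)
  }
  adarri <- abs(diff(v))
  thr <- max(stats::median(adarri) + k * stats::mad(adarri), floor_ms)
  flagged <- logical(length(v))
  ref <- v[1]
  # the first interval has no predecessor; compare it forward instead
  if (abs(v[2] - v[1]) > thr && length(v) > 2 && abs(v[3] - v[2]) <= thr) {
    flagged[1] <- TRUE
    ref <- v[2]
  }
  for (i in 2:length(v)) {
    if (abs(v[i] - ref) > thr) {
      flagged[i] <- TRUE
    } else {
      ref <- v[i]
    }
  }
  if (all(flagged)) warning("every interval flagged as artifact")
  nn$flagged <- flagged
  attr(nn, "n_flagged") <- sum(flagged)
  attr(nn, "threshold_ms") <- thr
  nn
}

#' Segment an NN series into 5-minute windows
#'
#' Consecutive non-overlapping half-open windows `[k*300, (k+1)*300)` from
#' admission time. An interval belongs to the window containing its
#' end-time. A window is retained iff its count of unflagged intervals is at
#' least `min_beats` (default 60 = 20% of the 300 beats minimally expected
#' in 5 minutes).
#'
#' @param nn An `nn_series` (artifact-corrected).
#' @param record_duration Record length (s); defaults to the last interval
#'   end-time. Determines the candidate window count
#'   `ceiling(duration / window_s)`.
#' @param window_s Window length (s).
#' @param min_beats Retention threshold on unflagged beats per window.
#' @return Data frame with `window_index` (0-based), `start`, `end`,
#'   `n_beats` (unflagged), `n_flagged`, `retained`.
#' @export
segment_windows <- function(nn, record_duration = NULL, window_s = 300,
                            min_beats = 60) {
  dur <- record_duration %||% if (nrow(nn)) max(nn$time_s) else 0
  n_win <- ceiling(dur / window_s)
  if (n_win < 1) n_win <- 0
  idx <- seq_len(n_win) - 1L
  out <- data.frame(window_index = idx, start = idx * window_s,
                    end = (idx + 1) * window_s)
  if (n_win == 0) {
    out$n_beats <- integer(0); out$n_flagged <- integer(0)
    out$retained <- logical(0)
    return(out)
  }
  w <- floor(nn$time_s / window_s)
  good <- tabulate(w[!nn$flagged & w >= 0 & w < n_win] + 1L, nbins = n_win)
  bad <- tabulate(w[nn$flagged & w >= 0 & w < n_win] + 1L, nbins = n_win)
  out$n_beats <- good
  out$n_flagged <- bad
  out$retained <- good >= min_beats
  out
}

#' Extract the unflagged intervals of one window
#'
#' @param nn An `nn_series`.
#' @param window One row of the [segment_windows()] table (or a list with
#'   `start` and `end`).
#' @return Data frame with `time_s` and `nn_ms` of the unflagged member
#'   intervals.
#' @export
window_intervals <- function(nn, window) {
  sel <- !nn$flagged & nn$time_s >= window$start & nn$time_s < window$end
  nn[sel, c("time_s", "nn_ms")]
}

#' Run the full preprocessing chain on an ECG record
#'
#' @param ecg An `ecg_record`.
#' @param record_duration Record length (s) for window bookkeeping.
#' @param ... Passed to [detect_r_peaks()] and [correct_artifacts()].
#' @param window_s,min_beats See [segment_windows()].
#' @return List with `peaks`, `nn` (corrected) and `windows`.
#' @export
preprocess_ecg <- function(ecg, record_duration = length(ecg$samples) / ecg$fs,
                           window_s = 300, min_beats = 60, ...) {
  peaks <- detect_r_peaks(ecg)
  nn <- compute_nn_intervals(peaks)
  if (nrow(nn)) nn <- correct_artifacts(nn)
  windows <- segment_windows(nn, record_duration, window_s, min_beats)
  list(peaks = peaks, nn = nn, windows = windows)
}
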