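# Readers and writers for the pipeline's delimited formats, plus the
# structured configuration.

#' Read an ECG record from a delimited time/voltage table
#'
#' Expects a header line `time_s<tab>voltage_mv` (any of tab, comma or
#' whitespace separation) and one numeric row per sample. The sampling rate
#' is inferred from the (uniform) time column; the admission offset is the
#' first time stamp.
#'
#' @param path File path.
#' @param patient_id Identifier; defaults to the file name.
#' @return An `ecg_record`.
#' @export
read_ecg <- function(path, patient_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "",
                           colClasses = "character")
  if (ncol(tab) < 2) tab <- utils::read.table(path, header = TRUE, sep = ",",
                                              colClasses = "character")
  if (ncol(tab) < 2) stop("expected two columns (time, voltage) in ", path)
  tt <- suppressWarnings(as.numeric(tab[[1]]))
  vv <- suppressWarnings(as.numeric(tab[[2]]))
  if (anyNA(tt)) stop("non-numeric time value at row ", which(is.na(tt))[1])
  if (anyNA(vv)) stop("non-numeric voltage value at row ", which(is.na(vv))[1])
  if (length(tt) > 1) {
    dt <- diff(tt)
    if (any(dt <= 0)) stop("time column must be strictly increasing")
    if (diff(range(dt)) > 1e-3 * stats::median(dt))
      stop("time column must be uniformly sampled")
    fs <- 1 / stats::median(dt)
  } else fs <- NA_real_
  ecg_record(vv, fs = fs, t0 = tt[1], patient_id = patient_id)
}

#' Write an ECG record as a delimited time/voltage table
#'
#' @param ecg An `ecg_record`.
#' @param path File path.
#' @export
write_ecg <- function(ecg, path) {
  tt <- ecg$t0 + (seq_along(ecg$samples) - 1) / ecg$fs
  utils::write.table(data.frame(time_s = sprintf("%.8f", tt),
                                voltage_mv = sprintf("%.6f", ecg$samples)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an NN-interval series
#'
#' Columns: `time_s`, `nn_ms`, `flagged`. Missing values serialise as empty
#' fields.
#'
#' @param nn An `nn_series`.
#' @param path File path.
#' @export
write_nn_series <- function(nn, path) {
  utils::write.table(nn, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_nn_series
#' @export
read_nn_series <- function(path) {
  nn <- utils::read.table(path, header = TRUE, sep = "\t")
  nn$flagged <- as.logical(nn$flagged)
  class(nn) <- c("nn_series", "data.frame")
  nn
}

#' Write a stage table with provenance comments
#'
#' Plain tab-separated table preceded by `#`-comment lines carrying the
#' configuration hash and seed, so reruns are identifiable.
#'
#' @param x Data frame.
#' @param path File path.
#' @param config_hash,seed Provenance fields (optional).
#' @export
write_stage_table <- function(x, path, config_hash = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash)) writeLines(paste0("# config_hash: ", config_hash), con)
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  utils::write.table(format(x, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default: 5-minute
#' windows retained at 60 unflagged beats (20% of the 300 minimally
#' expected), 3-hour bins, detector and artifact parameters, sample-entropy
#' settings, the 0.05 screening level and 0.20 candidate gate, and the
#' simulation settings.
#'
#' @param ... Overrides of the defaults (nested lists merged shallowly).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    window_s = 300,
    min_beats = 60,
    bin_h = 3,
    detector = list(bandpass = c(5, 15), integration_s = 0.150,
                    refractory_s = 0.200),
    adarri = list(k = 5, floor_ms = 200),
    sampen = list(m = 2, r_factor = 0.2),
    spectral_method = "lomb",
    alpha = 0.05,
    gate = 0.20,
    screen_kinds = "mean",
    aki_rise_umol = 25.6,
    horizon_h = 72,
    seed = 1L,
    sim = list(),
    render_ecg = FALSE,
    out_dir = NULL)
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(defaults[[nm]]) && is.list(over[[nm]])) {
      for (k in names(over[[nm]])) defaults[[nm]][[k]] <- over[[nm]][[k]]
    } else defaults[[nm]] <- over[[nm]]
  }
  if (defaults$gate <= 0 || defaults$gate >= 1) stop("gate must lie in (0,1)")
  if (defaults$window_s <= 0 || defaults$min_beats <= 0 || defaults$bin_h <= 0)
    stop("thresholds must be positive")
  class(defaults) <- "pipeline_config"
  defaults
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys override [pipeline_config()] defaults.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}
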