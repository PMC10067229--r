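# Admission-aligned 3-hour summaries: per-feature mean and OLS slope per bin.

#' Assign windows to 3-hour bins
#'
#' Bin k covers `[3k, 3k+3)` hours from ED admission; a 48-hour record
#' yields 16 bins.
#'
#' @param features Per-window feature table ([hrv_features()] output);
#'   `window_start` must be admission-aligned seconds.
#' @param bin_h Bin length (hours).
#' @return The table with a `bin_index` column added.
#' @export
bin_windows <- function(features, bin_h = 3) {
  if (any(features$window_start < 0)) stop("negative window start times")
  features$bin_index <- floor(features$window_start / (bin_h * 3600))
  features
}

# closed-form OLS slope of y on x; NA when fewer than 2 points or x constant
ols_slope <- function(x, y) {
  ok <- !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) return(NA_real_)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) return(NA_real_)
  sum(xc * y) / sxx
}

#' Summarise features into per-bin mean and slope
#'
#' The mean is the arithmetic mean of the feature over non-missing windows
#' in the bin; the slope is the ordinary-least-squares slope of the feature
#' against the window midpoint time in hours (units: feature units per
#' hour). The mean is missing when no windows contribute, the slope when
#' fewer than two do.
#'
#' @param features Per-window feature table (may span several patients).
#' @param feature_names Features to summarise.
#' @param bin_h Bin length (hours).
#' @param window_s Window length (s), used for the midpoint.
#' @return Long data frame: `patient_id`, `bin_index`, `feature`,
#'   `mean`, `slope`, `n_windows`.
#' @export
summarize_bins <- function(features, feature_names = hrv_feature_names(),
                           bin_h = 3, window_s = 300) {
  features <- bin_windows(features, bin_h)
  features$mid_h <- (features$window_start + window_s / 2) / 3600
  groups <- split(features,
                  list(features$patient_id, features$bin_index), drop = TRUE)
  rows <- lapply(groups, function(g) {
    do.call(rbind, lapply(feature_names, function(f) {
      y <- g[[f]]
      ok <- !is.na(y)
      data.frame(patient_id = g$patient_id[1], bin_index = g$bin_index[1],
                 feature = f,
                 mean = if (any(ok)) mean(y[ok]) else NA_real_,
                 slope = ols_slope(g$mid_h, y),
                 n_windows = sum(ok))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$patient_id, out$bin_index, match(out$feature, feature_names)), ]
}

#' Bin-0 design matrix for modelling
#'
#' One row per patient holding the bin-0 (first three hours) feature means,
#' optionally also the slopes. Patients with no retained bin-0 windows are
#' excluded and listed in the `excluded` attribute.
#'
#' @param summaries Output of [summarize_bins()].
#' @param feature_names Features to include, in column order.
#' @param include_slopes Also include bin-0 slopes (columns suffixed
#'   `_slope`). Off by default.
#' @return Data frame with rownames = patient ids; attribute `excluded`
#'   names the dropped patients.
#' @export
first_interval_matrix <- function(summaries,
                                  feature_names = hrv_feature_names(),
                                  include_slopes = FALSE) {
  b0 <- summaries[summaries$bin_index == 0 & summaries$n_windows > 0, ]
  all_pat <- unique(summaries$patient_id)
  pats <- unique(b0$patient_id)
  excluded <- setdiff(all_pat, pats)
  if (!length(pats)) stop("no patients with bin-0 data")
  out <- data.frame(row.names = pats)
  for (f in feature_names) {
    sub <- b0[b0$feature == f, ]
    out[[f]] <- sub$mean[match(pats, sub$patient_id)]
    if (include_slopes)
      out[[paste0(f, "_slope")]] <- sub$slope[match(pats, sub$patient_id)]
  }
  attr(out, "excluded") <- excluded
  out
}
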