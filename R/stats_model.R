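# Group screening and modelling: Kruskal-Wallis per feature x kind x bin,
# univariate logistic screening (POD vs SOD+NOD), forward-stepwise-AIC
# logistic regression, AUROC and DeLong's test for correlated ROC curves.

#' Kruskal-Wallis screen of per-bin summaries across groups
#'
#' Rank test (with tie correction, via [stats::kruskal.test()]) of each
#' feature's per-bin mean and slope across the NOD/SOD/POD groups.
#' Uncorrected p-values; significance flag at `alpha`.
#'
#' @param summaries Long summary table from [summarize_bins()].
#' @param labels Data frame with `patient_id` and `label`.
#' @param kinds Which summary kinds to test.
#' @param alpha Significance level (default 0.05).
#' @return Data frame: `feature`, `kind`, `bin_index`, `statistic`, `df`,
#'   `p_value`, `significant`, `n`, `n_groups`, plus per-group medians and
#'   IQRs.
#' @export
kruskal_wallis_screen <- function(summaries, labels,
                                  kinds = c("mean", "slope"), alpha = 0.05) {
  summaries$label <- labels$label[match(summaries$patient_id,
                                        labels$patient_id)]
  grp_levels <- sort(unique(labels$label))
  rows <- list()
  for (kind in kinds) {
    groups <- split(summaries, list(summaries$feature, summaries$bin_index),
                    drop = TRUE)
    for (g in groups) {
      y <- g[[kind]]
      ok <- !is.na(y) & !is.na(g$label)
      y <- y[ok]; lab <- factor(g$label[ok], levels = grp_levels)
      lab <- droplevels(lab)
      if (length(y) < 2 || nlevels(lab) < 2) next
      if (diff(range(y)) == 0) {
        # every observation tied: no evidence of any group difference
        kt <- list(statistic = 0, parameter = nlevels(lab) - 1, p.value = 1)
      } else {
        kt <- stats::kruskal.test(y, lab)
      }
      row <- data.frame(feature = g$feature[1], kind = kind,
                        bin_index = g$bin_index[1],
                        statistic = unname(kt$statistic),
                        df = unname(kt$parameter),
                        p_value = kt$p.value,
                        significant = kt$p.value < alpha,
                        n = length(y), n_groups = nlevels(lab))
      for (lv in grp_levels) {
        yy <- y[lab == lv]
        row[[paste0("median_", lv)]] <- if (length(yy)) stats::median(yy) else NA_real_
        row[[paste0("iqr_", lv)]] <- if (length(yy)) stats::IQR(yy) else NA_real_
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$kind, out$bin_index, out$feature), ]
}

# Wald summary for one glm fit, on the odds-ratio scale
glm_or_table <- function(fit, conf_level = 0.95) {
  s <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
             or = exp(s[, 1]),
             or_lo = exp(s[, 1] - z * s[, 2]),
             or_hi = exp(s[, 1] + z * s[, 2]),
             p_value = s[, 4], row.names = NULL)
}

fit_is_degenerate <- function(fit) {
  s <- summary(fit)$coefficients
  !fit$converged || any(s[, 2] > 50) ||
    any(abs(s[-1, 1]) > 50)  # separation blows up slopes / SEs on the link scale
}

#' Univariate logistic screening of bin-0 features
#'
#' One logistic fit per feature with outcome POD = 1 versus SOD and NOD
#' combined as controls. Wald 95% CIs on the odds-ratio scale. Features
#' with p below `gate` (default 0.20) are flagged as candidates for the
#' multivariate model; non-converged or separated fits are excluded from
#' candidacy with a warning.
#'
#' @param design Bin-0 design matrix ([first_interval_matrix()]).
#' @param outcome Logical or 0/1 vector (TRUE/1 = POD), aligned with the
#'   design rows.
#' @param gate Candidate p-value gate.
#' @param conf_level Confidence level for the CIs.
#' @return Data frame: `feature`, `or`, `or_lo`, `or_hi`, `p_value`,
#'   `candidate`, `degenerate`, `n`.
#' @export
univariate_logistic <- function(design, outcome, gate = 0.20,
                                conf_level = 0.95) {
  y <- as.integer(outcome)
  if (length(unique(y[!is.na(y)])) < 2)
    stop("outcome must contain both classes")
  rows <- lapply(names(design), function(f) {
    x <- design[[f]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3 || length(unique(y[ok])) < 2 || stats::var(x[ok]) == 0)
      return(data.frame(feature = f, or = NA_real_, or_lo = NA_real_,
                        or_hi = NA_real_, p_value = NA_real_,
                        candidate = FALSE, degenerate = TRUE, n = sum(ok)))
    fit <- suppressWarnings(stats::glm(y[ok] ~ x[ok], family = stats::binomial()))
    tb <- glm_or_table(fit, conf_level)[2, ]
    deg <- fit_is_degenerate(fit)
    if (deg) warning("degenerate fit (separation or non-convergence) for ", f)
    data.frame(feature = f, or = tb$or, or_lo = tb$or_lo, or_hi = tb$or_hi,
               p_value = tb$p_value,
               candidate = !deg && !is.na(tb$p_value) && tb$p_value < gate,
               degenerate = deg, n = sum(ok))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Forward-stepwise logistic regression by AIC
#'
#' Starts from the intercept-only model and at each step adds the candidate
#' giving the largest AIC decrease, stopping when no addition decreases the
#' AIC. Exact AIC ties are broken by candidate list order.
#'
#' @param design Design matrix (data frame of features).
#' @param outcome Logical or 0/1 vector (TRUE/1 = case).
#' @param candidates Candidate feature names (e.g. the `candidate` rows of
#'   [univariate_logistic()]); an empty set returns the intercept-only
#'   model with a note.
#' @return A `stepwise_model`: list with `fit` (the glm), `selected`,
#'   `aic_trace`, `table` (odds ratios with CIs), and `note`.
#' @export
forward_stepwise_aic <- function(design, outcome, candidates) {
  y <- as.integer(outcome)
  dat <- cbind(data.frame(.y = y), design)
  dat <- dat[stats::complete.cases(dat[, c(".y", candidates), drop = FALSE]), ]
  note <- NULL
  if (!length(candidates)) note <- "empty candidate set: intercept-only model"
  fit <- stats::glm(.y ~ 1, family = stats::binomial(), data = dat)
  selected <- character(0)
  trace <- data.frame(step = 0L, added = NA_character_, aic = stats::AIC(fit))
  remaining <- candidates
  while (length(remaining)) {
    aics <- vapply(remaining, function(f) {
      fml <- stats::reformulate(c(selected, f), response = ".y")
      stats::AIC(suppressWarnings(
        stats::glm(fml, family = stats::binomial(), data = dat)))
    }, numeric(1))
    best <- which.min(aics)  # first minimum wins: candidate-order tie-break
    if (aics[best] >= stats::AIC(fit) - 1e-10) break
    selected <- c(selected, remaining[best])
    remaining <- remaining[-best]
    fit <- stats::glm(stats::reformulate(selected, response = ".y"),
                      family = stats::binomial(), data = dat)
    trace <- rbind(trace, data.frame(step = nrow(trace),
                                     added = selected[length(selected)],
                                     aic = stats::AIC(fit)))
  }
  structure(list(fit = fit, selected = selected, aic_trace = trace,
                 table = glm_or_table(fit), note = note,
                 n = nrow(dat)),
            class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat("Forward-stepwise-AIC logistic model\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  cat("  selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  cat(sprintf("  AIC %.2f on n = %d\n", stats::AIC(x$fit), x$n))
  invisible(x)
}

#' Model evaluation diagnostics
#'
#' Deviance (-2 log-likelihood), model degrees of freedom (non-intercept
#' terms), pseudo-R2 (McFadden by default, Nagelkerke optional) and the
#' likelihood-ratio p-value against the intercept-only model.
#'
#' @param model A fitted binomial `glm` or a `stepwise_model`.
#' @param pseudo_r2 `"mcfadden"` (default) or `"nagelkerke"`.
#' @return Named list: `deviance`, `df`, `pseudo_r2`, `r2_method`,
#'   `lr_statistic`, `lr_p_value`, `aic`.
#' @export
evaluate_model <- function(model, pseudo_r2 = c("mcfadden", "nagelkerke")) {
  pseudo_r2 <- match.arg(pseudo_r2)
  fit <- if (inherits(model, "stepwise_model")) model$fit else model
  yy <- fit$y
  null_fit <- stats::glm(yy ~ 1, family = stats::binomial())
  ll <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(null_fit))
  n <- length(fit$y)
  df <- length(stats::coef(fit)) - 1L
  r2 <- if (pseudo_r2 == "mcfadden") {
    if (ll0 == 0) 0 else 1 - ll / ll0
  } else {
    (1 - exp(2 * (ll0 - ll) / n)) / (1 - exp(2 * ll0 / n))
  }
  lr <- 2 * (ll - ll0)
  list(deviance = -2 * ll, df = df, pseudo_r2 = r2, r2_method = pseudo_r2,
       lr_statistic = lr,
       lr_p_value = if (df > 0) stats::pchisq(lr, df, lower.tail = FALSE) else 1,
       aic = stats::AIC(fit))
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Probability that a random case outranks a random control; ties count
#' one half.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Logical or 0/1 vector (TRUE/1 = case).
#' @return AUROC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(y)
  scores <- scores[ok]; y <- y[ok]
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components: for each case, the mean of the
# case-vs-control comparison kernel over controls, and vice versa.
delong_components <- function(scores, y) {
  cases <- scores[y]; controls <- scores[!y]
  psi <- function(x, yv) (x > yv) + 0.5 * (x == yv)
  v10 <- vapply(cases, function(x) mean(psi(x, controls)), numeric(1))
  v01 <- vapply(controls, function(yv) mean(psi(cases, yv)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated ROC curves
#'
#' Structural-components estimate of the variance of the AUROC difference
#' for two scores on the same subjects; two-sided normal test.
#'
#' @param scores_a,scores_b Paired scores on identical subjects.
#' @param labels Logical or 0/1 vector (TRUE/1 = case).
#' @return List: `auc_a`, `auc_b`, `difference`, `se`, `z`, `p_value`,
#'   `covariance` (2x2 matrix of the AUC estimates).
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  y <- as.logical(labels)
  ok <- !is.na(scores_a) & !is.na(scores_b) & !is.na(y)
  a <- scores_a[ok]; b <- scores_b[ok]; y <- y[ok]
  if (!any(y) || all(y)) stop("both classes must be present")
  ca <- delong_components(a, y)
  cb <- delong_components(b, y)
  m <- sum(y); n <- sum(!y)
  v10 <- cbind(ca$v10, cb$v10); v01 <- cbind(ca$v01, cb$v01)
  s10 <- stats::cov(v10); s01 <- stats::cov(v01)
  S <- s10 / m + s01 / n
  d <- ca$auc - cb$auc
  var_d <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (var_d <= 0) {
    z <- 0; p <- 1; se <- 0
    if (abs(d) > 0) { se <- 0; z <- Inf * sign(d); p <- 0 }
  } else {
    se <- sqrt(var_d)
    z <- d / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = ca$auc, auc_b = cb$auc, difference = d, se = se, z = z,
       p_value = p, covariance = S)
}

#' qSOFA score
#'
#' One point each for respiratory rate >= 22 /min, systolic blood pressure
#' <= 100 mmHg, and GCS < 15 (Sepsis-3 definition).
#'
#' @param rr Respiratory rate (/min).
#' @param sbp Systolic blood pressure (mmHg).
#' @param gcs Glasgow Coma Scale.
#' @return Integer 0..3 (NA when any component is missing). Vectorised.
#' @export
qsofa_score <- function(rr, sbp, gcs) {
  out <- (rr >= 22) + (sbp <= 100) + (gcs < 15)
  out[is.na(rr) | is.na(sbp) | is.na(gcs)] <- NA_integer_
  as.integer(out)
}
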