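# Kruskal-Wallis screen, logistic screening and stepwise selection, AUROC,
# DeLong comparison, qSOFA and model diagnostics.

make_summaries <- function(values_by_group, feature = "AVNN", bin = 0) {
  pid <- 0
  rows <- lapply(names(values_by_group), function(g) {
    v <- values_by_group[[g]]
    ids <- sprintf("%s%02d", g, seq_along(v) + pid)
    data.frame(patient_id = ids, bin_index = bin, feature = feature,
               mean = v, slope = 0, n_windows = 3, group = g)
  })
  s <- do.call(rbind, rows)
  list(summaries = s[, c("patient_id", "bin_index", "feature", "mean",
                         "slope", "n_windows")],
       labels = data.frame(patient_id = s$patient_id, label = s$group))
}

test_that("Kruskal-Wallis screen reproduces the hand-computed statistic", {
  ms <- make_summaries(list(NOD = c(1, 2, 3), SOD = c(4, 5, 6),
                            POD = c(7, 8, 9)))
  kw <- kruskal_wallis_screen(ms$summaries, ms$labels, kinds = "mean")
  h <- oracle_kw_h(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$statistic, h, tolerance = 1e-12)
  expect_equal(kw$df, 2)
  expect_equal(kw$median_POD, 8)

  # identical constant groups: H = 0 is not significant
  msc <- make_summaries(list(NOD = rep(5, 4), SOD = rep(5, 4), POD = rep(5, 4)))
  kwc <- kruskal_wallis_screen(msc$summaries, msc$labels, kinds = "mean")
  expect_equal(kwc$statistic, 0)
  expect_false(kwc$significant)

  # a bin with one group missing is tested over the present groups
  ms2 <- make_summaries(list(NOD = c(1, 2, 3), SOD = c(9, 10, 11)))
  kw2 <- kruskal_wallis_screen(ms2$summaries, ms2$labels, kinds = "mean")
  expect_equal(kw2$n_groups, 2)
})

test_that("screen p-values are invariant to patient order", {
  set.seed(21)
  ms <- make_summaries(list(NOD = rnorm(10), SOD = rnorm(10), POD = rnorm(10)))
  p1 <- kruskal_wallis_screen(ms$summaries, ms$labels, kinds = "mean")$p_value
  perm <- sample(nrow(ms$summaries))
  p2 <- kruskal_wallis_screen(ms$summaries[perm, ], ms$labels,
                              kinds = "mean")$p_value
  expect_equal(p1, p2)
})

test_that("univariate screening gates candidates at p < 0.20", {
  set.seed(22)
  n <- 120
  y <- rbinom(n, 1, 0.25)
  d <- data.frame(strong = y + rnorm(n, 0, 0.8),
                  weak = rnorm(n),
                  sep = y * 10 + seq_len(n) / 1000)  # perfect separation
  u <- suppressWarnings(univariate_logistic(d, y))
  expect_equal(u$candidate, !is.na(u$p_value) & u$p_value < 0.20 & !u$degenerate)
  expect_true(u$candidate[u$feature == "strong"])
  expect_true(u$degenerate[u$feature == "sep"])
  expect_false(u$candidate[u$feature == "sep"])
  expect_error(univariate_logistic(d, rep(1, n)), "both classes")
})

test_that("Wald CIs cover the null odds ratio at the nominal rate", {
  set.seed(23)
  cover <- mean(replicate(300, {
    y <- rbinom(150, 1, 0.3)
    u <- univariate_logistic(data.frame(f = rnorm(150)), y)
    u$or_lo <= 1 && u$or_hi >= 1
  }))
  expect_gte(cover, 0.92)
  expect_lte(cover, 0.98)
})

test_that("forward stepwise AIC keeps the informative feature and obeys its contract", {
  set.seed(24)
  n <- 200
  y <- rbinom(n, 1, 0.35)
  d <- data.frame(signal = y * 2 + rnorm(n))
  for (k in 1:6) d[[paste0("noise", k)]] <- rnorm(n)
  m <- forward_stepwise_aic(d, y, names(d))
  expect_true("signal" %in% m$selected)
  expect_lte(AIC(m$fit), m$aic_trace$aic[1])
  # monotone decreasing AIC trace
  expect_true(all(diff(m$aic_trace$aic) < 0))

  # no candidates: intercept-only with a note
  m0 <- forward_stepwise_aic(d, y, character(0))
  expect_length(m0$selected, 0)
  expect_match(m0$note, "intercept-only")

  # order invariance away from ties
  m2 <- forward_stepwise_aic(d, y, rev(names(d)))
  expect_setequal(m2$selected, m$selected)
})

test_that("AUROC equals pair enumeration and the rank identity", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10), c(0, 0, 0, 1)), 1.0)
  set.seed(25)
  for (i in 1:20) {
    s <- sample(1:10, 40, replace = TRUE)  # ties present
    y <- rbinom(40, 1, 0.4)
    if (sum(y) == 0 || sum(y) == 40) next
    expect_equal(roc_auc(s, y), oracle_auc(s, y))
    w <- wilcox.test(s[y == 1], s[y == 0], exact = FALSE, correct = FALSE)
    expect_equal(roc_auc(s, y), w$statistic[[1]] / (sum(y) * sum(1 - y)))
  }
  expect_error(roc_auc(1:5, rep(0, 5)), "both classes")
})

test_that("DeLong comparison matches brute-force components and pROC", {
  skip_if_not_installed("pROC")
  set.seed(26)
  y <- c(rep(TRUE, 3), rep(FALSE, 3))
  a <- c(0.9, 0.7, 0.4, 0.5, 0.3, 0.2)
  b <- c(0.8, 0.3, 0.6, 0.7, 0.2, 0.4)
  d <- delong_compare(a, b, y)
  o <- oracle_delong(a, b, y)
  expect_equal(d$difference, o$diff, tolerance = 1e-12)
  expect_equal(d$se^2, o$var, tolerance = 1e-12)

  yy <- rbinom(60, 1, 0.4); aa <- rnorm(60) + yy; bb <- rnorm(60) + 0.3 * yy
  dd <- delong_compare(aa, bb, yy)
  pr <- pROC::roc.test(pROC::roc(yy, aa, quiet = TRUE),
                       pROC::roc(yy, bb, quiet = TRUE), method = "delong")
  expect_equal(dd$p_value, pr$p.value, tolerance = 1e-10)

  # identical scores: difference 0, p = 1
  di <- delong_compare(aa, aa, yy)
  expect_equal(di$difference, 0)
  expect_equal(di$p_value, 1)
})

test_that("qSOFA scores its three components", {
  expect_equal(qsofa_score(24, 95, 15), 2L)
  expect_equal(qsofa_score(12, 130, 15), 0L)
  expect_equal(qsofa_score(30, 80, 10), 3L)
  expect_equal(qsofa_score(22, 100, 14), 3L)  # boundary values all score
  expect_true(is.na(qsofa_score(NA, 100, 15)))
  expect_equal(qsofa_score(c(24, 12), c(95, 130), c(15, 15)), c(2L, 0L))
})

test_that("model diagnostics reproduce closed forms", {
  # balanced intercept-only deviance = 20 ln 2 at n = 10
  y <- rep(c(0, 1), 5)
  f0 <- glm(y ~ 1, family = binomial())
  ev0 <- evaluate_model(f0)
  expect_equal(ev0$deviance, 20 * log(2), tolerance = 1e-9)
  expect_equal(ev0$pseudo_r2, 0)
  expect_equal(ev0$df, 0)
  expect_equal(ev0$lr_p_value, 1)

  # perfect prediction drives the deviance to (numerically) zero
  x <- c(rep(-5, 5), rep(5, 5))
  fp <- suppressWarnings(glm(y2 ~ x, family = binomial(),
                             data = data.frame(y2 = c(rep(0, 5), rep(1, 5)), x = x)))
  expect_lt(evaluate_model(fp)$deviance, 1e-5)

  # Nagelkerke option is reported and bounded
  set.seed(27)
  yy <- rbinom(80, 1, 0.5); xx <- yy + rnorm(80)
  fit <- glm(yy ~ xx, family = binomial())
  evn <- evaluate_model(fit, pseudo_r2 = "nagelkerke")
  expect_equal(evn$r2_method, "nagelkerke")
  expect_gt(evn$pseudo_r2, 0); expect_lte(evn$pseudo_r2, 1)
})
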