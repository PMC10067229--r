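# Synthetic-cohort generator: determinism, degenerate cases, spectral
# fidelity of the injected modulation, artifact bookkeeping, ECG rendering,
# and the clinical-course round trip.

test_that("degenerate modulation gives exactly constant intervals", {
  cfg <- sim_config(band_amp = c(ULF = 0, VLF = 0, LF = 0, HF = 0),
                    ectopic_rate = 0, missed_beat_rate = 0,
                    record_duration = 60, mean_nn = 800)
  s <- simulate_nn_series(cfg, seed = 1)
  expect_true(all(abs(s$nn$nn_ms - 800) < 1e-9))
  expect_equal(s$truth$true_nn, s$nn$nn_ms)
  expect_length(s$truth$injected_artifact_indices, 0)
})

test_that("identical seed and config reproduce the series exactly", {
  cfg <- sim_config(record_duration = 600)
  a <- simulate_nn_series(cfg, seed = 7)
  b <- simulate_nn_series(cfg, seed = 7)
  expect_identical(a, b)
  c <- simulate_nn_series(cfg, seed = 8)
  expect_false(identical(a$nn$nn_ms, c$nn$nn_ms))
})

test_that("single-band LF modulation concentrates spectral power in the LF band", {
  cfg <- sim_config(band_amp = c(ULF = 0, VLF = 0, LF = 50, HF = 0),
                    ectopic_rate = 0, missed_beat_rate = 0,
                    record_duration = 300, mean_nn = 800)
  s <- simulate_nn_series(cfg, seed = 2)
  # independent periodogram oracle on the generated series
  freq <- seq(1 / 1200, 0.4, by = 1 / 1200)
  p <- oracle_lomb_power(s$nn$time_s, s$nn$nn_ms, freq)
  expect_gte(freq[which.max(p)], 0.04)
  expect_lt(freq[which.max(p)], 0.15)
  in_band <- freq >= 0.04 & freq < 0.15
  wide <- freq >= 0.04 & freq < 0.4
  expect_gte(sum(p[in_band]) / sum(p[wide]), 0.8)
})

test_that("injected artifacts are recorded and shaped as specified", {
  cfg <- sim_config(band_amp = c(ULF = 0, VLF = 10, LF = 8, HF = 5),
                    ectopic_rate = 0.03, missed_beat_rate = 0.02,
                    record_duration = 1800, mean_nn = 800)
  s <- simulate_nn_series(cfg, seed = 3)
  idx <- s$truth$injected_artifact_indices
  expect_gt(length(idx), 0)
  expect_true(all(idx >= 1 & idx <= nrow(s$nn)))
  # merged intervals are roughly doubled; ectopic pairs are short-then-long
  expect_gt(max(s$nn$nn_ms[idx]), 1.5 * 800)
  expect_lt(min(s$nn$nn_ms[idx]), 0.75 * 800)
  # uncorrupted intervals stay near the modulation envelope
  clean <- setdiff(seq_len(nrow(s$nn)), idx)
  expect_lt(max(abs(s$nn$nn_ms[clean] - 800)), sum(cfg$band_amp) + 1)
})

test_that("rendered ECG has the right sample count and peak alignment", {
  cfg <- sim_config(sampling_rate = 500, ecg_noise_sd = 0, baseline_amp = 0)
  e <- render_ecg(numeric(0), cfg, duration = 10)
  expect_length(e$samples, 5000)
  expect_true(all(e$samples == 0))

  peaks <- seq(0.5, 59.5, by = 1)  # 60 interior beats over one minute
  e2 <- render_ecg(peaks, cfg, duration = 60, include_pt = FALSE)
  expect_length(e2$samples, 30000)
  for (p in peaks[c(1, 30, 60)]) {
    sel <- which(abs((seq_along(e2$samples) - 1) / 500 - p) <= 0.1)
    am <- sel[which.max(e2$samples[sel])]
    expect_lte(abs((am - 1) / 500 - p), 1 / 500 + 1e-12)
  }
  expect_error(render_ecg(c(1, 1, 2), cfg), "strictly increasing")
})

test_that("simulated clinical courses classify to their intended group", {
  for (g in c("NOD", "SOD", "POD")) {
    labs <- vapply(1:40, function(s) {
      classify_outcome(simulate_patient_course(g, seed = s))$label
    }, character(1))
    expect_true(all(labs == g), label = paste("group", g))
  }
})

test_that("POD courses carry exactly one realised trigger", {
  trig <- vapply(1:60, function(s) {
    classify_outcome(simulate_patient_course("POD", seed = s))$trigger
  }, character(1))
  expect_true(all(trig %in% c("de_novo_aki", "de_novo_liver", "de_novo_resp",
                              "icu_admission", "death")))
  expect_gt(length(unique(trig)), 2)  # the trigger mix is actually sampled
})

test_that("cohort respects group sizes, dropout and injected effect direction", {
  cfg <- sim_config(record_duration = 900,
                    group_sizes = c(NOD = 12, SOD = 5, POD = 8),
                    dropout_times = rep(48, 25), seed = 5)
  co <- simulate_cohort(cfg)
  expect_length(co$patients, 25)
  groups <- vapply(co$patients, `[[`, "", "group")
  expect_equal(unname(table(groups)[c("NOD", "SOD", "POD")]),
               c(12, 5, 8), ignore_attr = TRUE)
  # dropout >= record duration: every record runs to the full 900 s
  durs <- vapply(co$patients, function(p) max(p$nn$time_s), numeric(1))
  expect_true(all(durs > 880))
  # injected direction: POD mean NN below NOD mean NN on pooled truth
  mnn <- function(g) mean(unlist(lapply(co$patients[groups == g],
                                        function(p) p$truth$true_nn)))
  expect_lt(mnn("POD"), mnn("NOD"))
  expect_error(simulate_cohort(sim_config(group_sizes = c(NOD = 0, SOD = 0, POD = 0))),
               "at least one patient")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(mean_nn = -5), "positive")
  expect_error(sim_config(record_duration = 0), "positive")
  expect_error(sim_config(ectopic_rate = 1.4), "rates")
  expect_error(sim_config(band_freq = c(ULF = 0.002, VLF = 0.01, LF = 0.2, HF = 0.25)),
               "outside its band")
  expect_error(sim_config(group_sizes = c(NOD = -1, SOD = 2, POD = 1)),
               "nonnegative")
})
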