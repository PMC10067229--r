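# Feature oracles: brute-force formula equivalence, SampEn exact counting,
# spectral localisation, algebraic identities, and scale equivariance.

test_that("constant and toy windows give the textbook values", {
  td <- time_domain_features(rep(800, 10))
  expect_equal(td$AVNN, 800)
  expect_equal(td$SDNN, 0)
  expect_equal(td$RMSSD, 0)
  expect_equal(td$NN50, 0)
  expect_equal(td$pNN50, 0)
  expect_equal(td$CV, 0)

  td2 <- time_domain_features(c(800, 851, 800, 851))
  expect_equal(td2$NN50, 3)
  expect_equal(td2$pNN50, 100)

  pc <- poincare_features(rep(700, 10))
  expect_equal(pc$SD1, 0)
  expect_equal(pc$SD2, 0)

  expect_equal(sample_entropy(rep(650, 50), r = 10), 0)
})

test_that("time-domain and Poincare features match brute-force formulas", {
  set.seed(101)
  for (i in 1:200) {
    v <- rnorm(sample(50:400, 1), 800, 50)
    td <- time_domain_features(v); o <- oracle_time_domain(v)
    for (f in names(o))
      expect_equal(td[[f]], o[[f]], tolerance = 1e-9, label = f)
    pc <- poincare_features(v); op <- oracle_poincare(v)
    expect_equal(pc$SD1, op$SD1, tolerance = 1e-9)
    expect_equal(pc$SD2, op$SD2, tolerance = 1e-9)
    # algebraic identity of the Poincare axes
    expect_equal(pc$SD1^2 + pc$SD2^2, 2 * sd(v)^2, tolerance = 1e-9)
  }
})

test_that("sample entropy equals direct O(n^2) template counting", {
  set.seed(102)
  for (i in 1:25) {
    v <- runif(100)
    expect_identical(sample_entropy(v, m = 2, r = 0.2 * sd(v)),
                     oracle_sampen(v, m = 2, r = 0.2 * sd(v)))
  }
  # strictly monotone series with steps far above r: no matches -> missing
  expect_warning(se <- sample_entropy(seq(1, 100), m = 2, r = 0.01),
                 "undefined")
  expect_true(is.na(se))
})

test_that("Lomb-Scargle implementation matches the literal formula", {
  set.seed(103)
  t <- cumsum(runif(150, 0.6, 1.0))
  y <- 800 + 40 * sin(2 * pi * 0.1 * t) + rnorm(150, 0, 10)
  ps <- lomb_psd(t, y)
  po <- oracle_lomb_power(t, y, ps$freq)
  expect_equal(ps$power, po, tolerance = 1e-8)
})

test_that("spectral features localise single-band modulation", {
  cfg <- sim_config(band_amp = c(ULF = 0, VLF = 0, LF = 50, HF = 0),
                    ectopic_rate = 0, missed_beat_rate = 0,
                    record_duration = 300, mean_nn = 800)
  s <- simulate_nn_series(cfg, seed = 2)
  sp <- spectral_features(s$nn$time_s, s$nn$nn_ms)
  expect_gte(sp$LFnorm, 0.9)
  expect_equal(sp$TotalPower, sp$LF + sp$HF)

  cfg2 <- sim_config(band_amp = c(ULF = 0, VLF = 0, LF = 0, HF = 50),
                     ectopic_rate = 0, missed_beat_rate = 0,
                     record_duration = 300, mean_nn = 800)
  s2 <- simulate_nn_series(cfg2, seed = 2)
  sp2 <- spectral_features(s2$nn$time_s, s2$nn$nn_ms)
  expect_gte(sp2$HFnorm, 0.9)

  # equal injected power at 0.1 and 0.3 Hz balances the ratio
  cfg3 <- sim_config(band_amp = c(ULF = 0, VLF = 0, LF = 40, HF = 40),
                     band_freq = c(ULF = 0.002, VLF = 0.01, LF = 0.1, HF = 0.3),
                     ectopic_rate = 0, missed_beat_rate = 0,
                     record_duration = 300, mean_nn = 800)
  s3 <- simulate_nn_series(cfg3, seed = 3)
  sp3 <- spectral_features(s3$nn$time_s, s3$nn$nn_ms)
  expect_gte(sp3$LFHFratio, 0.8)
  expect_lte(sp3$LFHFratio, 1.25)

  # ULF/VLF cannot be resolved inside a 5-minute window and say so
  expect_true(sp$ULF_unresolved)
  expect_true(sp$VLF_unresolved)
})

test_that("constant window yields zero variability and missing spectral ratios", {
  fv <- feature_vector(make_window(rep(800, 300)))
  expect_equal(fv$SDNN, 0)
  expect_equal(fv$RMSSD, 0)
  expect_true(is.na(fv$LFnorm))
  expect_true(is.na(fv$LFHFratio))
  expect_equal(fv$TotalPower, 0)
})

test_that("the feature vector has the 17 named features in order", {
  s <- simulate_nn_series(sim_config(record_duration = 300), seed = 6)
  fv <- feature_vector(s$nn[, c("time_s", "nn_ms")])
  expect_equal(names(fv)[seq_len(17)], hrv_feature_names())
  # componentwise agreement with the oracles
  v <- s$nn$nn_ms
  o <- oracle_time_domain(v)
  expect_equal(fv$AVNN, o$AVNN, tolerance = 1e-12)
  expect_equal(fv$SDNN, o$SDNN, tolerance = 1e-12)
  expect_identical(fv$SampEn, oracle_sampen(v, 2, 0.2 * fv$SDNN))
})

test_that("features are scale-equivariant in the interval values", {
  set.seed(104)
  v <- rnorm(300, 800, 40)
  w <- make_window(v)
  w2 <- w; w2$nn_ms <- 3 * w2$nn_ms  # same sample times, scaled values
  f1 <- feature_vector(w); f2 <- feature_vector(w2)
  for (f in c("AVNN", "SDNN", "RMSSD", "SD1", "SD2"))
    expect_equal(f2[[f]], 3 * f1[[f]], tolerance = 1e-6, label = f)
  for (f in c("ULF", "VLF", "LF", "HF", "TotalPower"))
    expect_equal(f2[[f]], 9 * f1[[f]], tolerance = 1e-6, label = f)
  for (f in c("CV", "LFnorm", "HFnorm", "LFHFratio", "SampEn"))
    expect_equal(f2[[f]], f1[[f]], tolerance = 1e-6, label = f)
  # NN50/pNN50 compare against an absolute 50 ms threshold, so their scale
  # invariance only holds when no difference crosses the threshold under
  # either scale; check it on such a series
  vb <- 800 + rep(c(0, 200), 150) + rnorm(300, 0, 5)  # all |diffs| >> 50
  wb <- make_window(vb); wb2 <- wb; wb2$nn_ms <- 3 * wb2$nn_ms
  expect_equal(feature_vector(wb2)$pNN50, feature_vector(wb)$pNN50)
})

test_that("white interval noise shows no spurious band dominance", {
  set.seed(105)
  lfn <- replicate(30, {
    v <- rnorm(300, 800, 30)
    sp <- spectral_features(make_window(v)$time_s, v)
    sp$LFnorm
  })
  expect_gte(mean(lfn), 0.2)
  expect_lte(mean(lfn), 0.8)
})

test_that("Lomb and resample+Welch routes agree on band dominance", {
  cfg <- sim_config(band_amp = c(ULF = 0, VLF = 0, LF = 45, HF = 0),
                    ectopic_rate = 0, missed_beat_rate = 0,
                    record_duration = 300, mean_nn = 800)
  s <- simulate_nn_series(cfg, seed = 8)
  spl <- spectral_features(s$nn$time_s, s$nn$nn_ms, method = "lomb")
  spw <- spectral_features(s$nn$time_s, s$nn$nn_ms, method = "welch")
  expect_gte(spw$LFnorm, 0.85)
  expect_equal(spl$LF, spw$LF, tolerance = 0.25)
})
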