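# Independent brute-force oracles used to freeze expected values. These are
# deliberately literal transcriptions of the defining formulas and stay
# independent of the package's implementation paths.

oracle_time_domain <- function(v) {
  n <- length(v)
  avnn <- sum(v) / n
  sdnn <- sqrt(sum((v - avnn)^2) / (n - 1))
  d <- v[-1] - v[-n]
  rmssd <- sqrt(sum(d^2) / (n - 1))
  nn50 <- sum(abs(d) > 50)
  list(AVNN = avnn, SDNN = sdnn, RMSSD = rmssd, NN50 = nn50,
       pNN50 = 100 * nn50 / (n - 1), CV = sdnn / avnn)
}

oracle_poincare <- function(v) {
  n <- length(v)
  d <- v[-1] - v[-n]
  sdsd <- sqrt(sum((d - mean(d))^2) / (length(d) - 1))
  sd1 <- sdsd / sqrt(2)
  sdnn <- sqrt(sum((v - mean(v))^2) / (n - 1))
  list(SD1 = sd1, SD2 = sqrt(max(0, 2 * sdnn^2 - sd1^2)))
}

# O(n^2) pair counting with explicit loops (Richman-Moorman convention)
oracle_sampen <- function(v, m = 2, r = 0.2 * sd(v)) {
  n <- length(v)
  nt <- n - m
  B <- 0L; A <- 0L
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      dmax <- 0
      for (k in 0:(m - 1)) dmax <- max(dmax, abs(v[i + k] - v[j + k]))
      if (dmax <= r) {
        B <- B + 1L
        if (max(dmax, abs(v[i + m] - v[j + m])) <= r) A <- A + 1L
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# literal Lomb-Scargle transcription (direct trig, no recurrences), same
# scaling convention as lomb_psd(): band power = sum of returned bins
oracle_lomb_power <- function(t, y, freq, ofac = 4) {
  n <- length(y)
  yc <- y - mean(y)
  p <- vapply(freq, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    0.5 * (sum(yc * ct)^2 / sum(ct^2) + sum(yc * st)^2 / sum(st^2))
  }, numeric(1))
  p * 2 / (n * ofac)
}

# closed-form least squares via the normal equations
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  unname(solve(t(X) %*% X, t(X) %*% y)[2, 1])
}

# Kruskal-Wallis H without tie correction (valid for untied data)
oracle_kw_h <- function(groups) {
  all <- unlist(groups)
  n <- length(all)
  r <- rank(all)
  idx <- split(seq_along(all), rep(seq_along(groups), lengths(groups)))
  s <- sum(vapply(idx, function(i) sum(r[i])^2 / length(i), numeric(1)))
  12 / (n * (n + 1)) * s - 3 * (n + 1)
}

# AUROC by direct pair enumeration
oracle_auc <- function(scores, labels) {
  y <- as.logical(labels)
  cs <- scores[y]; ct <- scores[!y]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# DeLong variance of the AUC difference by direct structural components
oracle_delong <- function(a, b, labels) {
  y <- as.logical(labels)
  psi <- function(x, yv) (x > yv) + 0.5 * (x == yv)
  comp <- function(s) {
    cs <- s[y]; ct <- s[!y]
    v10 <- vapply(cs, function(x) mean(psi(x, ct)), numeric(1))
    v01 <- vapply(ct, function(x) mean(psi(cs, x)), numeric(1))
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  ca <- comp(a); cb <- comp(b)
  m <- sum(y); n <- sum(!y)
  s10 <- cov(cbind(ca$v10, cb$v10)); s01 <- cov(cbind(ca$v01, cb$v01))
  S <- s10 / m + s01 / n
  list(diff = ca$auc - cb$auc, var = S[1, 1] + S[2, 2] - 2 * S[1, 2])
}

# build a window interval table from values at roughly even spacing
make_window <- function(v, start = 0) {
  t <- start + cumsum(v) / 1000
  data.frame(time_s = t, nn_ms = v)
}

# nn_series constructor for tests
make_nn <- function(values_ms, start = 0, flagged = FALSE) {
  t <- start + cumsum(values_ms) / 1000
  nn <- data.frame(time_s = t, nn_ms = values_ms,
                   flagged = rep_len(flagged, length(values_ms)))
  class(nn) <- c("nn_series", "data.frame")
  nn
}
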