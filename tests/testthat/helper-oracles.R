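# Independent brute-force oracles: deliberately naive loop implementations,
# kept free of any vectorised code path shared with the package.

oracle_dap <- function(ax, ay, az, H1) {
  out <- numeric(length(ax))
  for (i in seq_along(ax)) out[i] <- H1 * az[i] / sqrt(ay[i]^2 + ax[i]^2)
  out
}

oracle_dml <- function(ax, ay, az, H2) {
  out <- numeric(length(ax))
  for (i in seq_along(ax)) out[i] <- H2 * ax[i] / sqrt(ay[i]^2 + az[i]^2)
  out
}

oracle_range <- function(x) {
  lo <- x[1]; hi <- x[1]
  for (v in x) { if (v < lo) lo <- v; if (v > hi) hi <- v }
  hi - lo
}

oracle_sd_sample <- function(x) {
  n <- length(x)
  m <- 0; for (v in x) m <- m + v
  m <- m / n
  s <- 0; for (v in x) s <- s + (v - m)^2
  sqrt(s / (n - 1))
}

oracle_cea <- function(dap, dml, confidence = 0.95) {
  k <- sqrt(qchisq(confidence, df = 2))
  pi * k * oracle_sd_sample(dap) * k * oracle_sd_sample(dml)
}

oracle_rms <- function(dap, dml) {
  n <- length(dap)
  s <- 0
  for (i in 2:n) s <- s + (dap[i] - dap[i - 1])^2 + (dml[i] - dml[i - 1])^2
  sqrt(s / (n - 1))
}

oracle_q <- function(pred, expected) {
  bad <- 0
  for (i in seq_along(pred)) if (pred[i] != expected[i]) bad <- bad + 1
  100 * (1 - bad / length(pred))
}

oracle_ri <- function(p) {
  p1 <- -Inf; p2 <- -Inf
  for (v in p) {
    if (v > p1) { p2 <- p1; p1 <- v } else if (v > p2) p2 <- v
  }
  if (p1 <= 0) 0 else (p1 - p2) / p1
}

oracle_ri_aggregates <- function(ri) {
  n <- length(ri)
  m <- 0; for (v in ri) m <- m + v
  m <- m / n
  s <- 0; for (v in ri) s <- s + (v - m)^2
  c(mean = 100 * m, std = 100 * sqrt(s / n))  # population std
}

# Brute-force Youden threshold: sweep every candidate cutpoint.
oracle_youden <- function(scores, positive) {
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, (head(u, -1) + tail(u, -1)) / 2, u[length(u)] + 1)
  bestJ <- -Inf; bestT <- NA
  for (th in cand) {
    sens <- mean(scores[positive] > th)
    spec <- mean(scores[!positive] <= th)
    if (sens + spec - 1 > bestJ + 1e-12) {
      bestJ <- sens + spec - 1; bestT <- th
    }
  }
  list(threshold = bestT, J = bestJ)
}

# A random stabilogram window for oracle comparisons.
random_window <- function(n = 50) {
  structure(data.frame(t = seq_len(n) / 100,
                       dap_m = rnorm(n, sd = runif(1, 0.001, 0.1)),
                       dml_m = rnorm(n, sd = runif(1, 0.001, 0.1))),
            fs = 100, class = c("stabilogram_trace", "data.frame"))
}
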