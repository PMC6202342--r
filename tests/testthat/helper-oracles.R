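# Independent oracles used to cross-check the package's numerics. These are
# deliberately literal, loop-based implementations kept free of any code
# path they verify.

# Literal taper-multiply-DFT-average cross-spectral estimator.
oracle_cross_spectra <- function(windows, tapers, fs, fmin, fmax) {
  n_samp <- ncol(windows[[1]])
  n_ch <- nrow(windows[[1]])
  k <- ncol(tapers)
  freqs <- (seq_len(n_samp) - 1) * fs / n_samp
  sel <- which(freqs <= fs / 2 & freqs >= fmin & freqs <= fmax)
  acc <- array(complex(real = 0), dim = c(n_ch, n_ch, length(sel)))
  for (w in seq_along(windows)) {
    for (j in seq_len(k)) {
      spec <- matrix(complex(real = 0), n_ch, length(sel))
      for (ch in seq_len(n_ch)) {
        tap <- windows[[w]][ch, ] * tapers[, j]
        ft <- vapply(sel, function(b) {
          sum(tap * exp(-2i * pi * (freqs[b] / fs) * (seq_len(n_samp) - 1)))
        }, complex(1))
        spec[ch, ] <- ft
      }
      for (b in seq_along(sel)) {
        acc[, , b] <- acc[, , b] + spec[, b] %o% Conj(spec[, b])
      }
    }
  }
  list(freqs = freqs[sel], csd = acc / (k * length(windows) * fs))
}

# Band coherence from an oracle CSD: per-bin normalization then bin average.
oracle_band_coherence <- function(csd_arr) {
  n_ch <- dim(csd_arr)[1]
  out <- matrix(0, n_ch, n_ch)
  for (i in seq_len(n_ch)) for (j in seq_len(n_ch)) {
    cij <- vapply(seq_len(dim(csd_arr)[3]), function(b) {
      Mod(csd_arr[i, j, b]) /
        sqrt(Re(csd_arr[i, i, b]) * Re(csd_arr[j, j, b]))
    }, numeric(1))
    out[i, j] <- mean(cij)
  }
  out
}

# Normal-equations OLS.
oracle_ols <- function(x, y) {
  as.numeric(solve(t(x) %*% x) %*% t(x) %*% y)
}

# Brute-force Benjamini-Hochberg step-up adjusted p-values.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# Rank-based AUC for separating two score samples (pos expected larger).
oracle_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# One-sample t statistic from the textbook formula.
oracle_onesample_t <- function(x) mean(x) / (sd(x) / sqrt(length(x)))
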