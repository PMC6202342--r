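#' Multitaper estimation settings
#'
#' Bundles the Slepian-taper parameters used for both connectivity windows
#' (1 s) and trial power windows (0.9 s): time-bandwidth product NW = 4, at
#' most 8 tapers, tapers with spectral concentration below 0.9 dropped.
#'
#' @param time_bandwidth Time-bandwidth product NW (> 0).
#' @param max_tapers Maximum number of tapers retained (>= 1).
#' @param min_concentration Concentration threshold in (0, 1); tapers whose
#'   in-band energy fraction falls below it are discarded.
#' @param window_s Nominal analysis window length in seconds.
#' @return An object of class `multitaper_spec`.
#' @export
multitaper_spec <- function(time_bandwidth = 4, max_tapers = 8,
                            min_concentration = 0.9, window_s = 1.0) {
  stopifnot(time_bandwidth > 0, max_tapers >= 1,
            min_concentration > 0, min_concentration < 1, window_s > 0)
  structure(list(time_bandwidth = time_bandwidth, max_tapers = max_tapers,
                 min_concentration = min_concentration, window_s = window_s),
            class = "multitaper_spec")
}

# Cache of computed taper sets, keyed by (n, nw, k): the tridiagonal
# eigenproblem is a few seconds at n = 1000 and identical across calls.
.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` for time-bandwidth
#' product `nw` from the classic symmetric tridiagonal eigenproblem, plus
#' each taper's spectral concentration (fraction of energy inside the
#' half-bandwidth W = nw/n), evaluated as the quadratic form of the
#' Dirichlet-kernel Toeplitz matrix.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product.
#' @param k Number of tapers to return.
#' @return List with `tapers` (n x k matrix, columns unit-norm) and
#'   `concentrations` (length-k vector in (0, 1), decreasing).
#' @export
dpss_tapers <- function(n, nw, k) {
  stopifnot(n >= 2, nw > 0, k >= 1, k <= n)
  key <- paste(n, nw, k, sep = "_")
  cached <- .dpss_cache[[key]]
  if (!is.null(cached)) return(cached)

  w <- nw / n
  i <- seq_len(n) - 1
  diag_v <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off_v <- (i[-1] * (n - i[-1])) / 2
  tri <- matrix(0, n, n)
  diag(tri) <- diag_v
  tri[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off_v
  tri[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off_v
  es <- eigen(tri, symmetric = TRUE)
  tapers <- es$vectors[, seq_len(k), drop = FALSE]

  # Fix sign conventions: symmetric tapers have positive mean; for
  # antisymmetric tapers the leading lobe is positive.
  for (j in seq_len(k)) {
    v <- tapers[, j]
    s <- sum(v)
    if (abs(s) > 1e-8) {
      if (s < 0) tapers[, j] <- -v
    } else if (v[which.max(abs(cumsum(v)))] < 0 || sum(v[seq_len(ceiling(n / 2))]) < 0) {
      tapers[, j] <- -v
    }
  }

  # Concentration: lambda_j = h' A h with A the sinc Toeplitz matrix.
  d <- outer(i, i, "-")
  A <- sin(2 * pi * w * d) / (pi * d)
  diag(A) <- 2 * w
  conc <- vapply(seq_len(k), function(j) {
    h <- tapers[, j]
    drop(crossprod(h, A %*% h))
  }, numeric(1))

  out <- list(tapers = tapers, concentrations = conc)
  .dpss_cache[[key]] <- out
  out
}

# Tapers retained under a multitaper_spec for window length n: at most
# max_tapers, concentration >= min_concentration.
retained_tapers <- function(n, spec) {
  d <- dpss_tapers(n, spec$time_bandwidth, spec$max_tapers)
  keep <- d$concentrations >= spec$min_concentration
  if (!any(keep)) stop("no tapers meet the concentration threshold of ",
                       spec$min_concentration)
  list(tapers = d$tapers[, keep, drop = FALSE],
       concentrations = d$concentrations[keep])
}

#' Averaged multitaper cross-spectral matrices
#'
#' Estimates cross-spectral density matrices on a grid of frequency bins,
#' averaging tapered periodograms over tapers and windows. This is the
#' engine behind both coherence networks and trial band power.
#'
#' @param windows List of `n_channels x n_samples` numeric matrices (equal
#'   lengths; microvolts).
#' @param spec A [multitaper_spec()].
#' @param fmin,fmax Frequency range in Hz; all FFT bins whose center lies in
#'   `[fmin, fmax]` (endpoints inclusive) are returned.
#' @param fs Sampling rate in Hz.
#' @return List with `freqs` (bin centers, Hz), `csd` (complex array
#'   `[n_channels, n_channels, n_freqs]`, Hermitian per frequency, units
#'   uV^2/Hz), `n_windows`, `n_tapers`.
#' @export
multitaper_cross_spectra <- function(windows, spec, fmin, fmax, fs) {
  if (!is.list(windows)) windows <- list(windows)
  stopifnot(length(windows) >= 1, fs > 0, fmin >= 0, fmax > fmin)
  n_samp <- unique(vapply(windows, ncol, integer(1)))
  if (length(n_samp) != 1) stop("all windows must have equal length")
  n_ch <- nrow(windows[[1]])

  freqs_all <- (seq_len(n_samp) - 1) * fs / n_samp
  half <- freqs_all <= fs / 2
  sel <- which(half & freqs_all >= fmin & freqs_all <= fmax)
  if (length(sel) == 0) {
    stop("no frequency bins inside [", fmin, ", ", fmax,
         "] Hz at this window length; window too short for the requested resolution")
  }

  tp <- retained_tapers(n_samp, spec)
  k <- ncol(tp$tapers)
  n_win <- length(windows)

  # Tapered spectra for every (window, taper): G[bin, channel, slice]
  g <- array(complex(real = 0), dim = c(length(sel), n_ch, k * n_win))
  slice <- 0L
  for (w in seq_len(n_win)) {
    xw <- t(windows[[w]])          # n_samp x n_ch
    for (j in seq_len(k)) {
      slice <- slice + 1L
      f <- stats::mvfft(xw * tp$tapers[, j])
      g[, , slice] <- f[sel, , drop = FALSE]
    }
  }

  scale <- 1 / fs  # tapers are unit-norm, so PSD = |X|^2 / fs
  csd <- array(complex(real = 0), dim = c(n_ch, n_ch, length(sel)))
  for (b in seq_along(sel)) {
    z <- matrix(g[b, , ], nrow = n_ch)
    csd[, , b] <- (z %*% Conj(t(z))) * (scale / (k * n_win))
  }
  list(freqs = freqs_all[sel], csd = csd, n_windows = n_win, n_tapers = k)
}

#' Multitaper band power of one trial segment
#'
#' Average multitaper PSD over the FFT bins inside a frequency band, for a
#' single-channel trial window (0.9 s at the recording rate).
#'
#' @param segment Numeric vector, one channel's trial window in microvolts.
#' @param band A [band_spec()] or list with `fmin`, `fmax` in Hz.
#' @param spec A [multitaper_spec()].
#' @param fs Sampling rate in Hz.
#' @return Band-averaged PSD (uV^2/Hz), strictly positive for non-zero
#'   input. An all-zero segment returns 0 carrying attribute
#'   `degenerate = TRUE` with a warning (its log is undefined downstream).
#' @export
trial_band_power <- function(segment, band, spec, fs) {
  stopifnot(is.numeric(segment), length(segment) >= 8)
  if (all(segment == 0)) {
    warning("all-zero segment: band power is 0 and undefined on the log scale")
    return(structure(0, degenerate = TRUE))
  }
  mt <- multitaper_cross_spectra(list(matrix(segment, nrow = 1)), spec,
                                 band$fmin, band$fmax, fs)
  mean(Re(mt$csd[1, 1, ]))
}
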