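#' Adjacency matrix with connectivity metadata
#'
#' @param values Symmetric `n x n` numeric matrix; the diagonal is masked
#'   (`NA`) because self-connectivity is undefined for every method here.
#' @param method `"coherence"` (values in `[0,1]`), `"hfb_envelope"`
#'   (Fisher-z correlations) or `"distance_lin"` (values in `(0,1]`).
#' @param band Frequency band `c(fmin, fmax)` in Hz, a single frequency, or
#'   `NULL` (distance).
#' @param labels Node labels.
#' @param n_windows Number of windows averaged into the estimate.
#' @return Object of class `adjacency`.
#' @export
adjacency <- function(values, method = c("coherence", "hfb_envelope",
                                         "distance_lin"),
                      band = NULL, labels = NULL, n_windows = NA_integer_) {
  method <- match.arg(method)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("adjacency must be square")
  diag(values) <- NA_real_
  off <- values[upper.tri(values)]
  if (length(off) > 0 && max(abs(values - t(values)), na.rm = TRUE) > 1e-8)
    stop("adjacency must be symmetric")
  if (method == "coherence" && any(off < -1e-12 | off > 1 + 1e-12))
    stop("coherence values must lie in [0, 1]")
  if (method == "distance_lin" && any(off <= 0 | off > 1 + 1e-12))
    stop("linearized distances must lie in (0, 1]")
  if (method == "hfb_envelope" && any(!is.finite(off)))
    stop("Fisher-z values must be finite")
  labels <- labels %||% paste0("n", seq_len(nrow(values)))
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, method = method, band = band,
                 labels = labels, n_windows = n_windows),
            class = "adjacency")
}

# Accept either an adjacency object or a bare symmetric matrix.
adjacency_values <- function(x) {
  if (inherits(x, "adjacency")) x$values else as.matrix(x)
}

#' @export
print.adjacency <- function(x, ...) {
  band <- if (is.null(x$band)) "" else
    paste0(", band ", paste(x$band, collapse = "-"), " Hz")
  cat(sprintf("<adjacency> %s, %d nodes%s\n", x$method, nrow(x$values), band))
  invisible(x)
}

#' Cut a baseline recording into sequential analysis windows
#'
#' @param rec A [recording()].
#' @param window_s Window length in seconds (1 s for connectivity).
#' @return List of `n_channels x n_samples` matrices.
#' @export
baseline_windows <- function(rec, window_s = 1) {
  n <- round(window_s * rec$fs)
  n_win <- floor(ncol(rec$samples) / n)
  if (n_win < 1) stop("recording shorter than one window")
  lapply(seq_len(n_win), function(w)
    rec$samples[, ((w - 1) * n + 1):(w * n), drop = FALSE])
}

#' Multitaper coherence network
#'
#' Cross-spectra are averaged over tapers and windows, normalized per
#' frequency bin as `C_xy(f) = |<S_xy>| / sqrt(<S_xx> <S_yy>)`, and the band
#' value is the mean of `C_xy(f)` over all bins whose center lies inside
#' the band (endpoints inclusive).
#'
#' @param windows List of equal-length `n_channels x n_samples` segments
#'   (1-s windows from baseline periods).
#' @param spec A [multitaper_spec()].
#' @param band `c(fmin, fmax)` in Hz; the low-frequency networks use
#'   5-13 Hz.
#' @param fs Sampling rate, Hz.
#' @param labels Optional node labels.
#' @param min_windows Warn below this window count (100 in the paradigm).
#' @return An [adjacency()] of method `"coherence"`.
#' @export
coherence_network <- function(windows, spec = multitaper_spec(),
                              band = c(5, 13), fs, labels = NULL,
                              min_windows = 100) {
  if (length(windows) < min_windows)
    warning("only ", length(windows), " windows; network estimates are ",
            "noisy below ", min_windows)
  mt <- multitaper_cross_spectra(windows, spec, band[1], band[2], fs)
  coh <- coherence_from_csd(mt$csd)
  vals <- apply(coh, c(1, 2), mean)
  adjacency(vals, "coherence", band = band, labels = labels,
            n_windows = length(windows))
}

# Per-bin coherence from a CSD array: |S_xy| / sqrt(S_xx S_yy).
coherence_from_csd <- function(csd) {
  n_ch <- dim(csd)[1]; n_f <- dim(csd)[3]
  out <- array(0, dim = dim(csd))
  for (b in seq_len(n_f)) {
    p <- Re(diag(csd[, , b]))
    out[, , b] <- Mod(csd[, , b]) / sqrt(outer(p, p))
  }
  out
}

#' Per-frequency coherence networks (4-50 Hz, 1 Hz spacing)
#'
#' One network per integer frequency with no averaging over bands: the
#' adjacency at frequency f uses only the bins whose center lies in
#' `[f - 0.5, f + 0.5)` of the window's FFT grid; with 1-s windows this is
#' the single bin at f.
#'
#' @inheritParams coherence_network
#' @param fmin,fmax,step Frequency grid, Hz.
#' @return List of [adjacency()] objects, one per frequency (47 for the
#'   default 4-50 Hz grid).
#' @export
per_frequency_networks <- function(windows, spec = multitaper_spec(), fs,
                                   fmin = 4, fmax = 50, step = 1,
                                   labels = NULL, min_windows = 100) {
  if (length(windows) < min_windows)
    warning("only ", length(windows), " windows; network estimates are ",
            "noisy below ", min_windows)
  mt <- multitaper_cross_spectra(windows, spec, fmin, fmax, fs)
  coh <- coherence_from_csd(mt$csd)
  freqs <- seq(fmin, fmax, by = step)
  lapply(freqs, function(f) {
    sel <- which(abs(mt$freqs - f) < step / 2 |
                 abs(mt$freqs - f) == step / 2 & mt$freqs <= f)
    if (length(sel) == 0) sel <- which.min(abs(mt$freqs - f))
    vals <- apply(coh[, , sel, drop = FALSE], c(1, 2), mean)
    adjacency(vals, "coherence", band = f, labels = labels,
              n_windows = length(windows))
  })
}

# Analytic signal via the frequency-domain construction.
analytic_signal <- function(x) {
  n <- length(x)
  f <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(f * h, inverse = TRUE) / n
}

#' High-frequency broadband amplitude-envelope correlation network
#'
#' Notch-filters the resting recording, band-passes it sequentially in
#' 10 Hz sub-bands from 50 to 200 Hz, extracts each sub-band's analytic
#' amplitude, normalizes by its own mean, averages across sub-bands,
#' low-pass filters the resulting broadband envelope below 1 Hz, and
#' correlates the slow envelopes between all channel pairs. Correlations
#' are Fisher z-transformed; the diagonal is masked.
#'
#' @param rec A resting [recording()], nominally ~240 s.
#' @param line_freq Line frequency for the notch, Hz.
#' @param band_edges Sub-band range, Hz.
#' @param band_width Sub-band width, Hz.
#' @param lp_cutoff Envelope low-pass cutoff, Hz.
#' @return An [adjacency()] of method `"hfb_envelope"` (Fisher z).
#' @export
hfb_envelope_network <- function(rec, line_freq = 60, band_edges = c(50, 200),
                                 band_width = 10, lp_cutoff = 1) {
  if (rec$fs <= 2 * band_edges[2])
    stop("sampling rate too low for a ", band_edges[2], " Hz band edge")
  dur <- ncol(rec$samples) / rec$fs
  if (dur < 30) stop("recording shorter than 30 s")
  if (dur < 240) warning("recording shorter than 240 s (", round(dur),
                         " s); envelope correlations will be noisy")
  rec <- notch_filter(rec, line_freq)
  n_ch <- nrow(rec$samples)
  lo_edges <- seq(band_edges[1], band_edges[2] - band_width, by = band_width)
  env_sum <- matrix(0, n_ch, ncol(rec$samples))
  for (lo in lo_edges) {
    bf <- signal::butter(4, c(lo, lo + band_width) / (rec$fs / 2),
                         type = "pass")
    for (ch in seq_len(n_ch)) {
      xb <- signal::filtfilt(bf, rec$samples[ch, ])
      amp <- Mod(analytic_signal(xb))
      env_sum[ch, ] <- env_sum[ch, ] + amp / mean(amp)
    }
  }
  env <- env_sum / length(lo_edges)
  lp <- signal::butter(4, lp_cutoff / (rec$fs / 2), type = "low")
  for (ch in seq_len(n_ch)) env[ch, ] <- signal::filtfilt(lp, env[ch, ])
  r <- stats::cor(t(env))
  z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  diag(z) <- NA_real_
  adjacency(z, "hfb_envelope", band = band_edges, labels = rec$labels,
            n_windows = 1L)
}

#' Linearized inter-electrode distance network
#'
#' Pairwise Euclidean distances (mm) are normalized by the layout's maximum
#' pairwise distance and linearized as `exp(-distance)`, so zero separation
#' maps to 1.0 and the maximally separated pair to `exp(-1)`. Distinct
#' electrodes at coincident coordinates get value 1.0 with a warning.
#'
#' @param layout An [electrode_layout()] with >= 2 electrodes.
#' @return An [adjacency()] of method `"distance_lin"`.
#' @export
distance_network <- function(layout) {
  n <- length(layout$labels)
  if (n < 2) stop("distance network needs at least 2 electrodes")
  d <- as.matrix(stats::dist(layout$coordinates))
  off_zero <- d[upper.tri(d)] == 0
  if (any(off_zero))
    warning("coincident electrodes (zero separation); linearized value 1.0")
  dmax <- max(d)
  if (dmax == 0) {
    vals <- matrix(1, n, n)
  } else {
    vals <- exp(-d / dmax)
  }
  adjacency(vals, "distance_lin", labels = layout$labels)
}

#' Normalized node strength (hub score)
#'
#' Sum of a node's off-diagonal connection weights divided by the number of
#' possible connections (`n - 1`), yielding values in `[0, 1]` for
#' coherence networks.
#'
#' @param adj An [adjacency()] or symmetric matrix with >= 2 nodes.
#' @param node Node index or label.
#' @return Normalized strength.
#' @export
node_strength <- function(adj, node) {
  v <- adjacency_values(adj)
  if (nrow(v) < 2) stop("node strength undefined for a single-node network")
  if (is.character(node)) node <- match(node, rownames(v))
  if (is.na(node) || node < 1 || node > nrow(v)) stop("unknown node")
  sum(v[node, -node], na.rm = FALSE) / (nrow(v) - 1)
}

#' Write / read an adjacency matrix as TSV with JSON metadata
#'
#' @param adj An [adjacency()].
#' @param path Output TSV path; metadata goes to `<path>.json`.
#' @export
write_adjacency <- function(adj, path) {
  utils::write.table(as.data.frame(adj$values), path, sep = "\t",
                     quote = FALSE, row.names = TRUE, col.names = NA)
  jsonlite::write_json(list(method = adj$method, band = adj$band,
                            n_windows = adj$n_windows),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- m
  diag(vals) <- NA_real_
  adjacency(vals, meta$method, band = meta$band, labels = rownames(m),
            n_windows = meta$n_windows %||% NA_integer_)
}
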