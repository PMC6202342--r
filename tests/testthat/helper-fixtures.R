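# Fixtures built in code at test time: small layouts, connectivity
# matrices, sessions, and a byte-level EDF writer for exercising the
# read-only EDF parser.

fixture_coherence <- function(n, seed = 1, lo = 0.05, hi = 0.9) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, lo, hi)
  m <- m + t(m)
  diag(m) <- NA
  adjacency(m, "coherence", band = c(5, 13),
            labels = sprintf("VE%03d", seq_len(n)))
}

fixture_layout <- function(n, seed = 1, ...) generate_layout(n, seed = seed, ...)

# A null-truth study context (layout + random coherence + distance) that
# Monte-Carlo NMA loops share.
fixture_site_context <- function(n = 60, seed = 1) {
  lay <- fixture_layout(n, seed = seed)
  list(layout = lay,
       coherence = fixture_coherence(n, seed = seed + 1),
       distance = distance_network(lay))
}

# Draw one power-level session under the given truth and return its theta
# power contrast.
fixture_contrast <- function(ctx, truth, stim = "VE001", n_trials = 240,
                             seed = 1) {
  s <- generate_stim_session(ctx$layout, ctx$coherence, ctx$distance, truth,
                             stim, n_trials = n_trials, seed = seed,
                             synthesize = FALSE, artifact_windows = FALSE)
  pw <- session_band_powers(s)
  power_contrast(pw$pre, pw$post)
}

# Minimal EDF writer (one data record per second, int16 little-endian),
# independent of the package's reader.
write_edf_fixture <- function(path, samples, fs, labels,
                              pmin = -500, pmax = 500) {
  ns <- nrow(samples)
  n_records <- ncol(samples) / fs
  stopifnot(n_records == round(n_records))
  dmin <- -32768; dmax <- 32767
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(pad("0", 8), pad("patient", 80), pad("recording", 80),
                   pad("01.01.20", 8), pad("00.00.00", 8),
                   pad(256 + ns * 256, 8), pad("", 44), pad(n_records, 8),
                   pad(1, 8), pad(ns, 4)),
            con, eos = NULL)
  wfield <- function(vals, w)
    writeChar(paste(vapply(vals, pad, character(1), w = w), collapse = ""),
              con, eos = NULL)
  wfield(labels, 16)
  wfield(rep("transducer", ns), 80)
  wfield(rep("uV", ns), 8)
  wfield(rep(pmin, ns), 8)
  wfield(rep(pmax, ns), 8)
  wfield(rep(dmin, ns), 8)
  wfield(rep(dmax, ns), 8)
  wfield(rep("", ns), 80)
  wfield(rep(fs, ns), 8)
  wfield(rep("", ns), 32)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      x <- samples[s, ((r - 1) * fs + 1):(r * fs)]
      dig <- round((x - pmin) / (pmax - pmin) * (dmax - dmin) + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}
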