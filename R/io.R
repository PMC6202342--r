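#' Multichannel recording container
#'
#' @param samples `n_channels x n_samples` numeric matrix, microvolts.
#' @param fs Sampling rate in Hz (> 0).
#' @param labels Character vector of unique channel labels.
#' @param montage `"monopolar"` or `"bipolar"`.
#' @return Object of class `recording`.
#' @export
recording <- function(samples, fs, labels, montage = c("monopolar", "bipolar")) {
  montage <- match.arg(montage)
  samples <- as.matrix(samples)
  if (nrow(samples) == 0) stop("recording must have at least one channel")
  stopifnot(is.numeric(fs), length(fs) == 1, fs > 0)
  if (!all(is.finite(samples))) stop("recording samples must be finite")
  labels <- as.character(labels)
  if (length(labels) != nrow(samples)) stop("labels must match channel count")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  structure(list(samples = samples, fs = fs, labels = labels,
                 montage = montage),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%s montage)\n",
              nrow(x$samples), ncol(x$samples), x$fs, x$montage))
  invisible(x)
}

#' Electrode layout metadata
#'
#' Coordinates refer to bipolar midpoints of virtual electrodes; clinical
#' flags (seizure-onset zone, inter-ictal spiking) and distance to nearest
#' white matter are inputs provided per electrode, not computed here.
#'
#' @param labels Virtual electrode labels (unique).
#' @param coordinates `n x 3` matrix of x/y/z positions in mm.
#' @param soz_flag,spiking_flag Logical vectors (clinician-provided).
#' @param wm_distance Distance to nearest white matter, mm, >= 0.
#' @param in_wm_label Logical: expert "in white matter" label.
#' @param contact_members `n x 2` character matrix naming the two physical
#'   contacts forming each virtual electrode.
#' @return Object of class `electrode_layout`.
#' @export
electrode_layout <- function(labels, coordinates, soz_flag = NULL,
                             spiking_flag = NULL, wm_distance = NULL,
                             in_wm_label = NULL, contact_members = NULL) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 1) stop("layout needs at least one electrode")
  if (anyDuplicated(labels)) stop("electrode labels must be unique")
  coordinates <- as.matrix(coordinates)
  if (nrow(coordinates) != n || ncol(coordinates) != 3)
    stop("coordinates must be an n x 3 matrix (mm)")
  soz_flag <- soz_flag %||% rep(FALSE, n)
  spiking_flag <- spiking_flag %||% rep(FALSE, n)
  wm_distance <- wm_distance %||% rep(0, n)
  in_wm_label <- in_wm_label %||% rep(FALSE, n)
  if (is.null(contact_members)) {
    contact_members <- cbind(paste0(labels, ".a"), paste0(labels, ".b"))
  }
  contact_members <- as.matrix(contact_members)
  stopifnot(length(soz_flag) == n, length(spiking_flag) == n,
            length(wm_distance) == n, length(in_wm_label) == n,
            nrow(contact_members) == n, ncol(contact_members) == 2)
  if (any(wm_distance < 0)) stop("wm_distance must be >= 0")
  structure(list(labels = labels, coordinates = coordinates,
                 soz_flag = as.logical(soz_flag),
                 spiking_flag = as.logical(spiking_flag),
                 wm_distance = as.numeric(wm_distance),
                 in_wm_label = as.logical(in_wm_label),
                 contact_members = contact_members),
            class = "electrode_layout")
}

#' Write / read an electrode layout as TSV
#'
#' Columns: label, x_mm, y_mm, z_mm, soz, spiking, wm_distance_mm, in_wm,
#' contact_a, contact_b.
#' @param layout An [electrode_layout()].
#' @param path File path.
#' @export
write_layout <- function(layout, path) {
  df <- data.frame(label = layout$labels,
                   x_mm = layout$coordinates[, 1],
                   y_mm = layout$coordinates[, 2],
                   z_mm = layout$coordinates[, 3],
                   soz = layout$soz_flag,
                   spiking = layout$spiking_flag,
                   wm_distance_mm = layout$wm_distance,
                   in_wm = layout$in_wm_label,
                   contact_a = layout$contact_members[, 1],
                   contact_b = layout$contact_members[, 2])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  electrode_layout(df$label, as.matrix(df[, c("x_mm", "y_mm", "z_mm")]),
                   soz_flag = df$soz, spiking_flag = df$spiking,
                   wm_distance = df$wm_distance_mm, in_wm_label = df$in_wm,
                   contact_members = cbind(df$contact_a, df$contact_b))
}

#' Write a recording to the native binary container
#'
#' The container is a flat little-endian float64 dump of the sample matrix
#' (channel-major) with a JSON sidecar (`<path>.json`) carrying fs, labels,
#' montage, and dimensions. Round trips are bit-exact, unlike EDF which
#' quantizes to 16 bits.
#'
#' @param rec A [recording()].
#' @param path Output file path (sidecar written alongside).
#' @param format Only `"container"` is writable; EDF is read-only.
#' @export
write_recording <- function(rec, path, format = "container") {
  if (!inherits(rec, "recording")) stop("rec must be a recording")
  if (format != "container") stop("only the container format is writable")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(rec$samples)), con, size = 8, endian = "little")
  meta <- list(fs = rec$fs, labels = rec$labels, montage = rec$montage,
               n_channels = nrow(rec$samples), n_samples = ncol(rec$samples),
               dtype = "float64le", order = "channel_major")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording (native container or EDF)
#'
#' @param path File path.
#' @param format `"container"` (bit-exact native format) or `"edf"`
#'   (European Data Format, 16-bit quantized, read-only).
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("container", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("recording file not found: ", path)
  if (format == "container") {
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    con <- file(path, "rb")
    on.exit(close(con))
    x <- readBin(con, numeric(), n = meta$n_channels * meta$n_samples,
                 size = 8, endian = "little")
    samples <- t(matrix(x, nrow = meta$n_samples, ncol = meta$n_channels))
    recording(samples, as.numeric(meta$fs), meta$labels, meta$montage)
  } else {
    read_edf(path)
  }
}

# Minimal EDF reader: fixed 256-byte header, per-signal header block,
# int16 little-endian data records scaled to physical units.
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(nchar) trimws(rawToChar(readBin(con, raw(), nchar)))
  hdr(8)                     # version
  hdr(80); hdr(80); hdr(8); hdr(8)   # patient, recording ids, dates
  readBin(con, raw(), 8)     # header bytes (recomputed below)
  hdr(44)                    # reserved
  n_records <- as.integer(hdr(8))
  record_dur <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  if (is.na(ns) || ns < 1) stop("EDF parse error: bad signal count")
  field <- function(w) vapply(seq_len(ns), function(i) hdr(w), character(1))
  labels <- field(16)
  field(80); field(8)        # transducer, dimension
  pmin <- as.numeric(field(8)); pmax <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
  field(80)                  # prefiltering
  nsamp <- as.integer(field(8))
  field(32)                  # reserved
  if (length(unique(nsamp)) != 1)
    stop("EDF with per-signal sampling rates is not supported")
  fs <- nsamp[1] / record_dur
  dat <- matrix(0, nrow = ns, ncol = n_records * nsamp[1])
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      d <- readBin(con, integer(), n = nsamp[s], size = 2, signed = TRUE,
                   endian = "little")
      phys <- (d - dmin[s]) * (pmax[s] - pmin[s]) / (dmax[s] - dmin[s]) + pmin[s]
      dat[s, ((r - 1) * nsamp[s] + 1):(r * nsamp[s])] <- phys
    }
  }
  if (anyDuplicated(labels)) stop("EDF has duplicated channel labels")
  if (!all(is.finite(dat))) stop("EDF contains non-finite data after scaling")
  recording(dat, fs, labels, "monopolar")
}

#' Bipolar re-referencing
#'
#' Differences named physical contacts to form virtual electrodes, removing
#' signal common to both (e.g. the recording reference). Output channel i is
#' the first member minus the second; labels are `"A-B"`.
#'
#' @param rec A monopolar [recording()].
#' @param pairs List of length-2 character vectors naming contacts.
#' @return A bipolar [recording()] with one channel per pair.
#' @export
bipolar_rereference <- function(rec, pairs) {
  if (!inherits(rec, "recording")) stop("rec must be a recording")
  if (rec$montage != "monopolar") stop("input must be monopolar")
  out <- matrix(0, nrow = length(pairs), ncol = ncol(rec$samples))
  labs <- character(length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    if (length(p) != 2) stop("each pair must name exactly two contacts")
    if (p[1] == p[2]) stop("pair of identical contacts: ", p[1])
    ia <- match(p[1], rec$labels); ib <- match(p[2], rec$labels)
    if (is.na(ia) || is.na(ib))
      stop("unknown contact in pair: ", paste(p, collapse = ", "))
    out[i, ] <- rec$samples[ia, ] - rec$samples[ib, ]
    labs[i] <- paste0(p[1], "-", p[2])
  }
  recording(out, rec$fs, labs, "bipolar")
}

#' Notch filter at the line frequency
#'
#' Zero-phase (forward-backward) Butterworth band-stop around the line
#' frequency. Attenuation at the line frequency exceeds 20 dB while the
#' passband below 0.8x line frequency is changed by less than 1%.
#'
#' @param rec A [recording()].
#' @param line_freq Line frequency in Hz (50 or 60 typically).
#' @param halfwidth Stop-band half width in Hz.
#' @return Filtered [recording()].
#' @export
notch_filter <- function(rec, line_freq, halfwidth = 2.5) {
  if (!inherits(rec, "recording")) stop("rec must be a recording")
  if (rec$fs <= 2 * line_freq)
    stop("sampling rate must exceed twice the line frequency")
  bf <- signal::butter(4, c(line_freq - halfwidth, line_freq + halfwidth) /
                            (rec$fs / 2), type = "stop")
  out <- rec$samples
  for (i in seq_len(nrow(out))) {
    out[i, ] <- signal::filtfilt(bf, rec$samples[i, ])
  }
  recording(out, rec$fs, rec$labels, rec$montage)
}
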