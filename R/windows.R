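#' Stimulation session container
#'
#' Holds per-trial windows around stimulation events: 900 ms power windows
#' (-950 to -50 ms before onset; +50 to +950 ms after offset) and 350 ms
#' artifact-check windows abutting the stimulation interval on both sides.
#'
#' @param stim_pair Character vector of the two stimulated physical contacts.
#' @param labels Channel (virtual electrode) labels.
#' @param fs Sampling rate, Hz.
#' @param onsets Trial onsets, seconds.
#' @param stim_duration Stimulation duration, seconds (0.5 in the paradigm).
#' @param pre_power,post_power Arrays `[n_trials, n_channels, n_samples]` of
#'   the 900 ms power windows (may be `NULL` for power-level synthetic
#'   sessions carrying `log_pre`/`log_post` instead).
#' @param pre_art,post_art Arrays of the 350 ms artifact-check windows.
#' @param amplitudes,pulse_freqs Per-trial stimulation parameters.
#' @param log_pre,log_post Optional `[n_trials, n_channels]` matrices of
#'   ground-truth log theta power (synthetic sessions).
#' @param n_dropped Number of out-of-bounds trials dropped on extraction.
#' @return Object of class `stim_session`.
#' @export
stim_session <- function(stim_pair, labels, fs, onsets, stim_duration,
                         pre_power = NULL, post_power = NULL,
                         pre_art = NULL, post_art = NULL,
                         amplitudes = NULL, pulse_freqs = NULL,
                         log_pre = NULL, log_post = NULL, n_dropped = 0L) {
  stopifnot(length(stim_pair) == 2, fs > 0, stim_duration > 0)
  n_trials <- length(onsets)
  if (n_trials < 1) stop("a session needs at least 1 trial")
  structure(list(stim_pair = as.character(stim_pair),
                 labels = as.character(labels), fs = fs,
                 onsets = as.numeric(onsets), stim_duration = stim_duration,
                 pre_power = pre_power, post_power = post_power,
                 pre_art = pre_art, post_art = post_art,
                 amplitudes = amplitudes %||% rep(NA_real_, n_trials),
                 pulse_freqs = pulse_freqs %||% rep(NA_real_, n_trials),
                 log_pre = log_pre, log_post = log_post,
                 n_dropped = n_dropped),
            class = "stim_session")
}

#' @export
print.stim_session <- function(x, ...) {
  cat(sprintf("<stim_session> %d trials, %d channels, stim pair %s @ %g Hz\n",
              length(x$onsets), length(x$labels),
              paste(x$stim_pair, collapse = "-"), x$fs))
  if (x$n_dropped > 0) cat("  (", x$n_dropped, "out-of-bounds trials dropped )\n")
  invisible(x)
}

# 0-based, half-open window indices: start = round(t * fs), fixed length in
# samples so the 900/350 ms windows are sample-exact at 500/1000/1600 Hz.
window_index <- function(t_start, len_s, fs) {
  start <- round(t_start * fs)
  len <- round(len_s * fs)
  c(start, start + len)   # [start, end)
}

#' Cut a recording into stimulation trial windows
#'
#' Per trial: the pre power window spans -950 to -50 ms relative to onset,
#' the post power window +50 to +950 ms after stimulation offset, and the
#' 350 ms artifact-check windows abut the stimulation interval. Trials whose
#' windows fall outside the recording are dropped with a warning.
#'
#' @param rec A [recording()] (bipolar montage expected).
#' @param onsets Stimulation onsets, seconds.
#' @param stim_duration Stimulation duration, seconds.
#' @param stim_pair Stimulated physical contact names (metadata).
#' @param amplitudes,pulse_freqs Optional per-trial parameters.
#' @return A [stim_session()].
#' @export
extract_trial_windows <- function(rec, onsets, stim_duration,
                                  stim_pair = c("?", "?"),
                                  amplitudes = NULL, pulse_freqs = NULL) {
  if (!inherits(rec, "recording")) stop("rec must be a recording")
  stopifnot(length(onsets) >= 1, stim_duration > 0)
  fs <- rec$fs
  n_total <- ncol(rec$samples)
  idx <- lapply(onsets, function(on) {
    list(pre  = window_index(on - 0.950, 0.9, fs),
         post = window_index(on + stim_duration + 0.050, 0.9, fs),
         pre_art  = window_index(on - 0.350, 0.35, fs),
         post_art = window_index(on + stim_duration, 0.35, fs))
  })
  ok <- vapply(idx, function(w) {
    lo <- min(vapply(w, `[`, numeric(1), 1))
    hi <- max(vapply(w, `[`, numeric(1), 2))
    lo >= 0 && hi <= n_total
  }, logical(1))
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    warning(n_dropped, " trial(s) dropped: windows exceed recording bounds")
  if (!any(ok)) stop("zero trials with in-bounds windows")
  idx <- idx[ok]
  keep <- which(ok)

  n_ch <- nrow(rec$samples)
  take <- function(which_win) {
    len <- idx[[1]][[which_win]][2] - idx[[1]][[which_win]][1]
    arr <- array(0, dim = c(length(idx), n_ch, len))
    for (t in seq_along(idx)) {
      w <- idx[[t]][[which_win]]
      arr[t, , ] <- rec$samples[, (w[1] + 1):w[2], drop = FALSE]
    }
    arr
  }
  stim_session(stim_pair, rec$labels, fs, onsets[keep], stim_duration,
               pre_power = take("pre"), post_power = take("post"),
               pre_art = take("pre_art"), post_art = take("post_art"),
               amplitudes = (amplitudes %||% rep(NA_real_, length(onsets)))[keep],
               pulse_freqs = (pulse_freqs %||% rep(NA_real_, length(onsets)))[keep],
               n_dropped = n_dropped)
}

#' Channel inclusion mask
#'
#' @param included Logical vector per electrode.
#' @param reasons List of character vectors; nonempty exactly where
#'   `included` is `FALSE`. Reason codes: `artifact`, `soz_or_spiking`,
#'   `shares_stim_contact`, `stim_site`, `user`.
#' @return Object of class `channel_mask`.
#' @export
channel_mask <- function(included, reasons = NULL) {
  included <- as.logical(included)
  reasons <- reasons %||% lapply(included, function(i) character(0))
  stopifnot(length(reasons) == length(included))
  empty <- lengths(reasons) == 0
  if (any(empty != included))
    stop("reasons must be nonempty exactly on excluded electrodes")
  structure(list(included = included, reasons = reasons),
            class = "channel_mask")
}

#' Artifact test statistics on per-trial window means
#'
#' The paired t-test compares the trialwise mean voltage of the 350 ms
#' pre-stimulation window with the 350 ms post-stimulation window; the
#' Levene test (Brown-Forsythe, median-centered, by default) compares their
#' variances. This is the per-channel primitive behind
#' [detect_artifact_channels()] and is exposed for calibration studies.
#'
#' @param pre_means,post_means Numeric vectors of per-trial window means.
#' @param center `"median"` (Brown-Forsythe, default) or `"mean"` (classic
#'   Levene).
#' @return List with `p_t` and `p_levene`.
#' @export
artifact_tests <- function(pre_means, post_means, center = c("median", "mean")) {
  center <- match.arg(center)
  stopifnot(length(pre_means) == length(post_means), length(pre_means) >= 2)
  p_t <- stats::t.test(post_means, pre_means, paired = TRUE)$p.value
  g <- factor(rep(c("pre", "post"), each = length(pre_means)))
  lev <- car::leveneTest(c(pre_means, post_means), g,
                         center = if (center == "median") stats::median else mean)
  list(p_t = p_t, p_levene = lev[["Pr(>F)"]][1])
}

#' Detect channels contaminated by post-stimulation artifact
#'
#' For each channel, the average voltage in the 350 ms before stimulation is
#' compared across trials with the average voltage in the 350 ms after
#' stimulation, by a paired t-test (mean shift) and a Levene test (variance
#' change). A channel failing either test at `p_thresh` is excluded.
#'
#' @param session A [stim_session()] with artifact windows.
#' @param p_thresh Exclusion threshold (0.01 in the paradigm).
#' @param center Levene centering, see [artifact_tests()].
#' @return A [channel_mask()] with reason `artifact` on excluded channels.
#' @export
detect_artifact_channels <- function(session, p_thresh = 0.01,
                                     center = c("median", "mean")) {
  center <- match.arg(center)
  if (is.null(session$pre_art) || is.null(session$post_art))
    stop("session carries no artifact-check windows")
  n_trials <- dim(session$pre_art)[1]
  if (n_trials < 2) stop("artifact detection needs at least 2 trials")
  n_ch <- dim(session$pre_art)[2]
  included <- rep(TRUE, n_ch)
  reasons <- vector("list", n_ch)
  for (ch in seq_len(n_ch)) {
    pre_m <- rowMeans(session$pre_art[, ch, , drop = FALSE][, 1, ])
    post_m <- rowMeans(session$post_art[, ch, , drop = FALSE][, 1, ])
    p <- artifact_tests(pre_m, post_m, center)
    reasons[[ch]] <- character(0)
    if (min(p$p_t, p$p_levene, na.rm = TRUE) < p_thresh) {
      included[ch] <- FALSE
      reasons[[ch]] <- "artifact"
    }
  }
  channel_mask(included, reasons)
}

#' Apply the full electrode exclusion rule set
#'
#' Union of exclusions: post-stimulation artifact (from `artifact_mask`),
#' clinician-flagged seizure-onset-zone or spiking electrodes, any virtual
#' electrode sharing a physical contact with the stimulated pair, and the
#' stimulation site itself. Sessions retaining fewer than `min_electrodes`
#' electrodes are discarded with an error, mirroring the subject-discard
#' rule.
#'
#' @param layout An [electrode_layout()].
#' @param artifact_mask A [channel_mask()] aligned with the layout, or
#'   `NULL` for no artifact exclusions.
#' @param stim_pair Character vector of the two stimulated physical contacts.
#' @param min_electrodes Hard lower bound on surviving electrodes (10).
#' @return A [channel_mask()] with per-electrode reason codes.
#' @export
apply_exclusions <- function(layout, artifact_mask, stim_pair,
                             min_electrodes = 10) {
  n <- length(layout$labels)
  if (!is.null(artifact_mask) && length(artifact_mask$included) != n)
    stop("artifact mask not aligned with layout")
  included <- rep(TRUE, n)
  reasons <- lapply(seq_len(n), function(i) character(0))
  for (i in seq_len(n)) {
    r <- character(0)
    if (!is.null(artifact_mask) && !artifact_mask$included[i])
      r <- c(r, artifact_mask$reasons[[i]])
    if (layout$soz_flag[i] || layout$spiking_flag[i])
      r <- c(r, "soz_or_spiking")
    members <- layout$contact_members[i, ]
    shared <- sum(members %in% stim_pair)
    if (shared == 2) {
      r <- c(r, "stim_site")
    } else if (shared == 1) {
      r <- c(r, "shares_stim_contact")
    }
    if (length(r) > 0) {
      included[i] <- FALSE
      reasons[[i]] <- unique(r)
    }
  }
  if (sum(included) < min_electrodes)
    stop("fewer than ", min_electrodes, " electrodes remain after exclusions (",
         sum(included), "); session discarded")
  channel_mask(included, reasons)
}
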