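#' Ground truth parameters for synthetic studies
#'
#' Collects everything the generator plants and the pipeline should
#' recover: the latent-source mixing that creates 5-13 Hz coherence
#' structure, the linear connectivity/distance effect on post-stimulation
#' log theta power, artifact plumbing, and slow envelope coupling.
#'
#' @param mixing_weights `n_sources x n_channels` matrix of unitless source
#'   weights.
#' @param source_freqs Source frequencies in Hz (must stay below Nyquist of
#'   any recording generated from this truth).
#' @param beta0 Baseline shift of mean log post power (natural-log units).
#' @param beta_conn Planted effect per unit logit-coherence.
#' @param beta_dist Planted effect per unit linearized distance.
#' @param noise_sd Trialwise log-power noise SD (> 0, natural-log units).
#' @param artifact_channels Integer indices of channels to contaminate.
#' @param artifact_offset_uv Post-stimulation DC offset, microvolts.
#' @param artifact_var_factor Post-stimulation variance scaling (>= 1).
#' @param envelope_coupling Optional symmetric unit-diagonal matrix in
#'   `[0, 1]` of slow HFB amplitude co-modulation.
#' @param seed Integer seed recorded with the truth.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(mixing_weights, source_freqs, beta0 = 0,
                         beta_conn = 0, beta_dist = 0, noise_sd = 0.2,
                         artifact_channels = integer(0),
                         artifact_offset_uv = 0, artifact_var_factor = 1,
                         envelope_coupling = NULL, seed = 1L) {
  mixing_weights <- as.matrix(mixing_weights)
  stopifnot(nrow(mixing_weights) == length(source_freqs),
            all(is.finite(mixing_weights)), all(source_freqs > 0),
            noise_sd > 0, artifact_var_factor >= 1)
  if (!is.null(envelope_coupling)) {
    envelope_coupling <- as.matrix(envelope_coupling)
    if (!isSymmetric(envelope_coupling) ||
        any(abs(diag(envelope_coupling) - 1) > 1e-12) ||
        any(envelope_coupling < 0 | envelope_coupling > 1))
      stop("envelope_coupling must be symmetric with unit diagonal, in [0,1]")
  }
  structure(list(mixing_weights = mixing_weights,
                 source_freqs = as.numeric(source_freqs),
                 beta0 = beta0, beta_conn = beta_conn, beta_dist = beta_dist,
                 noise_sd = noise_sd,
                 artifact_channels = as.integer(artifact_channels),
                 artifact_offset_uv = artifact_offset_uv,
                 artifact_var_factor = artifact_var_factor,
                 envelope_coupling = envelope_coupling,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Generate a virtual electrode layout
#'
#' Samples electrode midpoints uniformly in a 60 x 60 x 40 mm box with
#' rejection to enforce the minimum inter-contact spacing of depth
#' electrodes (3.5 mm). Distance to nearest white matter is drawn
#' Uniform(0, 10) mm; configurable subsets are flagged as in-white-matter,
#' seizure-onset-zone or spiking.
#'
#' @param n_electrodes Number of virtual electrodes (>= 1).
#' @param seed RNG seed; layouts are deterministic given `(n, seed)`.
#' @param n_soz,n_spiking,n_wm Sizes of the flagged subsets.
#' @param box Box dimensions, mm.
#' @param min_spacing Minimum pairwise separation, mm.
#' @param wm_max Upper bound of the white-matter distance draw, mm.
#' @return An [electrode_layout()].
#' @export
generate_layout <- function(n_electrodes, seed = 1L, n_soz = 0, n_spiking = 0,
                            n_wm = 0, box = c(60, 60, 40), min_spacing = 3.5,
                            wm_max = 10) {
  if (n_electrodes < 1) stop("n_electrodes must be >= 1")
  with_seed(seed, {
    pts <- matrix(NA_real_, n_electrodes, 3)
    accepted <- 0
    tries <- 0
    while (accepted < n_electrodes) {
      tries <- tries + 1
      if (tries > 100000 * n_electrodes)
        stop("could not place electrodes at the requested spacing")
      p <- stats::runif(3) * box
      if (accepted == 0 ||
          min(sqrt(colSums((t(pts[seq_len(accepted), , drop = FALSE]) - p)^2))) >=
            min_spacing) {
        accepted <- accepted + 1
        pts[accepted, ] <- p
      }
    }
    labels <- sprintf("VE%03d", seq_len(n_electrodes))
    soz <- spk <- wm <- rep(FALSE, n_electrodes)
    if (n_soz > 0) soz[sample.int(n_electrodes, n_soz)] <- TRUE
    if (n_spiking > 0) spk[sample.int(n_electrodes, n_spiking)] <- TRUE
    if (n_wm > 0) wm[sample.int(n_electrodes, n_wm)] <- TRUE
    electrode_layout(labels, pts, soz_flag = soz, spiking_flag = spk,
                     wm_distance = stats::runif(n_electrodes, 0, wm_max),
                     in_wm_label = wm,
                     contact_members = cbind(paste0("C", seq_len(n_electrodes), "a"),
                                             paste0("C", seq_len(n_electrodes), "b")))
  })
}

#' Generate a baseline recording with planted coherence structure
#'
#' Each channel is a weighted sum of narrowband latent sources (sinusoids
#' whose phase is re-randomized independently per source and per baseline
#' period) plus independent white noise. Channel pairs loading on a common
#' source exhibit elevated coherence at that source's frequency; with unit
#' source amplitude and noise SD `noise_sd`, the amplitude SNR is
#' `weight / noise_sd`.
#'
#' @param layout An [electrode_layout()]; channel count follows it.
#' @param truth A [ground_truth()] providing mixing weights and frequencies.
#' @param n_periods Number of baseline periods (>= 1), each `period_s` long.
#' @param period_s Period length, seconds (10 in the paradigm).
#' @param fs Sampling rate, Hz.
#' @param seed RNG seed.
#' @param noise_sd White-noise SD in microvolts.
#' @return A bipolar [recording()] of `n_periods * period_s` seconds.
#' @export
generate_baseline <- function(layout, truth, n_periods = 10, period_s = 10,
                              fs = 1000, seed = 1L, noise_sd = 1) {
  stopifnot(n_periods >= 1, period_s > 0)
  if (any(truth$source_freqs >= fs / 2))
    stop("source frequency at or above Nyquist")
  n_ch <- length(layout$labels)
  if (ncol(truth$mixing_weights) != n_ch)
    stop("mixing_weights channel count does not match layout")
  n_src <- nrow(truth$mixing_weights)
  n_per <- round(period_s * fs)
  tgrid <- (seq_len(n_per) - 1) / fs
  with_seed(seed, {
    samples <- matrix(0, n_ch, n_per * n_periods)
    for (p in seq_len(n_periods)) {
      src <- matrix(0, n_src, n_per)
      for (s in seq_len(n_src)) {
        phase <- stats::runif(1, 0, 2 * pi)
        src[s, ] <- sin(2 * pi * truth$source_freqs[s] * tgrid + phase)
      }
      block <- t(truth$mixing_weights) %*% src +
        matrix(stats::rnorm(n_ch * n_per, sd = noise_sd), n_ch, n_per)
      samples[, ((p - 1) * n_per + 1):(p * n_per)] <- block
    }
    recording(samples, fs, layout$labels, "bipolar")
  })
}

# Theta carrier used by segment synthesis: a 6.5 Hz sinusoid whose
# multitaper theta-band power P0 is computed once, so scaling a segment by
# sqrt(target / P0) makes the measured power hit the drawn value exactly
# (band power is quadratically homogeneous).
theta_carrier <- function(fs, spec, band) {
  n <- round(0.9 * fs)
  carrier <- sin(2 * pi * 6.5 * (seq_len(n) - 1) / fs)
  p0 <- trial_band_power(carrier, band, spec, fs)
  list(carrier = carrier, p0 = p0)
}

#' Generate a stimulation session with a planted connectivity effect
#'
#' For each non-stimulated electrode `e`, trial log theta power is drawn
#' `pre ~ N(mu, noise_sd^2)` and `post ~ N(mu + delta_e, noise_sd^2)` with
#' `delta_e = beta0 + beta_conn * logit(coherence[stim, e]) + beta_dist *
#' distance_lin[stim, e]` — the linear model the NMA regression is built to
#' recover. With `synthesize = TRUE`, 900 ms segments are synthesized by
#' scaling a fixed theta-band carrier so that multitaper theta power of the
#' segment reproduces the drawn value exactly; with `synthesize = FALSE`
#' the session carries the drawn log powers only (`log_pre` / `log_post`),
#' which is what large Monte-Carlo calibrations consume.
#'
#' @param layout An [electrode_layout()].
#' @param coherence,distance [adjacency()] matrices (or plain symmetric
#'   matrices) over the layout's electrodes.
#' @param truth A [ground_truth()] with `beta0`, `beta_conn`, `beta_dist`,
#'   `noise_sd`.
#' @param stim_pair Either the label of the stimulated virtual electrode or
#'   the two physical contact names of the stimulated pair.
#' @param n_trials Number of stimulation trials (>= 2; 240 in the paradigm).
#' @param fs Sampling rate, Hz.
#' @param seed RNG seed.
#' @param synthesize Synthesize waveform segments (see above).
#' @param mu_log Baseline mean log theta power (natural log of uV^2/Hz).
#' @param voltage_noise_sd SD of the artifact-window voltage noise, uV.
#' @param artifact_windows Generate the 350 ms artifact-check windows.
#' @return A [stim_session()].
#' @export
generate_stim_session <- function(layout, coherence, distance, truth,
                                  stim_pair, n_trials = 240, fs = 1000,
                                  seed = 1L, synthesize = TRUE,
                                  mu_log = log(100), voltage_noise_sd = 20,
                                  artifact_windows = synthesize) {
  if (n_trials < 2) stop("n_trials must be >= 2")
  n_ch <- length(layout$labels)
  stim_idx <- resolve_stim(layout, stim_pair)
  coh <- adjacency_values(coherence)
  dst <- adjacency_values(distance)
  stopifnot(nrow(coh) == n_ch, nrow(dst) == n_ch)

  delta <- rep(0, n_ch)
  others <- setdiff(seq_len(n_ch), stim_idx)
  delta[others] <- truth$beta0 +
    truth$beta_conn * suppressWarnings(logit(coh[stim_idx, others])) +
    truth$beta_dist * dst[stim_idx, others]

  with_seed(seed, {
    onsets <- 5 + (seq_len(n_trials) - 1) * 3.5 +
      stats::runif(n_trials, 0, 0.25)
    log_pre <- matrix(stats::rnorm(n_trials * n_ch, mu_log, truth$noise_sd),
                      n_trials, n_ch)
    log_post <- matrix(stats::rnorm(n_trials * n_ch, mu_log, truth$noise_sd),
                       n_trials, n_ch) + matrix(delta, n_trials, n_ch,
                                                byrow = TRUE)
    pre_power <- post_power <- pre_art <- post_art <- NULL
    if (synthesize) {
      spec <- multitaper_spec(window_s = 0.9)
      tc <- theta_carrier(fs, spec, band_spec("theta"))
      n_samp <- length(tc$carrier)
      pre_power <- array(0, dim = c(n_trials, n_ch, n_samp))
      post_power <- array(0, dim = c(n_trials, n_ch, n_samp))
      for (ch in seq_len(n_ch)) {
        pre_power[, ch, ] <- sqrt(exp(log_pre[, ch]) / tc$p0) %o% tc$carrier
        post_power[, ch, ] <- sqrt(exp(log_post[, ch]) / tc$p0) %o% tc$carrier
      }
    }
    if (artifact_windows) {
      n_art <- round(0.35 * fs)
      pre_art <- array(stats::rnorm(n_trials * n_ch * n_art,
                                    sd = voltage_noise_sd),
                       dim = c(n_trials, n_ch, n_art))
      post_art <- array(stats::rnorm(n_trials * n_ch * n_art,
                                     sd = voltage_noise_sd),
                        dim = c(n_trials, n_ch, n_art))
    }
    sess <- stim_session(layout$contact_members[stim_idx, ], layout$labels,
                         fs, onsets, 0.5,
                         pre_power = pre_power, post_power = post_power,
                         pre_art = pre_art, post_art = post_art,
                         amplitudes = rep(0.5, n_trials),
                         pulse_freqs = rep(50, n_trials),
                         log_pre = log_pre, log_post = log_post)
    if (length(truth$artifact_channels) > 0 && artifact_windows) {
      sess <- inject_artifact(sess, truth$artifact_channels,
                              truth$artifact_offset_uv,
                              truth$artifact_var_factor)
    }
    sess
  })
}

# Map a stim_pair argument (virtual label or two contact names) to the
# index of the stimulated virtual electrode.
resolve_stim <- function(layout, stim_pair) {
  if (length(stim_pair) == 1) {
    idx <- match(stim_pair, layout$labels)
    if (is.na(idx)) stop("unknown stimulation electrode: ", stim_pair)
    return(idx)
  }
  if (length(stim_pair) == 2) {
    hit <- which(apply(layout$contact_members, 1, function(m)
      setequal(m, stim_pair)))
    if (length(hit) != 1) stop("stim pair not found in layout: ",
                               paste(stim_pair, collapse = ", "))
    return(hit)
  }
  stop("stim_pair must be one virtual label or two contact names")
}

#' Inject a post-stimulation voltage artifact
#'
#' Adds a DC offset and/or variance scaling to the post-stimulation 350 ms
#' artifact-check windows on the listed channels; other channels and all
#' other windows are untouched. With `offset_uv = 0` and `var_factor = 1`
#' the session is returned bit-identical.
#'
#' @param session A [stim_session()] with artifact windows.
#' @param channels Integer indices or labels of channels to contaminate.
#' @param offset_uv DC offset, microvolts.
#' @param var_factor Variance scaling factor (>= 1 typical).
#' @return The modified [stim_session()].
#' @export
inject_artifact <- function(session, channels, offset_uv, var_factor = 1) {
  if (is.null(session$post_art)) stop("session carries no artifact windows")
  if (is.character(channels)) channels <- match(channels, session$labels)
  channels <- as.integer(channels)
  if (any(is.na(channels)) || any(channels < 1) ||
      any(channels > length(session$labels)))
    stop("unknown channel index in artifact injection")
  if (offset_uv == 0 && var_factor == 1) return(session)
  for (ch in channels) {
    session$post_art[, ch, ] <- offset_uv +
      sqrt(var_factor) * session$post_art[, ch, ]
  }
  session
}

#' Simulate a full synthetic study
#'
#' Convenience wrapper tying the generator together: layout, baseline with
#' planted coherence, the coherence/distance networks estimated from that
#' baseline, and one or more stimulation sessions with the planted
#' connectivity effect.
#'
#' @param n_electrodes Number of virtual electrodes.
#' @param truth A [ground_truth()]; its `mixing_weights` must match
#'   `n_electrodes` columns.
#' @param stim_sites Virtual electrode labels to stimulate (one session
#'   each).
#' @param n_trials Trials per session.
#' @param n_periods Baseline periods (10 s each).
#' @param fs Sampling rate, Hz.
#' @param seed Master seed; child seeds are derived per stage.
#' @param synthesize Passed to [generate_stim_session()].
#' @return List of class `synthetic_study`: `layout`, `baseline`,
#'   `coherence`, `distance`, `sessions`, `truth`.
#' @export
simulate_study <- function(n_electrodes, truth, stim_sites, n_trials = 240,
                           n_periods = 10, fs = 1000, seed = 1L,
                           synthesize = FALSE) {
  layout <- generate_layout(n_electrodes, seed = child_seed(seed, 1))
  baseline <- generate_baseline(layout, truth, n_periods = n_periods,
                                fs = fs, seed = child_seed(seed, 2))
  windows <- baseline_windows(baseline, window_s = 1)
  coh <- coherence_network(windows, multitaper_spec(), band = c(5, 13),
                           fs = fs, labels = layout$labels)
  dst <- distance_network(layout)
  sessions <- lapply(seq_along(stim_sites), function(i) {
    generate_stim_session(layout, coh, dst, truth, stim_sites[i],
                          n_trials = n_trials, fs = fs,
                          seed = child_seed(seed, 10 + i),
                          synthesize = synthesize)
  })
  structure(list(layout = layout, baseline = baseline, coherence = coh,
                 distance = dst, sessions = sessions, truth = truth,
                 seed = as.integer(seed)),
            class = "synthetic_study")
}
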