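#' Frequency band definitions
#'
#' The four analysis bands: theta 5-8 Hz, alpha/beta 10-25 Hz, gamma
#' 30-50 Hz, high-frequency broadband (HFB) 50-200 Hz.
#'
#' @param name One of `"theta"`, `"alpha_beta"`, `"gamma"`, `"hfb"`, or
#'   `"custom"` (then give `fmin`/`fmax`).
#' @param fmin,fmax Band edges in Hz for a custom band.
#' @return Object of class `band_spec` with `name`, `fmin`, `fmax`.
#' @export
band_spec <- function(name = c("theta", "alpha_beta", "gamma", "hfb",
                               "custom"),
                      fmin = NULL, fmax = NULL) {
  name <- match.arg(name)
  edges <- switch(name,
                  theta = c(5, 8), alpha_beta = c(10, 25),
                  gamma = c(30, 50), hfb = c(50, 200),
                  custom = c(fmin, fmax))
  if (is.null(edges[1]) || is.null(edges[2]))
    stop("custom band needs fmin and fmax")
  if (!(edges[1] > 0 && edges[1] < edges[2]))
    stop("band edges must satisfy 0 < fmin < fmax")
  structure(list(name = name, fmin = edges[1], fmax = edges[2]),
            class = "band_spec")
}

#' Per-trial band powers for every channel of a session
#'
#' Multitaper band power of the 900 ms pre and post windows of each trial.
#' Sessions generated at the power level (no waveforms) return the
#' exponentiated drawn log powers directly — by construction identical to
#' what measurement of the synthesized segments yields, for the theta band.
#'
#' @param session A [stim_session()].
#' @param band A [band_spec()].
#' @param spec A [multitaper_spec()] (window_s is taken from the data).
#' @return List with `pre` and `post`, `n_trials x n_channels` matrices of
#'   band power (uV^2/Hz).
#' @export
session_band_powers <- function(session, band = band_spec("theta"),
                                spec = multitaper_spec(window_s = 0.9)) {
  if (is.null(session$pre_power)) {
    if (is.null(session$log_pre))
      stop("session has neither waveform windows nor drawn log powers")
    return(list(pre = exp(session$log_pre), post = exp(session$log_post)))
  }
  measure <- function(arr) {
    n_trials <- dim(arr)[1]; n_ch <- dim(arr)[2]; n_samp <- dim(arr)[3]
    # One cross-spectra call per trial over all channels keeps the FFTs
    # batched (mvfft) instead of per-segment.
    out <- matrix(0, n_trials, n_ch)
    for (t in seq_len(n_trials)) {
      seg <- matrix(arr[t, , ], nrow = n_ch)
      mt <- multitaper_cross_spectra(list(seg), spec, band$fmin, band$fmax,
                                     session$fs)
      out[t, ] <- vapply(seq_len(n_ch), function(ch)
        mean(Re(mt$csd[ch, ch, ])), numeric(1))
    }
    out
  }
  list(pre = measure(session$pre_power), post = measure(session$post_power))
}

#' Paired t-statistics of pre- vs post-stimulation log band power
#'
#' Per electrode, `d = ln(post) - ln(pre)` across trials and
#' `t = mean(d) / (sd(d) / sqrt(n))`. No per-electrode p-values are
#' produced: sequential trials are non-independent, so the t-statistics are
#' used only as inputs to later correlation analyses.
#'
#' @param pre_powers,post_powers `n_trials x n_electrodes` matrices of band
#'   power (linear scale, uV^2/Hz).
#' @param band A [band_spec()] recorded as metadata.
#' @param mask Optional [channel_mask()].
#' @return Object of class `power_contrast` with `t_stat` (per electrode;
#'   `NA` where the trial differences have zero variance, with
#'   `zero_variance` flagged), `n_trials`, `band`, `mask`.
#' @export
power_contrast <- function(pre_powers, post_powers,
                           band = band_spec("theta"), mask = NULL) {
  pre_powers <- as.matrix(pre_powers); post_powers <- as.matrix(post_powers)
  if (!all(dim(pre_powers) == dim(post_powers)))
    stop("pre and post power matrices must have identical shape")
  n <- nrow(pre_powers)
  if (n < 2) stop("paired t-statistic needs at least 2 trials")
  if (any(pre_powers <= 0) || any(post_powers <= 0))
    stop("band powers must be positive for the log transform")
  d <- log(post_powers) - log(pre_powers)
  m <- colMeans(d)
  s <- apply(d, 2, stats::sd)
  zero_var <- s == 0
  t_stat <- ifelse(zero_var, NA_real_, m / (s / sqrt(n)))
  structure(list(t_stat = t_stat, n_trials = n, band = band,
                 mask = mask, zero_variance = zero_var),
            class = "power_contrast")
}

#' @export
print.power_contrast <- function(x, ...) {
  cat(sprintf("<power_contrast> %s band, %d electrodes, %d trials\n",
              x$band$name, length(x$t_stat), x$n_trials))
  invisible(x)
}

# Electrodes usable from a contrast: included by mask, finite t.
included_t <- function(contrast) {
  inc <- if (is.null(contrast$mask)) rep(TRUE, length(contrast$t_stat))
         else contrast$mask$included
  inc & is.finite(contrast$t_stat)
}

#' Whole-brain average power change
#'
#' Mean t-statistic over included electrodes, additionally dropping
#' electrodes with t > 10 whose raw power is potentially corrupted by
#' residual stimulation artifact.
#'
#' @param contrast A [power_contrast()].
#' @param t_cap Exclusion threshold (10).
#' @return Mean t over surviving electrodes.
#' @export
whole_brain_power_change <- function(contrast, t_cap = 10) {
  keep <- included_t(contrast) & contrast$t_stat <= t_cap
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stop("no electrodes remain after the t > ", t_cap,
                       " exclusion")
  mean(contrast$t_stat[keep])
}

#' Power change at theta-responsive electrodes
#'
#' Electrodes with theta t strictly greater than `threshold` are selected;
#' for each higher band, the mean t over that subset is returned. A site
#' with no theta-responsive electrode is flagged as non-contributing rather
#' than erroring.
#'
#' @param contrasts Named list of [power_contrast()] objects; must contain
#'   `"theta"`.
#' @param threshold Responsiveness cut (strict inequality; 2).
#' @return List with `responsive` (logical per electrode), `n_responsive`,
#'   `mean_t` (named vector over the non-theta bands, `NA` if empty), and
#'   `contributing` (FALSE when no electrode passes).
#' @export
theta_responsive_subset <- function(contrasts, threshold = 2) {
  if (!"theta" %in% names(contrasts)) stop("theta contrast is required")
  theta <- contrasts[["theta"]]
  responsive <- included_t(theta) & theta$t_stat > threshold
  responsive[is.na(responsive)] <- FALSE
  others <- setdiff(names(contrasts), "theta")
  mean_t <- vapply(others, function(b) {
    if (!any(responsive)) return(NA_real_)
    mean(contrasts[[b]]$t_stat[responsive])
  }, numeric(1))
  list(responsive = responsive, n_responsive = sum(responsive),
       mean_t = mean_t, contributing = any(responsive))
}

#' Write a power contrast table as TSV
#'
#' Columns: electrode, band, t, n_trials, included, reason.
#' @param contrast A [power_contrast()].
#' @param labels Electrode labels.
#' @param path Output path.
#' @export
write_contrast <- function(contrast, labels, path) {
  inc <- if (is.null(contrast$mask)) rep(TRUE, length(contrast$t_stat))
         else contrast$mask$included
  reason <- if (is.null(contrast$mask)) rep("", length(inc))
            else vapply(contrast$mask$reasons, paste, character(1),
                        collapse = ";")
  df <- data.frame(electrode = labels, band = contrast$band$name,
                   t = contrast$t_stat, n_trials = contrast$n_trials,
                   included = inc, reason = reason)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
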