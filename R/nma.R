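#' Distance-controlled OLS of power change on connectivity
#'
#' Ordinary least squares with intercept of per-electrode power
#' t-statistics on logit connectivity and linearized distance to the
#' stimulation site. This controls for distance from the stimulation
#' target, which is correlated with both power change and connectivity.
#'
#' @param t_stats Response: per-electrode t-statistics.
#' @param conn_logit Predictor: logit-transformed connectivity.
#' @param dist_lin Predictor: linearized distance `exp(-d/dmax)`.
#' @param min_electrodes Minimum rows (10, the subject-discard rule).
#' @return Named vector `c(intercept, beta_dist, beta_conn)`.
#' @export
fit_regression <- function(t_stats, conn_logit, dist_lin,
                           min_electrodes = 10) {
  n <- length(t_stats)
  stopifnot(length(conn_logit) == n, length(dist_lin) == n)
  if (n < min_electrodes)
    stop("fewer than ", min_electrodes, " electrodes for the regression")
  x <- cbind(intercept = 1, beta_dist = dist_lin, beta_conn = conn_logit)
  fit <- stats::lm.fit(x, t_stats)
  if (fit$rank < 3)
    stop("rank-deficient design: predictors are collinear")
  co <- fit$coefficients
  if (any(!is.finite(co))) stop("non-finite regression coefficients")
  co
}

#' Permutation null distribution of the connectivity coefficient
#'
#' The predictor rows are uniformly permuted against the responses and the
#' regression re-run, recording the connectivity coefficient each time. In
#' the default `"joint"` mode the connectivity and distance columns are
#' shuffled together as rows (their pairing preserved); `"connectivity"`
#' shuffles the connectivity column alone. Joint shuffling leaves the
#' predictor cross-product matrix unchanged, so the null coefficients
#' reduce to one projection matrix applied to permuted responses — the
#' numbers are identical to a literal re-fit.
#'
#' @inheritParams fit_regression
#' @param n_perm Number of permutations (1000; below 100 the z-score is
#'   unstable and a warning is issued).
#' @param seed RNG seed; the null vector is deterministic given it.
#' @param mode `"joint"` (default) or `"connectivity"`.
#' @return Numeric vector of `n_perm` null connectivity coefficients.
#' @export
permutation_null <- function(t_stats, conn_logit, dist_lin, n_perm = 1000,
                             seed = 1L, mode = c("joint", "connectivity"),
                             min_electrodes = 10) {
  mode <- match.arg(mode)
  n <- length(t_stats)
  stopifnot(length(conn_logit) == n, length(dist_lin) == n)
  if (n < min_electrodes)
    stop("fewer than ", min_electrodes, " electrodes for the regression")
  if (n_perm < 100) warning("n_perm < 100: permutation z-score is unstable")
  x <- cbind(1, dist_lin, conn_logit)
  with_seed(seed, {
    if (mode == "joint") {
      xtx <- crossprod(x)
      proj <- solve(xtx, t(x))          # 3 x n
      # X_perm = P X  =>  beta = (X'X)^{-1} X' P' y = proj %*% y[inv(perm)]
      yperm <- vapply(seq_len(n_perm), function(i) {
        p <- sample.int(n)
        inv <- integer(n); inv[p] <- seq_len(n)
        t_stats[inv]
      }, numeric(n))
      as.numeric(proj[3, , drop = FALSE] %*% yperm)
    } else {
      vapply(seq_len(n_perm), function(i) {
        p <- sample.int(n)
        xp <- cbind(1, dist_lin, conn_logit[p])
        stats::lm.fit(xp, t_stats)$coefficients[3]
      }, numeric(1))
    }
  })
}

#' Network-mediated activation (NMA) of a stimulation site
#'
#' The package's central statistic. Over the included electrodes, the
#' stimulation-evoked power t-statistics are regressed on the site's logit
#' connectivity and linearized distance to every other electrode; the true
#' connectivity coefficient is compared with a predictor-permutation null
#' distribution to yield a z-score (the NMA) and a two-tailed empirical
#' p-value.
#'
#' @param contrast A [power_contrast()] (its mask, if any, is honored) or a
#'   bare numeric vector of t-statistics.
#' @param connectivity An [adjacency()]; coherence values are logit
#'   transformed, Fisher-z envelope correlations enter untransformed.
#' @param distance An [adjacency()] of linearized distances.
#' @param stim_site Label or index of the stimulated virtual electrode.
#' @param n_perm Number of permutations (1000).
#' @param seed RNG seed for the permutation null.
#' @param mask Optional [channel_mask()] overriding the contrast's mask.
#' @param perm_mode Passed to [permutation_null()].
#' @param min_electrodes Minimum included electrodes (10).
#' @return Object of class `nma` with elements `beta_conn`, `beta_dist`,
#'   `intercept`, `null_betas`, `z`, `p_two_tailed`, `n_electrodes`,
#'   `n_perm`, `seed`, `band`, `network_method`, `stim_site`.
#' @export
compute_nma <- function(contrast, connectivity, distance, stim_site,
                        n_perm = 1000, seed = 1L, mask = NULL,
                        perm_mode = c("joint", "connectivity"),
                        min_electrodes = 10) {
  perm_mode <- match.arg(perm_mode)
  conn <- if (inherits(connectivity, "adjacency")) connectivity else
    adjacency(connectivity, "coherence")
  dst_v <- adjacency_values(distance)
  t_all <- if (inherits(contrast, "power_contrast")) contrast$t_stat
           else as.numeric(contrast)
  n_ch <- length(t_all)
  labels <- conn$labels
  if (is.character(stim_site)) {
    stim_idx <- match(stim_site, labels)
    if (is.na(stim_idx)) stop("stimulation site not found in connectivity")
  } else stim_idx <- as.integer(stim_site)
  stopifnot(nrow(conn$values) == n_ch, nrow(dst_v) == n_ch,
            stim_idx >= 1, stim_idx <= n_ch)

  inc <- if (!is.null(mask)) mask$included
         else if (inherits(contrast, "power_contrast") &&
                  !is.null(contrast$mask)) contrast$mask$included
         else rep(TRUE, n_ch)
  inc[stim_idx] <- FALSE
  inc <- inc & is.finite(t_all)
  if (sum(inc) < min_electrodes)
    stop("fewer than ", min_electrodes,
         " included electrodes; site discarded")

  # canonical electrode order (by label) so results do not depend on the
  # storage order of electrodes, including the realized permutation stream
  idx <- which(inc)[order(labels[inc])]
  inc <- seq_len(n_ch) %in% idx
  conn_row <- conn$values[stim_idx, idx]
  if (stats::sd(conn_row) == 0)
    stop("degenerate connectivity: constant across electrodes")
  conn_pred <- if (conn$method == "coherence")
    suppressWarnings(logit(conn_row)) else conn_row
  dist_pred <- dst_v[stim_idx, idx]
  t_inc <- t_all[idx]

  co <- fit_regression(t_inc, conn_pred, dist_pred, min_electrodes)
  null_betas <- permutation_null(t_inc, conn_pred, dist_pred,
                                 n_perm = n_perm, seed = seed,
                                 mode = perm_mode,
                                 min_electrodes = min_electrodes)
  mu <- mean(null_betas)
  sdn <- stats::sd(null_betas)
  z <- (co[["beta_conn"]] - mu) / sdn
  p <- (1 + sum(abs(null_betas - mu) >= abs(co[["beta_conn"]] - mu))) /
    (n_perm + 1)

  band <- if (inherits(contrast, "power_contrast")) contrast$band else NULL
  structure(list(beta_conn = co[["beta_conn"]],
                 beta_dist = co[["beta_dist"]],
                 intercept = co[["intercept"]],
                 null_betas = null_betas, z = z, p_two_tailed = p,
                 n_electrodes = sum(inc), n_perm = n_perm,
                 seed = as.integer(seed), band = band,
                 network_method = conn$method,
                 stim_site = if (is.character(stim_site)) stim_site
                             else labels[stim_idx]),
            class = "nma")
}

#' @export
print.nma <- function(x, ...) {
  cat(sprintf("Network-mediated activation, site %s (%s network%s)\n",
              x$stim_site, x$network_method,
              if (!is.null(x$band)) paste0(", ", x$band$name, " power")
              else ""))
  cat(sprintf("  NMA z = %.3f, two-tailed p = %.4g (%d permutations, %d electrodes)\n",
              x$z, x$p_two_tailed, x$n_perm, x$n_electrodes))
  invisible(x)
}

#' @export
summary.nma <- function(object, ...) {
  out <- list(stim_site = object$stim_site,
              network_method = object$network_method,
              band = if (!is.null(object$band)) object$band$name else NA,
              coefficients = c(intercept = object$intercept,
                               beta_dist = object$beta_dist,
                               beta_conn = object$beta_conn),
              null_mean = mean(object$null_betas),
              null_sd = stats::sd(object$null_betas),
              z = object$z, p_two_tailed = object$p_two_tailed,
              n_electrodes = object$n_electrodes, n_perm = object$n_perm)
  class(out) <- "summary.nma"
  out
}

#' @export
print.summary.nma <- function(x, ...) {
  cat("Network-mediated activation\n")
  cat("  site:", x$stim_site, " network:", x$network_method, "\n")
  cat("  coefficients:\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  null: mean %.4f, sd %.4f over %d permutations\n",
              x$null_mean, x$null_sd, x$n_perm))
  cat(sprintf("  z = %.3f, p = %.4g, n = %d electrodes\n",
              x$z, x$p_two_tailed, x$n_electrodes))
  invisible(x)
}

#' @export
coef.nma <- function(object, ...) {
  c(intercept = object$intercept, beta_dist = object$beta_dist,
    beta_conn = object$beta_conn)
}

#' @export
plot.nma <- function(x, ...) {
  graphics::hist(x$null_betas, breaks = 40, col = "grey85", border = "white",
                 main = paste0("Permutation null, site ", x$stim_site),
                 xlab = "null connectivity coefficient", ...)
  graphics::abline(v = x$beta_conn, col = "firebrick", lwd = 2)
  graphics::mtext(sprintf("observed beta (z = %.2f, p = %.3g)", x$z,
                          x$p_two_tailed), side = 3, line = 0, cex = 0.8)
  invisible(x)
}

#' Serialize an NMA result to JSON
#'
#' Scalars plus a five-number summary of the null distribution; the full
#' null vector stays in R.
#' @param x An `nma` object.
#' @param path Output path.
#' @export
write_nma <- function(x, path) {
  jsonlite::write_json(list(
    stim_site = x$stim_site, network_method = x$network_method,
    band = if (!is.null(x$band)) x$band$name else NULL,
    beta_conn = x$beta_conn, beta_dist = x$beta_dist,
    intercept = x$intercept, z = x$z, p_two_tailed = x$p_two_tailed,
    n_electrodes = x$n_electrodes, n_perm = x$n_perm, seed = x$seed,
    null_summary = as.list(stats::setNames(
      as.numeric(stats::quantile(x$null_betas, c(0, .25, .5, .75, 1))),
      c("min", "q25", "median", "q75", "max")))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
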