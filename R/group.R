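#' Group-level test result container
#'
#' @param test_name Short test identifier.
#' @param statistic Test statistic.
#' @param p P-value in (0, 1].
#' @param p_corrected Optional corrected p (>= p).
#' @param n Number of units entering the test.
#' @return Object of class `group_result`.
#' @export
group_result <- function(test_name, statistic, p, p_corrected = NULL, n) {
  stopifnot(p > 0, p <= 1)
  if (!is.null(p_corrected) && p_corrected < p)
    stop("corrected p cannot be smaller than raw p")
  structure(list(test_name = test_name, statistic = statistic, p = p,
                 p_corrected = p_corrected, n = n),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("<group_result> %s: statistic %.4g, p %.4g%s (n = %d)\n",
              x$test_name, x$statistic, x$p,
              if (!is.null(x$p_corrected))
                sprintf(", corrected p %.4g", x$p_corrected) else "",
              x$n))
  invisible(x)
}

#' Categorize stimulation sites by white-matter proximity
#'
#' Expert in-white-matter labels take precedence (`"in"`). The remaining
#' sites are split at the median distance-to-white-matter: with the default
#' direction, distance at or below the median is `"near"` white matter and
#' above it `"gray"` matter. The figure caption describing the split admits
#' the opposite reading, so the direction is configurable.
#'
#' @param wm_distance Distance to nearest white matter, mm.
#' @param in_wm_label Logical expert labels.
#' @param direction `"near_is_close"` (default) or `"near_is_far"`.
#' @return Factor with levels `gray < near < in`.
#' @export
classify_wm <- function(wm_distance, in_wm_label = NULL,
                        direction = c("near_is_close", "near_is_far")) {
  direction <- match.arg(direction)
  in_wm_label <- in_wm_label %||% rep(FALSE, length(wm_distance))
  stopifnot(length(in_wm_label) == length(wm_distance))
  free <- !in_wm_label
  if (sum(free) < 2)
    stop("all sites are expert-labeled in white matter; nothing to split")
  med <- stats::median(wm_distance[free])
  if (all(wm_distance[free] == med))
    warning("all white-matter distances equal; every site categorized 'near'")
  cat_free <- if (direction == "near_is_close") {
    ifelse(wm_distance[free] <= med, "near", "gray")
  } else {
    ifelse(wm_distance[free] <= med, "gray", "near")
  }
  out <- character(length(wm_distance))
  out[in_wm_label] <- "in"
  out[free] <- cat_free
  factor(out, levels = c("gray", "near", "in"), ordered = TRUE)
}

# Pooled-variance two-sample t statistic, mean(x) - mean(y).
two_sample_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  d <- mean(x) - mean(y)
  if (sp2 == 0) return(if (d == 0) 0 else sign(d) * Inf)
  d / sqrt(sp2 * (1 / nx + 1 / ny))
}

#' Permutation trend test of NMA across white-matter categories
#'
#' The observed statistic is the minimum of the two ordered contrasts
#' (two-sample t of near vs gray, and of in vs near). White-matter labels
#' are permuted `n_perm` times and the statistic recomputed; the p-value is
#' the (add-one smoothed) fraction of permutations whose minimum t meets or
#' exceeds the observed one.
#'
#' @param nma_values Per-site NMA z-scores.
#' @param categories Factor from [classify_wm()] (all three categories must
#'   be non-empty).
#' @param n_perm Number of label permutations (1000).
#' @param seed RNG seed.
#' @return A [group_result()] with the observed minimum t.
#' @export
wm_trend_permutation_test <- function(nma_values, categories, n_perm = 1000,
                                      seed = 1L) {
  stopifnot(length(nma_values) == length(categories))
  counts <- table(factor(categories, levels = c("gray", "near", "in")))
  if (any(counts == 0))
    stop("empty white-matter category: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  min_t <- function(vals, cats) {
    min(two_sample_t(vals[cats == "near"], vals[cats == "gray"]),
        two_sample_t(vals[cats == "in"], vals[cats == "near"]))
  }
  obs <- min_t(nma_values, categories)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    min_t(nma_values, categories[sample.int(length(categories))])
  }, numeric(1)))
  p <- (1 + sum(null >= obs)) / (n_perm + 1)
  group_result("wm_trend_permutation", obs, p, n = length(nma_values))
}

#' Mean power change at the strongest- and weakest-connected electrodes
#'
#' Ranks the included electrodes by their connectivity to the stimulation
#' site residualized on linearized distance (OLS with intercept), and
#' returns the mean power t-statistic over the `k` strongest- and `k`
#' weakest-connected electrodes.
#'
#' @inheritParams compute_nma
#' @param k Number of electrodes per extreme (5).
#' @return List with `strong_mean_t`, `weak_mean_t`, `order` (electrode
#'   indices by decreasing residual connectivity).
#' @export
ranked_connection_contrast <- function(contrast, connectivity, distance,
                                       stim_site, k = 5, mask = NULL) {
  rows <- site_rows(contrast, connectivity, distance, stim_site, mask)
  n <- length(rows$t)
  if (n < 2 * k)
    stop("need at least ", 2 * k, " included electrodes, have ", n)
  resid <- stats::lm.fit(cbind(1, rows$dist), rows$conn)$residuals
  ord <- order(resid, decreasing = TRUE)
  list(strong_mean_t = mean(rows$t[ord[seq_len(k)]]),
       weak_mean_t = mean(rows$t[ord[(n - k + 1):n]]),
       order = rows$which[ord])
}

# Assemble (t, conn predictor, dist predictor) rows over included
# electrodes for one stimulation site; mirrors compute_nma's assembly.
site_rows <- function(contrast, connectivity, distance, stim_site,
                      mask = NULL) {
  conn <- if (inherits(connectivity, "adjacency")) connectivity else
    adjacency(connectivity, "coherence")
  dst_v <- adjacency_values(distance)
  t_all <- if (inherits(contrast, "power_contrast")) contrast$t_stat
           else as.numeric(contrast)
  stim_idx <- if (is.character(stim_site)) match(stim_site, conn$labels)
              else as.integer(stim_site)
  if (is.na(stim_idx)) stop("stimulation site not found")
  inc <- if (!is.null(mask)) mask$included
         else if (inherits(contrast, "power_contrast") &&
                  !is.null(contrast$mask)) contrast$mask$included
         else rep(TRUE, length(t_all))
  inc[stim_idx] <- FALSE
  inc <- inc & is.finite(t_all)
  conn_row <- conn$values[stim_idx, inc]
  conn_pred <- if (conn$method == "coherence")
    suppressWarnings(logit(conn_row)) else conn_row
  list(t = t_all[inc], conn = conn_pred, dist = dst_v[stim_idx, inc],
       which = which(inc))
}

# Rank-based terciles; remainder rows are assigned to the middle bin, so
# e.g. 40 sites split 13 / 14 / 13.
tercile_bins <- function(scores) {
  n <- length(scores)
  q <- n %/% 3
  r <- n %% 3
  sizes <- c(q, q + r, q)
  bins <- rep(c("weak", "middle", "strong"), times = sizes)
  out <- character(n)
  out[order(scores)] <- bins
  factor(out, levels = c("weak", "middle", "strong"), ordered = TRUE)
}

#' Hub-tercile contrast of connected power change
#'
#' Bins stimulation sites by tercile of hub score (normalized node
#' strength); compares the mean power change at the strongest-connected
#' electrodes between weak-hub (lowest tercile) and strong-hub (highest
#' tercile) sites with a pooled two-sample t-test (weak minus strong).
#'
#' @param hub_scores Per-site hub score in `[0, 1]`.
#' @param strongest5_mean_t Per-site mean t over the five
#'   strongest-connected electrodes (see [ranked_connection_contrast()]).
#' @return A [group_result()]; also carries `bins` as an attribute.
#' @export
hub_tercile_contrast <- function(hub_scores, strongest5_mean_t) {
  stopifnot(length(hub_scores) == length(strongest5_mean_t))
  if (length(hub_scores) < 3) stop("need at least 3 sites for terciles")
  bins <- tercile_bins(hub_scores)
  weak <- strongest5_mean_t[bins == "weak"]
  strong <- strongest5_mean_t[bins == "strong"]
  tt <- stats::t.test(weak, strong, var.equal = TRUE)
  res <- group_result("hub_tercile_contrast", unname(tt$statistic),
                      tt$p.value, n = length(hub_scores))
  attr(res, "bins") <- bins
  res
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjustment of a vector of p-values; a hypothesis is rejected
#' when its adjusted p is at or below `q`.
#'
#' @param pvals P-values in (0, 1].
#' @param q FDR level (0.05).
#' @return List with `adjusted` and logical `rejected`.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (any(pvals <= 0 | pvals > 1 | !is.finite(pvals)))
    stop("p-values must lie in (0, 1]")
  adjusted <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adjusted, rejected = adjusted <= q)
}

#' NMA as a function of connectivity frequency
#'
#' Recomputes each site's NMA against coherence networks at every
#' frequency of a 1 Hz grid (4-50 Hz, 47 networks), then across sites runs
#' a one-sample t-test against zero per frequency with Benjamini-Hochberg
#' correction over the grid. A three-point moving average of the mean curve
#' is returned for display only; all statistics use the raw values.
#'
#' @param site_inputs List, one element per site, each a list with
#'   `t_stats` (included electrodes), `conn_by_freq` (list of coherence
#'   vectors, one per frequency, values in (0,1)), and `dist_lin`.
#' @param freqs Frequency grid, Hz.
#' @param n_perm Permutations per NMA.
#' @param seed Master seed (child seeds per site x frequency).
#' @param q FDR level.
#' @param smoothing Display smoothing window (odd; 3).
#' @return List with `freqs`, `z` (site x frequency matrix), `mean_z`,
#'   `t`, `p`, `p_adjusted`, `significant`, `display_curve`.
#' @export
nma_frequency_profile <- function(site_inputs, freqs = 4:50, n_perm = 1000,
                                  seed = 1L, q = 0.05, smoothing = 3) {
  if (length(site_inputs) < 2) stop("need at least 2 sites")
  nf <- length(freqs)
  bad <- vapply(site_inputs, function(s) length(s$conn_by_freq) != nf,
                logical(1))
  if (any(bad)) stop("mismatched network list length for ", sum(bad),
                     " site(s)")
  z <- matrix(NA_real_, length(site_inputs), nf)
  for (s in seq_along(site_inputs)) {
    si <- site_inputs[[s]]
    for (f in seq_len(nf)) {
      cp <- suppressWarnings(logit(si$conn_by_freq[[f]]))
      co <- fit_regression(si$t_stats, cp, si$dist_lin)
      nb <- permutation_null(si$t_stats, cp, si$dist_lin, n_perm = n_perm,
                             seed = child_seed(seed, s * 1000 + f))
      z[s, f] <- (co[["beta_conn"]] - mean(nb)) / stats::sd(nb)
    }
  }
  tstat <- numeric(nf); p <- numeric(nf)
  for (f in seq_len(nf)) {
    tt <- stats::t.test(z[, f])
    tstat[f] <- unname(tt$statistic); p[f] <- tt$p.value
  }
  fdr <- bh_fdr(p, q)
  mean_z <- colMeans(z)
  list(freqs = freqs, z = z, mean_z = mean_z, t = tstat, p = p,
       p_adjusted = fdr$adjusted, significant = fdr$rejected,
       display_curve = moving_average(mean_z, smoothing))
}

#' Count of directionally significant stimulation sites
#'
#' Splits sites whose NMA is two-tailed significant at `alpha` by the sign
#' of the z-score and tests the total significant count against the
#' expected false-positive rate with an exact (upper-tail) binomial test.
#'
#' @param nma_results List of `nma` objects, or a data frame with columns
#'   `z` and `p_two_tailed`.
#' @param alpha Site-level significance threshold (0.05).
#' @return List with `n_negative`, `n_positive`, and a [group_result()]
#'   carrying the binomial p.
#' @export
directional_count_test <- function(nma_results, alpha = 0.05) {
  if (is.data.frame(nma_results)) {
    z <- nma_results$z; p <- nma_results$p_two_tailed
  } else {
    z <- vapply(nma_results, `[[`, numeric(1), "z")
    p <- vapply(nma_results, `[[`, numeric(1), "p_two_tailed")
  }
  if (length(z) < 1) stop("need at least one site")
  sig <- p < alpha
  n_neg <- sum(sig & z < 0)
  n_pos <- sum(sig & z > 0)
  bt <- stats::binom.test(n_neg + n_pos, length(z), p = alpha,
                          alternative = "greater")
  list(n_negative = n_neg, n_positive = n_pos,
       result = group_result("directional_binomial", n_neg + n_pos,
                             bt$p.value, n = length(z)))
}

#' One-sample t-test of site-level values against zero
#'
#' @param values Numeric vector (n >= 2, non-zero variance).
#' @return A [group_result()] with the t statistic and two-tailed p.
#' @export
group_onesample_test <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  if (stats::sd(values) == 0) stop("zero variance: t undefined")
  tt <- stats::t.test(values)
  group_result("one_sample_t", unname(tt$statistic), tt$p.value,
               n = length(values))
}
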