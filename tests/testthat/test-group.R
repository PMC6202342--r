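test_that("white-matter categorization splits at the median with expert precedence", {
  cats <- classify_wm(c(1, 2, 3, 4))
  expect_equal(as.character(cats), c("near", "near", "gray", "gray"))
  cats2 <- classify_wm(c(1, 2, 3, 4, 9), in_wm_label = c(FALSE, FALSE,
                                                         FALSE, FALSE, TRUE))
  expect_equal(as.character(cats2[5]), "in")
  expect_equal(as.character(cats2[1:4]), c("near", "near", "gray", "gray"))
  expect_warning(cats3 <- classify_wm(rep(2, 4)), "all.*equal")
  expect_true(all(cats3 == "near"))
  # flipped direction
  flip <- classify_wm(c(1, 2, 3, 4), direction = "near_is_far")
  expect_equal(as.character(flip), c("gray", "gray", "near", "near"))
  expect_error(classify_wm(c(1, 2), in_wm_label = c(TRUE, TRUE)),
               "nothing to split")
})

test_that("the trend permutation test detects ordered means and calibrates under the null", {
  cats <- factor(rep(c("gray", "near", "in"), c(10, 10, 5)),
                 levels = c("gray", "near", "in"), ordered = TRUE)
  set.seed(91)
  hits <- vapply(1:100, function(i) {
    vals <- rnorm(25) + rep(c(0, 1.2, 2.4), c(10, 10, 5))
    wm_trend_permutation_test(vals, cats, n_perm = 500,
                              seed = 1000 + i)$p <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # null p-values are approximately uniform
  pnull <- vapply(1:300, function(i) {
    wm_trend_permutation_test(rnorm(25), cats, n_perm = 300,
                              seed = 2000 + i)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pnull, punif))
  expect_lt(unname(ks$statistic), 0.1)
  # degenerate: identical values in every category
  expect_gt(wm_trend_permutation_test(rep(1, 25), cats, n_perm = 200,
                                      seed = 3)$p, 0.95)
  expect_error(wm_trend_permutation_test(rnorm(20),
                                         factor(rep(c("gray", "near"), 10),
                                                levels = c("gray", "near", "in"))),
               "empty")
})

test_that("ranked connection contrasts respond to connectivity, not distance", {
  ctx <- fixture_site_context(30, seed = 92)
  lc <- logit(ctx$coherence$values[1, -1])
  t_stats <- c(NA, 2 * lc)   # stim site dropped internally
  t_stats[1] <- 0
  out <- ranked_connection_contrast(t_stats, ctx$coherence, ctx$distance, 1)
  expect_gt(out$strong_mean_t, out$weak_mean_t)
  # distance-only gradient: residualization centers the contrast on zero
  # across random connectivity draws
  gaps <- vapply(1:40, function(i) {
    coh_i <- fixture_coherence(30, seed = 500 + i)
    set.seed(900 + i)
    tvals <- 3 * ctx$distance$values[1, ] + rnorm(30, 0, 0.1)
    o <- ranked_connection_contrast(tvals, coh_i, ctx$distance, 1)
    o$strong_mean_t - o$weak_mean_t
  }, numeric(1))
  expect_lt(abs(mean(gaps)), 0.2)
  expect_error(ranked_connection_contrast(rnorm(9), fixture_coherence(9),
                                          distance_network(fixture_layout(9)),
                                          1, k = 5),
               "at least 10")
})

test_that("hub terciles split ranks with remainders to the middle bin", {
  bins9 <- stimnet:::tercile_bins(rnorm(9))
  expect_equal(as.vector(table(bins9)), c(3, 3, 3))
  bins40 <- stimnet:::tercile_bins(rnorm(40))
  expect_equal(as.vector(table(bins40)), c(13, 14, 13))
  set.seed(94)
  # no hub effect -> |t| < 2 in most replicates
  calm <- vapply(1:30, function(i) {
    res <- hub_tercile_contrast(runif(24), rnorm(24))
    abs(res$statistic) < 2
  }, logical(1))
  expect_gte(mean(calm), 0.9)
  expect_error(hub_tercile_contrast(runif(2), rnorm(2)), "at least 3")
})

test_that("BH-FDR matches the brute-force step-up and never beats raw thresholding", {
  expect_equal(bh_fdr(rep(1, 5))$adjusted, rep(1, 5))
  expect_false(any(bh_fdr(rep(1, 5))$rejected))
  expect_true(all(bh_fdr(rep(0.001, 10))$rejected))
  set.seed(95)
  for (i in 1:5) {
    p <- runif(20)^2
    out <- bh_fdr(p)
    expect_equal(out$adjusted, oracle_bh(p), tolerance = 1e-12)
    expect_lte(sum(out$rejected), sum(p <= 0.05))
  }
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("frequency profiles locate the planted coupling band", {
  set.seed(96)
  nf <- 47
  freqs <- 4:50
  theta_idx <- which(freqs >= 5 & freqs <= 13)
  n_el <- 25
  make_site <- function() {
    conn_theta <- runif(n_el, 0.1, 0.9)
    conn_by_freq <- lapply(seq_len(nf), function(f) {
      if (f %in% theta_idx) conn_theta else runif(n_el, 0.1, 0.9)
    })
    list(t_stats = 2 * logit(conn_theta) + rnorm(n_el, 0, 0.5),
         conn_by_freq = conn_by_freq,
         dist_lin = runif(n_el, 0.4, 1))
  }
  sites <- lapply(1:3, function(i) make_site())
  prof <- nma_frequency_profile(sites, n_perm = 300, seed = 97)
  expect_length(prof$mean_z, nf)
  expect_length(prof$p_adjusted, nf)
  expect_true(freqs[which.max(prof$mean_z)] %in% 5:13)
  expect_true(all(prof$mean_z[theta_idx] >
                    max(prof$mean_z[-theta_idx])))
  expect_error(nma_frequency_profile(list(sites[[1]],
                                          list(t_stats = 1:25,
                                               conn_by_freq = sites[[1]]$conn_by_freq[1:3],
                                               dist_lin = runif(25)))),
               "mismatched")
})

test_that("display smoothing is a three-point moving average", {
  expect_equal(stimnet:::moving_average(c(1, 2, 3))[2], 2)
  expect_equal(stimnet:::moving_average(c(1, 2, 3)), c(1.5, 2, 2.5))
})

test_that("directional counts and the binomial test follow the exact computation", {
  mk <- function(z, p) structure(list(z = z, p_two_tailed = p), class = "nma")
  sites <- c(lapply(1:6, function(i) mk(-2.5, 0.01)),
             lapply(1:4, function(i) mk(2.5, 0.01)),
             lapply(1:62, function(i) mk(0.1, 0.8)))
  out <- directional_count_test(sites, alpha = 0.05)
  expect_equal(out$n_negative, 6)
  expect_equal(out$n_positive, 4)
  expect_equal(out$n_negative + out$n_positive, 10)
  expect_equal(out$result$p,
               binom.test(10, 72, 0.05, alternative = "greater")$p.value,
               tolerance = 1e-12)
  expect_lt(out$result$p, 0.01)
  none <- directional_count_test(lapply(1:20, function(i) mk(0, 0.9)))
  expect_equal(none$result$p, 1)
})

test_that("the one-sample group test matches the textbook formula", {
  expect_equal(group_onesample_test(c(-1, 1))$statistic, 0)
  expect_error(group_onesample_test(c(1, 1, 1)), "zero variance")
  expect_error(group_onesample_test(1), "at least 2")
  set.seed(98)
  for (i in 1:5) {
    x <- rnorm(12)
    expect_equal(group_onesample_test(x)$statistic, oracle_onesample_t(x),
                 tolerance = 1e-10)
  }
})
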