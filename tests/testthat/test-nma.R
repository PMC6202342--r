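test_that("logit matches its closed form and enforces the boundary policy", {
  expect_identical(logit(0.5), 0)
  expect_equal(logit(0.7310586), 1, tolerance = 1e-4)
  expect_warning(v <- logit(1.0), "clipped")
  expect_equal(v, log((1 - 1e-6) / 1e-6))
  expect_error(logit(1.5), "\\[0, 1\\]")
  expect_error(logit(-0.1), "\\[0, 1\\]")
})

test_that("the regression recovers exact coefficients and matches the normal equations", {
  set.seed(61)
  conn <- rnorm(30)
  dist <- rnorm(30)
  dist <- dist - conn * sum(dist * conn) / sum(conn^2)  # orthogonalize
  co <- fit_regression(2 * conn, conn, dist)
  expect_equal(unname(co["beta_conn"]), 2, tolerance = 1e-10)
  expect_equal(unname(co["beta_dist"]), 0, tolerance = 1e-10)
  for (rep in 1:5) {
    y <- rnorm(25); c1 <- rnorm(25); d1 <- rnorm(25)
    co2 <- fit_regression(y, c1, d1)
    oracle <- oracle_ols(cbind(1, d1, c1), y)
    expect_equal(unname(co2), oracle, tolerance = 1e-8)
  }
  x <- rnorm(20)
  expect_error(fit_regression(rnorm(20), x, x), "collinear")
  expect_error(fit_regression(rnorm(5), rnorm(5), rnorm(5)), "fewer than 10")
})

test_that("the permutation null is deterministic and equals a literal re-fit", {
  set.seed(62)
  y <- rnorm(20); conn <- rnorm(20); dist <- rnorm(20)
  null1 <- permutation_null(y, conn, dist, n_perm = 200, seed = 9)
  null2 <- permutation_null(y, conn, dist, n_perm = 200, seed = 9)
  expect_length(null1, 200)
  expect_identical(null1, null2)
  # literal joint row shuffle of the predictors, same RNG stream
  literal <- stimnet:::with_seed(9, vapply(1:200, function(i) {
    p <- sample.int(20)
    xp <- cbind(1, dist[p], conn[p])
    stats::lm.fit(xp, y)$coefficients[3]
  }, numeric(1)))
  expect_equal(null1, unname(literal), tolerance = 1e-10)
  expect_warning(permutation_null(y, conn, dist, n_perm = 50, seed = 1),
                 "unstable")
})

test_that("connectivity-only permutation mode shuffles one column", {
  set.seed(63)
  y <- rnorm(15); conn <- rnorm(15); dist <- rnorm(15)
  nb <- permutation_null(y, conn, dist, n_perm = 150, seed = 4,
                         mode = "connectivity")
  expect_length(nb, 150)
  expect_identical(nb, permutation_null(y, conn, dist, n_perm = 150,
                                        seed = 4, mode = "connectivity"))
})

test_that("under a true null the observed coefficient sits inside its permutation distribution", {
  set.seed(64)
  inside <- vapply(1:500, function(i) {
    y <- rnorm(30); conn <- rnorm(30); dist <- rnorm(30)
    b <- fit_regression(y, conn, dist)[["beta_conn"]]
    nb <- permutation_null(y, conn, dist, n_perm = 400, seed = i)
    b >= quantile(nb, 0.025) && b <= quantile(nb, 0.975)
  }, logical(1))
  expect_gt(mean(inside), 0.91)
  expect_lt(mean(inside), 0.985)
})

test_that("a strong planted effect yields decisive NMA", {
  ctx <- fixture_site_context(60, seed = 65)
  tr <- ground_truth(matrix(0, 1, 60), 8, beta_conn = 0.05, noise_sd = 0.05)
  pc <- fixture_contrast(ctx, tr, "VE001", seed = 66)
  fit <- compute_nma(pc, ctx$coherence, ctx$distance, "VE001",
                     n_perm = 1000, seed = 67)
  expect_gt(fit$z, 3)
  expect_lte(fit$p_two_tailed, 0.002)
  expect_equal(fit$n_electrodes, 59)
  expect_length(fit$null_betas, 1000)
  expect_s3_class(fit, "nma")
  expect_named(coef(fit), c("intercept", "beta_dist", "beta_conn"))
})

test_that("NMA is invariant to affine rescaling of t and to electrode relabeling", {
  ctx <- fixture_site_context(30, seed = 68)
  tr <- ground_truth(matrix(0, 1, 30), 8, beta_conn = 0.02, noise_sd = 0.2)
  pc <- fixture_contrast(ctx, tr, "VE001", seed = 69)
  f1 <- compute_nma(pc, ctx$coherence, ctx$distance, "VE001",
                    n_perm = 500, seed = 70)
  f2 <- compute_nma(3.2 * pc$t_stat + 1.5, ctx$coherence, ctx$distance,
                    "VE001", n_perm = 500, seed = 70)
  expect_equal(f1$z, f2$z, tolerance = 1e-8)
  # relabel: reverse electrode order everywhere
  n <- 30
  rev_idx <- n:1
  coh_r <- adjacency(ctx$coherence$values[rev_idx, rev_idx], "coherence",
                     labels = ctx$coherence$labels[rev_idx])
  dst_r <- adjacency(ctx$distance$values[rev_idx, rev_idx], "distance_lin",
                     labels = ctx$distance$labels[rev_idx])
  f3 <- compute_nma(pc$t_stat[rev_idx], coh_r, dst_r, "VE001",
                    n_perm = 500, seed = 70)
  expect_equal(f1$z, f3$z, tolerance = 1e-8)
})

test_that("p-value and z-score tails agree", {
  ctx <- fixture_site_context(20, seed = 71)
  tr <- ground_truth(matrix(0, 1, 20), 8, beta_conn = -0.05, noise_sd = 0.05)
  pc <- fixture_contrast(ctx, tr, "VE003", seed = 72)
  fit <- compute_nma(pc, ctx$coherence, ctx$distance, "VE003",
                     n_perm = 500, seed = 73)
  expect_lt(fit$z, 0)
  expect_lt(fit$p_two_tailed, 0.05)
  expect_gt(fit$p_two_tailed, 0)
})

test_that("a pure distance effect does not inflate the NMA", {
  # connectivity proportional to linearized distance plus small noise;
  # t driven by distance only -> regression credits the distance column
  lay <- generate_layout(40, seed = 74)
  dst <- distance_network(lay)
  flags <- vapply(1:20, function(r) {
    set.seed(300 + r)
    noise <- matrix(0, 40, 40)
    noise[upper.tri(noise)] <- rnorm(780, 0, 0.01)
    noise <- noise + t(noise)
    cv <- pmin(pmax(0.6 * dst$values + noise, 0.02), 0.98)
    diag(cv) <- NA
    coh <- adjacency(cv, "coherence", labels = lay$labels)
    t_stats <- 3 * dst$values[1, ] + rnorm(40, 0, 0.2)
    fit <- compute_nma(t_stats, coh, dst, 1, n_perm = 400, seed = 400 + r)
    abs(fit$z) < 2
  }, logical(1))
  expect_gte(mean(flags), 0.9)
})

test_that("NMA enforces the 10-electrode rule and rejects degenerate networks", {
  ctx <- fixture_site_context(9, seed = 75)
  tr <- ground_truth(matrix(0, 1, 9), 8, noise_sd = 0.2)
  pc <- fixture_contrast(ctx, tr, "VE001", n_trials = 20, seed = 76)
  expect_error(compute_nma(pc, ctx$coherence, ctx$distance, "VE001"),
               "fewer than 10")
  ctx2 <- fixture_site_context(15, seed = 77)
  const <- adjacency(matrix(0.4, 15, 15), "coherence",
                     labels = ctx2$coherence$labels)
  pc2 <- fixture_contrast(ctx2, tr <- ground_truth(matrix(0, 1, 15), 8,
                                                   noise_sd = 0.2),
                          "VE001", n_trials = 20, seed = 78)
  expect_error(compute_nma(pc2, const, ctx2$distance, "VE001"),
               "degenerate")
})

test_that("nma objects print, summarize, and serialize", {
  ctx <- fixture_site_context(15, seed = 79)
  tr <- ground_truth(matrix(0, 1, 15), 8, noise_sd = 0.2)
  pc <- fixture_contrast(ctx, tr, "VE002", n_trials = 30, seed = 80)
  fit <- compute_nma(pc, ctx$coherence, ctx$distance, "VE002",
                     n_perm = 200, seed = 81)
  expect_output(print(fit), "NMA z")
  s <- summary(fit)
  expect_s3_class(s, "summary.nma")
  expect_output(print(s), "coefficients")
  path <- file.path(tempdir(), "nma.json")
  write_nma(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$z, fit$z, tolerance = 1e-12)
  expect_equal(back$n_electrodes, 14)
})
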