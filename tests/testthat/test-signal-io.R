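test_that("the native container round-trips recordings bit-exactly", {
  set.seed(21)
  rec <- recording(matrix(rnorm(5 * 400), 5, 400), 200,
                   sprintf("ch%d", 1:5), "bipolar")
  path <- file.path(tempdir(), "roundtrip.bin")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_identical(back$samples, rec$samples)
  expect_identical(back$fs, rec$fs)
  expect_identical(back$labels, rec$labels)
  expect_identical(back$montage, "bipolar")
  expect_error(read_recording(file.path(tempdir(), "nope.bin")), "not found")
  expect_error(recording(matrix(numeric(0), 0, 0), 200, character(0)),
               "at least one channel")
})

test_that("EDF files are parsed with values within one quantization step", {
  fs <- 100
  x <- rbind(100 * sin(2 * pi * 3 * (0:(3 * fs - 1)) / fs),
             50 * cos(2 * pi * 7 * (0:(3 * fs - 1)) / fs))
  path <- file.path(tempdir(), "fixture.edf")
  write_edf_fixture(path, x, fs, c("LA1", "LA2"))
  rec <- read_recording(path, format = "edf")
  expect_equal(rec$fs, fs)
  expect_identical(rec$labels, c("LA1", "LA2"))
  qstep <- 1000 / 65535  # physical range / digital range
  expect_lt(max(abs(rec$samples - x)), qstep + 1e-9)
})

test_that("bipolar re-referencing cancels the common reference", {
  fs <- 100
  t <- (0:199) / fs
  ref <- 30 * sin(2 * pi * 1 * t)
  s <- 10 * sin(2 * pi * 9 * t)
  rec <- recording(rbind(s + ref, ref, 5 * cos(2 * pi * 4 * t) + ref),
                   fs, c("A", "B", "C"))
  bp <- bipolar_rereference(rec, list(c("A", "B"), c("C", "B")))
  expect_equal(bp$samples[1, ], s, tolerance = 1e-12)
  expect_identical(bp$labels, c("A-B", "C-B"))
  expect_identical(bp$montage, "bipolar")
  expect_equal(nrow(bp$samples), 2)
  # A = s(t), B = 0 convention check
  rec2 <- recording(rbind(s, numeric(200)), fs, c("A", "B"))
  expect_equal(bipolar_rereference(rec2, list(c("A", "B")))$samples[1, ], s)
  expect_error(bipolar_rereference(rec, list(c("A", "Z"))), "unknown contact")
  expect_error(bipolar_rereference(rec, list(c("A", "A"))), "identical")
})

test_that("the notch filter attenuates line noise and spares the passband", {
  fs <- 1000
  t <- (0:(4 * fs - 1)) / fs
  line <- recording(matrix(sin(2 * pi * 60 * t), 1), fs, "x")
  out <- notch_filter(line, 60)
  rms <- function(v) sqrt(mean(v^2))
  core <- (fs + 1):(3 * fs)  # avoid filter edge transients
  expect_lt(rms(out$samples[1, core]) / rms(line$samples[1, core]), 0.1)
  slow <- recording(matrix(sin(2 * pi * 8 * t), 1), fs, "x")
  out8 <- notch_filter(slow, 60)
  expect_lt(abs(rms(out8$samples[1, core]) / rms(slow$samples[1, core]) - 1),
            0.01)
  expect_error(notch_filter(recording(matrix(rnorm(100), 1), 100, "x"), 60),
               "twice the line frequency")
})

test_that("trial windows land on the exact stated sample indices", {
  fs <- 1000
  n <- 15 * fs
  x <- matrix(0, 1, n)
  # mark the expected 0-based index ranges with distinct constants
  x[1, (9050 + 1):9950] <- 1     # pre power window of onset 10 s
  x[1, (10550 + 1):11450] <- 2   # post power window (offset 10.5 s)
  x[1, (9650 + 1):10000] <- 3    # pre artifact window
  x[1, (10500 + 1):10850] <- 4   # post artifact window
  rec <- recording(x, fs, "ch1")
  sess <- extract_trial_windows(rec, onsets = 10, stim_duration = 0.5)
  expect_equal(dim(sess$pre_power), c(1, 1, 900))
  expect_true(all(sess$pre_power[1, 1, ] %in% c(1, 3)))
  expect_true(all(sess$post_power[1, 1, ] %in% c(2, 4)))
  expect_true(any(sess$post_power[1, 1, ] == 2))
  expect_true(all(sess$pre_art[1, 1, ] == 3))
  expect_true(all(sess$post_art[1, 1, ] == 4))
})

test_that("window lengths are sample-exact at all supported rates", {
  for (fs in c(500, 1000, 1600)) {
    rec <- recording(matrix(rnorm(6 * fs), 1), fs, "ch1")
    sess <- extract_trial_windows(rec, onsets = c(2, 4), stim_duration = 0.5)
    expect_equal(dim(sess$pre_power)[3], round(0.9 * fs))
    expect_equal(dim(sess$pre_art)[3], round(0.35 * fs))
  }
})

test_that("out-of-bounds trials are dropped with a warning, all-out errors", {
  rec <- recording(matrix(rnorm(5000), 1), 1000, "ch1")
  expect_warning(sess <- extract_trial_windows(rec, onsets = c(0.1, 2.5),
                                               stim_duration = 0.5),
                 "dropped")
  expect_length(sess$onsets, 1)
  expect_equal(sess$n_dropped, 1L)
  expect_error(suppressWarnings(
    extract_trial_windows(rec, onsets = 0.1, stim_duration = 0.5)),
    "zero trials")
})

test_that("artifact channels are flagged by mean shift or variance change", {
  ctx <- fixture_site_context(12, seed = 31)
  tr <- ground_truth(matrix(0, 1, 12), 8, noise_sd = 0.2)
  s <- generate_stim_session(ctx$layout, ctx$coherence, ctx$distance, tr,
                             "VE001", n_trials = 240, fs = 500, seed = 32,
                             synthesize = FALSE, artifact_windows = TRUE,
                             voltage_noise_sd = 20)
  s <- inject_artifact(s, 2, offset_uv = 50, var_factor = 1)
  s <- inject_artifact(s, 5, offset_uv = 0, var_factor = 4)
  mask <- detect_artifact_channels(s)
  expect_false(mask$included[2])   # t-test branch
  expect_false(mask$included[5])   # Levene branch
  expect_identical(mask$reasons[[2]], "artifact")
  expect_true(all(mask$included[setdiff(1:12, c(2, 5))] |
                    !mask$included[setdiff(1:12, c(2, 5))]))
})

test_that("exclusion rules union correctly and enforce the 10-electrode floor", {
  lay <- generate_layout(14, seed = 33)
  lay$soz_flag[3] <- TRUE
  lay$spiking_flag[4] <- TRUE
  # electrode 2 shares contact C1b-like membership with the stim pair
  lay$contact_members[2, ] <- c("C1b", "C2b")
  stim_pair <- lay$contact_members[1, ]
  art <- channel_mask(c(FALSE, rep(TRUE, 13)),
                      c(list("artifact"), rep(list(character(0)), 13)))
  mask <- apply_exclusions(lay, art, stim_pair)
  expect_false(mask$included[1])
  expect_true("stim_site" %in% mask$reasons[[1]])
  expect_true("artifact" %in% mask$reasons[[1]])
  expect_true("shares_stim_contact" %in% mask$reasons[[2]])
  expect_true("soz_or_spiking" %in% mask$reasons[[3]])
  expect_true("soz_or_spiking" %in% mask$reasons[[4]])
  expect_equal(sum(mask$included), 10)
  # idempotence / order independence: re-applying changes nothing
  again <- apply_exclusions(lay, art, stim_pair)
  expect_identical(mask, again)
  lay$soz_flag[5:6] <- TRUE  # pushes survivors below 10
  expect_error(apply_exclusions(lay, art, stim_pair), "fewer than 10")
})

test_that("artifact-detector null exclusion rate matches the two-test union", {
  set.seed(34)
  n_ch <- 1000
  sd_mean <- 20 / sqrt(175)  # per-trial 350 ms window mean at 500 Hz
  flagged <- vapply(seq_len(n_ch), function(i) {
    pre <- rnorm(240, 0, sd_mean)
    post <- rnorm(240, 0, sd_mean)
    p <- artifact_tests(pre, post)
    min(p$p_t, p$p_levene) < 0.01
  }, logical(1))
  rate <- mean(flagged)
  expect_gte(rate, 0.005)
  expect_lte(rate, 0.04)
})

test_that("layout TSV round-trips all metadata", {
  lay <- generate_layout(8, seed = 35, n_soz = 1, n_wm = 2)
  path <- file.path(tempdir(), "layout.tsv")
  write_layout(lay, path)
  back <- read_layout(path)
  expect_identical(back$labels, lay$labels)
  expect_equal(back$coordinates, lay$coordinates, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_identical(back$soz_flag, lay$soz_flag)
  expect_identical(back$in_wm_label, lay$in_wm_label)
})
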