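pipeline_defaults <- function() {
  list(
    stages = c("simulate", "preprocess", "connect", "evoked", "nma", "group"),
    out_dir = "stimnet_out",
    paths = list(baseline = NULL, layout = NULL),
    n_electrodes = 60, n_sites = 3, n_trials = 240, n_periods = 10,
    fs = 1000, line_freq = 60,
    synthesize = FALSE, write_recordings = FALSE,
    truth = list(beta0 = 0, beta_conn = 0.5, beta_dist = 0, noise_sd = 0.2,
                 n_sources = 6, source_band = c(5, 13), snr = 2),
    multitaper = list(time_bandwidth = 4, max_tapers = 8,
                      min_concentration = 0.9),
    bands = list(theta = c(5, 8), alpha_beta = c(10, 25),
                 gamma = c(30, 50), hfb = c(50, 200)),
    connectivity_band = c(5, 13),
    n_perm = 1000, alpha = 0.05,
    wm_direction = "near_is_close",
    perm_mode = "joint",
    seeds = list(simulate = 101L, nma = 202L, group = 303L)
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads YAML or JSON, fills documented defaults (1000 permutations, the
#' four analysis bands, NW = 4 with at most 8 tapers, joint predictor
#' permutation), and validates. Unknown top-level keys are an error in
#' strict mode so typos cannot silently fall back to defaults.
#'
#' @param path Config file (`.yaml`/`.yml`/`.json`), or `NULL` for pure
#'   defaults.
#' @param strict Reject unknown keys.
#' @return A validated config list of class `run_config`.
#' @export
load_config <- function(path = NULL, strict = TRUE) {
  cfg <- pipeline_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
            else jsonlite::read_json(path, simplifyVector = TRUE)
    user <- user %||% list()
    unknown <- setdiff(names(user), names(cfg))
    if (strict && length(unknown) > 0)
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    for (k in intersect(names(user), names(cfg))) {
      cfg[[k]] <- if (is.list(cfg[[k]]) && is.list(user[[k]]))
        utils::modifyList(cfg[[k]], user[[k]]) else user[[k]]
    }
  }
  if ("all" %in% cfg$stages) cfg$stages <- pipeline_defaults()$stages
  bad <- setdiff(cfg$stages, pipeline_defaults()$stages)
  if (length(bad) > 0) stop("unknown stages: ", paste(bad, collapse = ", "))
  for (b in names(cfg$bands)) {
    e <- cfg$bands[[b]]
    if (length(e) != 2 || !(e[1] > 0) || !(e[1] < e[2]))
      stop("invalid band edges for ", b, ": need 0 < fmin < fmax")
  }
  if (cfg$n_perm < 100)
    warning("n_perm = ", cfg$n_perm, ": permutation z-scores are unstable")
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$fs > 0)
  structure(cfg, class = "run_config")
}

#' Run the analysis pipeline from a single configuration
#'
#' Executes the requested stages in dependency order (simulate ->
#' preprocess -> connect -> evoked -> nma -> group), writing TSV tables and
#' a JSON report stamped with a hash of the configuration and all seeds.
#' Prerequisite stages of a requested subset are computed in memory but
#' their outputs are written only if requested. A stimulation site that
#' retains fewer than 10 electrodes is skipped with its reason recorded,
#' mirroring the discard rule; any other stage failure aborts with the
#' stage named.
#'
#' @param config A `run_config` from [load_config()].
#' @return The report list (also written to `<out_dir>/report.json`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("config must come from load_config()")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  wanted <- config$stages
  order_all <- pipeline_defaults()$stages
  upto <- max(match(wanted, order_all))
  # Prerequisite stages are auto-run in memory unless the config supplies
  # their products as input paths.
  auto <- is.null(config$paths$baseline) && is.null(config$paths$layout)
  run <- if (auto) order_all[seq_len(upto)] else wanted
  log <- list(); results <- list()
  state <- new.env(parent = emptyenv())

  stage <- function(name, fun) {
    if (!name %in% run) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    msgs <- character(0)
    res <- withCallingHandlers(
      tryCatch(fun(name %in% wanted),
               error = function(e) stop("stage ", name, ": ",
                                        conditionMessage(e), call. = FALSE)),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    log[[name]] <<- list(duration_s = round(proc.time()[["elapsed"]] - t0, 3),
                         warnings = msgs)
    res
  }

  stage("simulate", function(write_out) {
    tr_cfg <- config$truth
    n <- config$n_electrodes
    n_src <- tr_cfg$n_sources
    # Each source loads on a random subset of channels at amplitude
    # snr x baseline noise (1 uV), planting 5-13 Hz coherence structure.
    mix <- with_seed(child_seed(config$seeds$simulate, 99), {
      m <- matrix(0, n_src, n)
      for (s in seq_len(n_src))
        m[s, sample.int(n, max(2, round(n / n_src)))] <- tr_cfg$snr
      m
    })
    freqs <- seq(tr_cfg$source_band[1], tr_cfg$source_band[2],
                 length.out = n_src)
    truth <- ground_truth(mix, freqs, beta0 = tr_cfg$beta0,
                          beta_conn = tr_cfg$beta_conn,
                          beta_dist = tr_cfg$beta_dist,
                          noise_sd = tr_cfg$noise_sd,
                          seed = config$seeds$simulate)
    study <- simulate_study(n, truth,
                            stim_sites = sprintf("VE%03d", seq_len(config$n_sites)),
                            n_trials = config$n_trials,
                            n_periods = config$n_periods, fs = config$fs,
                            seed = config$seeds$simulate,
                            synthesize = config$synthesize)
    state$study <- study
    state$layout <- study$layout
    if (write_out) {
      write_layout(study$layout, file.path(config$out_dir, "layout.tsv"))
      if (config$write_recordings)
        write_recording(study$baseline,
                        file.path(config$out_dir, "baseline.bin"))
    }
    results$simulate <<- list(n_electrodes = n,
                              n_sessions = length(study$sessions),
                              truth_seed = truth$seed)
  })

  if (is.null(state$layout) && any(c("preprocess", "connect") %in% run)) {
    if (is.null(config$paths$layout))
      stop("stage preprocess: no simulated study and no layout path given")
    if (!file.exists(config$paths$layout))
      stop("stage preprocess: layout file not found: ", config$paths$layout)
    state$layout <- read_layout(config$paths$layout)
  }

  stage("preprocess", function(write_out) {
    study <- state$study
    masks <- lapply(study$sessions, function(s) {
      art <- if (!is.null(s$pre_art)) detect_artifact_channels(s) else NULL
      apply_exclusions(state$layout, art, s$stim_pair)
    })
    state$masks <- masks
    excl <- vapply(masks, function(m) sum(!m$included), integer(1))
    results$preprocess <<- list(n_excluded_per_session = excl)
  })

  stage("connect", function(write_out) {
    study <- state$study
    if (!is.null(study)) {
      state$coh <- study$coherence
      state$dst <- study$distance
    } else {
      if (is.null(config$paths$baseline))
        stop("no baseline recording available")
      if (!file.exists(config$paths$baseline))
        stop("input recording not found: ", config$paths$baseline)
      rec <- read_recording(config$paths$baseline)
      spec <- multitaper_spec(config$multitaper$time_bandwidth,
                              config$multitaper$max_tapers,
                              config$multitaper$min_concentration)
      state$coh <- coherence_network(baseline_windows(rec), spec,
                                     band = config$connectivity_band,
                                     fs = rec$fs, labels = rec$labels)
      state$dst <- distance_network(state$layout)
    }
    if (write_out) {
      write_adjacency(state$coh, file.path(config$out_dir, "coherence.tsv"))
      write_adjacency(state$dst, file.path(config$out_dir, "distance.tsv"))
    }
    results$connect <<- list(n_nodes = nrow(state$coh$values),
                             n_windows = state$coh$n_windows)
  })

  stage("evoked", function(write_out) {
    study <- state$study
    contrasts <- lapply(seq_along(study$sessions), function(i) {
      s <- study$sessions[[i]]
      pw <- session_band_powers(s, band_spec("theta"))
      power_contrast(pw$pre, pw$post, band_spec("theta"),
                     mask = state$masks[[i]])
    })
    state$contrasts <- contrasts
    if (write_out) {
      for (i in seq_along(contrasts))
        write_contrast(contrasts[[i]], state$layout$labels,
                       file.path(config$out_dir,
                                 sprintf("contrast_site%02d.tsv", i)))
    }
    results$evoked <<- list(
      whole_brain_t = vapply(contrasts, whole_brain_power_change, numeric(1)))
  })

  stage("nma", function(write_out) {
    study <- state$study
    fits <- list(); skipped <- list()
    for (i in seq_along(study$sessions)) {
      site <- study$sessions[[i]]
      lab <- state$layout$labels[resolve_stim(state$layout, site$stim_pair)]
      fit <- tryCatch(
        compute_nma(state$contrasts[[i]], state$coh, state$dst, lab,
                    n_perm = config$n_perm,
                    seed = child_seed(config$seeds$nma, i),
                    perm_mode = config$perm_mode),
        error = function(e) e)
      if (inherits(fit, "error")) {
        skipped[[lab]] <- conditionMessage(fit)
      } else {
        fits[[lab]] <- fit
        if (write_out)
          write_nma(fit, file.path(config$out_dir,
                                   sprintf("nma_%s.json", lab)))
      }
    }
    state$fits <- fits
    results$nma <<- list(
      z = vapply(fits, `[[`, numeric(1), "z"),
      p = vapply(fits, `[[`, numeric(1), "p_two_tailed"),
      skipped = skipped)
  })

  stage("group", function(write_out) {
    fits <- state$fits
    if (length(fits) < 2) {
      results$group <<- list(note = "fewer than 2 NMA sites; group stage summarized only")
      return(invisible(NULL))
    }
    z <- vapply(fits, `[[`, numeric(1), "z")
    one <- group_onesample_test(z)
    dirs <- directional_count_test(fits, alpha = config$alpha)
    site_idx <- match(names(fits), state$layout$labels)
    wm <- state$layout$wm_distance[site_idx]
    trend <- tryCatch({
      cats <- classify_wm(wm, state$layout$in_wm_label[site_idx],
                          direction = config$wm_direction)
      wm_trend_permutation_test(z, cats, n_perm = config$n_perm,
                                seed = config$seeds$group)
    }, error = function(e) conditionMessage(e))
    results$group <<- list(
      one_sample = list(t = one$statistic, p = one$p, n = one$n),
      directional = list(n_negative = dirs$n_negative,
                         n_positive = dirs$n_positive,
                         binomial_p = dirs$result$p),
      wm_trend = if (inherits(trend, "group_result"))
        list(min_t = trend$statistic, p = trend$p) else list(note = trend))
  })

  cfg_for_hash <- unclass(config)
  cfg_for_hash$out_dir <- NULL
  report <- list(config_hash = object_hash(cfg_for_hash),
                 seeds = config$seeds,
                 stages = log, results = results)
  report$results_hash <- object_hash(results)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
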