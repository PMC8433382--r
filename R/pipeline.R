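# Pipeline orchestration: simulate -> modulate -> population -> bands ->
# decode -> statespace, with a YAML config, per-stage CSV outputs and a
# JSON manifest. Deterministic given the seed.

#' Default pipeline configuration
#'
#' All analysis constants default to their standard values (band tables,
#' the 80% duration threshold, the 10 a.u. modulation criterion, the
#' +-8 s trial window, 16 phase bins, dependence factor 7); generator
#' parameters default to a 600 s locomotor-like session.
#'
#' @param seed integer seed used by every stochastic stage.
#' @return nested list; see the YAML written by [run_pipeline()] for the
#'   layout.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    stages = c("simulate", "modulate", "population", "bands", "decode",
               "statespace"),
    simulate = list(duration = 600, submovement_freq = 4.7, amplitude = 6,
                    tracking_noise_sd = 0.79, n_units = 6,
                    lags = c(-0.5, -0.2, -0.05, 0, 0.2, 0.5),
                    modulation_sigma = c(0.3, 0.15, 0.05, 0.05, 0.15, 0.3),
                    gain = 1.5, baseline_rate = 8),
    modulate = list(max_lag = 4, n_bins = 10, peak_frac = 0.8,
                    mod_criterion = 10),
    population = list(half_window = 8, ratio_threshold = 2),
    bands = list(),
    decode = list(),
    statespace = list(execution_lag = -0.04),
    stats = list(dependence_factor = 7)
  )
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Executes the configured stages in dependency order, writing per-stage CSV
#' outputs, the session itself, the effective YAML config and a JSON
#' manifest (seed, parameters, per-stage wall time, output files with
#' checksums) into `out_dir`. Rerunning with the same config and seed
#' reproduces the metric tables bit for bit.
#'
#' @param config a config list as from [default_config()], or a path to a
#'   YAML file with the same layout.
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, config = cfg, stages = list())
  outputs <- character()
  tick <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    list(value = val, wall_s = proc.time()[["elapsed"]] - t0)
  }
  sess <- NULL

  for (stage in cfg$stages) {
    res <- switch(
      stage,
      simulate = tick({
        sc <- cfg$simulate
        beh <- generate_behavior(sc$duration,
                                 submovement_freq = sc$submovement_freq,
                                 amplitude = sc$amplitude,
                                 tracking_noise_sd = sc$tracking_noise_sd,
                                 seed = cfg$seed)
        specs <- lapply(seq_len(sc$n_units), function(i)
          unit_spec(lag = sc$lags[((i - 1L) %% length(sc$lags)) + 1L],
                    modulation_sigma =
                      sc$modulation_sigma[((i - 1L) %% length(sc$modulation_sigma)) + 1L],
                    gain = sc$gain, baseline_rate = sc$baseline_rate))
        sess <- generate_session(beh, specs, seed = cfg$seed + 1L)
        write_session(sess, file.path(out_dir, "session"))
        file.path(out_dir, "session")
      }),
      modulate = tick({
        if (is.null(sess)) stopf("stage 'modulate' needs the 'simulate' stage output")
        mc <- cfg$modulate
        tab <- do.call(rbind, lapply(seq_along(sess$units), function(i) {
          act <- instantaneous_rate(sess$units[[i]], sess$duration,
                                    sess$behavior$dt)
          prof <- modulation_metrics(
            compute_awd(act, sess$behavior, max_lag = mc$max_lag,
                        n_bins = mc$n_bins),
            peak_frac = mc$peak_frac, mod_criterion = mc$mod_criterion)
          data.frame(unit = i, area = sess$units[[i]]$area,
                     duration_s = prof$duration, lag_s = prof$lag,
                     modulated = prof$modulated,
                     psi_percent = planning_sensory_index(prof))
        }))
        f <- file.path(out_dir, "modulation.csv")
        utils::write.csv(tab, f, row.names = FALSE)
        f
      }),
      population = tick({
        if (is.null(sess)) stopf("stage 'population' needs the 'simulate' stage output")
        pop <- preprocess_population(sess)
        trials <- detect_trials(sess$behavior,
                                ratio_threshold = cfg$population$ratio_threshold,
                                half_window = cfg$population$half_window)
        f <- file.path(out_dir, "population.csv")
        if (length(trials$centers)) {
          cm <- trial_correlation_matrix(pop, trials)
          tc <- decay_timecourse(cm, dt = sess$behavior$dt)
          utils::write.csv(data.frame(time_s = tc$time, tau_s = tc$tau), f,
                           row.names = FALSE)
        } else {
          utils::write.csv(data.frame(time_s = numeric(), tau_s = numeric()),
                           f, row.names = FALSE)
        }
        f
      }),
      bands = tick({
        if (is.null(sess)) stopf("stage 'bands' needs the 'simulate' stage output")
        act <- t(vapply(sess$units, function(u)
          instantaneous_rate(u, sess$duration, sess$behavior$dt),
          numeric(length(sess$behavior))))
        bv <- band_velocity_correlation(act, sess$behavior)
        f <- file.path(out_dir, "bands.csv")
        utils::write.csv(bv, f, row.names = FALSE)
        f
      }),
      decode = tick({
        if (is.null(sess)) stopf("stage 'decode' needs the 'simulate' stage output")
        enc <- fit_encoding(sess, seed = cfg$seed + 2L)
        sweep_df <- two_point_decode_sweep(enc$denoised, sess$behavior)
        f <- file.path(out_dir, "decode.csv")
        utils::write.csv(sweep_df, f, row.names = FALSE)
        f
      }),
      statespace = tick({
        if (is.null(sess)) stopf("stage 'statespace' needs the 'simulate' stage output")
        ss <- lag_tuning_projection(sess,
                                    execution_lag = cfg$statespace$execution_lag)
        sv <- state_vs_frequency(ss)
        f <- file.path(out_dir, "statespace.csv")
        utils::write.csv(data.frame(lag_s = ss$lags_s,
                                    state_tuning = ss$state_tuning,
                                    frequency_tuning = sv$frequency_tuning),
                         f, row.names = FALSE)
        f
      }),
      stopf("unknown stage '%s'", stage)
    )
    manifest$stages[[stage]] <- list(wall_s = res$wall_s, output = res$value)
    outputs <- c(outputs, res$value)
  }
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  files <- setdiff(list.files(out_dir, recursive = TRUE, full.names = TRUE),
                   file.path(out_dir, "manifest.json"))
  manifest$outputs <- lapply(files, function(f)
    list(file = sub(paste0("^", out_dir, "/?"), "", f),
         md5 = as.character(tools::md5sum(f))))
  manifest$r_version <- as.character(getRversion())
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
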