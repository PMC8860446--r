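analysis_defaults <- function() {
  list(raster_window = c(-0.1, 0.3),
       early_window = c(0.05, 0.10),
       late_window = c(0.20, 0.30),
       sigma = 0.010,
       grid_step = 0.001,
       alpha = 0.05,
       search_window = c(0, 0.30),
       decoder = list(window = c(0.05, 0.10), n_repeats = 20,
                      feature_mode = "rate"),
       dprime_step = 0.025,
       n_behavior_sessions = 6)
}

#' Pipeline run configuration
#'
#' Bundles generator, behavior and analysis parameters with a global seed.
#' Unknown analysis keys are rejected so configuration typos fail loudly.
#'
#' @param generator a [generator_config()].
#' @param behavior a [behavior_config()].
#' @param analysis named list overriding any of: `raster_window`,
#'   `early_window`, `late_window`, `sigma`, `grid_step`, `alpha`,
#'   `search_window`, `decoder` (`window`, `n_repeats`, `feature_mode`),
#'   `dprime_step`, `n_behavior_sessions`.
#' @param seed global integer seed; every stochastic stage derives its
#'   sub-stream from it.
#' @return object of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       behavior = behavior_config(),
                       analysis = list(), seed = 1) {
  stopifnot(inherits(generator, "generator_config"),
            inherits(behavior, "behavior_config"))
  def <- analysis_defaults()
  unknown <- setdiff(names(analysis), names(def))
  if (length(unknown) > 0)
    stop("unknown analysis key(s): ", paste(unknown, collapse = ", "))
  if ("decoder" %in% names(analysis)) {
    bad <- setdiff(names(analysis$decoder), names(def$decoder))
    if (length(bad) > 0)
      stop("unknown decoder key(s): ", paste(bad, collapse = ", "))
    analysis$decoder <- utils::modifyList(def$decoder, analysis$decoder)
  }
  an <- utils::modifyList(def, analysis)
  structure(list(generator = generator, behavior = behavior,
                 analysis = an, seed = seed), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The file may contain `generator:`, `behavior:`, `analysis:` and `seed:`
#' sections whose keys match the corresponding constructor arguments;
#' unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  bad <- setdiff(names(y), c("generator", "behavior", "analysis", "seed"))
  if (length(bad) > 0)
    stop("unknown config section(s): ", paste(bad, collapse = ", "))
  gen_args <- y$generator %||% list()
  for (nm in c("n_units", "latency_mean", "latency_shift_per_doubling",
               "rate_gain_per_doubling"))
    if (!is.null(gen_args[[nm]])) gen_args[[nm]] <- unlist(gen_args[[nm]])
  bad <- setdiff(names(gen_args), names(formals(generator_config)))
  if (length(bad) > 0)
    stop("unknown generator key(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(names(y$behavior %||% list()),
                 names(formals(behavior_config)))
  if (length(bad) > 0)
    stop("unknown behavior key(s): ", paste(bad, collapse = ", "))
  run_config(generator = do.call(generator_config, gen_args),
             behavior = do.call(behavior_config, y$behavior %||% list()),
             analysis = y$analysis %||% list(),
             seed = y$seed %||% 1)
}

#' Write an event/result table as tidy CSV
#'
#' @param table data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_events <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read an event table from CSV
#'
#' @param path CSV path.
#' @param time_col optional name of a time column whose ordering is
#'   checked.
#' @param on_unsorted what to do when `time_col` is out of order:
#'   `"error"` (default), `"sort"`, or `"ignore"`.
#' @return data frame.
#' @export
read_events <- function(path, time_col = NULL,
                        on_unsorted = c("error", "sort", "ignore")) {
  on_unsorted <- match.arg(on_unsorted)
  tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e)
                    stop("malformed CSV at ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (!is.null(time_col)) {
    if (!time_col %in% names(tab))
      stop("missing time column '", time_col, "' in ", path)
    if (is.unsorted(tab[[time_col]], na.rm = TRUE)) {
      if (on_unsorted == "error")
        stop("times out of order in ", path,
             " (first at row ",
             which(diff(tab[[time_col]]) < 0)[1] + 1L, ")")
      if (on_unsorted == "sort")
        tab <- tab[order(tab[[time_col]]), , drop = FALSE]
    }
  }
  tab
}

#' Run the full synthetic-session analysis pipeline
#'
#' Executes simulate -> detect -> align -> raster -> single-unit metrics ->
#' population geometry -> decoding -> temporal statistics -> behavior, as
#' configured, writing tidy CSV outputs and a provenance manifest (config
#' hash, seed, package version) into `out_dir`. With one global seed the
#' outputs are byte-identical across runs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param verbose print per-stage progress.
#' @return invisible named list of the result objects.
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  an <- config$analysis
  say <- function(...) if (verbose) message("[sniffcode] ", ...)
  log_lines <- character(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    dt <- proc.time()[["elapsed"]] - t0
    line <- sprintf("%s: %.2f s", name, dt)
    say(line)
    log_lines <<- c(log_lines, line)
    val
  }

  sess <- stage("simulate", simulate_session(config$generator,
                                             seed = config$seed))
  write_events(sess$trials, file.path(out_dir, "trials.csv"))
  write_events(sess$spikes, file.path(out_dir, "spikes.csv"))
  write_events(sess$units, file.path(out_dir, "units.csv"))
  write_events(sess$ground_truth$responses,
               file.path(out_dir, "ground_truth_responses.csv"))
  write_events(sess$ground_truth$latencies,
               file.path(out_dir, "ground_truth_latencies.csv"))
  write_events(data.frame(time_s = sess$trace$time,
                          pressure = sess$trace$pressure),
               file.path(out_dir, "respiration.csv"))

  onsets <- stage("detect", detect_inhalation_onsets(sess$trace))
  trials <- stage("align", align_trials(sess$trials, onsets,
                                        config$generator$odor_duration))
  raster <- stage("raster", build_raster(sess$spikes, trials,
                                         window = an$raster_window))
  write_events(as.data.frame(raster), file.path(out_dir, "raster.csv"))

  act <- stage("activation", activation_matrix(raster, trials,
                                               window = an$early_window,
                                               alpha = an$alpha))
  write_events(act, file.path(out_dir, "activation.csv"))
  sp <- stage("sparseness", sparseness_table(act))
  write_events(sp, file.path(out_dir, "sparseness.csv"))
  hist <- responsive_count_histogram(act)
  write_events(hist$histogram, file.path(out_dir, "responsive_histogram.csv"))
  write_events(hist$per_odor, file.path(out_dir, "percent_per_odor.csv"))

  sdf <- stage("sdf", spike_density(raster, trials, sigma = an$sigma,
                                    grid_step = an$grid_step))
  rec <- list(list(raster = raster, trials = trials, units = sess$units))
  tens_fine <- stage("tensor",
                     build_pseudopopulation(rec, window = an$raster_window,
                                            bin = an$grid_step,
                                            seed = config$seed))
  traj <- stage("pca", pca_trajectories(tens_fine, K = 3))
  id_pairs <- condition_pairs(traj$conditions, "identity")
  dist <- stage("distance",
                euclidean_distance_timecourse(traj, id_pairs))
  write_events(dist, file.path(out_dir, "pc_distance.csv"))

  dec_window <- an$decoder$window
  tens_win <- build_pseudopopulation(rec, window = dec_window,
                                     bin = diff(dec_window),
                                     seed = config$seed)
  dec_id <- stage("decode_identity",
                  decode_fixed(tens_win, "identity", window = dec_window,
                               feature_mode = an$decoder$feature_mode,
                               n_repeats = an$decoder$n_repeats,
                               seed = config$seed))
  multi_conc <- length(unique(stats::na.omit(
    tens_win$conditions$concentration))) > 1
  dec_int <- if (multi_conc)
    stage("decode_intensity",
          decode_fixed(tens_win, "intensity", window = dec_window,
                       feature_mode = an$decoder$feature_mode,
                       n_repeats = an$decoder$n_repeats,
                       seed = config$seed)) else NULL
  dec_tab <- data.frame(
    label = c("identity", if (multi_conc) "intensity"),
    accuracy = c(dec_id$mean, if (multi_conc) dec_int$mean),
    sd = c(dec_id$sd, if (multi_conc) dec_int$sd),
    chance = c(dec_id$chance, if (multi_conc) dec_int$chance))
  write_events(dec_tab, file.path(out_dir, "decoding.csv"))

  peaks <- stage("peaks", peak_stats(sdf, search_window = an$search_window,
                                     activation = act))
  write_events(peaks, file.path(out_dir, "peak_stats.csv"))
  trends <- if (multi_conc) {
    tr_t <- concentration_trend(peaks, "peak_time")
    tr_r <- concentration_trend(peaks, "peak_rate")
    data.frame(variable = c("peak_time", "peak_rate"),
               rho = c(tr_t$rho, tr_r$rho), p = c(tr_t$p, tr_r$p),
               n = c(tr_t$n, tr_r$n))
  } else NULL
  if (!is.null(trends))
    write_events(trends, file.path(out_dir, "concentration_trends.csv"))
  sync <- if (multi_conc) {
    act_peaks <- peaks[which(peaks$activated), , drop = FALSE]
    if (nrow(act_peaks) >= 2)
      suppressWarnings(pairwise_peak_time_diff(act_peaks)) else NULL
  } else NULL
  if (!is.null(sync))
    write_events(sync, file.path(out_dir, "pairwise_peak_diff.csv"))

  behav <- stage("behavior", {
    lapply(seq_len(an$n_behavior_sessions), function(i) {
      simulate_behavior(config$behavior,
                        seed = sub_seed(config$seed, 2000L + i),
                        session_id = sprintf("session%d", i))
    })
  })
  pc <- do.call(rbind, lapply(behav, function(s) {
    p <- percent_correct(s)
    p$session_id <- attr(s, "session_id")
    p
  }))
  write_events(pc, file.path(out_dir, "percent_correct.csv"))
  led <- led_comparison(pc)
  write_events(as.data.frame(led), file.path(out_dir, "led_comparison.csv"))
  onset <- stage("dprime",
                 dprime_onset(behav, step = an$dprime_step,
                              seed = config$seed))
  write_events(data.frame(t_s = onset$t_s, dprime = onset$dprime_mean,
                          null = onset$null_mean, p = onset$p),
               file.path(out_dir, "dprime_curve.csv"))
  write_events(data.frame(onset_s = onset$onset_s),
               file.path(out_dir, "dprime_onset.csv"))

  ## provenance manifest: config hash, seed, versions (no timestamps so
  ## that repeated runs are byte-identical)
  cfg_json <- file.path(out_dir, "config.json")
  jsonlite::write_json(config_to_list(config), cfg_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_json)),
    seed = config$seed,
    package = "sniffcode",
    package_version = as.character(utils::packageVersion("sniffcode")),
    outputs = sort(setdiff(list.files(out_dir), "manifest.json")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(list(session = sess, trials = trials, raster = raster,
                 activation = act, sparseness = sp, sdf = sdf,
                 trajectory = traj, distance = dist,
                 decoding = dec_tab, peaks = peaks, trends = trends,
                 synchrony = sync, behavior = behav,
                 percent_correct = pc, led = led, dprime = onset))
}

## Strip classes so the config serializes cleanly to JSON.
config_to_list <- function(config) {
  list(generator = unclass(config$generator),
       behavior = unclass(config$behavior),
       analysis = config$analysis,
       seed = config$seed)
}
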