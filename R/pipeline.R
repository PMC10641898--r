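#' Default pipeline configuration
#'
#' Nested list of every stage parameter with its published default, plus the
#' three RNG seeds (simulation, modulation, correlation). See
#' [validate_config()] for the schema.
#'
#' @param ... Named overrides: either top-level sections (`simulate`,
#'   `behavior`, `events`, `modulation`, `connectivity`, `network`, `stats`,
#'   `seeds`) given as lists, or left at defaults.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    simulate = list(
      duration_s = 600, fs = 20, n_cells = 50,
      rest_rate = 1.71, run_rate = 2.79,
      rise_s = 0.5, decay_s = 1.0,
      amp_mean = 0.5, amp_sd = 0.1, noise_sd = 0.02,
      bout_mean_s = 12, n_bouts = 20,
      shared_fraction = 0, n_shared_pairs = 0,
      modulated_fraction = 0.25
    ),
    behavior = list(
      theta_deg = 78, fuzzy_a = 0.8, smooth_s = 1.5, frac_thresh = 0.10,
      min_bout_s = 2, c_floor = 5, c_quantile = 0.20,
      qc_min_state_s = 60, qc_min_run_bouts = 5
    ),
    events = list(
      power_band_hz = 2, window_s = 1, step_s = 0.05, nw = 2, k_tapers = 3,
      mad_k = 3, sd0 = 7, sd_decay = 0.40, win0_s = 10, win_growth = 0.75,
      min_rise_s = 0.15, method = "multitaper"
    ),
    modulation = list(n_shuffles = 1000, percentile = 97.5),
    connectivity = list(n_shuffles = 2000, percentile = 95, min_dist_px = 20,
                        scopes = c("rest", "run", "session")),
    network = list(log_base = "e"),
    stats = list(alpha = 0.05, posthoc = "gated"),
    seeds = list(simulation = 1L, modulation = 2L, correlation = 3L)
  )
  validate_config(utils::modifyList(defaults, list(...)), defaults = defaults)
}

#' Validate a pipeline configuration
#'
#' Injects defaults for missing keys, rejects unknown keys (strict mode) and
#' checks value ranges, naming the offending key in every error.
#'
#' @param config Possibly partial configuration list.
#' @param defaults Full default configuration (internal).
#' @return The completed, validated `pipeline_config`.
#' @export
validate_config <- function(config, defaults = NULL) {
  if (is.null(defaults)) defaults <- unclass(pipeline_config())
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("validate_config: unknown section(s): ", paste(unknown, collapse = ", "))
  }
  for (sec in names(config)) {
    bad <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
    if (length(bad)) {
      stop("validate_config: unknown key(s) in `", sec, "`: ",
           paste(bad, collapse = ", "))
    }
  }
  cfg <- utils::modifyList(defaults, config)
  chk_pos <- function(sec, key) {
    v <- cfg[[sec]][[key]]
    if (!is.numeric(v) || any(v <= 0)) {
      stop("validate_config: `", sec, "$", key, "` must be positive")
    }
  }
  for (key in c("duration_s", "fs", "n_cells")) chk_pos("simulate", key)
  for (key in c("fuzzy_a", "smooth_s", "min_bout_s")) chk_pos("behavior", key)
  for (key in c("n_shuffles", "percentile")) {
    chk_pos("modulation", key)
    chk_pos("connectivity", key)
  }
  if (cfg$behavior$theta_deg <= 0 || cfg$behavior$theta_deg >= 180) {
    stop("validate_config: `behavior$theta_deg` must lie in (0, 180)")
  }
  if (!cfg$network$log_base %in% c("e", "10")) {
    stop("validate_config: `network$log_base` must be \"e\" or \"10\"")
  }
  if (!all(cfg$connectivity$scopes %in% c("rest", "run", "session"))) {
    stop("validate_config: `connectivity$scopes` must be rest/run/session")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline on one (simulated) session
#'
#' Simulation -> bout segmentation -> session QC -> calcium event detection ->
#' binarization -> movement-modulation tests -> pairwise correlation tests per
#' scope -> state networks and closeness centrality -> session summary. When
#' `out_dir` is given, all tabular artifacts plus a manifest (parameters,
#' seeds, package version, MD5 of every written file) are written there;
#' reruns with identical configuration produce identical manifests.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @param simulation Optional pre-built `ca_simulation` (bypasses the simulate
#'   stage; its bout structure is used for segmentation ground truth).
#' @return A `ca1net_session` list with all intermediate and final results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         simulation = NULL) {
  cfg <- config
  scfg <- do.call(sim_config, c(cfg$simulate, list(seed = cfg$seeds$simulation)))
  if (is.null(simulation)) {
    sp <- simulate_speed(scfg)
    sim <- simulate_traces(scfg, sp$bouts)
    speed <- sp$speed
  } else {
    sim <- simulation
    sp <- NULL
    speed <- NULL
  }
  fs <- sim$fs
  if (is.null(speed)) {
    # reconstruct a speed trace from the simulation's planted bouts
    v <- numeric(nrow(sim$traces))
    for (k in seq_len(nrow(sim$truth$bouts))) {
      v[sim$truth$bouts$start[k]:sim$truth$bouts$end[k]] <- 12
    }
    speed <- speed_trace(v, fs = fs)
  }

  seg <- segment_bouts(speed, a = cfg$behavior$fuzzy_a,
                       smooth_s = cfg$behavior$smooth_s,
                       frac_thresh = cfg$behavior$frac_thresh,
                       min_s = cfg$behavior$min_bout_s,
                       c_floor = cfg$behavior$c_floor,
                       c_quantile = cfg$behavior$c_quantile)
  qc <- session_qc(seg, min_state_s = cfg$behavior$qc_min_state_s,
                   min_run_bouts = cfg$behavior$qc_min_run_bouts)
  kin <- bout_kinematics(speed, seg)

  ev_par <- do.call(detector_params, cfg$events)
  n_cells <- ncol(sim$traces)
  n <- nrow(sim$traces)
  events <- lapply(seq_len(n_cells), function(c) {
    detect_events(sim$traces[, c], fs = fs, params = ev_par)
  })
  trains <- vapply(events, binarize, integer(n), n_samples = n)
  event_rates <- list(
    session = mean(vapply(events, event_rate, numeric(1),
                          state = "session", n_samples = n, fs = fs)),
    rest = if (qc$eligible_for_locomotion_analysis) {
      mean(vapply(events, event_rate, numeric(1), seg = seg, state = "rest"))
    },
    run = if (qc$eligible_for_locomotion_analysis) {
      mean(vapply(events, event_rate, numeric(1), seg = seg, state = "run"))
    }
  )

  mod <- NULL
  modulated_fraction <- NA_real_
  if (qc$eligible_for_locomotion_analysis) {
    mod <- modulation_table(trains, seg,
                            n_shuffles = cfg$modulation$n_shuffles,
                            seed = cfg$seeds$modulation,
                            percentile = cfg$modulation$percentile)
    modulated_fraction <- mean(mod$is_modulated)
  }

  scopes <- cfg$connectivity$scopes
  if (!qc$eligible_for_locomotion_analysis) scopes <- intersect(scopes, "session")
  pair_results <- list()
  correlated_fraction <- list()
  mean_r <- list()
  for (scope in scopes) {
    pr <- classify_session(trains, seg, scope = scope,
                           centroids = sim$centroids,
                           n_shuffles = cfg$connectivity$n_shuffles,
                           seed = cfg$seeds$correlation,
                           percentile = cfg$connectivity$percentile,
                           min_dist_px = cfg$connectivity$min_dist_px)
    pair_results[[scope]] <- pr
    correlated_fraction[[scope]] <- attr(pr, "correlated_fraction")
    rc <- pr$r[pr$klass == "correlated"]
    mean_r[[scope]] <- if (length(rc)) mean(rc) else NA_real_
  }

  centrality <- list()
  cdiff <- NA_real_
  if (all(c("rest", "run") %in% names(pair_results))) {
    for (scope in c("rest", "run")) {
      g <- build_graph(pair_results[[scope]], n_cells = n_cells, state = scope)
      centrality[[scope]] <- closeness_centrality(g, log_base = cfg$network$log_base)
    }
    cdiff <- centrality_difference(centrality$rest, centrality$run)
  }

  subgroups <- NULL
  if (!is.null(mod) && "session" %in% names(pair_results)) {
    subgroups <- subgroup_means(pair_results$session, trains, seg,
                                mod$is_modulated)
  }

  out <- list(
    config = cfg, simulation = sim, speed = speed, seg = seg, qc = qc,
    kinematics = kin, events = events, trains = trains,
    event_rates = event_rates, modulation = mod,
    modulated_fraction = modulated_fraction, n_cells = n_cells,
    pairs = pair_results, correlated_fraction = correlated_fraction,
    mean_r = mean_r, subgroups = subgroups, centrality = centrality,
    centrality_difference = cdiff
  )
  class(out) <- "ca1net_session"
  if (!is.null(out_dir)) write_session(out, out_dir)
  out
}

#' @export
print.ca1net_session <- function(x, ...) {
  cat("CA1 pipeline session\n")
  cat(sprintf("  cells: %d; eligible for locomotion analysis: %s\n",
              x$n_cells, x$qc$eligible_for_locomotion_analysis))
  cat(sprintf("  mean event rate: %.2f events/min (session)\n",
              x$event_rates$session))
  if (is.finite(x$modulated_fraction)) {
    cat(sprintf("  movement-modulated cells: %.1f%%\n",
                100 * x$modulated_fraction))
  }
  for (scope in names(x$correlated_fraction)) {
    cat(sprintf("  correlated pair fraction [%s]: %.2f%%\n", scope,
                100 * x$correlated_fraction[[scope]]))
  }
  if (is.finite(x$centrality_difference)) {
    cat(sprintf("  rest - run network closeness: %.4f\n",
                x$centrality_difference))
  }
  invisible(x)
}

# Write all session artifacts plus a deterministic manifest.
write_session <- function(session, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  p <- function(f) file.path(out_dir, f)

  write_trace_table(session$simulation$traces, session$simulation$time_s,
                    p("traces.tsv"))
  files <- c(files, "traces.tsv")
  write_bout_table(session$seg, p("bouts.tsv"))
  files <- c(files, "bouts.tsv")

  ev <- do.call(rbind, lapply(seq_along(session$events), function(c) {
    e <- as.data.frame(session$events[[c]])
    if (nrow(e)) cbind(cell = c, e) else NULL
  }))
  if (is.null(ev)) {
    ev <- data.frame(cell = integer(0), t_on = integer(0), t_peak = integer(0),
                     amplitude = numeric(0), rise_s = numeric(0),
                     fwhm_s = numeric(0), fwhm_excluded_reason = character(0))
  }
  utils::write.table(ev, p("events.tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  files <- c(files, "events.tsv")

  if (!is.null(session$modulation)) {
    utils::write.table(session$modulation, p("modulation.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    files <- c(files, "modulation.tsv")
  }
  for (scope in names(session$pairs)) {
    f <- sprintf("pairs_%s.tsv", scope)
    utils::write.table(as.data.frame(session$pairs[[scope]]), p(f), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  for (scope in names(session$centrality)) {
    f <- sprintf("centrality_%s.tsv", scope)
    utils::write.table(session$centrality[[scope]]$nodes, p(f), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  manifest <- list(
    package = "ca1net",
    version = as.character(utils::packageVersion("ca1net")),
    seeds = session$config$seeds,
    parameters = session$config[setdiff(names(session$config), "seeds")],
    files = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  names(manifest$files) <- files
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
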