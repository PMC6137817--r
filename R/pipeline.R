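#' Normalized pre-reward lick histogram along the corridor
#'
#' Sums pre-reward (non-drinking) licks in position bins, split by gain and
#' cue condition, and scales each split so its maximum bin equals 100%.
#'
#' @param licks,trials session-bundle tables.
#' @param geometry a [task_geometry()].
#' @param bin_width bin width in cm (default 5).
#' @param reference `"virtual"` (default) or `"treadmill"` position of each
#'   lick.
#' @param split if `TRUE` (default) produce one histogram per
#'   (gain, cued) combination present; otherwise one pooled histogram.
#' @return data.frame with columns `gain`, `cued`, `bin_center`, `count`,
#'   `pct` (empty when there are no pre-reward licks).
#' @export
lick_histogram <- function(licks, trials, geometry, bin_width = 5,
                           reference = c("virtual", "treadmill"),
                           split = TRUE) {
  reference <- match.arg(reference)
  pre <- licks[!licks$drinking, , drop = FALSE]
  empty <- data.frame(gain = numeric(0), cued = logical(0),
                      bin_center = numeric(0), count = integer(0),
                      pct = numeric(0))
  if (nrow(pre) == 0L) return(empty)
  idx <- match(pre$trial_id, trials$trial_id)
  pre$gain <- trials$gain[idx]
  pre$cued <- trials$cued[idx]
  pos <- if (reference == "virtual") pre$virtual_cm else pre$treadmill_cm
  max_pos <- geometry$corridor_length / min(trials$gain)
  edges <- seq(0, ceiling(max_pos / bin_width) * bin_width, by = bin_width)
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  groups <- if (split) split(seq_len(nrow(pre)),
                             interaction(pre$gain, pre$cued, drop = TRUE))
  else list(all = seq_len(nrow(pre)))
  out <- lapply(groups, function(ii) {
    counts <- tabulate(findInterval(pos[ii], edges), length(centers))
    data.frame(gain = pre$gain[ii[1L]], cued = pre$cued[ii[1L]],
               bin_center = centers, count = counts,
               pct = if (max(counts) > 0) 100 * counts / max(counts) else
                 counts * 0)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

default_run_config <- function() {
  list(
    geometry = list(),
    calcium = list(),
    population = list(corridor = 6, locomotion = 6, lick = 6,
                      reward_zone = 6, untuned = 6),
    analysis = list(n_permutations = 1000, alpha = 0.001, width_cm = 20,
                    speed_r_min = 0.3, lick_alpha = 0.001),
    days = list(
      list(name = "novice", policy = list(mode = "uniform"), n_trials = 40,
           tuning_scale = 0.25),
      list(name = "mid", policy = list(mode = "expert", target_sd = 15),
           n_trials = 40, tuning_scale = 0.6),
      list(name = "expert", policy = list(mode = "expert", target_sd = 6),
           n_trials = 40, tuning_scale = 1)),
    seed = 1)
}

#' Read a run configuration from YAML or JSON
#'
#' Missing keys fall back to the package defaults (see
#' [run_experiment()]).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a config list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  merge_config(default_run_config(), cfg)
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]) &&
        !is.null(names(user[[k]])) && k != "days") {
      base[[k]] <- merge_config(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Run a multi-day simulated experiment end to end
#'
#' For each configured day: simulate a session (lick policy and
#' tuning-strength schedule emulate learning), extract dF/F0, compute
#' behaviour metrics (success rate, SMI), classify every neuron, and run
#' the outcome decoder (plus the cue decoder when both cue conditions have
#' enough successful trials). The per-day neuron population is the shared
#' `population` spec with `peak_rate` scaled by the day's `tuning_scale`,
#' emulating learning-related recruitment of task-coupled activity.
#'
#' Fully deterministic given the config and its `seed`: day `d` uses seed
#' `seed + 101 * d` for the simulation and `seed + 101 * d + 50` for the
#' SMI permutations and decoder subsampling.
#'
#' @param config nested list as produced by [read_run_config()]; omitted
#'   keys use package defaults.
#' @return an object of class `experiment_summary`: list with `summary`
#'   (per-day data.frame), `days` (per-day detail: session, behavior
#'   report, label table, decoder reports, lick histograms), `config`.
#' @export
run_experiment <- function(config = list()) {
  cfg <- merge_config(default_run_config(), config)
  if (length(cfg$days) == 0L) fail("run_experiment: schedule non-empty")
  geometry <- do.call(task_geometry, cfg$geometry)
  calcium <- do.call(calcium_model, cfg$calcium)
  an <- cfg$analysis
  base_seed <- as.integer(cfg$seed)

  days <- vector("list", length(cfg$days))
  rows <- vector("list", length(cfg$days))
  for (d in seq_along(cfg$days)) {
    day <- cfg$days[[d]]
    if (is.null(day$n_trials) || day$n_trials < 1) {
      fail("run_experiment halted at stage 'simulate' (day ", d,
           "): invalid trial count")
    }
    pop_cfg <- day$population %||% cfg$population
    specs <- do.call(neuron_population, pop_cfg)
    scale <- day$tuning_scale %||% 1
    specs <- lapply(specs, function(s) {
      s$peak_rate <- s$peak_rate * scale
      s
    })
    policy <- do.call(lick_policy, day$policy %||% list(mode = "uniform"))
    sim_seed <- base_seed + 101L * d
    session <- simulate_session(geometry, policy, specs, calcium,
                                day$n_trials, seed = sim_seed)
    dff <- compute_dff(session$fluor, calcium$frame_rate)
    behavior <- compute_smi(session$trials, session$licks, geometry,
                            n_permutations = an$n_permutations,
                            seed = sim_seed + 50L)
    labels <- classify_neurons(session, dff, width_cm = an$width_cm,
                               alpha = an$alpha,
                               speed_r_min = an$speed_r_min,
                               lick_alpha = an$lick_alpha,
                               seed = sim_seed + 51L)
    dec_outcome <- tryCatch(
      decode_outcome(session, dff, seed = sim_seed + 52L),
      error = function(e) NULL)
    dec_cue <- tryCatch(
      decode_cue_type(session, dff, seed = sim_seed + 53L),
      error = function(e) NULL)
    hists <- lick_histogram(session$licks, session$trials, geometry)

    days[[d]] <- list(name = day$name %||% paste0("day", d),
                      session = session, behavior = behavior,
                      labels = labels, decoder_outcome = dec_outcome,
                      decoder_cue = dec_cue, lick_histograms = hists)
    rows[[d]] <- data.frame(
      day = d, name = days[[d]]$name, n_trials = nrow(session$trials),
      success_rate = behavior$success_rate, smi = behavior$smi,
      frac_task_responsive = mean(labels$task_responsive, na.rm = TRUE),
      decoder_outcome_acc =
        if (is.null(dec_outcome)) NA_real_ else dec_outcome$accuracy,
      decoder_cue_acc =
        if (is.null(dec_cue)) NA_real_ else dec_cue$accuracy)
  }
  structure(list(summary = do.call(rbind, rows), days = days,
                 config = cfg),
            class = "experiment_summary")
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat("Simulated corridor-task experiment\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
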