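#' Virtual-corridor task geometry
#'
#' Describes the linear corridor used in the visually guided reward task.
#' Distances are in centimetres of *virtual* corridor unless stated otherwise.
#' The reward zone starts at `reward_zone_onset`; a lick within the early
#' window `[reward_zone_onset, early_window_end)` triggers an early reward at
#' the lick position, otherwise a default reward is dispensed at
#' `default_reward_pos` (which must equal `early_window_end`).
#'
#' Cue and gain manipulations are scheduled cyclically: every
#' `uncued_period`-th trial has its reward-zone landmark removed (uncued), and
#' within each cue class every `gain_period`-th trial runs at the reduced gain
#' `gain_low` (virtual distance = gain x treadmill distance). Gain cycling
#' within cue class (rather than on the global trial index) guarantees that
#' all four cue-by-gain combinations occur while keeping the overall one-in-k
#' rate. A period of `0` disables the manipulation.
#'
#' @param corridor_length total virtual corridor length (cm).
#' @param reward_zone_onset virtual position where the reward zone begins (cm).
#' @param early_window_end end of the early-reward window (cm).
#' @param default_reward_pos position of the default reward (cm); must equal
#'   `early_window_end`.
#' @param gain_low the reduced treadmill-to-virtual gain used on
#'   gain-manipulated trials (in (0, 1]).
#' @param uncued_period every `uncued_period`-th trial is uncued (0 = never).
#' @param gain_period every `gain_period`-th trial of each cue class runs at
#'   `gain_low` (0 = never).
#' @return an object of class `task_geometry`.
#' @export
#' @examples
#' g <- task_geometry()
#' g$reward_zone_onset
task_geometry <- function(corridor_length = 120,
                          reward_zone_onset = 80,
                          early_window_end = 100,
                          default_reward_pos = 100,
                          gain_low = 0.75,
                          uncued_period = 5,
                          gain_period = 5) {
  g <- list(corridor_length = corridor_length,
            reward_zone_onset = reward_zone_onset,
            early_window_end = early_window_end,
            default_reward_pos = default_reward_pos,
            gain_low = gain_low,
            uncued_period = as.integer(uncued_period),
            gain_period = as.integer(gain_period))
  class(g) <- "task_geometry"
  validate_geometry(g)
  g
}

validate_geometry <- function(g) {
  if (!(g$reward_zone_onset > 0)) fail("reward_zone_onset must be > 0")
  if (!(g$reward_zone_onset < g$early_window_end)) {
    fail("reward_zone_onset must be < early_window_end")
  }
  if (!(g$early_window_end <= g$corridor_length)) {
    fail("early_window_end must be <= corridor_length")
  }
  if (g$default_reward_pos != g$early_window_end) {
    fail("default_reward_pos must equal early_window_end")
  }
  if (!(g$gain_low > 0 && g$gain_low <= 1)) fail("gain_low must be in (0, 1]")
  if (g$uncued_period < 0 || g$gain_period < 0) fail("periods must be >= 0")
  invisible(g)
}

#' @export
print.task_geometry <- function(x, ...) {
  cat("Virtual-corridor task geometry\n")
  cat(sprintf("  corridor length     : %g cm\n", x$corridor_length))
  cat(sprintf("  reward zone onset   : %g cm\n", x$reward_zone_onset))
  cat(sprintf("  early window        : [%g, %g) cm\n",
              x$reward_zone_onset, x$early_window_end))
  cat(sprintf("  default reward      : %g cm\n", x$default_reward_pos))
  cat(sprintf("  reduced gain        : %g (1 in %d trials per cue class)\n",
              x$gain_low, x$gain_period))
  cat(sprintf("  uncued trials       : 1 in %d\n", x$uncued_period))
  invisible(x)
}

#' Licking policy for the synthetic session generator
#'
#' Controls where the simulated animal licks before the reward. The expected
#' number of pre-reward licks per trial is `rate * default_reward_pos`
#' (`rate` is in licks per cm of pre-reward corridor), drawn Poisson.
#'
#' Modes:
#' \describe{
#'   \item{`uniform` / `novice`}{lick positions uniform on
#'     `[0, default_reward_pos)` virtual cm — spatially indiscriminate
#'     licking, as seen on early training days.}
#'   \item{`expert`}{a fraction `1 - stray_frac` of licks is Gaussian around
#'     `target_center` with SD `target_sd`; the rest are stray licks uniform
#'     over the pre-reward corridor (residual novice-like licking, which
#'     also provides the off-zone lick events needed by the lick-response
#'     control analysis). On cued trials the target is anchored in virtual
#'     coordinates (the animal follows the landmark); on uncued trials it is
#'     anchored in the frame named by `uncued_frame` (default `"treadmill"`,
#'     emulating path integration from self-motion).}
#'   \item{`confined_off_target`}{frequent licking uniform on
#'     `[0, reward_zone_onset - 20)` cm — misses the reward zone entirely.}
#' }
#'
#' @param mode one of `"expert"`, `"novice"`, `"uniform"`,
#'   `"confined_off_target"`.
#' @param rate licks per cm of pre-reward corridor (>= 0). Default depends on
#'   mode: 0.03 for expert (about 3 licks/trial), 0.08 otherwise.
#' @param target_center centre of expert licking (cm in the anchor frame).
#' @param target_sd SD of expert licking (cm, > 0).
#' @param uncued_frame coordinate frame anchoring expert licks on uncued
#'   trials: `"treadmill"` or `"virtual"`.
#' @param stray_frac fraction of expert licks drawn uniformly over the
#'   pre-reward corridor instead of from the target Gaussian (default 0.1).
#' @return an object of class `lick_policy`.
#' @export
lick_policy <- function(mode = c("expert", "novice", "uniform",
                                 "confined_off_target"),
                        rate = NULL,
                        target_center = 86,
                        target_sd = 6,
                        uncued_frame = c("treadmill", "virtual"),
                        stray_frac = 0.1) {
  mode <- match.arg(mode)
  uncued_frame <- match.arg(uncued_frame)
  if (is.null(rate)) rate <- if (mode == "expert") 0.05 else 0.08
  if (!is.numeric(rate) || rate < 0) fail("rate must be >= 0")
  if (mode == "expert" && !(target_sd > 0)) {
    fail("target_sd must be > 0 for expert mode")
  }
  if (stray_frac < 0 || stray_frac > 1) fail("stray_frac must be in [0, 1]")
  structure(list(mode = mode, rate = rate, target_center = target_center,
                 target_sd = target_sd, uncued_frame = uncued_frame,
                 stray_frac = stray_frac),
            class = "lick_policy")
}

#' Planted tuning specification for one synthetic neuron
#'
#' Each neuron is an inhomogeneous-Poisson event source whose rate function
#' depends on its category:
#' \describe{
#'   \item{`corridor`}{drives on the grating wall pattern: active at
#'     `virtual < reward_zone_onset` on cued trials and along the whole
#'     corridor on uncued trials (where the landmark is absent and the
#'     grating continues).}
#'   \item{`locomotion`}{rate proportional to running speed.}
#'   \item{`lick`}{transient rate increase around every lick.}
#'   \item{`reward_zone`}{Gaussian rate bump inside the reward zone
#'     (virtual frame), present on cued and uncued trials alike.}
#'   \item{`grating_offset`}{responds at the grating-to-black transition,
#'     cued trials only (an "off" response; no transition exists uncued).}
#'   \item{`gain_anchored_treadmill`}{Gaussian bump at `anchor_pos` cm of
#'     treadmill (physical) distance, independent of gain.}
#'   \item{`gain_anchored_virtual`}{Gaussian bump at `anchor_pos` cm of
#'     virtual distance.}
#'   \item{`time_locked`}{Gaussian bump at `anchor_pos` *seconds* from trial
#'     start (used for distance-vs-time consistency checks).}
#'   \item{`untuned`}{baseline rate only.}
#' }
#'
#' @param category tuning category (see Details).
#' @param peak_rate event-rate amplitude above baseline (events/s).
#' @param anchor_pos tuning anchor (cm; seconds for `time_locked`).
#' @param anchor_frame `"virtual"` or `"treadmill"` (informational for most
#'   categories; the gain-anchored categories fix it by name).
#' @param baseline_rate baseline event rate (events/s).
#' @param tuning_sd SD of Gaussian spatial/temporal bumps (cm, or s for
#'   `time_locked`).
#' @return an object of class `neuron_spec` (a one-row list).
#' @export
neuron_spec <- function(category = c("untuned", "corridor", "locomotion",
                                     "lick", "reward_zone", "grating_offset",
                                     "gain_anchored_treadmill",
                                     "gain_anchored_virtual", "time_locked"),
                        peak_rate = 8,
                        anchor_pos = 80,
                        anchor_frame = c("virtual", "treadmill"),
                        baseline_rate = 0.3,
                        tuning_sd = 6) {
  category <- match.arg(category)
  anchor_frame <- match.arg(anchor_frame)
  if (peak_rate < 0 || baseline_rate < 0) fail("rates must be >= 0")
  if (!(tuning_sd > 0)) fail("tuning_sd must be > 0")
  structure(list(category = category, peak_rate = peak_rate,
                 anchor_pos = anchor_pos, anchor_frame = anchor_frame,
                 baseline_rate = baseline_rate, tuning_sd = tuning_sd),
            class = "neuron_spec")
}

#' Build a population of neuron specs from per-category counts
#'
#' @param ... named integer counts, e.g. `corridor = 8, untuned = 4`.
#' @param peak_rate,baseline_rate,tuning_sd shared spec parameters.
#' @return a list of [neuron_spec()] objects.
#' @export
#' @examples
#' pop <- neuron_population(corridor = 2, reward_zone = 2, untuned = 1)
#' length(pop)
neuron_population <- function(..., peak_rate = 8, baseline_rate = 0.3,
                              tuning_sd = 6) {
  counts <- list(...)
  if (length(counts) == 0L) return(list())
  specs <- list()
  for (cat in names(counts)) {
    n <- counts[[cat]]
    for (i in seq_len(n)) {
      specs[[length(specs) + 1L]] <-
        neuron_spec(category = cat, peak_rate = peak_rate,
                    baseline_rate = baseline_rate, tuning_sd = tuning_sd)
    }
  }
  specs
}

#' Calcium-indicator forward model
#'
#' Event trains are convolved with a single-exponential kernel
#' (GCaMP6f-like decay) and scaled onto a baseline fluorescence:
#' `F = baseline_F * (1 + amplitude_per_event * s) + noise`, where `s` is the
#' kernel-convolved event count.
#'
#' @param frame_rate imaging frame rate (Hz).
#' @param decay_tau indicator decay time constant (s).
#' @param amplitude_per_event dF/F0 contributed by one event at its peak.
#' @param baseline_F baseline fluorescence (arbitrary units, > 0).
#' @param noise_sd Gaussian noise SD (same units as `baseline_F`).
#' @return an object of class `calcium_model`.
#' @export
calcium_model <- function(frame_rate = 40, decay_tau = 0.4,
                          amplitude_per_event = 0.2, baseline_F = 100,
                          noise_sd = 1.5) {
  if (!is_pos_num(frame_rate)) fail("frame_rate must be > 0")
  if (!is_pos_num(decay_tau)) fail("decay_tau must be > 0")
  if (!is_pos_num(baseline_F)) fail("baseline_F must be > 0")
  if (noise_sd < 0) fail("noise_sd must be >= 0")
  structure(list(frame_rate = frame_rate, decay_tau = decay_tau,
                 amplitude_per_event = amplitude_per_event,
                 baseline_F = baseline_F, noise_sd = noise_sd),
            class = "calcium_model")
}
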