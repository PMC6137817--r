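#' Simulate one behavioural + imaging session
#'
#' Generates a complete session bundle: per-frame behaviour (time, treadmill
#' and virtual position, speed, lick flag), per-trial records (cue flag, gain,
#' reward event), lick events, a raw fluorescence matrix produced by passing
#' planted event-rate functions through the calcium forward model, and the
#' ground-truth neuron specs.
#'
#' Within each trial, positions start at 0 and `virtual = gain * treadmill`.
#' The per-trial mean running speed is drawn log-normally (median 15 cm/s,
#' sdlog 0.4), modulated by a smooth within-trial oscillation and by a
#' slowdown once the animal enters the reward zone (mice decelerate to lick).
#' The reward rule is applied exactly: the first lick whose virtual position
#' falls in `[reward_zone_onset, early_window_end)` triggers an early reward
#' at that position; otherwise a default reward is dispensed at
#' `default_reward_pos`. A burst of post-reward drinking licks is generated
#' and flagged `drinking` so behavioural metrics can exclude them.
#'
#' @param geometry a [task_geometry()].
#' @param policy a [lick_policy()].
#' @param neuron_specs list of [neuron_spec()] (may be empty).
#' @param calcium a [calcium_model()].
#' @param n_trials number of trials (>= 1).
#' @param seed integer seed; the bundle is bit-identical given the same seed.
#' @return an object of class `session_bundle`: a list with elements
#'   `frames` (data.frame), `trials` (data.frame), `licks` (data.frame),
#'   `fluor` (neurons x frames matrix of raw F), `clean` (the noise-free
#'   dF/F0 signal, i.e. the event train convolved with the indicator kernel
#'   before baseline scaling and noise), `rates` (noise-free planted
#'   event-rate matrix, events/s), `ground_truth` (data.frame),
#'   `geometry`, `policy`, `calcium`, `seed`.
#' @export
#' @examples
#' s <- simulate_session(task_geometry(), lick_policy("uniform"),
#'                       neuron_population(untuned = 2), calcium_model(),
#'                       n_trials = 3, seed = 1)
#' s$trials$reward_type
simulate_session <- function(geometry, policy, neuron_specs, calcium,
                             n_trials, seed) {
  stopifnot(inherits(geometry, "task_geometry"),
            inherits(policy, "lick_policy"),
            inherits(calcium, "calcium_model"))
  if (!is.numeric(n_trials) || length(n_trials) != 1L || is.na(n_trials) ||
      n_trials < 1) {
    fail("invalid trial count")
  }
  n_trials <- as.integer(n_trials)

  with_seed(seed, {
    dt <- 1 / calcium$frame_rate
    frames_l <- vector("list", n_trials)
    trials_l <- vector("list", n_trials)
    licks_l <- vector("list", n_trials)
    t0 <- 0
    frame0 <- 0L
    n_cued_seen <- 0L
    n_uncued_seen <- 0L
    for (i in seq_len(n_trials)) {
      cued <- !(geometry$uncued_period > 0 &&
                  i %% geometry$uncued_period == 0L)
      if (cued) n_cued_seen <- n_cued_seen + 1L else
        n_uncued_seen <- n_uncued_seen + 1L
      idx_in_class <- if (cued) n_cued_seen else n_uncued_seen
      gain <- if (geometry$gain_period > 0 &&
                    idx_in_class %% geometry$gain_period == 0L) {
        geometry$gain_low
      } else 1
      tr <- simulate_trial(i, gain, cued, geometry, policy, dt, t0, frame0)
      frames_l[[i]] <- tr$frames
      trials_l[[i]] <- tr$trial
      licks_l[[i]] <- tr$licks
      t0 <- tr$frames$time_s[nrow(tr$frames)] + dt
      frame0 <- frame0 + nrow(tr$frames)
    }
    frames <- do.call(rbind, frames_l)
    trials <- do.call(rbind, trials_l)
    licks <- do.call(rbind, licks_l)
    rownames(frames) <- rownames(trials) <- rownames(licks) <- NULL

    gt <- ground_truth_table(neuron_specs)
    rates <- planted_rates(neuron_specs, frames, trials, licks, geometry)
    fw <- calcium_forward(rates, calcium)

    bundle <- structure(
      list(frames = frames, trials = trials, licks = licks,
           fluor = fw$fluor, clean = fw$clean, rates = rates,
           ground_truth = gt, geometry = geometry, policy = policy,
           calcium = calcium, seed = as.integer(seed)),
      class = "session_bundle")
    bundle
  })
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("Session bundle: %d trials, %d neurons, %d frames (%.1f Hz)\n",
              nrow(x$trials), nrow(x$fluor), nrow(x$frames),
              x$calcium$frame_rate))
  cat(sprintf("  early rewards: %d/%d; uncued trials: %d; gain-%.2f trials: %d\n",
              sum(x$trials$reward_type == "early"), nrow(x$trials),
              sum(!x$trials$cued), x$geometry$gain_low,
              sum(x$trials$gain < 1)))
  invisible(x)
}

# One corridor traversal. Positions reset to zero; integration at frame rate.
simulate_trial <- function(id, gain, cued, geometry, policy, dt, t0, frame0) {
  L_virt <- geometry$corridor_length
  onset <- geometry$reward_zone_onset

  v_base <- stats::rlnorm(1, log(15), 0.4)
  phase <- stats::runif(1, 0, 2 * pi)
  period <- stats::runif(1, 3, 6)

  max_frames <- ceiling((L_virt / gain) / (0.25 * v_base) / dt) + 200L
  tread <- numeric(max_frames)
  speed <- numeric(max_frames)
  pos <- 0
  n <- 0L
  t_rel <- 0
  while (gain * pos < L_virt && n < max_frames) {
    n <- n + 1L
    slow <- if (gain * pos >= onset) 0.55 else 1
    v <- v_base * (1 + 0.3 * sin(2 * pi * t_rel / period + phase)) * slow
    v <- max(v, 2)
    tread[n] <- pos
    speed[n] <- v
    pos <- pos + v * dt
    t_rel <- t_rel + dt
  }
  tread <- tread[seq_len(n)]
  speed <- speed[seq_len(n)]
  virt <- gain * tread
  time_s <- t0 + (seq_len(n) - 1L) * dt

  # pre-reward licks in virtual coordinates
  lick_virt <- draw_lick_positions(policy, gain, cued, geometry)
  lick_virt <- sort(lick_virt)

  in_window <- lick_virt >= onset & lick_virt < geometry$early_window_end
  if (any(in_window)) {
    reward_type <- "early"
    reward_virt <- lick_virt[which(in_window)[1L]]
  } else {
    reward_type <- "default"
    reward_virt <- geometry$default_reward_pos
  }
  # licks after the reward event are replaced by the drinking burst
  lick_virt <- lick_virt[lick_virt <= reward_virt]

  frame_at_virt <- function(p) {
    j <- findInterval(p, virt)  # last frame with virt <= p
    max(1L, min(n, j))
  }
  reward_frame <- frame_at_virt(reward_virt)
  reward_time <- time_s[reward_frame]

  lick_frames <- vapply(lick_virt, frame_at_virt, integer(1))
  # drinking burst after reward delivery
  n_drink <- stats::rpois(1, 6)
  drink_times <- reward_time + sort(stats::runif(n_drink, 0.1, 1.5))
  drink_frames <- pmin(n, findInterval(drink_times, time_s))
  drink_frames <- drink_frames[drink_frames >= 1L]

  lk <- data.frame(
    trial_id = id,
    time_s = c(time_s[lick_frames], time_s[drink_frames]),
    virtual_cm = c(lick_virt, virt[drink_frames]),
    treadmill_cm = c(if (gain > 0) lick_virt / gain else lick_virt * 0,
                     tread[drink_frames]),
    drinking = c(rep(FALSE, length(lick_frames)),
                 rep(TRUE, length(drink_frames))))

  lick_flag <- integer(n)
  lick_flag[unique(c(lick_frames, drink_frames))] <- 1L

  fr <- data.frame(time_s = time_s, trial_id = id, treadmill_cm = tread,
                   virtual_cm = virt, speed_cm_s = speed, lick = lick_flag)
  trial <- data.frame(trial_id = id, gain = gain, cued = cued,
                      reward_type = reward_type,
                      reward_virtual_cm = reward_virt,
                      reward_treadmill_cm = reward_virt / gain,
                      reward_time_s = reward_time,
                      start_frame = frame0 + 1L,
                      end_frame = frame0 + n)
  list(frames = fr, trial = trial, licks = lk)
}

# Pre-reward lick positions (virtual cm) for one trial.
draw_lick_positions <- function(policy, gain, cued, geometry) {
  lambda <- policy$rate * geometry$default_reward_pos
  k <- stats::rpois(1, lambda)
  if (k == 0L) return(numeric(0))
  switch(policy$mode,
    uniform = ,
    novice = stats::runif(k, 0, geometry$default_reward_pos),
    confined_off_target = stats::runif(
      k, 0, max(1, geometry$reward_zone_onset - 20)),
    expert = {
      frame <- if (cued) "virtual" else policy$uncued_frame
      stray <- stats::runif(k) < policy$stray_frac
      p <- stats::rnorm(k, policy$target_center, policy$target_sd)
      if (frame == "treadmill") p <- p * gain
      p[stray] <- stats::runif(sum(stray), 0, geometry$default_reward_pos)
      pmin(pmax(p, 0.5), geometry$corridor_length - 0.5)
    })
}

#' Build a trial table directly from per-trial lick positions
#'
#' Applies the task's reward rule to caller-supplied pre-reward lick
#' positions, producing `trials` and `licks` tables consumable by
#' [success_rate()] and [compute_smi()] without simulating a full session.
#' All supplied licks are treated as recorded pre-reward licks.
#'
#' @param lick_positions list (one element per trial) of numeric virtual lick
#'   positions in cm.
#' @param geometry a [task_geometry()].
#' @param gain,cued scalars or vectors recycled over trials.
#' @return a list with `trials` and `licks` data.frames in the session-bundle
#'   layout.
#' @export
#' @examples
#' tl <- trials_from_licks(list(c(85, 40), c(10, 20)), task_geometry())
#' tl$trials$reward_type
trials_from_licks <- function(lick_positions, geometry, gain = 1,
                              cued = TRUE) {
  n <- length(lick_positions)
  if (n < 1) fail("no trials")
  gain <- rep_len(gain, n)
  cued <- rep_len(cued, n)
  trials <- vector("list", n)
  licks <- vector("list", n)
  for (i in seq_len(n)) {
    p <- sort(lick_positions[[i]])
    hit <- p >= geometry$reward_zone_onset & p < geometry$early_window_end
    if (any(hit)) {
      rtype <- "early"
      rpos <- p[which(hit)[1L]]
    } else {
      rtype <- "default"
      rpos <- geometry$default_reward_pos
    }
    trials[[i]] <- data.frame(trial_id = i, gain = gain[i], cued = cued[i],
                              reward_type = rtype, reward_virtual_cm = rpos,
                              reward_treadmill_cm = rpos / gain[i],
                              reward_time_s = NA_real_,
                              start_frame = NA_integer_,
                              end_frame = NA_integer_)
    licks[[i]] <- if (length(p)) {
      data.frame(trial_id = i, time_s = NA_real_, virtual_cm = p,
                 treadmill_cm = p / gain[i], drinking = FALSE)
    } else NULL
  }
  lk <- do.call(rbind, licks)
  if (is.null(lk)) {
    lk <- data.frame(trial_id = integer(0), time_s = numeric(0),
                     virtual_cm = numeric(0), treadmill_cm = numeric(0),
                     drinking = logical(0))
  }
  list(trials = do.call(rbind, trials), licks = lk)
}

#' Ground-truth table from a list of neuron specs
#' @noRd
ground_truth_table <- function(neuron_specs) {
  if (length(neuron_specs) == 0L) {
    return(data.frame(neuron_id = integer(0), category = character(0),
                      peak_rate = numeric(0), anchor_pos = numeric(0),
                      anchor_frame = character(0), baseline_rate = numeric(0),
                      tuning_sd = numeric(0)))
  }
  do.call(rbind, lapply(seq_along(neuron_specs), function(i) {
    s <- neuron_specs[[i]]
    data.frame(neuron_id = i, category = s$category, peak_rate = s$peak_rate,
               anchor_pos = s$anchor_pos, anchor_frame = s$anchor_frame,
               baseline_rate = s$baseline_rate, tuning_sd = s$tuning_sd)
  }))
}

#' Noise-free planted event-rate functions
#'
#' Evaluates each spec's deterministic rate function (events/s) on the given
#' frames. Exposed so tests can verify tuning anchors on noise-free rates.
#'
#' @param neuron_specs list of [neuron_spec()].
#' @param frames,trials,licks session-bundle tables.
#' @param geometry a [task_geometry()].
#' @return neurons x frames matrix (0 x frames when `neuron_specs` is empty).
#' @export
planted_rates <- function(neuron_specs, frames, trials, licks, geometry) {
  nf <- nrow(frames)
  rates <- matrix(0, nrow = length(neuron_specs), ncol = nf)
  if (length(neuron_specs) == 0L) return(rates)

  cued_by_trial <- stats::setNames(trials$cued, trials$trial_id)
  cued_f <- unname(cued_by_trial[as.character(frames$trial_id)])
  tstart <- stats::setNames(
    frames$time_s[match(trials$trial_id, frames$trial_id)], trials$trial_id)
  t_in_trial <- frames$time_s -
    unname(tstart[as.character(frames$trial_id)])

  real_licks <- licks$time_s[is.finite(licks$time_s)]
  lick_near <- rep(FALSE, nf)
  if (length(real_licks)) {
    idx <- findInterval(frames$time_s, sort(real_licks))
    srt <- sort(real_licks)
    lo <- c(-Inf, srt)[idx + 1L]
    hi <- c(srt, Inf)[idx + 1L]
    lick_near <- pmin(frames$time_s - lo, hi - frames$time_s) <= 0.1
  }

  onset <- geometry$reward_zone_onset
  for (i in seq_along(neuron_specs)) {
    s <- neuron_specs[[i]]
    base <- s$baseline_rate
    pk <- s$peak_rate
    sd2 <- 2 * s$tuning_sd^2
    r <- switch(s$category,
      untuned = rep(base, nf),
      corridor = {
        grating <- ifelse(cued_f, frames$virtual_cm < onset, TRUE)
        base + pk * as.numeric(grating)
      },
      locomotion = base + pk * pmin(frames$speed_cm_s / 15, 2),
      lick = base + pk * as.numeric(lick_near),
      reward_zone = base +
        pk * exp(-(frames$virtual_cm - (onset + 10))^2 / sd2),
      grating_offset = base + pk * as.numeric(cued_f) *
        exp(-(frames$virtual_cm - onset)^2 / sd2),
      gain_anchored_treadmill = base +
        pk * exp(-(frames$treadmill_cm - s$anchor_pos)^2 / sd2),
      gain_anchored_virtual = base +
        pk * exp(-(frames$virtual_cm - s$anchor_pos)^2 / sd2),
      time_locked = base +
        pk * exp(-(t_in_trial - s$anchor_pos)^2 / (2 * 0.5^2)))
    rates[i, ] <- r
  }
  rates
}

#' Calcium forward model: rates -> raw fluorescence (+ noise-free dF/F0)
#' @noRd
calcium_forward <- function(rates, calcium) {
  n <- nrow(rates)
  nf <- ncol(rates)
  if (n == 0L) {
    z <- matrix(numeric(0), nrow = 0, ncol = nf)
    return(list(fluor = z, clean = z))
  }
  dt <- 1 / calcium$frame_rate
  events <- matrix(stats::rpois(n * nf, lambda = pmax(rates, 0) * dt),
                   nrow = n)
  decay <- exp(-dt / calcium$decay_tau)
  fluor <- matrix(0, nrow = n, ncol = nf)
  clean <- matrix(0, nrow = n, ncol = nf)
  for (i in seq_len(n)) {
    s <- as.numeric(stats::filter(events[i, ], decay, method = "recursive"))
    clean[i, ] <- calcium$amplitude_per_event * s
    fluor[i, ] <- calcium$baseline_F * (1 + clean[i, ]) +
      stats::rnorm(nf, 0, calcium$noise_sd)
  }
  # raw F must stay positive for dF/F0 extraction
  list(fluor = pmax(fluor, 1e-3), clean = clean)
}
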