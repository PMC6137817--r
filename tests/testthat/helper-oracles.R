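# Independent oracles and small fixture builders shared across test files.
# Oracles are deliberately naive (enumeration / brute-force loops) and do not
# reuse package internals.

# Exact paired signed-rank p-value by full enumeration of the 2^n sign
# assignments (assumes no zero differences and no tied |d|).
enum_signed_rank_p <- function(d, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  n <- length(d)
  stopifnot(n <= 15, all(d != 0), !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  if (alternative == "greater") p_ge else min(1, 2 * min(p_ge, p_le))
}

# Brute-force per-bin mean by an explicit frame loop.
brute_bin_means <- function(values, positions, bin_edges) {
  nb <- length(bin_edges) - 1L
  out <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    acc <- c()
    for (i in seq_along(values)) {
      if (positions[i] >= bin_edges[b] && positions[i] < bin_edges[b + 1L]) {
        acc <- c(acc, values[i])
      }
    }
    if (length(acc)) out[b] <- mean(acc)
  }
  out
}

# Closed-form permutation-null success probability for a trial with k licks
# re-placed uniformly on [0, L): 1 - (1 - w/L)^k.
null_success_prob <- function(k, w, L) 1 - (1 - w / L)^k

# Default small-world pieces.
default_geom <- function(...) task_geometry(...)

quick_session <- function(specs, n_trials = 20, seed = 1,
                          policy = lick_policy("expert"),
                          geometry = task_geometry(),
                          calcium = calcium_model()) {
  simulate_session(geometry, policy, specs, calcium, n_trials, seed)
}

# Shared recovery-world session: transitional expert licking (focused on the
# reward zone with residual stray licks, so the lick-response control has
# qualifying events), uncued trials present, no gain manipulation.
recovery_session <- function(seed = 11) {
  quick_session(
    neuron_population(corridor = 5, locomotion = 5, lick = 5,
                      reward_zone = 5, grating_offset = 4, untuned = 5),
    n_trials = 75, seed = seed,
    policy = lick_policy("expert", rate = 0.06, stray_frac = 0.15),
    geometry = task_geometry(gain_period = 0))
}

# Deterministic hand-built session (equal-duration trials, constant speed);
# exercises functions that only need frames/trials/geometry fields.
toy_session <- function(n_trials = 12, speed = 15, frame_rate = 40,
                        geometry = task_geometry()) {
  dt <- 1 / frame_rate
  frames <- NULL
  trials <- NULL
  t0 <- 0
  f0 <- 0L
  for (i in seq_len(n_trials)) {
    pos <- seq(0, geometry$corridor_length - 1e-9, by = speed * dt)
    n <- length(pos)
    frames <- rbind(frames, data.frame(
      time_s = t0 + (seq_len(n) - 1) * dt, trial_id = i,
      treadmill_cm = pos, virtual_cm = pos,
      speed_cm_s = speed, lick = 0L))
    trials <- rbind(trials, data.frame(
      trial_id = i, gain = 1, cued = TRUE, reward_type = "default",
      reward_virtual_cm = geometry$default_reward_pos,
      reward_time_s = t0 + geometry$default_reward_pos / speed,
      start_frame = f0 + 1L, end_frame = f0 + n))
    t0 <- t0 + n * dt
    f0 <- f0 + n
  }
  list(frames = frames, trials = trials,
       licks = data.frame(trial_id = integer(0), time_s = numeric(0),
                          virtual_cm = numeric(0),
                          treadmill_cm = numeric(0), drinking = logical(0)),
       geometry = geometry)
}
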