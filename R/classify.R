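#' Paired signed-rank test on per-trial pre/post responses
#'
#' Core of the task-responsive criterion: a two-sided Wilcoxon signed-rank
#' test comparing per-trial mean responses before (`r_pre`) and after
#' (`r_post`) the reward-zone onset. All-tied differences yield p = 1 (not
#' flagged). Direction is the sign of the median difference.
#'
#' @param r_pre,r_post per-trial window means (equal length).
#' @param alpha significance level (default 0.001).
#' @param alternative `"two.sided"` (default) or `"greater"` (tests
#'   `r_post > r_pre`).
#' @return list with `flag`, `direction` (`"increase"`/`"decrease"`/`NA`),
#'   `p`, `n`, `r_pre_mean`, `r_post_mean`, `underpowered`.
#' @export
task_responsive_test <- function(r_pre, r_post, alpha = 0.001,
                                 alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  ok <- is.finite(r_pre) & is.finite(r_post)
  r_pre <- r_pre[ok]
  r_post <- r_post[ok]
  n <- length(r_pre)
  d <- r_post - r_pre
  # smallest attainable exact p is 2/2^n (two-sided) or 1/2^n (one-sided);
  # it must lie below alpha for the test to be decidable at all
  min_p <- (if (alternative == "two.sided") 2 else 1) / 2^n
  underpowered <- n < 1 || min_p >= alpha
  if (n < 2 || all(d == 0)) {
    return(list(flag = FALSE, direction = NA_character_, p = 1, n = n,
                r_pre_mean = mean(r_pre), r_post_mean = mean(r_post),
                underpowered = underpowered))
  }
  p <- suppressWarnings(
    stats::wilcox.test(r_post, r_pre, paired = TRUE,
                       alternative = alternative)$p.value)
  med <- stats::median(d)
  direction <- if (med > 0) "increase" else if (med < 0) "decrease"
  else NA_character_
  list(flag = is.finite(p) && p < alpha && !underpowered,
       direction = direction, p = p, n = n,
       r_pre_mean = mean(r_pre), r_post_mean = mean(r_post),
       underpowered = underpowered)
}

#' Classify a neuron as task-responsive
#'
#' Computes per-trial mean dF/F0 in `[onset - width, onset)` (R_pre) and
#' `[onset, onset + width)` (R_post) around the reward-zone onset, then runs
#' a paired two-sided signed-rank test across trials.
#'
#' @param session a `session_bundle`.
#' @param dff a `dff_traces`.
#' @param neuron neuron index.
#' @param width_cm window width on each side of the onset (default 20 cm,
#'   the width of the early-reward window).
#' @param alpha significance level (default 0.001).
#' @param reference coordinate frame for the windows (default virtual).
#' @param trials optional trial-id subset (default: all trials).
#' @param alternative passed to [task_responsive_test()].
#' @return as [task_responsive_test()].
#' @export
classify_task_responsive <- function(session, dff, neuron, width_cm = 20,
                                     alpha = 0.001,
                                     reference = "virtual", trials = NULL,
                                     alternative = "two.sided") {
  onset <- session$geometry$reward_zone_onset
  r_pre <- window_means_by_trial(dff, session, c(onset - width_cm, onset),
                                 reference, neuron, trials)
  r_post <- window_means_by_trial(dff, session, c(onset, onset + width_cm),
                                  reference, neuron, trials)
  task_responsive_test(r_pre, r_post, alpha, alternative)
}

#' Response of a neuron during corridor licking vs non-licking periods
#'
#' Compares mean dF/F0 in windows of `+/- window_s` around licks that occur
#' along the corridor against duration-matched non-lick control windows,
#' with a paired signed-rank test across events. Qualifying licks exclude
#' drinking licks and anything within `guard_cm` of the reward-zone onset
#' (so responses tied to the zone or the wall transition cannot leak into
#' the lick windows); control windows are drawn from the same corridor
#' section, at least 0.5 s from any lick.
#'
#' @param session a `session_bundle`.
#' @param dff a `dff_traces`.
#' @param neuron neuron index.
#' @param window_s half-width of the event window in seconds (default 0.25).
#' @param min_events minimum number of qualifying licks (default 10); below
#'   this the test is skipped with a notice.
#' @param guard_cm exclusion band before the reward-zone onset (default 15).
#' @param seed seed for control-window sampling.
#' @return list with `mean_lick`, `mean_nonlick`, `p`, `n_events`,
#'   `skipped`.
#' @export
lick_response_test <- function(session, dff, neuron, window_s = 0.25,
                               min_events = 10, guard_cm = 15, seed = 1) {
  g <- session$geometry
  lk <- session$licks
  lim <- g$reward_zone_onset - guard_cm
  qual <- !lk$drinking & lk$virtual_cm < lim
  times <- lk$time_s[qual]
  times <- times[is.finite(times)]
  if (length(times) < min_events) {
    return(list(mean_lick = NA_real_, mean_nonlick = NA_real_, p = NA_real_,
                n_events = length(times), skipped = TRUE,
                notice = "too few corridor licks; test skipped"))
  }
  v <- dff_vector(dff, neuron)
  ft <- session$frames$time_s
  all_licks <- lk$time_s[is.finite(lk$time_s)]
  win_mean_at <- function(t0) {
    sel <- ft >= t0 - window_s & ft <= t0 + window_s
    if (!any(sel)) NA_real_ else mean(v[sel])
  }
  lick_means <- vapply(times, win_mean_at, numeric(1))

  # control: frames > 0.5 s from any lick, in the same corridor section
  srt <- sort(all_licks)
  j <- findInterval(ft, srt)
  below <- c(-Inf, srt)[j + 1L]
  above <- c(srt, Inf)[j + 1L]
  nearest_lick <- pmin(ft - below, above - ft)
  candidates <- ft[nearest_lick > 0.5 & session$frames$virtual_cm < lim]
  if (length(candidates) < length(times)) {
    return(list(mean_lick = mean(lick_means, na.rm = TRUE),
                mean_nonlick = NA_real_, p = NA_real_,
                n_events = length(times), skipped = TRUE,
                notice = "too few non-lick control periods; test skipped"))
  }
  ctrl_times <- with_seed(seed, sample(candidates, length(times)))
  ctrl_means <- vapply(ctrl_times, win_mean_at, numeric(1))

  ok <- is.finite(lick_means) & is.finite(ctrl_means)
  d <- lick_means[ok] - ctrl_means[ok]
  p <- if (length(d) < 2 || all(d == 0)) 1 else suppressWarnings(
    stats::wilcox.test(lick_means[ok], ctrl_means[ok],
                       paired = TRUE)$p.value)
  list(mean_lick = mean(lick_means[ok]), mean_nonlick = mean(ctrl_means[ok]),
       p = p, n_events = sum(ok), skipped = FALSE)
}

#' Assign a response category to a task-responsive neuron
#'
#' Decision cascade over the field's standard categories. Decrease-type
#' neurons are `locomotion` when the dF/F0-vs-speed Pearson correlation
#' within the grating section exceeds `speed_r_min` (the correlation is
#' evaluated on grating-section frames only, to break the confound between
#' position and the reward-zone slowdown), otherwise `corridor` when
#' activity on the grating section exceeds activity in the reward zone.
#' Increase-type neurons are `lick` when the corridor-lick test is positive
#' (licking mean above non-licking, p < `lick_alpha`), otherwise
#' `reward_zone`. Neurons matching both decrease criteria are recorded as
#' ambiguous.
#'
#' @param session a `session_bundle`.
#' @param dff a `dff_traces`.
#' @param neuron neuron index.
#' @param tr result of [classify_task_responsive()] for this neuron; must be
#'   flagged.
#' @param speed_r_min locomotion threshold on the speed correlation
#'   (default 0.3).
#' @param lick_alpha significance level of the lick test (default 0.001).
#' @param seed seed for the lick-test control sampling.
#' @return list with `category` and `ambiguous`.
#' @export
assign_category <- function(session, dff, neuron, tr, speed_r_min = 0.3,
                            lick_alpha = 0.001, seed = 1) {
  if (!isTRUE(tr$flag)) {
    return(list(category = "other", ambiguous = FALSE))
  }
  g <- session$geometry
  v <- dff_vector(dff, neuron)
  frames <- session$frames
  cued_by_trial <- stats::setNames(session$trials$cued,
                                   session$trials$trial_id)
  cued_f <- unname(cued_by_trial[as.character(frames$trial_id)])
  grating_sel <- cued_f & frames$virtual_cm < g$reward_zone_onset
  rz_sel <- cued_f & frames$virtual_cm >= g$reward_zone_onset &
    frames$virtual_cm < g$early_window_end

  if (identical(tr$direction, "decrease")) {
    speed_r <- if (sum(grating_sel) > 10) {
      stats::cor(v[grating_sel], frames$speed_cm_s[grating_sel])
    } else NA_real_
    grating_gt_rz <- mean(v[grating_sel]) > mean(v[rz_sel])
    is_loco <- is.finite(speed_r) && speed_r >= speed_r_min
    category <- if (is_loco) "locomotion"
    else if (isTRUE(grating_gt_rz)) "corridor"
    else "other"
    return(list(category = category,
                ambiguous = is_loco && isTRUE(grating_gt_rz),
                speed_corr = speed_r))
  }
  lt <- lick_response_test(session, dff, neuron, seed = seed)
  is_lick <- !isTRUE(lt$skipped) && is.finite(lt$p) && lt$p < lick_alpha &&
    lt$mean_lick > lt$mean_nonlick
  list(category = if (is_lick) "lick" else "reward_zone", ambiguous = FALSE,
       speed_corr = NA_real_)
}

#' Classify a neuron as responding at the reward location in cued and
#' uncued trials
#'
#' One-sided (R_post > R_pre) signed-rank tests run separately on cued and
#' uncued trials; the neuron is flagged only when both reach significance.
#' Grating-offset ("off response") neurons fail the uncued test, since no
#' wall transition occurs on uncued trials, and are thereby excluded.
#'
#' @inheritParams classify_task_responsive
#' @param min_uncued minimum uncued-trial count (default 6); below this the
#'   flag is `NA` (undetermined).
#' @return list with `flag`, `p_cued`, `p_uncued`, `n_cued`, `n_uncued`.
#' @export
classify_reward_location <- function(session, dff, neuron, width_cm = 20,
                                     alpha = 0.001, min_uncued = 6) {
  trs <- session$trials
  normal <- trs[trs$gain == 1, , drop = FALSE]
  cued_ids <- normal$trial_id[normal$cued]
  uncued_ids <- normal$trial_id[!normal$cued]
  if (length(uncued_ids) < min_uncued) {
    return(list(flag = NA, p_cued = NA_real_, p_uncued = NA_real_,
                n_cued = length(cued_ids), n_uncued = length(uncued_ids)))
  }
  t_c <- classify_task_responsive(session, dff, neuron, width_cm, alpha,
                                  trials = cued_ids,
                                  alternative = "greater")
  t_u <- classify_task_responsive(session, dff, neuron, width_cm, alpha,
                                  trials = uncued_ids,
                                  alternative = "greater")
  flag <- if (isTRUE(t_c$underpowered) || isTRUE(t_u$underpowered)) {
    NA  # too few trials for p < alpha to be attainable: undetermined
  } else {
    isTRUE(t_c$flag) && isTRUE(t_u$flag)
  }
  list(flag = flag, p_cued = t_c$p, p_uncued = t_u$p,
       n_cued = length(cued_ids), n_uncued = length(uncued_ids))
}

#' Gain-window membership of peak positions
#'
#' A neuron is gain-modulated when its trial-averaged response peaks within
#' `[onset - 5, onset + 20)` cm of *treadmill* distance in both the gain-1
#' and the gain-0.75 condition (the expected reward-zone onset sits at the
#' same treadmill distance in both). Inclusive lower bound, exclusive upper.
#'
#' @param peak_gain1,peak_gain075 argmax positions of the two trial-averaged
#'   profiles, in treadmill cm.
#' @param geometry a [task_geometry()].
#' @return logical flag (`NA` if either peak is missing).
#' @export
gain_window_flag <- function(peak_gain1, peak_gain075, geometry) {
  if (!is.finite(peak_gain1) || !is.finite(peak_gain075)) return(NA)
  lo <- geometry$reward_zone_onset - 5
  hi <- geometry$reward_zone_onset + 20
  (peak_gain1 >= lo && peak_gain1 < hi) &&
    (peak_gain075 >= lo && peak_gain075 < hi)
}

#' Classify a neuron as gain-modulated
#'
#' Averages the neuron's spatially binned response across trials separately
#' for the two gain conditions (uncued trials only, so responses reflect
#' self-motion rather than the visual landmark), takes the argmax position
#' of each profile in treadmill coordinates, and applies
#' [gain_window_flag()].
#'
#' @param session a `session_bundle` containing both gain conditions.
#' @param dff a `dff_traces`.
#' @param neuron neuron index.
#' @param bin_width spatial bin width in cm (default 2).
#' @param cued_trials if `TRUE`, use cued instead of uncued trials.
#' @return list with `flag`, `peak_gain1_cm`, `peak_gain075_cm` (treadmill
#'   cm; `NA` and flag `NA` when a condition is absent or all-missing).
#' @export
classify_gain_modulated <- function(session, dff, neuron, bin_width = 2,
                                    cued_trials = FALSE) {
  trs <- session$trials
  sel <- if (cued_trials) trs$cued else !trs$cued
  ids1 <- trs$trial_id[sel & trs$gain == 1]
  ids075 <- trs$trial_id[sel & trs$gain < 1]
  if (length(ids1) == 0L || length(ids075) == 0L) {
    return(list(flag = NA, peak_gain1_cm = NA_real_,
                peak_gain075_cm = NA_real_))
  }
  edges <- seq(0, ceiling(max(session$frames$treadmill_cm) / bin_width) *
                 bin_width, by = bin_width)
  peak_of <- function(ids) {
    sp <- bin_by_position(dff, session, neuron, edges,
                          reference = "treadmill", trials = ids)
    prof <- position_profile(sp)
    if (all(!is.finite(prof))) return(NA_real_)
    sp$bin_centers[which.max(prof)]
  }
  p1 <- suppressWarnings(peak_of(ids1))
  p075 <- suppressWarnings(peak_of(ids075))
  list(flag = gain_window_flag(p1, p075, session$geometry),
       peak_gain1_cm = p1, peak_gain075_cm = p075)
}

#' Consistency of a neuron's response peak across distance vs time
#'
#' Aligns trials by corridor position and, separately, by time from trial
#' onset; for each alignment takes the per-trial peak location of the binned
#' response and returns the across-trial coefficient of variation of the
#' peak. A position-locked neuron has `cv_distance < cv_time` when running
#' speed varies across trials; a time-locked neuron the reverse.
#'
#' @param session a `session_bundle`.
#' @param dff a `dff_traces`.
#' @param neuron neuron index.
#' @param pos_bin position bin width (cm).
#' @param time_bin time bin width (s).
#' @param reference coordinate frame for the distance alignment.
#' @param min_trials minimum trial count (default 10).
#' @return list with `cv_distance`, `cv_time`, `n_trials`.
#' @export
distance_time_consistency <- function(session, dff, neuron, pos_bin = 2,
                                      time_bin = 0.25,
                                      reference = "virtual",
                                      min_trials = 10) {
  trs <- session$trials
  if (nrow(trs) < min_trials) fail("need at least ", min_trials, " trials")
  frames <- session$frames
  v <- dff_vector(dff, neuron)
  durations <- numeric(nrow(trs))
  peak_pos <- peak_time <- rep(NA_real_, nrow(trs))
  pos_all <- frame_positions(frames, reference)
  for (r in seq_len(nrow(trs))) {
    sel <- which(frames$trial_id == trs$trial_id[r])
    tt <- frames$time_s[sel] - frames$time_s[sel][1L]
    durations[r] <- tt[length(tt)]
    pos <- pos_all[sel]
    pb <- floor(pos / pos_bin)
    tb <- floor(tt / time_bin)
    mp <- tapply(v[sel], pb, mean)
    mt <- tapply(v[sel], tb, mean)
    peak_pos[r] <- (as.numeric(names(mp)[which.max(mp)]) + 0.5) * pos_bin
    peak_time[r] <- (as.numeric(names(mt)[which.max(mt)]) + 0.5) * time_bin
  }
  if (stats::sd(durations) / mean(durations) < 0.05) {
    warning("near-constant trial durations: alignments are degenerate")
  }
  cv <- function(x) stats::sd(x, na.rm = TRUE) / mean(x, na.rm = TRUE)
  list(cv_distance = cv(peak_pos), cv_time = cv(peak_time),
       n_trials = nrow(trs))
}

#' Classify all neurons of a session
#'
#' Runs the full label cascade for every neuron: task-responsiveness
#' (two-sided signed-rank on R_pre vs R_post), response category,
#' reward-location flag (cued + uncued one-sided tests, when uncued trials
#' exist) and gain-modulation flag (when both gain conditions exist).
#'
#' @param session a `session_bundle`.
#' @param dff a `dff_traces` for the session.
#' @param width_cm R_pre/R_post window width (cm).
#' @param alpha per-neuron significance level (default 0.001; no
#'   multiple-testing correction across neurons, by design).
#' @param speed_r_min,lick_alpha category-cascade thresholds (see
#'   [assign_category()]).
#' @param seed seed for the lick-test control sampling.
#' @return data.frame with one row per neuron: `neuron_id`,
#'   `task_responsive`, `direction`, `category`, `reward_location`,
#'   `gain_modulated`, `p_pre_post`, `p_cued`, `p_uncued`,
#'   `peak_gain1_cm`, `peak_gain075_cm`, `r_pre`, `r_post`, `ambiguous`.
#' @export
classify_neurons <- function(session, dff, width_cm = 20, alpha = 0.001,
                             speed_r_min = 0.3, lick_alpha = 0.001,
                             seed = 1) {
  n <- nrow(dff$values)
  has_uncued <- any(!session$trials$cued)
  has_gain <- any(session$trials$gain < 1) && any(session$trials$gain == 1)
  onset <- session$geometry$reward_zone_onset
  pre_m <- window_means_matrix(dff, session, c(onset - width_cm, onset))
  post_m <- window_means_matrix(dff, session, c(onset, onset + width_cm))
  normal <- session$trials[session$trials$gain == 1, , drop = FALSE]
  cued_col <- as.character(normal$trial_id[normal$cued])
  uncued_col <- as.character(normal$trial_id[!normal$cued])
  rl_one <- function(i) {
    if (length(uncued_col) < 6L) {
      return(list(flag = NA, p_cued = NA_real_, p_uncued = NA_real_))
    }
    t_c <- task_responsive_test(pre_m[i, cued_col], post_m[i, cued_col],
                                alpha, alternative = "greater")
    t_u <- task_responsive_test(pre_m[i, uncued_col], post_m[i, uncued_col],
                                alpha, alternative = "greater")
    flag <- if (isTRUE(t_c$underpowered) || isTRUE(t_u$underpowered)) NA
    else isTRUE(t_c$flag) && isTRUE(t_u$flag)
    list(flag = flag, p_cued = t_c$p, p_uncued = t_u$p)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- task_responsive_test(pre_m[i, ], post_m[i, ], alpha)
    cat_res <- if (isTRUE(tr$flag)) {
      assign_category(session, dff, i, tr, speed_r_min, lick_alpha, seed)
    } else list(category = "other", ambiguous = FALSE)
    rl <- if (has_uncued) rl_one(i)
    else list(flag = NA, p_cued = NA_real_, p_uncued = NA_real_)
    gm <- if (has_gain) {
      classify_gain_modulated(session, dff, i)
    } else list(flag = NA, peak_gain1_cm = NA_real_,
                peak_gain075_cm = NA_real_)
    rows[[i]] <- data.frame(
      neuron_id = i, task_responsive = tr$flag,
      direction = tr$direction %||% NA_character_,
      category = cat_res$category,
      reward_location = rl$flag, gain_modulated = gm$flag,
      p_pre_post = tr$p, p_cued = rl$p_cued, p_uncued = rl$p_uncued,
      peak_gain1_cm = gm$peak_gain1_cm,
      peak_gain075_cm = gm$peak_gain075_cm,
      r_pre = tr$r_pre_mean, r_post = tr$r_post_mean,
      ambiguous = isTRUE(cat_res$ambiguous))
  }
  do.call(rbind, rows)
}
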