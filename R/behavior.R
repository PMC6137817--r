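#' Proportion of early rewarded (successful) trials
#'
#' @param trials a trials data.frame (from a session bundle or
#'   [trials_from_licks()]).
#' @return fraction of trials with an early reward.
#' @export
success_rate <- function(trials) {
  if (is.null(trials) || nrow(trials) == 0L) fail("no trials")
  mean(trials$reward_type == "early")
}

#' Spatial modulation index (SMI) of licking
#'
#' The SMI measures how spatially targeted the animal's pre-reward licking
#' is. For each of `n_permutations` permutations, every trial's pre-reward
#' licks (drinking licks excluded) are re-placed uniformly at random over the
#' pre-reward corridor `[0, default_reward_pos)`, preserving each trial's
#' lick count; a permuted trial succeeds if at least one re-placed lick falls
#' in the early-reward window `[reward_zone_onset, early_window_end)`. The
#' SMI is the observed success rate divided by the mean permuted success
#' rate. Values near 1 indicate spatially indiscriminate licking, values > 1
#' few well-placed licks, values < 1 frequent licking that misses the reward
#' window.
#'
#' If no trial has any pre-reward lick the permuted mean is 0 and the SMI is
#' reported as `NA` with `undefined = TRUE` rather than infinity.
#'
#' @param trials,licks session-bundle tables (`licks` needs columns
#'   `trial_id`, `virtual_cm`, `drinking`).
#' @param geometry a [task_geometry()].
#' @param n_permutations number of lick permutations (default 1000).
#' @param seed integer seed (mandatory; the permutation is deterministic
#'   given the seed).
#' @return an object of class `behavior_report`: list with `n_trials`,
#'   `n_early`, `success_rate`, `smi`, `shuffled_mean_success`,
#'   `n_permutations`, `seed`, `undefined`, and `permutation_domain`
#'   metadata describing the chosen null (uniform re-placement of lick
#'   positions over the pre-reward corridor).
#' @export
#' @examples
#' tl <- trials_from_licks(list(c(85, 90), c(82)), task_geometry())
#' compute_smi(tl$trials, tl$licks, task_geometry(), 200, seed = 1)$smi
compute_smi <- function(trials, licks, geometry, n_permutations = 1000,
                        seed) {
  if (is.null(trials) || nrow(trials) == 0L) fail("no trials")
  stopifnot(inherits(geometry, "task_geometry"))
  obs <- success_rate(trials)
  n_trials <- nrow(trials)

  pre <- licks[!is.na(licks$trial_id) & !licks$drinking, , drop = FALSE]
  k_by_trial <- table(factor(pre$trial_id, levels = trials$trial_id))
  K <- sum(k_by_trial)

  if (K == 0L) {
    rep <- behavior_report(n_trials, sum(trials$reward_type == "early"),
                           obs, NA_real_, 0, n_permutations, seed,
                           undefined = TRUE)
    return(rep)
  }

  L <- geometry$default_reward_pos
  w_lo <- geometry$reward_zone_onset
  w_hi <- geometry$early_window_end
  tid <- rep(seq_len(n_trials), times = as.integer(k_by_trial))

  succ <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(p) {
      pos <- stats::runif(K, 0, L)
      hit <- pos >= w_lo & pos < w_hi
      length(unique(tid[hit])) / n_trials
    }, numeric(1))
  })

  shuffled_mean <- mean(succ)
  behavior_report(n_trials, sum(trials$reward_type == "early"), obs,
                  obs / shuffled_mean, shuffled_mean, n_permutations, seed,
                  undefined = FALSE)
}

behavior_report <- function(n_trials, n_early, success_rate, smi,
                            shuffled_mean, n_permutations, seed, undefined) {
  structure(list(
    n_trials = n_trials, n_early = n_early, success_rate = success_rate,
    smi = smi, shuffled_mean_success = shuffled_mean,
    n_permutations = n_permutations, seed = as.integer(seed),
    undefined = undefined,
    permutation_domain = paste(
      "lick positions re-placed uniformly on [0, default_reward_pos)",
      "per trial, drinking licks excluded")),
    class = "behavior_report")
}

#' @export
print.behavior_report <- function(x, ...) {
  cat(sprintf("Behavior: %d/%d early rewards (success rate %.3f)\n",
              x$n_early, x$n_trials, x$success_rate))
  if (isTRUE(x$undefined)) {
    cat("  SMI undefined (no pre-reward licks)\n")
  } else {
    cat(sprintf("  SMI %.3f (shuffled mean success %.3f, %d permutations)\n",
                x$smi, x$shuffled_mean_success, x$n_permutations))
  }
  invisible(x)
}

#' Tabulate behaviour across sessions (learning curve)
#'
#' @param reports list of `behavior_report` objects, in day order.
#' @param expert_threshold strict success-rate threshold for the expert flag
#'   (default 0.75; a session at exactly the threshold is not expert).
#' @return data.frame with columns `day`, `n_trials`, `success_rate`, `smi`,
#'   `expert`.
#' @export
learning_curve <- function(reports, expert_threshold = 0.75) {
  if (length(reports) == 0L) {
    return(data.frame(day = integer(0), n_trials = integer(0),
                      success_rate = numeric(0), smi = numeric(0),
                      expert = logical(0)))
  }
  do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    data.frame(day = i, n_trials = r$n_trials,
               success_rate = r$success_rate, smi = r$smi,
               expert = r$success_rate > expert_threshold)
  }))
}
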