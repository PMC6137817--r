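test_that("signed-rank p-values match full sign enumeration at small n", {
  set.seed(3)
  for (rep in 1:5) {
    n <- sample(6:12, 1)
    d <- round(rnorm(n, 0.3, 1), 6)
    while (any(d == 0) || anyDuplicated(abs(d))) d <- rnorm(n, 0.3, 1)
    r_pre <- rnorm(n)
    r_post <- r_pre + d
    res <- task_responsive_test(r_pre, r_post, alpha = 0.05)
    expect_equal(res$p, enum_signed_rank_p(d), tolerance = 1e-10)
    res1 <- task_responsive_test(r_pre, r_post, alpha = 0.05,
                                 alternative = "greater")
    expect_equal(res1$p, enum_signed_rank_p(d, "greater"),
                 tolerance = 1e-10)
  }
})

test_that("task-responsive test handles nulls, ties, and direction", {
  x <- rnorm(30)
  same <- task_responsive_test(x, x)
  expect_false(same$flag)
  expect_equal(same$p, 1)

  set.seed(5)
  r_pre <- rnorm(50, 1, 0.1)
  up <- task_responsive_test(r_pre, r_pre + 0.5 + rnorm(50, 0, 0.05))
  expect_true(up$flag)
  expect_identical(up$direction, "increase")
  dn <- task_responsive_test(r_pre, r_pre - 0.5 + rnorm(50, 0, 0.05))
  expect_true(dn$flag)
  expect_identical(dn$direction, "decrease")

  # too few trials for p < alpha: reported underpowered, never flagged
  tiny <- task_responsive_test(r_pre[1:6], r_pre[1:6] + 1, alpha = 0.001)
  expect_true(tiny$underpowered)
  expect_false(tiny$flag)
})

test_that("null neurons are flagged at close to the nominal rate", {
  # scaled-down calibration (acceptance runs the full 1000-neuron version)
  set.seed(9)
  flags <- vapply(1:300, function(i) {
    r_pre <- rnorm(40)
    task_responsive_test(r_pre, rnorm(40), alpha = 0.001)$flag
  }, logical(1))
  expect_lte(mean(flags), 5 * 0.001 + 3 * sqrt(0.005 * 0.995 / 300))
})

test_that("planted categories are recovered from the synthetic session", {
  s <- recovery_session()
  d <- compute_dff(s$fluor)
  labels <- classify_neurons(s, d, seed = 2)
  # grating-offset neurons are increase-type reward-zone-transition
  # responders: the category cascade folds them into reward_zone (their
  # exclusion happens in the reward-location analysis, not here)
  truth <- ifelse(s$ground_truth$category == "grating_offset",
                  "reward_zone", s$ground_truth$category)

  for (cat in c("corridor", "locomotion", "lick", "reward_zone")) {
    planted <- truth == cat
    sens <- mean(labels$category[planted] == cat)
    spec <- mean(labels$category[!planted] != cat)
    expect_gte(sens, 0.9)
    expect_gte(spec, 0.9)
  }
  # untuned neurons stay unflagged
  expect_true(all(!labels$task_responsive[truth == "untuned"]))
})

test_that("reward-location flag requires both cued and uncued responses", {
  s <- recovery_session()
  d <- compute_dff(s$fluor)
  truth <- s$ground_truth$category
  rl <- vapply(seq_len(nrow(d$values)), function(i) {
    classify_reward_location(s, d, i)$flag
  }, logical(1))
  expect_true(all(rl[truth == "reward_zone"]))
  # grating-offset neurons respond only at the cued wall transition
  expect_true(all(!rl[truth == "grating_offset"]))
  expect_true(all(!rl[truth == "untuned"]))

  # too few uncued trials -> undetermined
  s2 <- quick_session(neuron_population(reward_zone = 1), n_trials = 9,
                      seed = 3,
                      geometry = task_geometry(gain_period = 0))
  d2 <- compute_dff(s2$fluor)
  expect_true(is.na(classify_reward_location(s2, d2, 1)$flag))
})

test_that("lick-response control separates lick from reward-zone neurons", {
  s <- recovery_session()
  d <- compute_dff(s$fluor)
  truth <- s$ground_truth$category
  i_lick <- which(truth == "lick")[1]
  i_rz <- which(truth == "reward_zone")[1]

  lt <- lick_response_test(s, d, i_lick, seed = 4)
  expect_false(lt$skipped)
  expect_gt(lt$mean_lick, lt$mean_nonlick)
  expect_lt(lt$p, 0.001)

  nt <- lick_response_test(s, d, i_rz, seed = 4)
  expect_false(nt$skipped)
  expect_gte(nt$p, 0.05)

  # no licks at all -> skipped with notice
  s0 <- quick_session(neuron_population(untuned = 1), n_trials = 10,
                      seed = 5, policy = lick_policy("uniform", rate = 0))
  d0 <- compute_dff(s0$fluor)
  expect_true(lick_response_test(s0, d0, 1)$skipped)
})

test_that("gain-modulation windows behave at the boundaries", {
  g <- task_geometry()
  expect_true(gain_window_flag(75, 75, g))    # inclusive lower bound
  expect_true(gain_window_flag(99.9, 75, g))
  expect_false(gain_window_flag(100, 80, g))  # exclusive upper bound
  expect_false(gain_window_flag(74.9, 80, g))
  expect_false(gain_window_flag(80, 107, g))  # virtual-anchored pattern
  expect_true(is.na(gain_window_flag(NA, 80, g)))
})

test_that("gain-modulated classification recovers anchoring frames", {
  specs <- list(
    neuron_spec("gain_anchored_treadmill", anchor_pos = 80,
                anchor_frame = "treadmill"),
    neuron_spec("gain_anchored_virtual", anchor_pos = 80))
  s <- quick_session(specs, n_trials = 125, seed = 5)
  d <- compute_dff(s$fluor)
  tm <- classify_gain_modulated(s, d, 1)
  vr <- classify_gain_modulated(s, d, 2)
  expect_true(tm$flag)
  expect_false(vr$flag)
  # virtual anchor at 80 cm sits near 107 cm of treadmill under gain 0.75
  # peak sits near the anchor, allowing for the indicator decay lag
  expect_lt(abs(vr$peak_gain075_cm - 80 / 0.75), 12)
  # scaling the responses must not change the outcome (argmax only)
  d10 <- d
  d10$values <- d$values * 10
  expect_identical(classify_gain_modulated(s, d10, 1)$flag, tm$flag)
})

test_that("distance vs time consistency separates the two codes", {
  specs <- list(neuron_spec("reward_zone"),
                neuron_spec("time_locked", anchor_pos = 3))
  s <- quick_session(specs, n_trials = 30, seed = 12,
                     geometry = task_geometry(gain_period = 0,
                                              uncued_period = 0))
  d <- compute_dff(s$fluor)
  pos_locked <- distance_time_consistency(s, d, 1)
  expect_lt(pos_locked$cv_distance, pos_locked$cv_time)
  time_locked <- distance_time_consistency(s, d, 2)
  expect_lt(time_locked$cv_time, time_locked$cv_distance)

  # deterministic equal-duration trials: the two alignments coincide
  toy <- toy_session(n_trials = 12)
  v <- 0.1 + exp(-(toy$frames$virtual_cm - 85)^2 / 50)
  expect_warning(res <- distance_time_consistency(toy, v, 1),
                 "near-constant trial durations")
  expect_equal(res$cv_distance, res$cv_time, tolerance = 0.05)
})
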