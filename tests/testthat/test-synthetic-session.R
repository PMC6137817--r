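test_that("simulation is deterministic and validates its inputs", {
  g <- task_geometry()
  pop <- neuron_population(reward_zone = 1, untuned = 1)
  a <- simulate_session(g, lick_policy("expert"), pop, calcium_model(), 8, 42)
  b <- simulate_session(g, lick_policy("expert"), pop, calcium_model(), 8, 42)
  expect_identical(a, b)

  expect_error(simulate_session(g, lick_policy("expert"), pop,
                                calcium_model(), 0, 1),
               "invalid trial count")
  empty <- simulate_session(g, lick_policy("uniform"), list(),
                            calcium_model(), 3, 1)
  expect_identical(nrow(empty$fluor), 0L)
  expect_identical(ncol(empty$fluor), nrow(empty$frames))
})

test_that("reward rule matches a direct scan of the lick list", {
  g <- task_geometry()
  for (mode in c("uniform", "expert", "confined_off_target")) {
    s <- quick_session(neuron_population(), n_trials = 30,
                       policy = lick_policy(mode), seed = 3)
    for (r in seq_len(nrow(s$trials))) {
      tr <- s$trials[r, ]
      lk <- s$licks[s$licks$trial_id == tr$trial_id & !s$licks$drinking, ]
      pos <- sort(lk$virtual_cm)
      hit <- pos[pos >= g$reward_zone_onset & pos < g$early_window_end]
      if (length(hit)) {
        expect_identical(tr$reward_type, "early")
        expect_equal(tr$reward_virtual_cm, hit[1])
      } else {
        expect_identical(tr$reward_type, "default")
        expect_equal(tr$reward_virtual_cm, g$default_reward_pos)
      }
    }
  }
})

test_that("trial flags cycle with the geometry periods and gain couples the
           two position frames", {
  g <- task_geometry(uncued_period = 5, gain_period = 5)
  s <- quick_session(list(), n_trials = 50, geometry = g, seed = 2)
  expect_identical(which(!s$trials$cued), seq(5L, 50L, by = 5L))
  # one in five trials of each cue class runs at reduced gain
  expect_equal(sum(s$trials$gain < 1), 10)
  expect_true(any(s$trials$gain < 1 & !s$trials$cued))
  expect_true(any(s$trials$gain < 1 & s$trials$cued))

  gain_f <- s$trials$gain[match(s$frames$trial_id, s$trials$trial_id)]
  expect_equal(s$frames$virtual_cm, gain_f * s$frames$treadmill_cm)
  # 80 cm of treadmill running = 60 cm of virtual corridor at gain 0.75
  gf <- s$frames[gain_f < 1, ]
  j <- which.min(abs(gf$treadmill_cm - 80))
  expect_equal(gf$virtual_cm[j], 0.75 * gf$treadmill_cm[j])
  expect_lt(abs(gf$virtual_cm[j] - 60), 1)

  expect_true(all(diff(s$frames$time_s) > 0))
})

test_that("uniform policy licks are uniform over the pre-reward corridor", {
  # checked on the policy's draw itself (the recorded per-trial lick set is
  # truncated at the reward event, which conditions the distribution)
  g <- task_geometry()
  pol <- lick_policy("uniform", rate = 1)
  pos <- withr::with_seed(9, {
    unlist(lapply(1:150, function(i) {
      corridortask:::draw_lick_positions(pol, 1, TRUE, g)
    }))
  })
  expect_gt(length(pos), 1e4)
  ks <- suppressWarnings(
    stats::ks.test(pos, "punif", 0, g$default_reward_pos))
  expect_gt(ks$p.value, 0.01)
})

test_that("gain-anchored rate functions peak in their own frame", {
  g <- task_geometry()
  specs <- list(
    neuron_spec("gain_anchored_treadmill", anchor_pos = 80,
                anchor_frame = "treadmill"),
    neuron_spec("gain_anchored_virtual", anchor_pos = 80))
  s <- quick_session(specs, n_trials = 50, geometry = g, seed = 4)
  gain_trials <- s$trials$trial_id[s$trials$gain < 1]
  sel <- s$frames$trial_id %in% gain_trials
  # noise-free rates: treadmill-anchored peaks at 80 cm treadmill...
  peak_tm <- s$frames$treadmill_cm[sel][which.max(s$rates[1, sel])]
  expect_lt(abs(peak_tm - 80), 2)
  # ...virtual-anchored at 80 cm virtual (~107 cm treadmill) under gain 0.75
  peak_vr <- s$frames$virtual_cm[sel][which.max(s$rates[2, sel])]
  expect_lt(abs(peak_vr - 80), 2)
  peak_vr_tm <- s$frames$treadmill_cm[sel][which.max(s$rates[2, sel])]
  expect_lt(abs(peak_vr_tm - 80 / 0.75), 3)
})

test_that("session bundles round-trip through disk exactly", {
  s <- quick_session(neuron_population(reward_zone = 2, untuned = 1),
                     n_trials = 6, seed = 13)
  dir <- file.path(tempdir(), "bundle-roundtrip")
  write_session(s, dir)
  s2 <- read_session(dir)
  expect_equal(s2, s)
  unlink(dir, recursive = TRUE)
})

test_that("malformed bundles on disk fail naming the violated invariant", {
  s <- quick_session(neuron_population(untuned = 1), n_trials = 6, seed = 13)
  base <- file.path(tempdir(), "bundle-bad")

  # early reward outside the early window
  write_session(s, base)
  trs <- read.csv(file.path(base, "trials.csv"))
  i <- which(trs$reward_type == "early")[1]
  trs$reward_virtual_cm[i] <- 105
  write.csv(trs, file.path(base, "trials.csv"), row.names = FALSE)
  expect_error(read_session(base), "early reward position")

  # truncated fluorescence matrix
  write_session(s, base)
  fl <- readLines(file.path(base, "fluor.csv"))
  short <- vapply(strsplit(fl, ","), function(x)
    paste(x[1:(length(x) - 10)], collapse = ","), character(1))
  writeLines(short, file.path(base, "fluor.csv"))
  expect_error(read_session(base), "frame count")
  unlink(base, recursive = TRUE)
})

test_that("trials_from_licks applies the reward rule to given lick lists", {
  g <- task_geometry()
  tl <- trials_from_licks(list(c(40, 85, 95), numeric(0), c(99.5)), g)
  expect_identical(tl$trials$reward_type, c("early", "default", "early"))
  expect_equal(tl$trials$reward_virtual_cm, c(85, 100, 99.5))
  # all supplied licks are retained as the recorded pre-reward set
  expect_equal(sum(tl$licks$trial_id == 1), 3)
})
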