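make_features <- function(n_per_class, mu_a, mu_b, noise_sd, p = 6,
                          seed = 1) {
  withr::with_seed(seed, {
    a <- matrix(rnorm(n_per_class * p, mu_a, noise_sd), n_per_class,
                byrow = TRUE)
    b <- matrix(rnorm(n_per_class * p, mu_b, noise_sd), n_per_class,
                byrow = TRUE)
    list(features = rbind(a, b),
         labels = rep(c("A", "B"), each = n_per_class))
  })
}

test_that("separable classes decode perfectly; every fold verified", {
  mu_a <- c(1, 0, 2, 0, 1, 3)
  mu_b <- c(0, 2, 0, 3, 2, 0)
  d <- make_features(10, mu_a, mu_b, noise_sd = 0)
  rep <- template_decode(d$features, d$labels, seed = 1)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$chance, 0.5)
  expect_identical(rep$per_trial$predicted, rep$per_trial$true)

  # brute-force verification of each LOO fold on standardized features
  fz <- apply(d$features, 2, function(x) (x - mean(x)) / sd(x))
  labs <- factor(d$labels)
  for (i in seq_len(nrow(fz))) {
    keep <- setdiff(seq_len(nrow(fz)), i)
    tA <- colMeans(fz[keep[labs[keep] == "A"], , drop = FALSE])
    tB <- colMeans(fz[keep[labs[keep] == "B"], , drop = FALSE])
    pred <- if (cor(fz[i, ], tA) >= cor(fz[i, ], tB)) "A" else "B"
    expect_identical(rep$per_trial$predicted[i], pred)
  }
})

test_that("label-shuffled and class-identical data decode at chance", {
  d <- make_features(100, rep(1, 6), rep(2, 6), noise_sd = 0.5, seed = 2)
  shuffled <- withr::with_seed(3, sample(d$labels))
  racc <- template_decode(d$features, shuffled, seed = 4)$accuracy
  se <- sqrt(0.25 / 200)
  expect_lt(abs(racc - 0.5), 3 * se)

  # identical class-conditional distributions, 200 trials
  d0 <- make_features(100, rep(1, 6), rep(1, 6), noise_sd = 0.5, seed = 5)
  acc0 <- template_decode(d0$features, d0$labels, seed = 6)$accuracy
  expect_lt(abs(acc0 - 0.5), 3 * se)
})

test_that("accuracy is invariant to per-neuron affine rescaling", {
  d <- make_features(20, c(1, 0, 2, 0, 1, 3), c(0, 2, 0, 3, 2, 0), 1,
                     seed = 7)
  base <- template_decode(d$features, d$labels, seed = 8)
  scale <- c(3, 0.1, 7, 2, 0.5, 11)
  shift <- c(-5, 2, 0, 100, -1, 4)
  f2 <- sweep(sweep(d$features, 2, scale, "*"), 2, shift, "+")
  resc <- template_decode(f2, d$labels, seed = 8)
  expect_equal(resc$accuracy, base$accuracy)
  expect_identical(resc$per_trial$predicted, base$per_trial$predicted)
})

test_that("LOO folds exclude the held-out trial from both templates", {
  d <- make_features(6, c(1, 0, 2, 0, 1, 3), c(0, 2, 0, 3, 2, 0), 1,
                     seed = 9)
  labs <- factor(d$labels)
  for (i in c(1, 5, 9)) {
    tmpl <- corridortask:::loo_templates(d$features, labs, i)
    oracle <- vapply(levels(labs), function(cl) {
      colMeans(d$features[-i, , drop = FALSE][labs[-i] == cl, ,
                                              drop = FALSE])
    }, numeric(ncol(d$features)))
    expect_equal(tmpl, oracle, tolerance = 1e-12)
  }
})

test_that("imbalanced classes are subsampled to the minority count", {
  d <- make_features(40, rep(1, 6), rep(1, 6), noise_sd = 0.5, seed = 10)
  f <- rbind(d$features, d$features[1:10, ])
  l <- c(d$labels, rep("A", 10))
  rep <- template_decode(f, l, seed = 11, n_repeats = 25)
  expect_match(rep$balance, "subsample-to-minority")
  expect_lt(abs(rep$accuracy - 0.5), 0.12)
  expect_identical(template_decode(f, l, seed = 11, n_repeats = 25)$accuracy,
                   rep$accuracy)
})

test_that("degenerate inputs fall back or error as specified", {
  f <- matrix(c(1, 1, 1, 1, 2, 2, 2, 2), ncol = 2)
  expect_error(template_decode(f, rep("A", 4)), "at least 2 classes")
  expect_error(template_decode(f, c("A", "B", "B", "B")),
               "at least 2 trials per class")
  # constant population vector: Euclidean fallback still predicts
  fc <- matrix(rep(c(0, 0, 5, 5), each = 2), ncol = 2)
  repc <- template_decode(fc, c("A", "A", "B", "B"), seed = 1)
  expect_true(is.finite(repc$accuracy))
})

test_that("cue decoding works on sessions and errors without uncued trials", {
  # cue-sensitive population: corridor + grating-offset neurons differ
  # between cued and uncued trials
  s <- quick_session(neuron_population(corridor = 4, grating_offset = 4),
                     n_trials = 60, seed = 21,
                     geometry = task_geometry(gain_period = 0),
                     policy = lick_policy("expert", target_sd = 4))
  d <- compute_dff(s$fluor)
  acc <- decode_cue_type(s, d, seed = 1)$accuracy
  expect_gt(acc, 0.7)

  # cue-invariant population: reward-zone responses identical in both
  s0 <- quick_session(neuron_population(reward_zone = 6, untuned = 2),
                      n_trials = 60, seed = 22,
                      geometry = task_geometry(gain_period = 0),
                      policy = lick_policy("expert", target_sd = 4))
  d0 <- compute_dff(s0$fluor)
  acc0 <- decode_cue_type(s0, d0, seed = 1)$accuracy
  expect_lt(acc0, acc - 0.15)

  # all-cued session: insufficient trials
  s1 <- quick_session(neuron_population(reward_zone = 2), n_trials = 12,
                      seed = 23,
                      geometry = task_geometry(uncued_period = 0,
                                               gain_period = 0))
  d1 <- compute_dff(s1$fluor)
  expect_error(decode_cue_type(s1, d1), "insufficient trials")
})

test_that("outcome decoding separates early from default trials when
           population activity differs", {
  # reward-zone neurons respond at the reward event; lick neurons at licks:
  # early trials carry earlier, lick-triggered activity
  s <- quick_session(neuron_population(reward_zone = 5, lick = 5,
                                       untuned = 2),
                     n_trials = 80, seed = 31,
                     geometry = task_geometry(gain_period = 0,
                                              uncued_period = 0),
                     policy = lick_policy("expert", rate = 0.02,
                                          target_sd = 25))
  d <- compute_dff(s$fluor)
  rep <- decode_outcome(s, d, seed = 2)
  expect_gte(rep$accuracy, 0.5)
  expect_true(all(c("trial_id", "true", "predicted") %in%
                    names(rep$per_trial)))
})
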