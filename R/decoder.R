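#' Population feature vectors for decoding
#'
#' For each trial, the feature vector holds every neuron's mean dF/F0 in a
#' window around the reward-zone onset (default `[onset - 20, onset + 20)`
#' virtual cm). Missing entries (window not visited) are imputed with the
#' neuron's across-trial mean; trials with more than `max_missing` missing
#' entries are dropped with a warning.
#'
#' @param session a `session_bundle`.
#' @param dff a `dff_traces`.
#' @param window numeric length-2 window in cm; default
#'   `onset + c(-20, 20)`.
#' @param reference coordinate frame (default virtual).
#' @param trials optional trial-id subset.
#' @param max_missing maximum tolerated fraction of missing neurons per
#'   trial (default 0.5).
#' @return trials x neurons matrix with `rownames` = trial ids and
#'   attributes `imputed` (count) and `dropped` (trial ids).
#' @export
build_features <- function(session, dff, window = NULL,
                           reference = "virtual", trials = NULL,
                           max_missing = 0.5) {
  onset <- session$geometry$reward_zone_onset
  window <- window %||% (onset + c(-20, 20))
  tids <- trials %||% session$trials$trial_id
  m <- t(window_means_matrix(dff, session, window, reference, tids))
  rownames(m) <- tids
  frac_missing <- rowMeans(is.na(m))
  drop <- frac_missing > max_missing
  if (any(drop)) {
    warning(sum(drop), " trial(s) dropped: >",
            round(100 * max_missing), "% of neurons unobserved")
    m <- m[!drop, , drop = FALSE]
  }
  n_imputed <- sum(is.na(m))
  if (n_imputed > 0L) {
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- mean(m[, j], na.rm = TRUE)
    }
  }
  attr(m, "imputed") <- n_imputed
  attr(m, "dropped") <- tids[drop]
  m
}

# class-mean templates excluding trial i (the leave-one-out fold)
loo_templates <- function(features, labels, i) {
  keep <- setdiff(seq_len(nrow(features)), i)
  vapply(levels(labels), function(cl) {
    colMeans(features[keep[labels[keep] == cl], , drop = FALSE])
  }, numeric(ncol(features)))
}

loo_predict <- function(features, labels) {
  n <- nrow(features)
  preds <- character(n)
  for (i in seq_len(n)) {
    tmpl <- loo_templates(features, labels, i)
    x <- features[i, ]
    sims <- if (ncol(features) >= 2L && stats::sd(x) > 0 &&
                  all(apply(tmpl, 2L, stats::sd) > 0)) {
      apply(tmpl, 2L, function(tm) stats::cor(x, tm))
    } else {
      # degenerate vectors: fall back to negative Euclidean distance
      -sqrt(colSums((tmpl - x)^2))
    }
    preds[i] <- colnames(tmpl)[which.max(sims)]
  }
  factor(preds, levels = levels(labels))
}

#' Template-matching decoder with leave-one-out cross-validation
#'
#' Each held-out trial is assigned to the class whose template (the mean
#' feature vector of that class, excluding the held-out trial) it is most
#' similar to, using Pearson correlation (falling back to negative Euclidean
#' distance for zero-variance vectors). Features are standardized per neuron
#' (z-score across trials) before matching, which makes the decoder exactly
#' invariant to per-neuron affine rescaling of the features. Class imbalance
#' is handled by repeated random subsampling of every class to the minority
#' count; the mean accuracy over repeats is reported.
#'
#' @param features trials x neurons matrix (rownames used as trial ids).
#' @param labels class labels, one per trial (>= 2 classes with >= 2 trials
#'   each).
#' @param seed integer seed for the balancing subsamples.
#' @param n_repeats subsampling repeats when classes are unbalanced
#'   (default 100).
#' @param task optional task name recorded in the report.
#' @return an object of class `decoder_report`: list with `task`,
#'   `accuracy`, `chance`, `per_trial` (data.frame of trial id, true label,
#'   majority-vote predicted label), `cv_scheme`, `balance`, `seed`.
#' @export
template_decode <- function(features, labels, seed = 1, n_repeats = 100,
                            task = "outcome") {
  labels <- factor(labels)
  if (nlevels(labels) < 2L) fail("need at least 2 classes")
  counts <- table(labels)
  if (any(counts < 2L)) fail("need at least 2 trials per class")
  tids <- rownames(features) %||% as.character(seq_len(nrow(features)))

  # per-neuron standardization: affine rescaling of any neuron cancels out
  features <- apply(features, 2L, function(col) {
    s <- stats::sd(col)
    if (!is.finite(s) || s == 0) rep(0, length(col)) else
      (col - mean(col)) / s
  })

  balanced <- length(unique(counts)) == 1L
  if (balanced) {
    preds <- loo_predict(features, labels)
    accuracy <- mean(preds == labels)
    per_trial <- data.frame(trial_id = tids, true = as.character(labels),
                            predicted = as.character(preds))
  } else {
    m <- min(counts)
    votes <- matrix(0L, nrow = nrow(features), ncol = nlevels(labels),
                    dimnames = list(NULL, levels(labels)))
    heldout_n <- integer(nrow(features))
    accs <- with_seed(seed, {
      vapply(seq_len(n_repeats), function(r) {
        idx <- unlist(lapply(levels(labels), function(cl) {
          sample(which(labels == cl), m)
        }))
        sub_pred <- loo_predict(features[idx, , drop = FALSE], labels[idx])
        for (k in seq_along(idx)) {
          votes[idx[k], as.character(sub_pred[k])] <<-
            votes[idx[k], as.character(sub_pred[k])] + 1L
        }
        heldout_n[idx] <<- heldout_n[idx] + 1L
        mean(sub_pred == labels[idx])
      }, numeric(1))
    })
    accuracy <- mean(accs)
    maj <- apply(votes, 1L, function(vv) {
      if (sum(vv) == 0L) NA_character_ else colnames(votes)[which.max(vv)]
    })
    per_trial <- data.frame(trial_id = tids, true = as.character(labels),
                            predicted = maj)
  }
  structure(list(task = task, accuracy = accuracy,
                 chance = 1 / nlevels(labels), per_trial = per_trial,
                 cv_scheme = "leave-one-out",
                 balance = if (balanced) "none" else
                   sprintf("subsample-to-minority x%d", n_repeats),
                 similarity = "pearson", seed = as.integer(seed)),
            class = "decoder_report")
}

#' @export
print.decoder_report <- function(x, ...) {
  cat(sprintf("Template-matching decoder (%s): accuracy %.3f (chance %.2f)\n",
              x$task, x$accuracy, x$chance))
  cat(sprintf("  CV %s; balance %s; similarity %s\n",
              x$cv_scheme, x$balance, x$similarity))
  invisible(x)
}

#' Decode trial outcome (early vs default reward) from population activity
#'
#' @param session a `session_bundle`.
#' @param dff a `dff_traces`.
#' @param seed integer seed.
#' @param ... passed to [build_features()] / [template_decode()].
#' @return a `decoder_report`.
#' @export
decode_outcome <- function(session, dff, seed = 1, ...) {
  feats <- build_features(session, dff, ...)
  keep <- rownames(feats)
  labels <- session$trials$reward_type[
    match(keep, as.character(session$trials$trial_id))]
  template_decode(feats, labels, seed = seed, task = "outcome")
}

#' Decode cue condition (cued vs uncued) from successful trials
#'
#' Restricted to successful (early rewarded) trials, as in the
#' cue-vs-uncued population comparison: requires at least two successful
#' trials in each cue condition.
#'
#' @inheritParams decode_outcome
#' @return a `decoder_report` with task `"cue"`.
#' @export
decode_cue_type <- function(session, dff, seed = 1, ...) {
  trs <- session$trials
  succ <- trs[trs$reward_type == "early", , drop = FALSE]
  if (sum(succ$cued) < 2L || sum(!succ$cued) < 2L) {
    fail("insufficient trials")
  }
  feats <- build_features(session, dff, trials = succ$trial_id, ...)
  keep <- rownames(feats)
  labels <- ifelse(succ$cued[match(keep, as.character(succ$trial_id))],
                   "cued", "uncued")
  template_decode(feats, labels, seed = seed, task = "cue")
}
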