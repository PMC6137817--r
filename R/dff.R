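#' Hamming-window low-pass FIR kernel
#'
#' Linear-phase windowed-sinc design; unity DC gain.
#'
#' @param order filter order (number of taps minus one; must be even so the
#'   kernel has an integer group delay).
#' @param cutoff_hz cutoff frequency (Hz).
#' @param frame_rate sampling rate (Hz).
#' @return numeric vector of `order + 1` taps.
#' @export
fir_lowpass_kernel <- function(order = 60, cutoff_hz = 1, frame_rate = 40) {
  if (order %% 2 != 0) fail("filter order must be even")
  if (cutoff_hz <= 0 || cutoff_hz >= frame_rate / 2) {
    fail("cutoff must lie in (0, frame_rate/2)")
  }
  n <- 0:order
  x <- n - order / 2
  fc <- cutoff_hz / frame_rate            # cycles per sample
  h <- ifelse(x == 0, 2 * fc, sin(2 * pi * fc * x) / (pi * x))
  w <- 0.54 - 0.46 * cos(2 * pi * n / order)
  h <- h * w
  h / sum(h)
}

#' Zero-phase application of a symmetric FIR kernel
#'
#' Forward-backward filtering (as in `filtfilt`): for a symmetric
#' linear-phase kernel this equals two centred convolutions. Edges are
#' handled by reflecting `length(h)` samples at each end.
#'
#' @param x numeric signal (length > `length(h)`).
#' @param h symmetric FIR kernel with an odd number of taps.
#' @return filtered signal, same length as `x`, with no phase shift.
#' @export
zero_phase_filter <- function(x, h) {
  nt <- length(h)
  if (length(x) < nt) fail("trace shorter than filter")
  pad <- nt
  xp <- c(x[pad:1], x, x[length(x):(length(x) - pad + 1L)])
  half <- (nt - 1L) / 2L
  centred <- function(v) {
    y <- stats::filter(v, h, method = "convolution", sides = 2)
    as.numeric(y)
  }
  y <- centred(centred(xp))
  y[(pad + 1L):(pad + length(x))]
}

#' Extract dF/F0 traces from raw fluorescence
#'
#' For each neuron the raw trace is smoothed with a zero-phase low-pass FIR
#' filter (default: 1 Hz cutoff, 60th order, Hamming window); the baseline
#' `F0` is the 5th percentile of the smoothed trace, and
#' `dF/F0 = (F - F0) / F0` on the raw trace. The result is invariant to
#' uniform rescaling of the raw fluorescence.
#'
#' @param raw fluorescence matrix (neurons x frames) or a single trace; all
#'   values must be positive.
#' @param frame_rate sampling rate (Hz).
#' @param cutoff_hz,order smoothing-filter specification.
#' @param percentile baseline percentile of the smoothed trace (default 5).
#' @return an object of class `dff_traces`: list with `values`
#'   (neurons x frames matrix of dF/F0), `f0` (per-neuron baseline) and
#'   `filter_spec`.
#' @export
#' @examples
#' f <- matrix(100 + rep(0, 200), nrow = 1)
#' compute_dff(f, frame_rate = 40)$values[1, 1]
compute_dff <- function(raw, frame_rate = 40, cutoff_hz = 1, order = 60,
                        percentile = 5) {
  if (is.vector(raw)) raw <- matrix(raw, nrow = 1)
  if (any(!is.finite(raw)) || any(raw <= 0)) fail("invalid fluorescence")
  h <- fir_lowpass_kernel(order, cutoff_hz, frame_rate)
  if (ncol(raw) < length(h)) fail("trace shorter than filter")
  n <- nrow(raw)
  f0 <- numeric(n)
  values <- matrix(NA_real_, n, ncol(raw))
  for (i in seq_len(n)) {
    smoothed <- zero_phase_filter(raw[i, ], h)
    f0[i] <- stats::quantile(smoothed, percentile / 100, names = FALSE)
    values[i, ] <- (raw[i, ] - f0[i]) / f0[i]
  }
  structure(list(values = values, f0 = f0,
                 filter_spec = list(cutoff_hz = cutoff_hz, order = order,
                                    zero_phase = TRUE,
                                    window = "hamming")),
            class = "dff_traces")
}

#' @export
print.dff_traces <- function(x, ...) {
  cat(sprintf("dF/F0 traces: %d neurons x %d frames (F0 median %.1f)\n",
              nrow(x$values), ncol(x$values), stats::median(x$f0)))
  invisible(x)
}

frame_positions <- function(frames, reference = c("virtual", "treadmill")) {
  reference <- match.arg(reference)
  if (reference == "virtual") frames$virtual_cm else frames$treadmill_cm
}

#' Spatially binned dF/F0 responses for one neuron
#'
#' Bins a neuron's dF/F0 along corridor position, per trial. Bins are
#' half-open `[a, b)`; a bin never visited on a trial is `NA`, never
#' zero-filled.
#'
#' @param dff a `dff_traces` object (or a numeric per-frame vector).
#' @param session a `session_bundle` (or any list with `frames` and
#'   `trials`).
#' @param neuron neuron row index into `dff$values` (ignored when `dff` is a
#'   vector).
#' @param bin_edges strictly increasing bin edges (cm); default 2-cm bins
#'   spanning the traversed range.
#' @param reference `"virtual"` (default) or `"treadmill"` coordinates.
#' @param trials optional subset of trial ids (default: all).
#' @return an object of class `spatial_response`: list with `matrix`
#'   (trials x bins), `bin_edges`, `bin_centers`, `reference`, `trial_ids`.
#' @export
bin_by_position <- function(dff, session, neuron = 1, bin_edges = NULL,
                            reference = c("virtual", "treadmill"),
                            trials = NULL) {
  reference <- match.arg(reference)
  v <- dff_vector(dff, neuron)
  frames <- session$frames
  stopifnot(length(v) == nrow(frames))
  pos_all <- frame_positions(frames, reference)
  if (is.null(bin_edges)) {
    bin_edges <- seq(0, ceiling(max(pos_all) / 2) * 2, by = 2)
  }
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    fail("bin_edges must be strictly increasing")
  }
  tids <- trials %||% session$trials$trial_id
  nb <- length(bin_edges) - 1L
  m <- matrix(NA_real_, nrow = length(tids), ncol = nb)
  for (r in seq_along(tids)) {
    sel <- frames$trial_id == tids[r]
    pos <- pos_all[sel]
    idx <- findInterval(pos, bin_edges, left.open = FALSE)
    keep <- idx >= 1L & idx <= nb & pos < bin_edges[nb + 1L]
    if (!any(keep)) next
    sums <- rowsum(v[sel][keep], idx[keep])
    m[r, as.integer(rownames(sums))] <-
      sums[, 1L] / tabulate(idx[keep], nb)[as.integer(rownames(sums))]
  }
  if (all(is.na(m))) {
    warning("all bins fall outside the traversed range")
  }
  structure(list(matrix = m, bin_edges = bin_edges,
                 bin_centers = (bin_edges[-1L] + bin_edges[-(nb + 1L)]) / 2,
                 reference = reference, trial_ids = tids),
            class = "spatial_response")
}

#' Trial-averaged position profile of a spatial response
#'
#' @param spatial a `spatial_response`.
#' @return numeric vector of per-bin means (NA where no trial visited).
#' @export
position_profile <- function(spatial) {
  colMeans(spatial$matrix, na.rm = TRUE)
}

dff_vector <- function(dff, neuron) {
  if (inherits(dff, "dff_traces")) dff$values[neuron, ] else as.numeric(dff)
}

#' Mean dF/F0 within a position window on one trial
#'
#' @param dff a `dff_traces` object or per-frame numeric vector.
#' @param session a `session_bundle`.
#' @param trial_id trial identifier.
#' @param window numeric length-2, half-open window `[start, end)` in cm.
#' @param reference `"virtual"` or `"treadmill"`.
#' @param neuron neuron index when `dff` is a `dff_traces`.
#' @return scalar mean dF/F0, or `NA` if no frame falls in the window.
#' @export
window_mean <- function(dff, session, trial_id, window,
                        reference = c("virtual", "treadmill"), neuron = 1) {
  reference <- match.arg(reference)
  v <- dff_vector(dff, neuron)
  frames <- session$frames
  sel <- frames$trial_id == trial_id
  pos <- frame_positions(frames, reference)[sel]
  inw <- pos >= window[1L] & pos < window[2L]
  if (!any(inw)) return(NA_real_)
  mean(v[sel][inw])
}

#' Per-trial window means for one neuron
#'
#' Vectorised helper: mean dF/F0 in `window` for every requested trial.
#'
#' @inheritParams window_mean
#' @param trials trial ids (default all trials of the session).
#' @return numeric vector, one value per trial (NA where unvisited).
#' @export
window_means_by_trial <- function(dff, session, window,
                                  reference = c("virtual", "treadmill"),
                                  neuron = 1, trials = NULL) {
  reference <- match.arg(reference)
  tids <- trials %||% session$trials$trial_id
  vapply(tids, function(tt) {
    window_mean(dff, session, tt, window, reference, neuron)
  }, numeric(1))
}

#' Window means for all neurons and trials at once
#'
#' Vectorised equivalent of [window_means_by_trial()] over every neuron:
#' returns the neurons x trials matrix of mean dF/F0 inside the half-open
#' position window.
#'
#' @param dff a `dff_traces` (or a neurons x frames matrix).
#' @param session a `session_bundle`.
#' @param window numeric length-2 window `[start, end)` in cm.
#' @param reference `"virtual"` or `"treadmill"`.
#' @param trials trial ids (default all).
#' @return neurons x trials matrix (NA where a trial never visits the
#'   window).
#' @export
window_means_matrix <- function(dff, session, window,
                                reference = c("virtual", "treadmill"),
                                trials = NULL) {
  reference <- match.arg(reference)
  vals <- if (inherits(dff, "dff_traces")) dff$values else dff
  frames <- session$frames
  tids <- trials %||% session$trials$trial_id
  pos <- frame_positions(frames, reference)
  inw <- pos >= window[1L] & pos < window[2L]
  out <- matrix(NA_real_, nrow = nrow(vals), ncol = length(tids))
  for (k in seq_along(tids)) {
    idx <- which(inw & frames$trial_id == tids[k])
    if (length(idx)) out[, k] <- rowMeans(vals[, idx, drop = FALSE])
  }
  colnames(out) <- tids
  out
}

#' Running speed from treadmill position
#'
#' Central-difference speed, smoothed with a 200-ms moving average, computed
#' per trial (no leakage across trial boundaries).
#'
#' @param session a `session_bundle`.
#' @return per-frame speed (cm/s).
#' @export
speed_from_position <- function(session) {
  frames <- session$frames
  dt <- diff(frames$time_s[1:2])
  out <- numeric(nrow(frames))
  k <- max(1L, round(0.2 / dt))
  kern <- rep(1 / k, k)
  for (tt in unique(frames$trial_id)) {
    sel <- which(frames$trial_id == tt)
    p <- frames$treadmill_cm[sel]
    n <- length(p)
    v <- numeric(n)
    if (n >= 3L) {
      v[2:(n - 1L)] <- (p[3:n] - p[1:(n - 2L)]) / (2 * dt)
      v[1L] <- v[2L]
      v[n] <- v[n - 1L]
    }
    if (n > k + 2L) {
      sm <- stats::filter(v, kern, sides = 2)
      v <- ifelse(is.na(sm), v, as.numeric(sm))
    }
    out[sel] <- v
  }
  out
}
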