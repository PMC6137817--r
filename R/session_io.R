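#' Write a session bundle to a directory
#'
#' The on-disk layout is plain text: `frames.csv`, `trials.csv`, `licks.csv`,
#' `fluor.csv` (neurons x frames, no header), `clean.csv` (noise-free dF/F0
#' signal), `rates.csv` (noise-free planted rates) and a `meta.json` sidecar holding the geometry, lick policy, calcium
#' model, ground-truth specs and the RNG seed. Numeric columns are written
#' with 17 significant digits so that `read_session(write_session(b))`
#' reproduces `b` exactly.
#'
#' @param bundle a `session_bundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(bundle, dir) {
  stopifnot(inherits(bundle, "session_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fw <- function(d, f) {
    data.table::fwrite(format_full(d), file.path(dir, f))
  }
  fw(bundle$frames, "frames.csv")
  fw(bundle$trials, "trials.csv")
  fw(bundle$licks, "licks.csv")
  write_matrix_csv(bundle$fluor, file.path(dir, "fluor.csv"))
  write_matrix_csv(bundle$clean, file.path(dir, "clean.csv"))
  write_matrix_csv(bundle$rates, file.path(dir, "rates.csv"))
  meta <- list(geometry = unclass(bundle$geometry),
               policy = unclass(bundle$policy),
               calcium = unclass(bundle$calcium),
               ground_truth = bundle$ground_truth,
               seed = bundle$seed,
               n_frames = nrow(bundle$frames),
               n_neurons = nrow(bundle$fluor))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

# format numerics at full precision so CSV round-trips bit-exactly
format_full <- function(d) {
  for (j in seq_along(d)) {
    if (is.double(d[[j]])) d[[j]] <- sprintf("%.17g", d[[j]])
  }
  d
}

write_matrix_csv <- function(m, path) {
  if (nrow(m) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- apply(m, 1L, function(r) paste(sprintf("%.17g", r),
                                          collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

read_matrix_csv <- function(path, n_frames) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(matrix(numeric(0), nrow = 0, ncol = n_frames))
  }
  do.call(rbind, lapply(strsplit(lines, ",", fixed = TRUE), as.numeric))
}

#' Read a session bundle from a directory
#'
#' Reads the layout produced by [write_session()] and validates the bundle's
#' invariants; a malformed bundle raises an error naming the first failed
#' invariant.
#'
#' @param dir directory containing `frames.csv`, `trials.csv`, `licks.csv`,
#'   `fluor.csv`, `rates.csv`, `meta.json`.
#' @return a `session_bundle`.
#' @export
read_session <- function(dir) {
  req <- c("frames.csv", "trials.csv", "licks.csv", "fluor.csv", "meta.json")
  missing <- req[!file.exists(file.path(dir, req))]
  if (length(missing)) fail("missing session files: ",
                            paste(missing, collapse = ", "))
  fr <- function(f) as.data.frame(data.table::fread(file.path(dir, f),
                                                    na.strings = "NA"))
  frames <- fr("frames.csv")
  trials <- fr("trials.csv")
  licks <- fr("licks.csv")
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  fluor <- read_matrix_csv(file.path(dir, "fluor.csv"), nrow(frames))
  aux <- function(f) {
    if (file.exists(file.path(dir, f))) {
      read_matrix_csv(file.path(dir, f), nrow(frames))
    } else {
      matrix(numeric(0), 0, nrow(frames))
    }
  }
  clean <- aux("clean.csv")
  rates <- aux("rates.csv")
  if (nrow(licks) == 0L) {
    licks <- data.frame(trial_id = integer(0), time_s = numeric(0),
                        virtual_cm = numeric(0), treadmill_cm = numeric(0),
                        drinking = logical(0))
  }
  geometry <- do.call(task_geometry, meta$geometry[
    names(meta$geometry) != "gain"])
  policy <- do.call(lick_policy, as.list(meta$policy))
  calcium <- do.call(calcium_model, as.list(meta$calcium))
  gt <- as.data.frame(meta$ground_truth)
  bundle <- structure(
    list(frames = frames, trials = trials, licks = licks, fluor = fluor,
         clean = clean, rates = rates, ground_truth = gt,
         geometry = geometry, policy = policy, calcium = calcium,
         seed = as.integer(meta$seed)),
    class = "session_bundle")
  validate_session(bundle)
  bundle
}

#' Validate session-bundle invariants
#'
#' Checks, in order: frame times strictly increasing; fluorescence matrix
#' frame count matches behaviour; `virtual == gain * treadmill` within each
#' trial; exactly one reward per trial; early rewards inside the early
#' window; default rewards at the default position. The first violated
#' invariant is named in the error.
#'
#' @param bundle a `session_bundle`.
#' @return the bundle, invisibly, if valid.
#' @export
validate_session <- function(bundle) {
  fr <- bundle$frames
  trs <- bundle$trials
  g <- bundle$geometry
  if (is.unsorted(fr$time_s, strictly = TRUE)) {
    fail("invariant violated: frame times must be strictly increasing")
  }
  if (nrow(bundle$fluor) > 0L && ncol(bundle$fluor) != nrow(fr)) {
    fail("invariant violated: fluorescence matrix frame count (",
         ncol(bundle$fluor), ") does not match behaviour frames (",
         nrow(fr), ")")
  }
  gain_f <- trs$gain[match(fr$trial_id, trs$trial_id)]
  if (any(abs(fr$virtual_cm - gain_f * fr$treadmill_cm) > 1e-6)) {
    fail("invariant violated: virtual_cm must equal gain * treadmill_cm")
  }
  if (anyDuplicated(trs$trial_id)) {
    fail("invariant violated: every trial must have exactly one reward event")
  }
  early <- trs$reward_type == "early"
  bad_early <- early & !(trs$reward_virtual_cm >= g$reward_zone_onset &
                           trs$reward_virtual_cm < g$early_window_end)
  if (any(bad_early)) {
    fail("invariant violated: early reward position outside [",
         g$reward_zone_onset, ", ", g$early_window_end, ") on trial ",
         trs$trial_id[which(bad_early)[1L]])
  }
  bad_def <- !early & trs$reward_virtual_cm != g$default_reward_pos
  if (any(bad_def)) {
    fail("invariant violated: default reward must sit at ",
         g$default_reward_pos, " cm (trial ",
         trs$trial_id[which(bad_def)[1L]], ")")
  }
  invisible(bundle)
}
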