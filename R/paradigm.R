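#' Paradigm configuration for the action-observation experiment
#'
#' Describes one participant run of the three-condition (Sd/Sm/Su)
#' hand-cup action-observation paradigm: three observed intentions
#' (grasp-to-drink, grasp-to-move, ambiguous touch) crossed with seven cup
#' colors and four repetitions, split into equal sessions separated by rest.
#' Per-trial timing is 6 s pre-rest fixation, a 0.5 s cue, 3.5 s action
#' observation and 6 s post-rest; observation onset defines time zero of
#' every trial.
#'
#' @param n_conditions Number of intention conditions (default 3).
#' @param n_colors Number of cup colors (default 7).
#' @param n_reps Repetitions of each condition x color cell (default 4).
#' @param pre_rest_s,cue_s,observation_s,post_rest_s Trial segment durations
#'   in seconds (defaults 6, 0.5, 3.5, 6).
#' @param n_sessions Number of equal sessions (default 4).
#' @param inter_session_rest_s Rest between sessions in seconds (default 120).
#' @param eeg_rate_hz EEG sampling rate in Hz (default 1000).
#' @param fnirs_dt_s fNIRS sampling interval in seconds (default 0.027).
#' @param seed Integer seed used when randomizing the trial sequence.
#' @return A `paradigm_config` object (list).
#' @export
#' @examples
#' cfg <- paradigm_config()
#' sch <- build_schedule(cfg)
#' nrow(sch)                      # 84 trials
#' attr(sch, "total_duration_s") # 1704 s = 28.4 min
paradigm_config <- function(n_conditions = 3L, n_colors = 7L, n_reps = 4L,
                            pre_rest_s = 6, cue_s = 0.5, observation_s = 3.5,
                            post_rest_s = 6, n_sessions = 4L,
                            inter_session_rest_s = 120,
                            eeg_rate_hz = 1000, fnirs_dt_s = 0.027,
                            seed = 1L) {
  dur <- c(pre_rest_s, cue_s, observation_s, post_rest_s)
  if (any(dur <= 0)) stop("all trial segment durations must be > 0")
  if (n_conditions < 1L || n_colors < 1L || n_reps < 1L || n_sessions < 1L)
    stop("counts must be >= 1")
  n_trials <- n_conditions * n_colors * n_reps
  if (n_trials %% n_sessions != 0L)
    stop("n_conditions * n_colors * n_reps (", n_trials,
         ") is not divisible by n_sessions (", n_sessions, ")")
  if (eeg_rate_hz <= 0 || fnirs_dt_s <= 0) stop("sampling parameters must be > 0")
  structure(list(
    n_conditions = as.integer(n_conditions), n_colors = as.integer(n_colors),
    n_reps = as.integer(n_reps),
    pre_rest_s = pre_rest_s, cue_s = cue_s, observation_s = observation_s,
    post_rest_s = post_rest_s, n_sessions = as.integer(n_sessions),
    inter_session_rest_s = inter_session_rest_s,
    eeg_rate_hz = eeg_rate_hz, fnirs_dt_s = fnirs_dt_s,
    seed = as.integer(seed)
  ), class = "paradigm_config")
}

#' Condition labels of the paradigm
#'
#' `Sd` grasp-to-drink, `Sm` grasp-to-move, `Su` touch with unclear intention.
#' The first `n` labels are used when a configuration asks for fewer than
#' three conditions (reduced test paradigms).
#'
#' @param n Number of conditions.
#' @return Character vector of condition labels.
#' @export
condition_labels <- function(n = 3L) {
  base <- c("Sd", "Sm", "Su")
  if (n <= 3L) base[seq_len(n)] else c(base, paste0("S", seq_len(n - 3L)))
}

#' Visual angle subtended by a stimulus
#'
#' Full visual angle of an extent viewed frontally at a given distance,
#' `2 * atan(extent / (2 * distance))`, in degrees.
#'
#' @param extent_cm Stimulus extent in cm (>= 0).
#' @param distance_cm Viewing distance in cm (> 0).
#' @return Angle in degrees.
#' @export
#' @examples
#' visual_angle(28, 80) # 19.85 deg, the horizontal extent of the stimuli
#' visual_angle(16, 80) # 11.42 deg, the vertical extent
visual_angle <- function(extent_cm, distance_cm) {
  if (any(distance_cm <= 0)) stop("invalid geometry: distance_cm must be > 0")
  if (any(extent_cm < 0)) stop("invalid geometry: extent_cm must be >= 0")
  2 * atan(extent_cm / (2 * distance_cm)) * 180 / pi
}

#' Stimulus geometry
#'
#' @param width_cm,height_cm,viewing_distance_cm Physical geometry in cm.
#' @return A `stimulus_geometry` object with the derived visual angles.
#' @export
stimulus_geometry <- function(width_cm = 28, height_cm = 16,
                              viewing_distance_cm = 80) {
  if (any(c(width_cm, height_cm, viewing_distance_cm) <= 0))
    stop("invalid geometry: all dimensions must be > 0")
  structure(list(
    width_cm = width_cm, height_cm = height_cm,
    viewing_distance_cm = viewing_distance_cm,
    width_deg = visual_angle(width_cm, viewing_distance_cm),
    height_deg = visual_angle(height_cm, viewing_distance_cm)
  ), class = "stimulus_geometry")
}

#' Build the randomized trial schedule
#'
#' Enumerates every condition x color x repetition cell, permutes the trials
#' with the configuration seed, splits them into `n_sessions` equal sessions,
#' and lays trials out in time.  Each trial occupies
#' `pre_rest + cue + observation + post_rest` seconds; sessions are separated
#' by `inter_session_rest_s` of quiet baseline.  The observation onset of a
#' trial (its time zero for epoching) falls `pre_rest + cue` seconds after
#' the trial starts.
#'
#' @param config A [paradigm_config()].
#' @return A data.frame of class `trial_schedule` with columns `trial`,
#'   `condition` (factor Sd/Sm/Su), `color`, `session`, `trial_start_s`,
#'   `observation_onset_s`, and attributes `total_duration_s`, `config`.
#' @export
build_schedule <- function(config = paradigm_config()) {
  stopifnot(inherits(config, "paradigm_config"))
  cells <- expand.grid(
    rep = seq_len(config$n_reps),
    color = seq_len(config$n_colors),
    condition = condition_labels(config$n_conditions),
    stringsAsFactors = FALSE
  )
  n <- nrow(cells)
  ord <- local({
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(config$seed)
    sample.int(n)
  })
  cells <- cells[ord, , drop = FALSE]
  per_session <- n %/% config$n_sessions
  session <- rep(seq_len(config$n_sessions), each = per_session)
  trial_len <- config$pre_rest_s + config$cue_s + config$observation_s +
    config$post_rest_s
  # trial start = preceding trials + rests between completed sessions
  start <- (seq_len(n) - 1L) * trial_len +
    (session - 1L) * config$inter_session_rest_s
  sch <- data.frame(
    trial = seq_len(n),
    condition = factor(cells$condition, levels = condition_labels(config$n_conditions)),
    color = cells$color,
    session = session,
    trial_start_s = start,
    observation_onset_s = start + config$pre_rest_s + config$cue_s
  )
  attr(sch, "total_duration_s") <- n * trial_len +
    (config$n_sessions - 1L) * config$inter_session_rest_s
  attr(sch, "config") <- config
  class(sch) <- c("trial_schedule", "data.frame")
  sch
}

# Save/restore .Random.seed so seeded helpers do not disturb the caller's RNG.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
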