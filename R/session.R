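#' Run a full closed-loop session
#'
#' Top-level entry: builds the game and signal sources, seeds all randomness
#' from `cfg$seed`, and delegates to [run_condition()]. Either a simulated
#' subject ([subject_params()]) closes the loop, or replay streams recorded
#' earlier (e.g. simulator output written via [write_stream()]) provide the
#' physiology while the game is played by a default policy.
#'
#' @param cfg a [session_config()].
#' @param subject a [subject_params()] for closed-loop simulation, or `NULL`
#'   when replaying.
#' @param alpha,valence replay sources (see [run_condition()]); ignored when
#'   `subject` is given.
#' @param player optional action policy overriding the subject's.
#' @return An [event_log()].
#' @export
run_session <- function(cfg, subject = NULL, alpha = NULL, valence = NULL,
                        player = NULL) {
  stopifnot(inherits(cfg, "session_config"))
  # seed R's RNG locally so sessions are reproducible without clobbering the
  # caller's random state
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)
  if (!is.null(subject)) {
    stopifnot(inherits(subject, "subject_params"))
    src <- subject_sources(subject)
    alpha <- src$alpha
    valence <- src$valence
    if (is.null(player)) player <- src$player
  } else if (is.null(player) && cfg$condition == "control") {
    player <- subject_player(subject_params())
  }
  game <- new_game(seed = cfg$seed,
                   level = speed_to_level(cfg$initial_speed_ms))
  run_condition(cfg, alpha = alpha, valence = valence, game = game,
                player = player)
}

#' Outcome metrics of a session
#'
#' Summarises an [event_log()] into the study's outcome measures: the mean
#' per-epoch level, deaths and score per minute, counts of adaptations, and
#' the dwell counts at the speed extremes — the number of 10 s pacing
#' periods spent entirely at level 15 (`dwell_fast`) or level 1
#' (`dwell_slow`) — from which the extreme-speed group label is derived
#' (5 or more periods at an extreme).
#'
#' @param log an [event_log()] from [run_session()]/[run_condition()].
#' @return Object of class `session_metrics`: `avg_level`, `deaths`,
#'   `deaths_per_min`, `final_score`, `score_per_min`, `n_adaptations`,
#'   `n_threshold_updates`, `dwell_fast`, `dwell_slow`, `group`, `duration`.
#' @export
compute_metrics <- function(log) {
  stopifnot(inherits(log, "event_log"))
  epochs <- log_records(log, "epoch")
  if (!length(epochs)) stop("event log contains no epoch records")
  ses <- log_records(log, "session")
  if (!length(ses)) stop("event log contains no session record")
  ses <- ses[[length(ses)]]
  duration <- ses$duration
  lv <- vapply(epochs, function(r) as.numeric(r$level), numeric(1))
  lv_min <- vapply(epochs, function(r) as.numeric(r$level_min), numeric(1))
  lv_max <- vapply(epochs, function(r) as.numeric(r$level_max), numeric(1))
  dwell_fast <- sum(lv_min == 15 & lv_max == 15)
  dwell_slow <- sum(lv_min == 1 & lv_max == 1)
  judgments <- log_records(log, "judgment")
  n_loosen <- sum(vapply(judgments, function(r)
    identical(r$verdict, "dissatisfied"), logical(1)))
  m <- structure(list(
    avg_level = mean(lv),
    deaths = ses$deaths,
    deaths_per_min = ses$deaths / (duration / 60),
    final_score = ses$final_score,
    score_per_min = ses$final_score / (duration / 60),
    lines_cleared = ses$lines_cleared,
    n_adaptations = length(log_records(log, "adaptation")),
    n_threshold_updates = n_loosen + length(log_records(log, "tighten")),
    dwell_fast = dwell_fast, dwell_slow = dwell_slow,
    duration = duration,
    final_upper = ses$upper, final_lower = ses$lower
  ), class = "session_metrics")
  m$group <- classify_group(m)
  m
}

#' @export
print.session_metrics <- function(x, ...) {
  cat("<session_metrics>\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Extreme-speed group label
#'
#' A session is `"high_speed"` when it spent 5 or more 10 s periods at the
#' fastest level, `"low_speed"` when 5 or more at the slowest; when both
#' counts qualify the larger dwell wins (an exact tie is `"neither"`).
#'
#' @param metrics a `session_metrics` object, or a list with `dwell_fast`
#'   and `dwell_slow`.
#' @param min_periods qualifying dwell count (default 5).
#' @return `"high_speed"`, `"low_speed"` or `"neither"`.
#' @export
classify_group <- function(metrics, min_periods = 5) {
  f <- metrics$dwell_fast
  s <- metrics$dwell_slow
  hi <- f >= min_periods
  lo <- s >= min_periods
  if (hi && lo) {
    if (f > s) "high_speed" else if (s > f) "low_speed" else "neither"
  } else if (hi) "high_speed" else if (lo) "low_speed" else "neither"
}

#' Per-epoch level trace of a session
#'
#' @param log an [event_log()].
#' @return `data.frame(t, level, upper, lower)` sampled at the pacing grid,
#'   suitable for plotting level trajectories or writing as CSV.
#' @export
level_trace <- function(log) {
  epochs <- log_records(log, "epoch")
  data.frame(
    t = vapply(epochs, function(r) as.numeric(r$t), numeric(1)),
    level = vapply(epochs, function(r) as.numeric(r$level), numeric(1)),
    upper = vapply(epochs, function(r) as.numeric(r$upper), numeric(1)),
    lower = vapply(epochs, function(r) as.numeric(r$lower), numeric(1))
  )
}
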