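#' Session configuration
#'
#' All parameters of a closed-loop session. Defaults follow the study design
#' this package implements: 15 min sessions, 400 ms initial gravity interval
#' within [100, 1500] ms moved 100 ms at a time, a 10 s adaptation pacing, a
#' 5 s alpha averaging window, 2 s valence windows and 0.5 s alpha epochs.
#'
#' @param condition `"control"` (progressive speed-up every 4 cleared rows),
#'   `"fixed"` (EEG loop with immutable thresholds) or `"dynamic"`
#'   (valence-tuned thresholds).
#' @param duration session length in seconds.
#' @param pacing interval between controller evaluations, seconds.
#' @param alpha_window length of the alpha averaging window preceding each
#'   evaluation, seconds.
#' @param valence_window pre/post window used to judge an adaptation, seconds.
#' @param epoch_len alpha epoch length, seconds.
#' @param initial_speed_ms,min_speed_ms,max_speed_ms,speed_step_ms gravity
#'   interval (ms per line) at session start and its bounds/step.
#' @param upper_threshold,lower_threshold initial decision thresholds in
#'   normalized alpha-ratio units (2.0 = a 100% increase over baseline, 0.5 =
#'   a two-fold decrease).
#' @param threshold_step ratio units moved per threshold update.
#' @param guard when `TRUE`, threshold updates are clamped so that
#'   `lower >= step` and `upper - lower >= 2 * step`; when `FALSE` the
#'   unguarded update rule is used verbatim, which can drive thresholds
#'   crossed or negative.
#' @param seed integer seed for all session randomness.
#' @return A validated list of class `session_config`.
#' @export
session_config <- function(condition = c("fixed", "control", "dynamic"),
                           duration = 900,
                           pacing = 10,
                           alpha_window = 5,
                           valence_window = 2,
                           epoch_len = 0.5,
                           initial_speed_ms = 400L,
                           min_speed_ms = 100L,
                           max_speed_ms = 1500L,
                           speed_step_ms = 100L,
                           upper_threshold = 2.0,
                           lower_threshold = 0.5,
                           threshold_step = 0.1,
                           guard = TRUE,
                           seed = 1L) {
  condition <- match.arg(condition)
  cfg <- structure(
    list(condition = condition, duration = as.numeric(duration),
         pacing = as.numeric(pacing), alpha_window = as.numeric(alpha_window),
         valence_window = as.numeric(valence_window),
         epoch_len = as.numeric(epoch_len),
         initial_speed_ms = as.integer(initial_speed_ms),
         min_speed_ms = as.integer(min_speed_ms),
         max_speed_ms = as.integer(max_speed_ms),
         speed_step_ms = as.integer(speed_step_ms),
         upper_threshold = as.numeric(upper_threshold),
         lower_threshold = as.numeric(lower_threshold),
         threshold_step = as.numeric(threshold_step),
         guard = isTRUE(guard), seed = as.integer(seed)),
    class = "session_config")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  with(cfg, {
    if (duration <= 0) stop("duration must be positive")
    if (min_speed_ms <= 0 || max_speed_ms < min_speed_ms)
      stop("speed bounds out of range: need 0 < min_speed_ms <= max_speed_ms")
    if (initial_speed_ms < min_speed_ms || initial_speed_ms > max_speed_ms)
      stop("initial_speed_ms (", initial_speed_ms, ") must lie within [",
           min_speed_ms, ", ", max_speed_ms, "]")
    if (pacing < alpha_window)
      stop("pacing (", pacing, " s) must be >= alpha_window (", alpha_window, " s)")
    for (w in c(pacing, alpha_window, valence_window)) {
      k <- w / epoch_len
      if (abs(k - round(k)) > 1e-9)
        stop("all windows must be integer multiples of epoch_len (", epoch_len, " s)")
    }
    if (threshold_step <= 0) stop("threshold_step must be positive")
    if (upper_threshold <= lower_threshold)
      stop("upper_threshold must exceed lower_threshold")
  })
  cfg
}

#' @export
print.session_config <- function(x, ...) {
  cat("<session_config>\n")
  for (k in names(x)) cat(sprintf("  %-18s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Load / save a session configuration (YAML)
#'
#' Missing keys take the [session_config()] defaults; unknown keys are an
#' error. All invariants are re-validated on load.
#'
#' @param path YAML file.
#' @return `load_config`: a `session_config`; `save_config`: `path` invisibly.
#' @export
load_config <- function(path) {
  raw <- if (file.exists(path)) yaml::read_yaml(path) else stop("config not found: ", path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(session_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  do.call(session_config, raw)
}

#' @rdname load_config
#' @param cfg a [session_config()].
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "session_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
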