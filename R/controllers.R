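#' Decision thresholds for the alpha-driven difficulty loop
#'
#' The controller compares the 5 s mean alpha ratio against two thresholds in
#' normalized ratio units: crossing the upper threshold (default 2.0, a 100%
#' increase over baseline) slows the game down; crossing the lower threshold
#' (default 0.5, a two-fold decrease) speeds it up. The dynamic condition
#' moves these thresholds by `step` (default 0.1) in response to valence
#' verdicts.
#'
#' In the field's worked examples thresholds are often quoted in
#' fractional-change units (a threshold "value of 1" = crossing at
#' baseline * (1 + 1)); [ratio_to_fractional()] and [fractional_to_ratio()]
#' interconvert (`fractional = ratio - 1`).
#'
#' @param upper,lower thresholds in ratio units, `upper > lower`.
#' @param step ratio units moved per update (> 0).
#' @param guard when `TRUE`, updates are clamped so `lower >= step` and
#'   `upper - lower >= 2 * step` always hold; when `FALSE` the update rule is
#'   applied verbatim, which under sustained negative valence can cross the
#'   thresholds or drive the lower one negative (unreachable by the
#'   non-negative alpha ratio).
#' @return Object of class `threshold_state`.
#' @export
threshold_state <- function(upper = 2.0, lower = 0.5, step = 0.1,
                            guard = TRUE) {
  if (step <= 0) stop("step must be positive")
  th <- structure(list(upper = as.numeric(upper), lower = as.numeric(lower),
                       step = as.numeric(step), guard = isTRUE(guard)),
                  class = "threshold_state")
  if (th$guard && (th$lower < th$step || th$upper - th$lower < 2 * th$step))
    stop("guarded thresholds require lower >= step and upper - lower >= 2*step")
  th
}

#' @export
print.threshold_state <- function(x, ...) {
  cat(sprintf("<threshold_state> upper=%.3g lower=%.3g step=%.3g guard=%s\n",
              x$upper, x$lower, x$step, x$guard))
  invisible(x)
}

#' @rdname threshold_state
#' @param ratio,fractional threshold values to convert.
#' @export
ratio_to_fractional <- function(ratio) ratio - 1

#' @rdname threshold_state
#' @export
fractional_to_ratio <- function(fractional) fractional + 1

thresholds_from_config <- function(cfg) {
  threshold_state(upper = cfg$upper_threshold, lower = cfg$lower_threshold,
                  step = cfg$threshold_step, guard = cfg$guard)
}

#' Control-condition speed progression
#'
#' The non-adaptive condition raises the level by one step every time four
#' rows (cumulatively) have been cleared, clamped at level 15; physiological
#' signals are ignored.
#'
#' @param state a `game_state` (carries the cumulative cleared-row counter).
#' @param n_newly_cleared rows cleared since the previous call.
#' @return Updated `game_state`.
#' @export
progression_update <- function(state, n_newly_cleared) {
  before <- state$prog_counter
  state$prog_counter <- before + as.integer(n_newly_cleared)
  ups <- floor(state$prog_counter / 4) - floor(before / 4)
  if (ups > 0) state <- set_level(state, state$level + ups)
  state
}

#' Evaluate one pacing epoch against the thresholds
#'
#' At each pacing boundary the controller averages the alpha ratio over the
#' `alpha_window` seconds preceding the boundary (artifact-flagged epochs
#' excluded) and tests it against the thresholds inclusively — a change of
#' 100% "or more" triggers: `crossed = "upper"` if the mean reaches or
#' exceeds the upper threshold (slow down), `"lower"` if at or below the
#' lower threshold (speed up), `"none"` otherwise. If every epoch in the
#' window is flagged the epoch is skipped (`crossed = "none"`,
#' `alpha_avg = NA`).
#'
#' @param alpha `data.frame(t, ratio, artifact)` of alpha epochs.
#' @param t_epoch pacing-boundary time in seconds.
#' @param th a [threshold_state()].
#' @param alpha_window averaging window length in seconds.
#' @return List with `t_epoch`, `alpha_avg`, `crossed` in
#'   `{"upper", "lower", "none"}` and `skipped`.
#' @export
evaluate_epoch <- function(alpha, t_epoch, th, alpha_window = 5) {
  sel <- alpha$t >= t_epoch - alpha_window & alpha$t < t_epoch & !alpha$artifact
  if (!any(sel))
    return(list(t_epoch = t_epoch, alpha_avg = NA_real_, crossed = "none",
                skipped = TRUE))
  avg <- mean(alpha$ratio[sel])
  crossed <- if (avg >= th$upper) "upper" else if (avg <= th$lower) "lower" else "none"
  list(t_epoch = t_epoch, alpha_avg = avg, crossed = crossed, skipped = FALSE)
}

#' Apply a threshold crossing to the game speed
#'
#' An upper crossing (high alpha) slows the game by one level; a lower
#' crossing speeds it up by one level; always one 100 ms step at a time,
#' clamped to levels 1..15 (1500--100 ms per line).
#'
#' @param state a `game_state`.
#' @param crossed `"upper"` or `"lower"`.
#' @return Updated `game_state`.
#' @export
apply_adaptation <- function(state, crossed) {
  crossed <- match.arg(crossed, c("upper", "lower"))
  set_level(state, state$level + if (crossed == "upper") -1L else 1L)
}

#' Loosen the crossed threshold after a dissatisfying adaptation
#'
#' When the valence delta following an adaptation is negative, only the
#' threshold that triggered it moves, away from the middle: the upper
#' threshold increases, or the lower threshold decreases, making the
#' criterion less severe (e.g. upper 2.0 -> 2.1; in fractional-change units
#' 1 -> 1.1, so with baseline 4 a crossing then requires raw alpha above
#' 8.4 instead of 8).
#'
#' @param th a [threshold_state()].
#' @param crossed which side triggered the adaptation.
#' @return Updated `threshold_state`.
#' @export
loosen_threshold <- function(th, crossed) {
  crossed <- match.arg(crossed, c("upper", "lower"))
  if (crossed == "upper") {
    th$upper <- round(th$upper + th$step, 10)
  } else {
    th$lower <- round(th$lower - th$step, 10)
    if (th$guard) th$lower <- max(th$step, th$lower)
  }
  th
}

#' Tighten both thresholds after a quiet dissatisfied epoch
#'
#' When a pacing epoch produces no adaptation yet the epoch valence delta is
#' negative, both thresholds are considered too loose and move toward the
#' middle: the upper threshold decreases and the lower increases, making the
#' criterion more severe. With the guard on, tightening stops once
#' `upper - lower == 2 * step`; unguarded, repeated tightening can cross the
#' thresholds.
#'
#' @param th a [threshold_state()].
#' @return Updated `threshold_state`.
#' @export
tighten_thresholds <- function(th) {
  # updates stay on the exact decimal step grid (no float accumulation)
  nu <- round(th$upper - th$step, 10)
  nl <- round(th$lower + th$step, 10)
  if (th$guard && nu - nl < 2 * th$step) {
    m <- (th$upper + th$lower) / 2
    nu <- m + th$step
    nl <- m - th$step
    if (nl < th$step) {
      nl <- th$step
      nu <- max(nu, nl + 2 * th$step)
    }
  }
  th$upper <- nu
  th$lower <- nl
  th
}

## ---- session loop -------------------------------------------------------

# normalize an alpha source into function(t0, level) -> list(ratio, artifact)
make_alpha_provider <- function(alpha, epoch_len) {
  if (is.null(alpha)) return(NULL)
  if (is.function(alpha)) return(alpha)
  stopifnot(is.data.frame(alpha), all(c("t", "ratio") %in% names(alpha)))
  if (is.null(alpha$artifact)) alpha$artifact <- FALSE
  function(t0, level) {
    sel <- alpha$t >= t0 - 1e-9 & alpha$t < t0 + epoch_len - 1e-9
    if (!any(sel)) return(NULL)
    list(ratio = mean(alpha$ratio[sel]), artifact = all(alpha$artifact[sel]))
  }
}

# normalize a valence source into
# function(t0, t1, level_at, adapt_times) -> data.frame(t, v)
make_valence_provider <- function(valence) {
  if (is.null(valence)) return(NULL)
  if (is.function(valence)) {
    if (length(formals(valence)) >= 4L) return(valence)
    return(function(t0, t1, level_at, adapt_times) valence(t0, t1, level_at))
  }
  v <- as_valence_samples(valence)
  function(t0, t1, level_at, adapt_times)
    v[v$t >= t0 - 1e-9 & v$t < t1 - 1e-9, , drop = FALSE]
}

on_grid <- function(t, grid) abs(t / grid - round(t / grid)) < 1e-9

#' Run one experimental condition end to end
#'
#' Drives the closed loop for `cfg$duration` seconds: the game advances
#' continuously (optionally played by a `player` policy), alpha epochs and
#' valence samples are drawn from the given sources, and at every pacing
#' boundary the controller acts according to the condition. `"control"`
#' ignores physiology and applies [progression_update()]; `"fixed"` runs
#' [evaluate_epoch()] + [apply_adaptation()] with immutable thresholds;
#' `"dynamic"` additionally judges each adaptation by its 2 s pre/post
#' valence delta ([adaptation_delta()]), loosens the crossed threshold on a
#' negative delta, and tightens both thresholds on quiet epochs whose
#' valence delta is negative. Pending adaptation judgments are resolved
#' before the next evaluation. Every decision is logged.
#'
#' @param cfg a [session_config()].
#' @param alpha alpha-ratio source: `data.frame(t, ratio, artifact)` (replay)
#'   or `function(t0, level)` returning `list(ratio, artifact)` for the epoch
#'   starting at `t0` (closed loop). Ignored in the control condition.
#' @param valence valence source: samples (`data.frame(t, v)` or 1-channel
#'   stream) or `function(t0, t1, level_at)` returning samples on `[t0, t1)`.
#'   Used only in the dynamic condition.
#' @param game starting `game_state` from [new_game()].
#' @param player optional action policy `function(state, t_ms)` returning an
#'   action string, e.g. from [subject_player()]; `NULL` lets pieces fall
#'   unsteered.
#' @param control_dt_ms game control-step granularity in ms.
#' @return An [event_log()] containing `epoch`, `adaptation`, `judgment`,
#'   `tighten`, `clear`, `death` and `session` records.
#' @export
run_condition <- function(cfg, alpha = NULL, valence = NULL,
                          game = NULL, player = NULL, control_dt_ms = 100) {
  stopifnot(inherits(cfg, "session_config"))
  if (is.null(game))
    game <- new_game(seed = cfg$seed, level = speed_to_level(cfg$initial_speed_ms))
  th <- thresholds_from_config(cfg)
  needs_alpha <- cfg$condition != "control"
  needs_valence <- cfg$condition == "dynamic"
  alpha_fn <- make_alpha_provider(alpha, cfg$epoch_len)
  valence_fn <- make_valence_provider(valence)
  if (needs_alpha && is.null(alpha_fn))
    stop("condition '", cfg$condition, "' requires an alpha source")
  if (needs_valence && is.null(valence_fn))
    stop("condition 'dynamic' requires a valence source")

  duration <- cfg$duration
  # replay underrun: truncate to whole pacing epochs covered by the sources
  avail <- duration
  if (needs_alpha && is.data.frame(alpha))
    avail <- min(avail, max(alpha$t) + cfg$epoch_len)
  if (needs_valence && !is.function(valence)) {
    vt <- as_valence_samples(valence)$t
    gap <- if (length(vt) > 1L) stats::median(diff(vt)) else 0
    avail <- min(avail, max(vt) + gap)
  }
  eff <- floor(avail / cfg$pacing + 1e-9) * cfg$pacing
  if (eff < duration) {
    warning("source shorter than session: truncating to ", eff, " s")
    duration <- eff
  }

  records <- vector("list", 4096L)
  n_rec <- 0L
  push <- function(rec) {
    n_rec <<- n_rec + 1L
    if (n_rec > length(records)) length(records) <<- 2L * n_rec
    records[[n_rec]] <<- rec
  }

  alpha_acc <- data.frame(t = numeric(0), ratio = numeric(0),
                          artifact = logical(0))
  val_acc <- data.frame(t = numeric(0), v = numeric(0))
  level_changes <- data.frame(t = 0, level = game$level)
  level_at <- function(t) {
    i <- findInterval(t, level_changes$t)
    level_changes$level[max(i, 1L)]
  }

  pending <- list()       # queued adaptation judgments (dynamic)
  adapt_times <- numeric(0)
  n_small <- round(duration / cfg$epoch_len)
  game_t_ms <- 0
  ep_level_min <- game$level
  ep_level_max <- game$level
  pace_start <- 0

  for (i in seq_len(n_small)) {
    t0 <- (i - 1L) * cfg$epoch_len
    t1 <- i * cfg$epoch_len

    # -- game advances over [t0, t1)
    while (game_t_ms < t1 * 1000 - 1e-6) {
      dt <- min(control_dt_ms, t1 * 1000 - game_t_ms)
      action <- if (is.null(player)) "none" else player(game, game_t_ms)
      lvl_before <- game$level
      game <- step(game, action, dt)
      ev <- game$last_events
      t_now <- (game_t_ms + dt) / 1000
      if (isTRUE(ev$locked) && ev$cleared > 0) {
        push(list(t = t_now, type = "clear", n = ev$cleared,
                  score = game$score))
        if (cfg$condition == "control")
          game <- progression_update(game, ev$cleared)
      }
      if (isTRUE(ev$died))
        push(list(t = t_now, type = "death", deaths = game$deaths))
      if (game$level != lvl_before)
        level_changes <- rbind(level_changes,
                               data.frame(t = t_now, level = game$level))
      ep_level_min <- min(ep_level_min, game$level)
      ep_level_max <- max(ep_level_max, game$level)
      game_t_ms <- game_t_ms + dt
    }

    # -- physiological samples for [t0, t1)
    if (needs_alpha) {
      ep <- alpha_fn(t0, game$level)
      if (!is.null(ep))
        alpha_acc <- rbind(alpha_acc,
                           data.frame(t = t0, ratio = ep$ratio,
                                      artifact = isTRUE(ep$artifact)))
    }
    if (needs_valence) {
      vs <- valence_fn(t0, t1, level_at, adapt_times)
      if (!is.null(vs) && nrow(vs)) val_acc <- rbind(val_acc, vs)
    }

    # -- pacing boundary
    if (on_grid(t1, cfg$pacing)) {
      # resolve due adaptation judgments before the next evaluation
      if (needs_valence && length(pending)) {
        due <- vapply(pending, function(p) p$t_due <= t1 + 1e-9, logical(1))
        for (p in pending[due]) {
          vd <- adaptation_delta(val_acc, p$t_adapt, cfg$valence_window)
          th_before <- th
          if (identical(vd$verdict, "dissatisfied"))
            th <- loosen_threshold(th, p$crossed)
          push(list(t = t1, type = "judgment", t_adapt = p$t_adapt,
                    crossed = p$crossed, pre_mean = vd$pre_mean,
                    post_mean = vd$post_mean, delta = vd$delta,
                    verdict = vd$verdict,
                    upper_before = th_before$upper,
                    lower_before = th_before$lower,
                    upper = th$upper, lower = th$lower))
        }
        pending <- pending[!due]
      }

      crossed <- "none"
      alpha_avg <- NA_real_
      if (needs_alpha) {
        dec <- evaluate_epoch(alpha_acc, t1, th, cfg$alpha_window)
        crossed <- dec$crossed
        alpha_avg <- dec$alpha_avg
        if (crossed != "none") {
          lvl_before <- game$level
          adapt_times <- c(adapt_times, t1)
          game <- apply_adaptation(game, crossed)
          if (game$level != lvl_before)
            level_changes <- rbind(level_changes,
                                   data.frame(t = t1, level = game$level))
          push(list(t = t1, type = "adaptation",
                    direction = if (crossed == "upper") "slow_down" else "speed_up",
                    crossed = crossed, alpha_avg = alpha_avg,
                    level_before = lvl_before, level_after = game$level,
                    upper = th$upper, lower = th$lower))
          if (needs_valence)
            pending <- c(pending, list(list(
              t_adapt = t1, t_due = t1 + cfg$valence_window,
              crossed = crossed)))
        } else if (needs_valence && !dec$skipped) {
          # quiet epoch: tighten when the epoch valence delta is negative
          w <- cfg$valence_window
          q_post <- tryCatch(window_mean(val_acc, t1 - w, t1),
                             error = function(e) NA_real_)
          q_pre <- tryCatch(window_mean(val_acc, pace_start - w, pace_start),
                            error = function(e) NA_real_)
          qd <- q_post - q_pre
          if (!is.na(qd) && qd < 0) {
            th <- tighten_thresholds(th)
            push(list(t = t1, type = "tighten", delta = qd,
                      upper = th$upper, lower = th$lower))
          }
        }
      }

      push(list(t = pace_start, type = "epoch", level = level_at(pace_start),
                level_min = ep_level_min, level_max = ep_level_max,
                alpha_avg = if (is.na(alpha_avg)) NULL else alpha_avg,
                crossed = crossed, upper = th$upper, lower = th$lower,
                score = game$score, deaths = game$deaths,
                lines = game$lines_cleared_total))
      pace_start <- t1
      ep_level_min <- game$level
      ep_level_max <- game$level
    }
  }

  push(list(t = duration, type = "session", condition = cfg$condition,
            duration = duration, pacing = cfg$pacing,
            final_score = game$score, deaths = game$deaths,
            lines_cleared = game$lines_cleared_total,
            final_level = game$level,
            upper = th$upper, lower = th$lower))
  recs <- records[seq_len(n_rec)]
  ord <- order(vapply(recs, function(r) r$t, numeric(1)))
  event_log(recs[ord])
}
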