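#' Simulated-subject parameters
#'
#' The subject model has three coupled parts: a greedy placement policy whose
#' reliability degrades as difficulty exceeds skill, a generative model for
#' the normalized alpha ratio (cognitive load rises with the gap between
#' level and skill), and a generative model for facial valence (a flow curve
#' peaking where challenge matches skill, responding to level changes with a
#' short latency). None of these are estimates of any human population; they
#' exist so every controller can be exercised closed-loop offline.
#'
#' @param skill_level level at which the subject is balanced (1..15,
#'   fractional allowed).
#' @param alpha_base mean alpha ratio when playing exactly at skill.
#' @param alpha_gain change in mean ratio per level above skill (sign
#'   configurable).
#' @param alpha_noise_sd stationary SD of the AR(1) alpha noise.
#' @param ar_coef AR(1) coefficient of the alpha noise (band-power series are
#'   autocorrelated, which is what makes 5 s averaging meaningful).
#' @param v_max peak valence at the flow optimum.
#' @param valence_width SD (in levels) of the Gaussian flow curve.
#' @param valence_noise_sd white-noise SD on valence samples.
#' @param response_latency seconds before valence reflects a level change;
#'   also scales the action rate (minimum inter-action interval is
#'   `response_latency * speed_ms`).
#' @param error_rate either `NULL` (logistic in `level - skill_level`) or a
#'   fixed misplacement probability in [0, 1].
#' @param valence_mode `"flow"` (cooperative, the model above);
#'   `"adversarial"` (a deterministic slowly declining ramp `v0 - drift * t`,
#'   so every adaptation and every quiet epoch is judged negatively for a
#'   full session without saturating at -1); or `"adaptation_averse"`
#'   (valence drops for 2.5 s after every speed adaptation and is flat
#'   otherwise, so adaptations are judged negatively but quiet epochs are
#'   not).
#' @param adversarial_v0,adversarial_drift parameters of the adversarial ramp.
#' @return Object of class `subject_params`.
#' @export
subject_params <- function(skill_level = 8, alpha_base = 1.0,
                           alpha_gain = 0.3, alpha_noise_sd = 0.4,
                           ar_coef = 0.8, v_max = 0.6, valence_width = 3,
                           valence_noise_sd = 0.05, response_latency = 0.5,
                           error_rate = NULL,
                           valence_mode = c("flow", "adversarial",
                                            "adaptation_averse"),
                           adversarial_v0 = 0.9, adversarial_drift = 0.002) {
  valence_mode <- match.arg(valence_mode)
  stopifnot(skill_level >= 1, skill_level <= 15,
            alpha_noise_sd >= 0, valence_noise_sd >= 0,
            ar_coef >= 0, ar_coef < 1, valence_width > 0,
            response_latency >= 0)
  if (!is.null(error_rate))
    stopifnot(error_rate >= 0, error_rate <= 1)
  structure(list(skill_level = skill_level, alpha_base = alpha_base,
                 alpha_gain = alpha_gain, alpha_noise_sd = alpha_noise_sd,
                 ar_coef = ar_coef, v_max = v_max,
                 valence_width = valence_width,
                 valence_noise_sd = valence_noise_sd,
                 response_latency = response_latency,
                 error_rate = error_rate, valence_mode = valence_mode,
                 adversarial_v0 = adversarial_v0,
                 adversarial_drift = adversarial_drift),
            class = "subject_params")
}

#' Misplacement probability at a level
#'
#' Logistic in the difficulty-skill gap unless a fixed `error_rate` was set:
#' low below skill, rising steeply once the level exceeds skill by a couple
#' of steps.
#'
#' @param level current game level.
#' @param params a [subject_params()].
#' @export
error_rate_at <- function(level, params) {
  if (!is.null(params$error_rate)) return(params$error_rate)
  0.9 * stats::plogis((level - params$skill_level - 2) / 0.8)
}

## ---- placement policy ---------------------------------------------------

# all feasible (rot, col) placements with the resulting landing row
enumerate_placements <- function(board, piece) {
  out <- list()
  for (rot in 1:4) {
    off <- .piece_states[[piece$id]]$states[[rot]]
    for (col in (1L - min(off[, 2])):(BOARD_W - max(off[, 2]))) {
      p <- piece
      p$rot <- rot
      p$col <- col
      p$row <- 1L - min(off[, 1])
      if (cells_collide(board, piece_cells(p))) next
      while (TRUE) {
        q <- p
        q$row <- p$row + 1L
        if (cells_collide(board, piece_cells(q))) break
        p <- q
      }
      out[[length(out) + 1L]] <- p
    }
  }
  out
}

board_after <- function(board, piece) {
  board[piece_cells(piece)] <- TRUE
  full <- which(rowSums(board) == BOARD_W)
  if (length(full))
    board <- rbind(matrix(FALSE, nrow = length(full), ncol = BOARD_W),
                   board[-full, , drop = FALSE])
  board
}

# heuristic cost: holes dominate, then aggregate height, then bumpiness
board_cost <- function(board) {
  heights <- vapply(seq_len(BOARD_W), function(j) {
    filled <- which(board[, j])
    if (length(filled)) BOARD_H - min(filled) + 1L else 0L
  }, integer(1))
  holes <- sum(vapply(seq_len(BOARD_W), function(j) {
    filled <- which(board[, j])
    if (!length(filled)) return(0L)
    sum(!board[min(filled):BOARD_H, j])
  }, integer(1)))
  100 * holes + 2 * sum(heights) + sum(abs(diff(heights)))
}

#' Plan actions for the active piece
#'
#' Greedy one-piece lookahead: every (rotation, column) placement is
#' enumerated, the piece is dropped, and the landing minimizing a weighted
#' (holes, aggregate height, bumpiness) cost is chosen (ties: fewer
#' rotations, then leftmost). With probability `error_rate_at(level)` a
#' uniformly random different placement is chosen instead. The returned
#' action strings (rotations first, then lateral moves) steer the piece; the
#' caller emits them at the subject's action rate. Uses R's RNG for the
#' error draw; seed at the session level for determinism.
#'
#' @param board the 20 x 10 occupancy matrix (`state$board`).
#' @param piece the active piece (`state$piece`).
#' @param params a [subject_params()].
#' @param level current level (sets the misplacement probability).
#' @return Character vector of actions (possibly empty).
#' @export
plan_actions <- function(board, piece, params, level = 1) {
  placements <- enumerate_placements(board, piece)
  if (!length(placements)) return(character(0))
  costs <- vapply(placements, function(p) board_cost(board_after(board, p)),
                  numeric(1))
  n_rot <- vapply(placements, function(p) (p$rot - piece$rot) %% 4L, integer(1))
  cols <- vapply(placements, function(p) p$col, integer(1))
  best <- order(costs, n_rot, cols)[1L]
  pick <- best
  if (length(placements) > 1L &&
      stats::runif(1) < error_rate_at(level, params)) {
    others <- setdiff(seq_along(placements), best)
    pick <- others[sample.int(length(others), 1L)]
  }
  target <- placements[[pick]]
  k <- (target$rot - piece$rot) %% 4L
  rot_actions <- if (k == 3L) "rotate_ccw" else rep("rotate_cw", k)
  d <- target$col - piece$col
  lat_actions <- rep(if (d < 0) "left" else "right", abs(d))
  c(rot_actions, lat_actions)
}

#' Action policy closure for [run_condition()]
#'
#' Wraps [plan_actions()] into a stateful `function(state, t_ms)` that plans
#' once per spawned piece and emits one queued action per
#' `response_latency * speed_ms` milliseconds.
#'
#' @param params a [subject_params()].
#' @return A function usable as the `player` argument of [run_condition()].
#' @export
subject_player <- function(params) {
  env <- new.env(parent = emptyenv())
  env$sig <- NULL
  env$queue <- character(0)
  env$next_action_ms <- 0
  function(state, t_ms) {
    if (!identical(env$sig, state$rng_state)) {
      env$sig <- state$rng_state
      env$queue <- plan_actions(state$board, state$piece, params, state$level)
    }
    if (t_ms < env$next_action_ms || !length(env$queue)) return("none")
    a <- env$queue[[1L]]
    # hold an action that is currently infeasible (e.g. a rotation whose box
    # would poke above the board at spawn) and retry once the piece has fallen
    p <- state$piece
    if (a %in% c("rotate_cw", "rotate_ccw")) {
      p$rot <- ((p$rot - 1L + if (a == "rotate_cw") 1L else -1L) %% 4L) + 1L
    } else {
      p$col <- p$col + if (a == "left") -1L else 1L
    }
    if (cells_collide(state$board, piece_cells(p))) return("none")
    env$queue <- env$queue[-1L]
    env$next_action_ms <- t_ms + max(params$response_latency * state$speed_ms, 1)
    a
  }
}

## ---- generative physiology ---------------------------------------------

#' One alpha-ratio epoch from the load model
#'
#' `ratio = max(0, alpha_base + alpha_gain * (level - skill_level) + e_t)`
#' where `e_t` is AR(1) noise with coefficient `ar_coef` and stationary SD
#' `alpha_noise_sd`. With the defaults long-run draws stay within [0, 7],
#' emulating the observed ratio range of a normalized upper-alpha pipeline
#' (roughly 0.008--6.87).
#'
#' @param level current game level.
#' @param params a [subject_params()].
#' @param state AR state from the previous call (`NULL` to start).
#' @return `list(ratio, state)`.
#' @export
gen_alpha <- function(level, params, state = NULL) {
  e_prev <- if (is.null(state)) 0 else state$e
  innov_sd <- params$alpha_noise_sd * sqrt(1 - params$ar_coef^2)
  e <- params$ar_coef * e_prev +
    if (innov_sd > 0) stats::rnorm(1, 0, innov_sd) else 0
  ratio <- max(0, params$alpha_base +
                 params$alpha_gain * (level - params$skill_level) + e)
  list(ratio = ratio, state = list(e = e))
}

#' One valence sample from the flow model
#'
#' Cooperative mode: a Gaussian flow curve
#' `v_max * exp(-(level - skill)^2 / (2 * width^2))` plus white noise,
#' clipped to [-1, 1]; the caller supplies the level that was active
#' `response_latency` seconds ago, which is how level changes reach valence
#' with a lag. Adversarial mode ignores the level and returns the
#' deterministic declining ramp.
#'
#' @param level (lagged) game level.
#' @param params a [subject_params()].
#' @param t sample time in seconds (used by the adversarial modes).
#' @param adapt_times times of speed adaptations so far (used by the
#'   `"adaptation_averse"` mode).
#' @return Scalar valence in [-1, 1].
#' @export
gen_valence <- function(level, params, t = 0, adapt_times = numeric(0)) {
  if (params$valence_mode == "adversarial") {
    return(min(1, max(-1, params$adversarial_v0 - params$adversarial_drift * t)))
  }
  if (params$valence_mode == "adaptation_averse") {
    hit <- length(adapt_times) &&
      any(adapt_times <= t & t < adapt_times + 2.5)
    return(if (hit) -0.5 else 0.5)
  }
  v <- params$v_max *
    exp(-(level - params$skill_level)^2 / (2 * params$valence_width^2))
  if (params$valence_noise_sd > 0)
    v <- v + stats::rnorm(1, 0, params$valence_noise_sd)
  min(1, max(-1, v))
}

#' Closed-loop sources for a simulated subject
#'
#' Builds the `alpha`, `valence` and `player` arguments of [run_condition()]
#' from one [subject_params()]: a stateful alpha generator (one ratio epoch
#' per `epoch_len`), a 30 Hz valence generator responding to the lagged
#' level trace, and the placement policy.
#'
#' @param params a [subject_params()].
#' @param valence_rate valence sampling rate in Hz.
#' @return `list(alpha, valence, player)`.
#' @export
subject_sources <- function(params, valence_rate = 30) {
  ar_env <- new.env(parent = emptyenv())
  ar_env$state <- NULL
  alpha_fn <- function(t0, level) {
    g <- gen_alpha(level, params, ar_env$state)
    ar_env$state <- g$state
    list(ratio = g$ratio, artifact = FALSE)
  }
  valence_fn <- function(t0, t1, level_at, adapt_times = numeric(0)) {
    n <- round((t1 - t0) * valence_rate)
    if (n < 1L) return(NULL)
    ts <- t0 + (seq_len(n) - 1L) / valence_rate
    v <- vapply(ts, function(tt)
      gen_valence(level_at(tt - params$response_latency), params, tt,
                  adapt_times),
      numeric(1))
    data.frame(t = ts, v = v)
  }
  list(alpha = alpha_fn, valence = valence_fn,
       player = subject_player(params))
}

#' Synthetic raw EEG exercising the full DSP pipeline
#'
#' Open-loop raw-EEG synthesis for a given level trace: an 11.75 Hz (upper
#' alpha) sinusoid on P3 and P4 whose amplitude tracks the load model
#' (`amplitude^2` proportional to the target ratio), plus 1/f background
#' noise on all channels. Useful for end-to-end tests of
#' [alpha_ratio_pipeline()]; the closed loop itself consumes ratio epochs
#' directly.
#'
#' @param duration seconds of signal.
#' @param level constant level or `data.frame(t, level)` trace.
#' @param params a [subject_params()].
#' @param rate sampling rate in Hz.
#' @param labels channel labels (must include P3 and P4).
#' @param alpha_amp RMS amplitude of the alpha sinusoid at ratio 1.
#' @param noise_amp SD of the 1/f background noise.
#' @return A raw [multichannel_stream()].
#' @export
gen_raw_eeg <- function(duration, level, params = subject_params(),
                        rate = 500, labels = c("P3", "P4", "Cz", "Fz"),
                        alpha_amp = 1, noise_amp = 0.2) {
  stopifnot(all(c("P3", "P4") %in% labels))
  n <- round(duration * rate)
  ts <- (seq_len(n) - 1L) / rate
  lv <- if (is.data.frame(level)) {
    level$level[pmax(findInterval(ts, level$t), 1L)]
  } else rep(level, n)
  target_ratio <- pmax(0.01, params$alpha_base +
                         params$alpha_gain * (lv - params$skill_level))
  amp <- alpha_amp * sqrt(target_ratio)
  carrier <- sqrt(2) * amp * sin(2 * pi * 11.75 * ts)
  x <- matrix(0, nrow = n, ncol = length(labels))
  colnames(x) <- labels
  for (j in seq_along(labels)) x[, j] <- pink_noise(n) * noise_amp
  x[, "P3"] <- x[, "P3"] + carrier
  x[, "P4"] <- x[, "P4"] + carrier
  multichannel_stream(x, rate = rate, labels = labels)
}

# 1/f-shaped noise via spectral shaping
pink_noise <- function(n) {
  m <- 2^ceiling(log2(max(n, 2)))
  f <- c(1, seq_len(m / 2), rev(seq_len(m / 2 - 1)))
  spec <- (stats::rnorm(m) + 1i * stats::rnorm(m)) / sqrt(pmax(f, 1))
  x <- Re(stats::fft(spec, inverse = TRUE))
  x <- x[seq_len(n)]
  (x - mean(x)) / stats::sd(x)
}
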