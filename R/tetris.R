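## Headless Tetris core: 10 x 20 board, no soft/hard drop, simple centered
## rotation with wall rejection (no kicks), no lock delay.

BOARD_W <- 10L
BOARD_H <- 20L

# base shapes in fixed k x k boxes so rotation never changes the box
.piece_base <- list(
  I = list(k = 4L, cells = rbind(c(1, 0), c(1, 1), c(1, 2), c(1, 3))),
  O = list(k = 2L, cells = rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))),
  T = list(k = 3L, cells = rbind(c(0, 0), c(0, 1), c(0, 2), c(1, 1))),
  S = list(k = 3L, cells = rbind(c(0, 1), c(0, 2), c(1, 0), c(1, 1))),
  Z = list(k = 3L, cells = rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 2))),
  J = list(k = 3L, cells = rbind(c(0, 0), c(1, 0), c(1, 1), c(1, 2))),
  L = list(k = 3L, cells = rbind(c(0, 2), c(1, 0), c(1, 1), c(1, 2)))
)

rotate_cells_cw <- function(cells, k) cbind(cells[, 2], k - 1 - cells[, 1])

# 4 rotation states per piece, precomputed at load
.piece_states <- lapply(.piece_base, function(p) {
  states <- vector("list", 4L)
  cells <- p$cells
  for (r in 1:4) {
    states[[r]] <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
    cells <- rotate_cells_cw(cells, p$k)
  }
  list(k = p$k, states = states)
})

piece_names <- names(.piece_base)

# absolute board cells (rows, cols) of a piece instance
piece_cells <- function(piece) {
  off <- .piece_states[[piece$id]]$states[[piece$rot]]
  cbind(off[, 1] + piece$row, off[, 2] + piece$col)
}

cells_collide <- function(board, cells) {
  if (any(cells[, 1] < 1L | cells[, 1] > BOARD_H |
          cells[, 2] < 1L | cells[, 2] > BOARD_W)) return(TRUE)
  any(board[cells])
}

make_piece <- function(id, rot = 1L) {
  k <- .piece_states[[id]]$k
  off <- .piece_states[[id]]$states[[rot]]
  list(id = id, rot = rot,
       row = 1L - min(off[, 1]),                 # flush with the top row
       col = as.integer(floor((BOARD_W - k) / 2) + 1L))
}

# linear congruential generator for the piece sequence (self-contained so the
# engine never touches R's global RNG)
lcg_next <- function(s) (1103515245 * s + 12345) %% 2147483648

#' Gravity interval for a difficulty level, and its inverse
#'
#' Levels 1..15 map linearly onto gravity intervals: `speed_ms = 1600 -
#' 100 * level`, so level 1 is the slowest (1500 ms per line) and level 15
#' the fastest (100 ms per line).
#'
#' @param level integer level in 1..15.
#' @param speed_ms gravity interval in ms, one of 100, 200, ..., 1500.
#' @return `level_to_speed`: speed in ms; `speed_to_level`: the level.
#' @export
level_to_speed <- function(level) {
  if (any(level != round(level)) || any(level < 1 | level > 15))
    stop("level must be an integer in 1..15")
  as.integer(1600 - 100 * level)
}

#' @rdname level_to_speed
#' @export
speed_to_level <- function(speed_ms) {
  lv <- (1600 - speed_ms) / 100
  if (any(lv != round(lv)) || any(lv < 1 | lv > 15))
    stop("speed_ms must be one of 100, 200, ..., 1500")
  as.integer(lv)
}

#' Create a fresh game state
#'
#' @param seed integer seed for the piece sequence.
#' @param level starting level (default 12, i.e. 400 ms per line).
#' @return A `game_state`: 10 x 20 board, active piece, level/speed, score,
#'   cumulative cleared-line and death counters, and the piece RNG state.
#' @export
new_game <- function(seed = 1L, level = 12L) {
  state <- structure(list(
    board = matrix(FALSE, nrow = BOARD_H, ncol = BOARD_W),
    piece = NULL, level = as.integer(level),
    speed_ms = level_to_speed(level),
    score = 0, lines_cleared_total = 0L, deaths = 0L,
    gravity_acc_ms = 0, prog_counter = 0L,
    rng_state = as.numeric(seed) %% 2147483648,
    last_events = list()
  ), class = "game_state")
  spawn_and_check(state)$state
}

#' @export
print.game_state <- function(x, ...) {
  cat(sprintf("<game_state> level %d (%d ms/line), score %g, lines %d, deaths %d\n",
              x$level, x$speed_ms, x$score, x$lines_cleared_total, x$deaths))
  invisible(x)
}

spawn_piece <- function(state) {
  state$rng_state <- lcg_next(state$rng_state)
  id <- piece_names[(state$rng_state %% 7) + 1]
  state$piece <- make_piece(id)
  state
}

spawn_and_check <- function(state) {
  state <- spawn_piece(state)
  check_death(state)
}

#' Death check after a spawn attempt
#'
#' If the freshly spawned piece collides with the stack the game "dies": the
#' board is cleared, the death counter increments, and the current level,
#' speed and cumulative score are retained (scores and deaths are logged per
#' condition, cumulatively).
#'
#' @param state a `game_state` whose active piece was just spawned.
#' @return `list(state, died)`.
#' @export
check_death <- function(state) {
  died <- cells_collide(state$board, piece_cells(state$piece))
  if (died) {
    state$board[] <- FALSE
    state$deaths <- state$deaths + 1L
  }
  list(state = state, died = died)
}

#' Remove full rows and score them
#'
#' Full rows are removed, rows above shift down, and the score increases by
#' 100, 300, 500 or 800 points for 1, 2, 3 or 4 simultaneous lines.
#'
#' @param state a `game_state` in which a piece just locked.
#' @return `list(state, n_cleared)`.
#' @export
clear_lines <- function(state) {
  full <- which(rowSums(state$board) == BOARD_W)
  n <- length(full)
  if (n > 0L) {
    keep <- state$board[-full, , drop = FALSE]
    state$board <- rbind(matrix(FALSE, nrow = n, ncol = BOARD_W), keep)
    state$score <- state$score + c(0, 100, 300, 500, 800)[n + 1L]
    state$lines_cleared_total <- state$lines_cleared_total + n
  }
  list(state = state, n_cleared = n)
}

try_shift <- function(state, d_col) {
  p <- state$piece
  p$col <- p$col + d_col
  if (!cells_collide(state$board, piece_cells(p))) state$piece <- p
  state
}

try_rotate <- function(state, dir) {
  p <- state$piece
  p$rot <- ((p$rot - 1L + dir) %% 4L) + 1L
  if (!cells_collide(state$board, piece_cells(p))) state$piece <- p
  state
}

#' Advance the game
#'
#' Applies at most one control action (lateral move or rotation; illegal
#' moves are silent no-ops — there is deliberately no soft or hard drop),
#' then applies gravity: the piece descends one row for every full
#' `speed_ms` of accumulated elapsed time. A piece whose descent is blocked
#' locks immediately (no lock delay), full rows are cleared and scored, and
#' the next piece spawns (with a death check).
#'
#' @param state a `game_state`.
#' @param action one of `"left"`, `"right"`, `"rotate_cw"`, `"rotate_ccw"`,
#'   `"none"`.
#' @param elapsed_ms elapsed time to simulate; defaults to one gravity tick.
#' @return The new `game_state`; `state$last_events` holds `locked`,
#'   `cleared` (lines) and `died` for the call.
#' @export
step <- function(state, action = "none", elapsed_ms = state$speed_ms) {
  stopifnot(inherits(state, "game_state"))
  action <- match.arg(action, c("none", "left", "right", "rotate_cw", "rotate_ccw"))
  state$last_events <- list(locked = FALSE, cleared = 0L, died = FALSE)
  state <- switch(action,
    left = try_shift(state, -1L),
    right = try_shift(state, 1L),
    rotate_cw = try_rotate(state, 1L),
    rotate_ccw = try_rotate(state, -1L),
    none = state)
  state$gravity_acc_ms <- state$gravity_acc_ms + elapsed_ms
  while (state$gravity_acc_ms >= state$speed_ms) {
    state$gravity_acc_ms <- state$gravity_acc_ms - state$speed_ms
    p <- state$piece
    p$row <- p$row + 1L
    if (!cells_collide(state$board, piece_cells(p))) {
      state$piece <- p
    } else {
      state$board[piece_cells(state$piece)] <- TRUE
      cl <- clear_lines(state)
      state <- cl$state
      sp <- spawn_and_check(state)
      state <- sp$state
      state$gravity_acc_ms <- 0
      state$last_events <- list(locked = TRUE, cleared = cl$n_cleared,
                                died = sp$died)
      break
    }
  }
  state
}

#' Set the game level (clamped) and its speed
#'
#' @param state a `game_state`.
#' @param level target level; clamped to [1, 15].
#' @export
set_level <- function(state, level) {
  level <- max(1L, min(15L, as.integer(level)))
  state$level <- level
  state$speed_ms <- level_to_speed(level)
  state
}

#' ASCII dump of the board (debugging aid)
#'
#' @param state a `game_state`.
#' @param show_piece draw the active piece as `*`.
#' @return Character vector, one string per board row (top first).
#' @export
ascii_board <- function(state, show_piece = TRUE) {
  b <- matrix(ifelse(state$board, "#", "."), nrow = BOARD_H)
  if (show_piece && !is.null(state$piece)) {
    cells <- piece_cells(state$piece)
    ok <- cells[, 1] >= 1 & cells[, 1] <= BOARD_H
    b[cells[ok, , drop = FALSE]] <- "*"
  }
  apply(b, 1L, paste, collapse = "")
}
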