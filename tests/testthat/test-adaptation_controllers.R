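test_that("control progression: one level per four cumulatively cleared rows", {
  g <- new_game(seed = 1, level = 12)
  g <- progression_update(g, 3)
  expect_equal(g$level, 12L)
  g <- progression_update(g, 1)          # counter reaches 4
  expect_equal(g$level, 13L)
  g <- progression_update(g, 4)          # one multiple crossed at once
  expect_equal(g$level, 14L)
  g <- set_level(g, 15)
  g <- progression_update(g, 4)          # clamped at the fastest level
  expect_equal(g$level, 15L)
})

test_that("epoch evaluation averages 5 s of unflagged ratios, inclusive crossings", {
  th <- threshold_state()
  mk <- function(ratio) data.frame(t = seq(5, 9.5, 0.5), ratio = ratio,
                                   artifact = FALSE)
  expect_equal(evaluate_epoch(mk(2.01), 10, th)$crossed, "upper")
  expect_equal(evaluate_epoch(mk(1.0), 10, th)$crossed, "none")
  expect_equal(evaluate_epoch(mk(0.4), 10, th)$crossed, "lower")
  # a change of 100% exactly ("100% or more") triggers
  expect_equal(evaluate_epoch(mk(2.0), 10, th)$crossed, "upper")
  expect_equal(evaluate_epoch(mk(0.5), 10, th)$crossed, "lower")
  expect_equal(evaluate_epoch(mk(1.99), 10, th)$crossed, "none")
  expect_equal(evaluate_epoch(mk(0.51), 10, th)$crossed, "none")
  # artifact epochs are excluded from the average
  a <- mk(1.0)
  a$ratio[1:5] <- 100
  a$artifact[1:5] <- TRUE
  d <- evaluate_epoch(a, 10, th)
  expect_equal(d$alpha_avg, 1.0)
  expect_equal(d$crossed, "none")
  # fully flagged window is skipped
  a$artifact <- TRUE
  d2 <- evaluate_epoch(a, 10, th)
  expect_true(d2$skipped)
  expect_equal(d2$crossed, "none")
})

test_that("adaptations move one level, clamped to [1, 15]", {
  g <- new_game(seed = 1, level = 12)
  g2 <- apply_adaptation(g, "upper")
  expect_equal(g2$level, 11L)
  expect_equal(g2$speed_ms, 500L)
  expect_equal(apply_adaptation(new_game(seed = 1, level = 1), "upper")$level, 1L)
  expect_equal(apply_adaptation(new_game(seed = 1, level = 15), "lower")$level, 15L)
})

test_that("loosening moves only the crossed threshold away from the middle", {
  th <- threshold_state()
  up <- loosen_threshold(th, "upper")
  expect_equal(up$upper, 2.1)
  expect_equal(up$lower, 0.5)
  expect_equal(ratio_to_fractional(up$upper), 1.1)
  # with baseline 4, crossing the loosened threshold needs raw alpha 8.4
  base <- baseline_profile(4)
  r <- normalize_epochs(data.frame(t = 0, power = 8.4), base)
  expect_true(r$ratio >= up$upper)
  r2 <- normalize_epochs(data.frame(t = 0, power = 8.39), base)
  expect_false(r2$ratio >= up$upper)

  lo <- loosen_threshold(threshold_state(guard = FALSE), "lower")
  expect_equal(lo$lower, 0.4)
  expect_equal(lo$upper, 2.0)
  for (i in 1:5) lo <- loosen_threshold(lo, "lower")
  expect_equal(lo$lower, -0.1)   # unguarded: unreachable by a ratio >= 0
  # guarded, the lower threshold bottoms out at one step
  lg <- threshold_state()
  for (i in 1:10) lg <- loosen_threshold(lg, "lower")
  expect_equal(lg$lower, 0.1)
})

test_that("tightening moves both thresholds toward the middle", {
  th <- tighten_thresholds(threshold_state())
  expect_equal(th$upper, 1.9)
  expect_equal(th$lower, 0.6)
  # unguarded repetition crosses the thresholds
  tu <- threshold_state(guard = FALSE)
  for (i in 1:9) tu <- tighten_thresholds(tu)
  expect_lt(tu$upper, tu$lower)
  # guarded tightening stops at a gap of two steps
  tg <- threshold_state()
  for (i in 1:20) tg <- tighten_thresholds(tg)
  expect_equal(tg$upper - tg$lower, 2 * tg$step)
  expect_gte(tg$lower, tg$step)
})

test_that("fixed condition with in-band alpha never adapts and keeps thresholds", {
  cfg <- session_config(condition = "fixed", duration = 900, seed = 1)
  log <- run_session(cfg, alpha = const_alpha(1.0, 900))
  expect_length(log_records(log, "adaptation"), 0L)
  ses <- log_records(log, "session")[[1]]
  expect_identical(ses$upper, cfg$upper_threshold)
  expect_identical(ses$lower, cfg$lower_threshold)
  expect_length(log_records(log, "epoch"), 90L)
})

test_that("fixed condition thresholds are immutable even when adapting", {
  # alternate 10 s blocks well above and below the thresholds
  ratios <- rep(rep(c(2.8, 0.2), each = 20), 6)
  alpha <- data.frame(t = seq(0, 119.5, 0.5), ratio = ratios, artifact = FALSE)
  cfg <- session_config(condition = "fixed", duration = 120, seed = 2)
  log <- run_session(cfg, alpha = alpha)
  expect_gt(length(log_records(log, "adaptation")), 0L)
  for (r in log_records(log, "epoch")) {
    expect_identical(r$upper, 2.0)
    expect_identical(r$lower, 0.5)
  }
})

test_that("dynamic loop: dissatisfied upper crossings raise the threshold until quiet", {
  # constant ratio 2.5; valence drops for 2 s after each adaptation, flat
  # otherwise, so only adaptation judgments are negative
  dur <- 150
  adapt_times <- seq(10, 60, 10)
  vfun <- function(t) {
    for (ta in adapt_times) if (t >= ta && t < ta + 2) return(-0.5)
    0.5
  }
  cfg <- session_config(condition = "dynamic", duration = dur, seed = 3)
  log <- run_session(cfg, alpha = const_alpha(2.5, dur),
                     valence = valence_from_fn(vfun, dur))
  adapts <- log_records(log, "adaptation")
  expect_equal(length(adapts), 6L)      # 2.5 >= 2.5 still crosses at 60 s
  expect_true(all(vapply(adapts, function(r) r$t, 0) <= 60))
  ses <- log_records(log, "session")[[1]]
  expect_equal(ses$upper, 2.6)          # 2.0 + 6 * 0.1, now above 2.5
  expect_equal(ses$lower, 0.5)
  verdicts <- vapply(log_records(log, "judgment"), `[[`, "", "verdict")
  expect_true(all(verdicts == "dissatisfied"))
})

test_that("satisfied adaptations leave thresholds unchanged", {
  dur <- 100
  cfg <- session_config(condition = "dynamic", duration = dur, seed = 4)
  log <- run_session(cfg, alpha = const_alpha(2.5, dur),
                     valence = valence_from_fn(function(t) 0.3, dur))
  expect_gt(length(log_records(log, "adaptation")), 0L)
  ses <- log_records(log, "session")[[1]]
  expect_identical(ses$upper, 2.0)
  expect_identical(ses$lower, 0.5)
  expect_length(log_records(log, "tighten"), 0L)
})

test_that("every adaptation sits on a pacing boundary, at most one per epoch", {
  set.seed(31)
  dur <- 200
  alpha <- data.frame(t = seq(0, dur - 0.5, 0.5),
                      ratio = runif(2 * dur, 0, 3), artifact = FALSE)
  cfg <- session_config(condition = "dynamic", duration = dur, seed = 5)
  log <- run_session(cfg, alpha = alpha,
                     valence = valence_from_fn(function(t) sin(t / 7) / 2, dur))
  t_adapt <- vapply(log_records(log, "adaptation"), function(r) r$t, 0)
  expect_true(all(abs(t_adapt / cfg$pacing - round(t_adapt / cfg$pacing)) < 1e-9))
  expect_false(any(duplicated(t_adapt)))
  for (r in log_records(log, "epoch")) {
    expect_gte(r$level, 1)
    expect_lte(r$level, 15)
  }
})

test_that("replay sources shorter than the session truncate with a warning", {
  cfg <- session_config(condition = "fixed", duration = 120, seed = 6)
  expect_warning(log <- run_session(cfg, alpha = const_alpha(1.0, 60)),
                 "truncating")
  expect_length(log_records(log, "epoch"), 6L)
})
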