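test_that("preprocess notches 60 Hz, removes common mode, keeps in-band content", {
  fs <- 500
  ts <- (seq_len(fs * 20) - 1L) / fs
  set.seed(1)
  x <- cbind(P3 = sin(2 * pi * 60 * ts) + rnorm(length(ts), 0, 0.1),
             P4 = sin(2 * pi * 60 * ts) + 2 * rnorm(length(ts), 0, 0.1),
             Cz = rnorm(length(ts), 0, 0.1))
  pp <- preprocess(multichannel_stream(x, fs))
  expect_equal(pp$rate, 256)
  expect_equal(ncol(pp$samples), 3L)
  sl <- function(sig, fs, a, b) sig[(a * fs):(b * fs)]
  atten_db <- 10 * log10(fft_band_power(sl(x[, 1], 500, 5, 15), 500, 60) /
                         fft_band_power(sl(pp$samples[, 1], 256, 5, 15), 256, 60))
  expect_gt(atten_db, 20)

  # constant offsets are pure common mode: CAR output ~ 0
  xo <- cbind(A = rep(3, 2000), B = rep(3, 2000))
  ppo <- preprocess(multichannel_stream(xo, 500))
  expect_lt(max(abs(ppo$samples)), 1e-6)

  # a 10 Hz passband tone survives downsampling from 500 to 256 Hz:
  # steady-state RMS is preserved within passband ripple
  x10 <- cbind(P3 = sin(2 * pi * 10 * ts), P4 = -sin(2 * pi * 10 * ts))
  pp10 <- preprocess(multichannel_stream(x10, 500))
  rms_out <- sd(sl(pp10$samples[, 1], 256, 5, 15))
  rms_in <- sd(sl(x10[, 1], 500, 5, 15))
  expect_gt(rms_out / rms_in, 0.9)
  expect_lt(rms_out / rms_in, 1.1)

  expect_error(preprocess(multichannel_stream(x10, 100)), "below the target")
  expect_error(preprocess(multichannel_stream(x10[, 1, drop = FALSE], 500)),
               "2 channels")
})

test_that("riemann_distance matches the closed form and satisfies the axioms", {
  expect_equal(riemann_distance(diag(2), 2 * diag(2)), sqrt(2 * log(2)^2))
  set.seed(42)
  for (i in 1:20) {
    d <- sample(2:5, 1)
    a <- random_spd(d); b <- random_spd(d)
    expect_equal(riemann_distance(a, a), 0, tolerance = 1e-7)
    expect_gte(riemann_distance(a, b), 0)
    expect_equal(riemann_distance(a, b), riemann_distance(b, a),
                 tolerance = 1e-8)
    m <- matrix(rnorm(d * d), d) + diag(d)
    expect_equal(riemann_distance(m %*% a %*% t(m), m %*% b %*% t(m)),
                 riemann_distance(a, b), tolerance = 1e-6)
  }
  expect_error(riemann_distance(diag(2), diag(3)), "dimensions")
})

test_that("artifact flags: quiet streams stay mostly unflagged, bursts get caught", {
  set.seed(2)
  x <- matrix(rnorm(256 * 60 * 3), ncol = 3)
  colnames(x) <- c("P3", "P4", "Cz")
  s <- multichannel_stream(x, 256)
  fl <- artifact_flags(s, z_thresh = 5, warmup_sec = 0)
  expect_length(fl, 120L)
  expect_lt(mean(fl), 0.10)

  burst_rows <- (256 * 30 + 1):(256 * 30.5)
  x2 <- x
  x2[burst_rows, ] <- 50 * x2[burst_rows, ]
  fl2 <- artifact_flags(multichannel_stream(x2, 256), warmup_sec = 0)
  expect_true(fl2[61])  # epoch [30, 30.5)

  # identical epochs -> all distances zero -> no flags
  one <- matrix(rnorm(128 * 2), ncol = 2)
  xid <- do.call(rbind, rep(list(one), 20))
  expect_false(any(artifact_flags(multichannel_stream(xid, 256),
                                  warmup_sec = 0)))
  # warm-up epochs are flagged unconditionally
  fl3 <- artifact_flags(s, warmup_sec = 2)
  expect_true(all(fl3[1:4]))
})

test_that("alpha_epochs measures upper-alpha band power per 0.5 s epoch", {
  s <- sine_stream(11.75, rate = 256, duration = 10)
  ae <- alpha_epochs(s)
  expect_equal(nrow(ae), 20L)
  expect_equal(ae$t, seq(0, 9.5, 0.5))
  # mean square of a unit in-band sinusoid is 1/2 (after filter settling)
  expect_equal(mean(ae$power[11:20]), 0.5, tolerance = 0.05)

  out_band <- alpha_epochs(sine_stream(20, rate = 256, duration = 10))
  expect_lt(mean(out_band$power[11:20]), 0.05 * mean(ae$power[11:20]))

  zero <- alpha_epochs(multichannel_stream(matrix(0, 2560, 2), 256,
                                           labels = c("P3", "P4")))
  expect_equal(max(zero$power), 0)

  s_bad <- multichannel_stream(matrix(0, 256, 2), 256, labels = c("O1", "O2"))
  expect_error(alpha_epochs(s_bad), "P3.*available|available")
})

test_that("in-band tones dominate out-of-band tones by at least 10x", {
  p_in <- mean(alpha_epochs(sine_stream(11.75, 256, 10))$power[11:20])
  for (f in c(4, 8, 8.5, 15, 20, 40)) {
    p_out <- mean(alpha_epochs(sine_stream(f, 256, 10))$power[11:20])
    expect_gt(p_in / p_out, 10)
  }
})

test_that("baseline is the mean of unflagged calibration epoch powers", {
  powers <- data.frame(t = seq(0, 59.5, 0.5), power = 4)
  expect_equal(compute_baseline(powers)$mean_alpha_power, 4)

  powers$power <- rep(c(2, 6), 60)
  expect_equal(compute_baseline(powers)$mean_alpha_power, 4)

  set.seed(3)
  powers$power <- rexp(120)
  flags <- rep(FALSE, 120)
  flags[sample(120, 12)] <- TRUE
  expect_equal(compute_baseline(powers, flags)$mean_alpha_power,
               mean(powers$power[!flags]))

  expect_error(compute_baseline(powers[1:50, ]), "shorter")
  expect_error(compute_baseline(powers, rep(TRUE, 120)), "artifact-flagged")
  expect_error(baseline_profile(0), "positive")
})

test_that("normalization against baseline gives the expected ratios", {
  b <- baseline_profile(4)
  r <- normalize_epochs(data.frame(t = c(0, 0.5), power = c(8, 2)), b)
  expect_equal(r$ratio, c(2.0, 0.5))

  # self-normalization: the calibration segment itself has mean ratio 1
  set.seed(4)
  powers <- data.frame(t = seq(0, 89.5, 0.5), power = rexp(180) + 0.1)
  flags <- runif(180) < 0.1
  base <- compute_baseline(powers, flags)
  ratios <- normalize_epochs(powers, base, flags)
  expect_equal(mean(ratios$ratio[!ratios$artifact]), 1, tolerance = 1e-9)
})

test_that("scaling the raw stream scales power by k^2 and leaves ratios fixed", {
  set.seed(5)
  n <- 256 * 8
  x <- matrix(rnorm(2 * n), ncol = 2)
  colnames(x) <- c("P3", "P4")
  k <- 3.7
  p1 <- alpha_epochs(multichannel_stream(x, 256))
  p2 <- alpha_epochs(multichannel_stream(k * x, 256))
  expect_equal(p2$power, k^2 * p1$power, tolerance = 1e-6)
  r1 <- normalize_epochs(p1, baseline_profile(mean(p1$power)))
  r2 <- normalize_epochs(p2, baseline_profile(k^2 * mean(p1$power)))
  expect_equal(r2$ratio, r1$ratio, tolerance = 1e-6)
})

test_that("the full raw-EEG pipeline recovers load-dependent alpha ratios", {
  set.seed(6)
  params <- subject_params(alpha_noise_sd = 0)
  cal <- gen_raw_eeg(70, level = params$skill_level, params = params)
  high <- gen_raw_eeg(30, level = 13, params = params)
  low <- gen_raw_eeg(30, level = 5, params = params)
  r_hi <- alpha_ratio_pipeline(high, cal)
  r_lo <- alpha_ratio_pipeline(low, cal)
  m_hi <- mean(r_hi$ratio[!r_hi$artifact])
  m_lo <- mean(r_lo$ratio[!r_lo$artifact])
  # target ratios: 1 + 0.3 * (13 - 8) = 2.5 and 1 + 0.3 * (5 - 8) = 0.1
  expect_gt(m_hi, 2)
  expect_lt(m_lo, 0.5)
})
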