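#' Online EEG preprocessing chain
#'
#' Reproduces the online preprocessing order used by the adaptive system:
#' down-sampling to 256 Hz, causal 4th-order Butterworth band-pass at
#' 1--50 Hz, a 60 Hz IIR notch (biquad, Q = 30), an optional blink-removal
#' stage, and re-referencing to the common average (CAR). Channel count is
#' preserved. The filters are applied causally because the original pipeline
#' ran online; the first `warmup` seconds of the output carry the IIR
#' transient and are marked so downstream artifact handling can drop them
#' (attribute `warmup_sec`).
#'
#' @param stream raw [multichannel_stream()], rate >= 256 Hz, >= 2 channels.
#' @param target_rate output rate in Hz.
#' @param band band-pass edges in Hz.
#' @param notch_hz,notch_q notch centre frequency and quality factor.
#' @param blink_fn optional blink-removal stage: a function
#'   `f(samples_matrix, rate)` returning a matrix of the same shape. The
#'   default passes the data through unchanged; [blink_interpolate()] is a
#'   simple amplitude-threshold alternative.
#' @param warmup seconds of initial output regarded as filter transient.
#' @return A preprocessed `multichannel_stream` at `target_rate` with
#'   attribute `warmup_sec`.
#' @export
preprocess <- function(stream, target_rate = 256, band = c(1, 50),
                       notch_hz = 60, notch_q = 30, blink_fn = NULL,
                       warmup = 2) {
  stopifnot(inherits(stream, "multichannel_stream"))
  if (stream$rate < target_rate)
    stop("stream rate (", stream$rate, " Hz) is below the target rate (",
         target_rate, " Hz); upsampling is not supported")
  if (ncol(stream$samples) < 2L)
    stop("common average referencing requires at least 2 channels")

  x <- stream$samples
  # rational-rate resampling to target_rate
  if (stream$rate != target_rate) {
    g <- gcd_int(round(target_rate), round(stream$rate))
    p <- round(target_rate) / g
    q <- round(stream$rate) / g
    x <- apply(x, 2L, function(col) as.numeric(signal::resample(col, p, q)))
  }
  fs <- target_rate

  bp <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- apply(x, 2L, function(col) as.numeric(signal::filter(bp, col)))

  if (!is.null(notch_hz) && notch_hz < fs / 2) {
    nc <- notch_biquad(notch_hz, fs, notch_q)
    x <- apply(x, 2L, function(col)
      as.numeric(signal::filter(nc$b, nc$a, col)))
  }

  if (!is.null(blink_fn)) x <- blink_fn(x, fs)

  x <- x - rowMeans(x)  # CAR

  out <- multichannel_stream(x, rate = fs, labels = stream$labels,
                             start_time = stream$start_time)
  attr(out, "warmup_sec") <- warmup
  out
}

# second-order IIR notch (RBJ audio-EQ cookbook coefficients)
notch_biquad <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Amplitude-threshold blink interpolation
#'
#' Minimal blink-removal stage for [preprocess()]: samples whose absolute
#' value exceeds `k` robust SDs (MAD) of their channel are replaced by linear
#' interpolation from the surrounding samples.
#'
#' @param k threshold in robust standard deviations.
#' @return A function usable as `blink_fn` in [preprocess()].
#' @export
blink_interpolate <- function(k = 8) {
  function(x, rate) {
    for (j in seq_len(ncol(x))) {
      col <- x[, j]
      s <- stats::mad(col)
      if (s == 0) next
      bad <- abs(col - stats::median(col)) > k * s
      if (any(bad) && !all(bad)) {
        idx <- seq_along(col)
        col[bad] <- stats::approx(idx[!bad], col[!bad], xout = idx[bad],
                                  rule = 2)$y
        x[, j] <- col
      }
    }
    x
  }
}

## ---- SPD geometry -------------------------------------------------------

sym <- function(m) (m + t(m)) / 2

spd_eigen <- function(m, reg = 1e-12) {
  m <- sym(m)
  e <- eigen(m, symmetric = TRUE)
  if (any(e$values <= 0)) {
    # Tikhonov regularization toward SPD
    bump <- abs(min(e$values)) + reg * max(abs(e$values), 1)
    m <- m + diag(bump, nrow(m))
    e <- eigen(m, symmetric = TRUE)
    if (any(e$values <= 0))
      stop("matrix is not positive definite even after regularization")
  }
  e
}

spd_logm <- function(m) {
  e <- spd_eigen(m)
  e$vectors %*% diag(log(e$values), length(e$values)) %*% t(e$vectors)
}

spd_expm <- function(m) {
  e <- eigen(sym(m), symmetric = TRUE)
  e$vectors %*% diag(exp(e$values), length(e$values)) %*% t(e$vectors)
}

spd_invsqrt <- function(m) {
  e <- spd_eigen(m)
  e$vectors %*% diag(1 / sqrt(e$values), length(e$values)) %*% t(e$vectors)
}

#' Affine-invariant Riemannian distance between SPD matrices
#'
#' The geodesic distance `sqrt(sum(log(lambda_i)^2))` over the eigenvalues
#' `lambda_i` of `solve(a) %*% b`, computed stably as the eigenvalues of
#' `a^{-1/2} b a^{-1/2}`. This is the metric used to compare a window's
#' channel covariance against the online mean for artifact detection.
#'
#' @param a,b symmetric positive-definite matrices of equal dimension.
#' @return Non-negative scalar; 0 iff `a == b`.
#' @export
riemann_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("matrices must have equal dimensions")
  isa <- spd_invsqrt(a)
  w <- spd_eigen(isa %*% sym(b) %*% isa)$values
  sqrt(sum(log(w)^2))
}

#' Per-epoch channel covariance matrices
#'
#' @param stream preprocessed [multichannel_stream()].
#' @param epoch_len epoch length in seconds.
#' @return List of covariance matrices, one per complete epoch (partial
#'   trailing epoch discarded).
#' @export
epoch_covariances <- function(stream, epoch_len = 0.5) {
  n_ep <- floor(stream_duration(stream) / epoch_len)
  spe <- round(epoch_len * stream$rate)
  if (spe < 2L) stop("epoch window shorter than 2 samples")
  lapply(seq_len(n_ep), function(i) {
    idx <- ((i - 1L) * spe + 1L):(i * spe)
    stats::cov(stream$samples[idx, , drop = FALSE])
  })
}

#' Riemannian-distance artifact flags
#'
#' For every epoch the channel covariance is compared (affine-invariant
#' Riemannian distance) against an online mean covariance maintained as the
#' running arithmetic mean in the log-Euclidean domain. An epoch is flagged
#' when its distance exceeds the running `median + z_thresh * MAD` of the
#' distances seen so far. Epochs inside the filter warm-up window are always
#' flagged.
#'
#' @param stream preprocessed [multichannel_stream()].
#' @param epoch_len epoch length in seconds.
#' @param z_thresh robust z threshold on the distance.
#' @param warmup_sec seconds at stream start flagged unconditionally; default
#'   taken from the stream's `warmup_sec` attribute (0 if absent).
#' @return Logical vector, one flag per complete epoch (`TRUE` = artifact).
#' @export
artifact_flags <- function(stream, epoch_len = 0.5, z_thresh = 5,
                           warmup_sec = NULL) {
  if (is.null(warmup_sec)) {
    warmup_sec <- attr(stream, "warmup_sec")
    if (is.null(warmup_sec)) warmup_sec <- 0
  }
  covs <- epoch_covariances(stream, epoch_len)
  n <- length(covs)
  flags <- logical(n)
  dists <- numeric(n)
  mean_log <- NULL
  for (i in seq_len(n)) {
    li <- spd_logm(covs[[i]])
    mean_log <- if (is.null(mean_log)) li else mean_log + (li - mean_log) / i
    dists[i] <- riemann_distance(covs[[i]], spd_expm(mean_log))
    d_seen <- dists[seq_len(i)]
    cut <- stats::median(d_seen) + z_thresh * stats::mad(d_seen)
    flags[i] <- dists[i] > cut
  }
  t_ep <- (seq_len(n) - 1L) * epoch_len
  flags[t_ep < warmup_sec] <- TRUE
  flags
}

#' Upper-alpha band power per epoch
#'
#' Band-pass filters the named parietal channels to the upper alpha band,
#' squares the samples, and averages within each epoch and across the
#' channels, yielding one power value per `epoch_len` window. Epochs are
#' half-open `[t, t + epoch_len)`; a partial trailing epoch is discarded.
#'
#' @param stream preprocessed [multichannel_stream()] containing the requested
#'   channels.
#' @param band band edges in Hz (upper alpha: 10.5--13).
#' @param channels channel labels to keep and average (default P3 and P4).
#' @param epoch_len epoch length in seconds.
#' @return `data.frame(t, power)` with `t` the epoch start time in seconds.
#' @export
alpha_epochs <- function(stream, band = c(10.5, 13), channels = c("P3", "P4"),
                         epoch_len = 0.5) {
  stopifnot(inherits(stream, "multichannel_stream"))
  missing <- setdiff(channels, stream$labels)
  if (length(missing))
    stop("channel(s) ", paste(missing, collapse = ", "),
         " not found; available: ", paste(stream$labels, collapse = ", "))
  fs <- stream$rate
  bp <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- stream$samples[, channels, drop = FALSE]
  x <- apply(x, 2L, function(col) as.numeric(signal::filter(bp, col)))^2
  spe <- round(epoch_len * fs)
  n_ep <- floor(nrow(x) / spe)
  power <- vapply(seq_len(n_ep), function(i)
    mean(x[((i - 1L) * spe + 1L):(i * spe), ]), numeric(1))
  data.frame(t = stream$start_time + (seq_len(n_ep) - 1L) * epoch_len,
             power = power)
}

#' Baseline profile from a calibration segment
#'
#' The mean upper-alpha epoch power over an (emotionally neutral) calibration
#' minute, used to normalize all subsequent epochs. Artifact-flagged epochs
#' are excluded from the mean.
#'
#' @param powers `data.frame(t, power)` from [alpha_epochs()].
#' @param artifact optional logical vector of flags (same length); `NULL`
#'   means no epoch is flagged.
#' @param epoch_len epoch length in seconds.
#' @param min_duration minimum calibration length in seconds (default 60).
#' @return Object of class `baseline_profile` with field `mean_alpha_power`.
#' @export
compute_baseline <- function(powers, artifact = NULL, epoch_len = 0.5,
                             min_duration = 60) {
  if (nrow(powers) * epoch_len < min_duration)
    stop("calibration segment shorter than ", min_duration, " s")
  if (is.null(artifact)) artifact <- logical(nrow(powers))
  keep <- !artifact
  if (!any(keep)) stop("all calibration epochs are artifact-flagged")
  baseline_profile(mean(powers$power[keep]))
}

#' @rdname compute_baseline
#' @param mean_alpha_power positive scalar.
#' @export
baseline_profile <- function(mean_alpha_power) {
  if (!is.finite(mean_alpha_power) || mean_alpha_power <= 0)
    stop("baseline mean alpha power must be positive")
  structure(list(mean_alpha_power = as.numeric(mean_alpha_power)),
            class = "baseline_profile")
}

#' Normalize epoch powers against the calibration baseline
#'
#' Each epoch power is divided by the calibration mean, giving the
#' dimensionless alpha ratio the decision rule consumes (2.0 = a 100%
#' increase over baseline; 0.5 = a two-fold decrease).
#'
#' @param powers `data.frame(t, power)` from [alpha_epochs()].
#' @param baseline a [baseline_profile()].
#' @param artifact optional logical flags carried through (default all
#'   `FALSE`).
#' @return `data.frame(t, ratio, artifact)` — the alpha-epoch series.
#' @export
normalize_epochs <- function(powers, baseline, artifact = NULL) {
  stopifnot(inherits(baseline, "baseline_profile"))
  if (baseline$mean_alpha_power <= 0) stop("baseline must be positive")
  if (is.null(artifact)) artifact <- logical(nrow(powers))
  stopifnot(length(artifact) == nrow(powers))
  data.frame(t = powers$t,
             ratio = powers$power / baseline$mean_alpha_power,
             artifact = as.logical(artifact))
}

#' Full stream-to-ratio pipeline
#'
#' Convenience wrapper chaining [preprocess()], [artifact_flags()],
#' [alpha_epochs()] and [normalize_epochs()] for a raw EEG stream, given a
#' previously computed baseline (or a raw calibration stream from which one
#' is computed).
#'
#' @param stream raw EEG [multichannel_stream()].
#' @param baseline a [baseline_profile()], or a raw calibration
#'   `multichannel_stream` at least 60 s long.
#' @param channels,band,epoch_len,z_thresh see the individual stages.
#' @return `data.frame(t, ratio, artifact)`.
#' @export
alpha_ratio_pipeline <- function(stream, baseline, channels = c("P3", "P4"),
                                 band = c(10.5, 13), epoch_len = 0.5,
                                 z_thresh = 5) {
  if (inherits(baseline, "multichannel_stream")) {
    cal <- preprocess(baseline)
    cal_pow <- alpha_epochs(cal, band = band, channels = channels,
                            epoch_len = epoch_len)
    cal_flags <- artifact_flags(cal, epoch_len = epoch_len, z_thresh = z_thresh)
    baseline <- compute_baseline(cal_pow, cal_flags[seq_len(nrow(cal_pow))],
                                 epoch_len = epoch_len)
  }
  pp <- preprocess(stream)
  pow <- alpha_epochs(pp, band = band, channels = channels,
                      epoch_len = epoch_len)
  flags <- artifact_flags(pp, epoch_len = epoch_len, z_thresh = z_thresh)
  normalize_epochs(pow, baseline, flags[seq_len(nrow(pow))])
}
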