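#' Valence ratio from facial-expression intensities
#'
#' The valence ratio is the intensity of the positive emotion minus the
#' intensity of the negative expression with the highest intensity. With all
#' intensities in [0, 1] the result lies in [-1, 1].
#'
#' @param intensities named numeric vector of expression intensities in
#'   [0, 1]; the entry named `positive` is the positive emotion, every other
#'   entry is treated as a negative emotion (e.g. sad, angry, scared,
#'   disgusted). Missing negative entries are treated as absent (0).
#' @param positive name of the positive-emotion entry.
#' @return Scalar valence in [-1, 1].
#' @export
valence_ratio <- function(intensities, positive = "happy") {
  if (is.null(names(intensities)) || any(!nzchar(names(intensities))))
    stop("intensities must be a fully named numeric vector")
  if (any(intensities < 0 | intensities > 1))
    stop("expression intensities must lie in [0, 1]")
  pos <- if (positive %in% names(intensities)) intensities[[positive]] else 0
  neg <- intensities[setdiff(names(intensities), positive)]
  max_neg <- if (length(neg)) max(neg) else 0
  unname(pos - max_neg)
}

# accept either data.frame(t, v) or a 1-channel multichannel_stream
as_valence_samples <- function(x) {
  if (inherits(x, "multichannel_stream")) {
    if (ncol(x$samples) != 1L)
      stop("valence stream must have exactly 1 channel")
    return(data.frame(t = stream_times(x), v = x$samples[, 1L]))
  }
  if (is.data.frame(x) && all(c("t", "v") %in% names(x))) return(x)
  stop("expected a data.frame(t, v) or a 1-channel multichannel_stream")
}

#' Mean valence over a half-open time window
#'
#' @param stream valence samples: `data.frame(t, v)` or a 1-channel
#'   [multichannel_stream()].
#' @param t0,t1 window bounds in seconds; samples with `t0 <= t < t1` count.
#' @return Arithmetic mean of `v` over the window.
#' @export
window_mean <- function(stream, t0, t1) {
  if (t1 <= t0) stop("t1 must exceed t0")
  s <- as_valence_samples(stream)
  sel <- s$t >= t0 & s$t < t1
  if (!any(sel)) stop("no valence samples in [", t0, ", ", t1, ")")
  mean(s$v[sel])
}

#' Pre/post valence delta around an adaptation
#'
#' Measures emotional valence over the `w` seconds before and after a speed
#' adaptation; the sign of `delta = post - pre` is the satisfaction verdict:
#' a positive (or zero) change means the adaptation was appropriate, a
#' negative change means the subject is dissatisfied and the thresholds
#' should move. Windows are half-open, the post window starting at `t_adapt`
#' inclusive. If either window holds no samples the verdict is `"unknown"`
#' and the caller must leave thresholds untouched.
#'
#' @inheritParams window_mean
#' @param t_adapt adaptation time in seconds.
#' @param w window length in seconds (default 2).
#' @return Object of class `valence_delta`: list with `t_adapt`, `pre_mean`,
#'   `post_mean`, `delta` and `verdict` in `{"satisfied", "dissatisfied",
#'   "unknown"}`.
#' @export
adaptation_delta <- function(stream, t_adapt, w = 2) {
  pre <- tryCatch(window_mean(stream, t_adapt - w, t_adapt),
                  error = function(e) NA_real_)
  post <- tryCatch(window_mean(stream, t_adapt, t_adapt + w),
                   error = function(e) NA_real_)
  delta <- post - pre
  verdict <- if (is.na(delta)) "unknown"
             else if (delta < 0) "dissatisfied" else "satisfied"
  structure(list(t_adapt = t_adapt, pre_mean = pre, post_mean = post,
                 delta = delta, verdict = verdict),
            class = "valence_delta")
}

#' @export
print.valence_delta <- function(x, ...) {
  cat(sprintf("<valence_delta> t=%g pre=%.4g post=%.4g delta=%.4g (%s)\n",
              x$t_adapt, x$pre_mean, x$post_mean, x$delta, x$verdict))
  invisible(x)
}

#' Valence stream from per-emotion intensity streams
#'
#' Applies [valence_ratio()] sample-wise to a multichannel stream whose
#' channels are expression intensities, producing a 1-channel valence stream
#' at the same rate (nominally 30 Hz).
#'
#' @param stream [multichannel_stream()] with one channel per emotion.
#' @inheritParams valence_ratio
#' @return 1-channel `multichannel_stream` labelled `"valence"`.
#' @export
valence_stream <- function(stream, positive = "happy") {
  stopifnot(inherits(stream, "multichannel_stream"))
  v <- apply(stream$samples, 1L, function(row) {
    names(row) <- stream$labels
    valence_ratio(row, positive = positive)
  })
  multichannel_stream(matrix(v, ncol = 1), rate = stream$rate,
                      labels = "valence", start_time = stream$start_time)
}
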