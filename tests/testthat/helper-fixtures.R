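# fixture builders shared across the suite

sine_stream <- function(freq, rate = 256, duration = 10,
                        labels = c("P3", "P4"), amp = 1) {
  ts <- (seq_len(round(rate * duration)) - 1L) / rate
  x <- sapply(labels, function(l) amp * sin(2 * pi * freq * ts))
  multichannel_stream(x, rate = rate, labels = labels)
}

random_stream <- function(n = 10, k = 3, rate = 500) {
  multichannel_stream(matrix(round(rnorm(n * k), 6), ncol = k),
                      rate = rate, labels = paste0("ch", seq_len(k)))
}

random_spd <- function(d = 3) {
  m <- matrix(rnorm(d * d), d)
  crossprod(m) + 0.1 * diag(d)
}

# band power of a signal at frequency f via the periodogram
fft_band_power <- function(sig, fs, f, halfwidth = 0.3) {
  n <- length(sig)
  spec <- abs(fft(sig))^2 / n
  fr <- (seq_len(n) - 1L) * fs / n
  mean(spec[abs(fr - f) < halfwidth])
}

# constant-ratio replay alpha series on the 0.5 s grid
const_alpha <- function(ratio, duration, epoch_len = 0.5) {
  data.frame(t = seq(0, duration - epoch_len, by = epoch_len),
             ratio = ratio, artifact = FALSE)
}

# 30 Hz valence samples from a function of time
valence_from_fn <- function(f, duration, rate = 30) {
  ts <- (seq_len(round(duration * rate)) - 1L) / rate
  data.frame(t = ts, v = vapply(ts, f, numeric(1)))
}

# a bare piece instance for plan_actions (fields: id, rot, row, col)
test_piece <- function(id, rot = 1L, row = 0L, col = 4L) {
  list(id = id, rot = as.integer(rot), row = as.integer(row),
       col = as.integer(col))
}
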