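# Independent brute-force references the fast implementations are checked
# against. Written as plain per-sample loops on purpose: no cumulative sums,
# no vectorized run logic.

# O(M * N) direct causal moving average of y^2
oracle_smooth <- function(y, window_n) {
  M <- length(y)
  y2 <- y^2
  out <- numeric(M)
  for (n in seq_len(M)) {
    lo <- max(1L, n - window_n + 1L)
    out[n] <- sum(y2[lo:n]) / window_n
  }
  out
}

# per-chunk thresholds by direct summation
oracle_thresholds <- function(y_sm, n_segments, a) {
  L <- length(y_sm)
  size <- L %/% n_segments
  thr <- numeric(n_segments)
  for (i in seq_len(n_segments)) {
    lo <- (i - 1L) * size + 1L
    hi <- if (i == n_segments) L else i * size
    s <- 0
    for (k in lo:hi) s <- s + y_sm[k]^2
    thr[i] <- a * s / (hi - lo + 1L)
  }
  thr
}

# per-sample state-machine scan: open a run when the statistic exceeds the
# current chunk's threshold, keep the START chunk's threshold while open,
# close the run (inclusive) where the statistic drops to/below it
oracle_events <- function(y_sm, theta2) {
  L <- length(y_sm)
  n_segments <- length(theta2)
  size <- L %/% n_segments
  chunk_of <- function(n) min((n - 1L) %/% size + 1L, n_segments)
  stat <- y_sm^2
  starts <- integer(0)
  durs <- integer(0)
  open <- FALSE
  s <- 0L
  thr <- NA_real_
  for (n in seq_len(L)) {
    if (!open) {
      if (stat[n] > theta2[chunk_of(n)]) {
        open <- TRUE
        s <- n
        thr <- theta2[chunk_of(n)]
      }
    } else if (stat[n] <= thr) {
      starts <- c(starts, s)
      durs <- c(durs, n - s)
      open <- FALSE
    }
  }
  if (open) {
    starts <- c(starts, s)
    durs <- c(durs, L - s + 1L)
  }
  data.frame(start = starts, duration_samples = durs)
}

oracle_chain <- function(y, cfg) {
  y_sm <- oracle_smooth(y, cfg$window_n)
  thr <- oracle_thresholds(y_sm, cfg$n_segments, cfg$a)
  ev <- oracle_events(y_sm, thr)
  dur_ms <- ev$duration_samples / cfg$rate * 1000
  ev[dur_ms >= cfg$d_min_ms & dur_ms <= cfg$d_max_ms, , drop = FALSE]
}

# quiet noise with exponentially damped spikes, for chain-equivalence and
# monotonicity properties
make_spiky_signal <- function(L, n_spikes, seed) {
  set.seed(seed)
  y <- stats::rnorm(L) * 0.001
  if (n_spikes > 0L) {
    starts <- sort(sample.int(L - 60L, n_spikes))
    for (s in starts) {
      w <- sample(5:50, 1)
      y[s:(s + w - 1L)] <- y[s:(s + w - 1L)] + 0.05 * exp(-(0:(w - 1L)) / w * 3)
    }
  }
  y
}

# raw 16-bit PCM WAV writer independent of the package's, for I/O tests;
# ints may be a vector (mono) or a frames x channels matrix
write_raw_wav <- function(ints, rate, path, channels = 1L) {
  if (is.matrix(ints)) {
    channels <- ncol(ints)
    ints <- as.integer(t(ints))
  }
  n_bytes <- length(ints) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(as.integer(channels), con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate) * 2L * channels, con, size = 4, endian = "little")
  writeBin(2L * channels, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(as.integer(ints), con, size = 2, endian = "little")
  invisible(path)
}
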