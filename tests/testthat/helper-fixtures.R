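# Shared fixtures, all generated in code.

# A sinusoid wrapped as a sensor_signal.
make_sine <- function(freq, duration_s, fs = 1000, amp = 1, offset = 0) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  sensor_signal(offset + amp * sin(2 * pi * freq * t), fs)
}

# A clean synthetic meal with fixed bouts (no noise/drift/artifacts):
# bouts of `counts` chews at `freqs` Hz separated by `gap_s` of rest.
make_clean_meal <- function(counts, freqs, fs = 1000, gap_s = 8,
                            lead_s = 10, amp = 0.5) {
  t_cursor <- lead_s
  chunks <- list()
  starts <- ends <- numeric(length(counts))
  for (k in seq_along(counts)) {
    b <- generate_bout(counts[k], freqs[k], fs = fs, amp_jitter = 0,
                       base_amp = amp)
    starts[k] <- t_cursor
    ends[k] <- t_cursor + b$duration_s
    chunks[[k]] <- b
    t_cursor <- ends[k] + gap_s
  }
  total_s <- t_cursor + lead_s - gap_s
  x <- numeric(round(total_s * fs))
  for (k in seq_along(counts)) {
    i0 <- round(starts[k] * fs)
    x[(i0 + 1):(i0 + length(chunks[[k]]$samples))] <- chunks[[k]]$samples
  }
  segs <- chew_segments("s1", "v1", starts, ends,
                        rep("intake", length(counts)), counts)
  list(signal = sensor_signal(x, fs), segments = segs,
       acnt = sum(counts))
}

# Linearly separable two-cluster feature set (38-dim, clusters 6 sd apart
# along the first coordinate).
make_separable <- function(n = 200, seed = 1, gap = 6) {
  set.seed(seed)
  y <- rep(c(-1L, 1L), length.out = n)
  x <- matrix(rnorm(n * 38), n, 38)
  x[, 1] <- x[, 1] + y * gap / 2
  colnames(x) <- feature_names()
  list(features = x, labels = y)
}

# Minimal stereo WAV (PCM16), for the multi-channel error path.
write_stereo_wav <- function(path, fs = 1000, n = 100) {
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- n * 2L * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # stereo
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 4L), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  writeBin(integer(n * 2L), con, size = 2, endian = "little")
  path
}
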