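# Build an acc_windows object directly from a sample matrix.
make_windows <- function(xyz, rate_hz = 25, window_s = 2) {
  segment_windows(acc_series(as.matrix(xyz), rate_hz = rate_hz), window_s)
}

# One random 2 s window (50 x 3) around a resting posture.
random_window <- function(seed, sd = 1) {
  set.seed(seed)
  cbind(rnorm(50, 0, sd), rnorm(50, 0, sd), rnorm(50, 9.8, sd))
}
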