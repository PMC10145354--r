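# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Zero-phase Butterworth band-pass (order 4), edges in Hz.
bandpass <- function(x, low_hz, high_hz, fs, order = 4) {
  ny <- fs / 2
  w <- c(max(low_hz, 1e-3), min(high_hz, ny * 0.99)) / ny
  bf <- signal::butter(order, w, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# Root-mean-square.
rms <- function(x) sqrt(mean(x^2))

# Truncated-at-zero normal draws: rejection sampling, so the zero-to-peak
# support constraint never produces negative amplitudes.
rnorm_trunc0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= 0
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}
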