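# Internal numeric helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed`, so simulator calls do not
#' perturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Zero-phase Butterworth low-pass with mirrored edge padding; padding keeps
# filtfilt's zero initial conditions from smearing transients into short
# segments whose DC level is far from zero.
lowpass <- function(x, fs, cutoff = 10, order = 4) {
  wc <- min(cutoff / (fs / 2), 0.99)
  bf <- signal::butter(order, wc, type = "low")
  pad_filtfilt(bf, x, fs)
}

bandpass <- function(x, fs, lo = 5, hi = 20, order = 2) {
  w <- c(lo, hi) / (fs / 2)
  w[2] <- min(w[2], 0.99)
  bf <- signal::butter(order, w, type = "pass")
  pad_filtfilt(bf, x, fs)
}

pad_filtfilt <- function(bf, x, fs) {
  n <- length(x)
  np <- min(n - 1, max(16L, round(fs)))
  if (np < 1) return(as.numeric(signal::filtfilt(bf, x)))
  head_pad <- 2 * x[1] - x[seq(np + 1, 2)]
  tail_pad <- 2 * x[n] - x[seq(n - 1, n - np)]
  y <- as.numeric(signal::filtfilt(bf, c(head_pad, x, tail_pad)))
  y[seq(np + 1, np + n)]
}

# Centred moving average (window w samples), same length as input.
moving_mean <- function(x, w) {
  w <- max(1L, as.integer(w))
  y <- stats::filter(x, rep(1 / w, w), sides = 2)
  y <- as.numeric(y)
  y[is.na(y)] <- 0
  y
}

# Central-difference derivative in per-sample units, same length as input.
central_diff <- function(x) {
  n <- length(x)
  if (n < 3) return(rep(0, n))
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1]
  d
}

stop_pulsebp <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
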