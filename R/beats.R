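#' Detect ECG R-peaks
#'
#' Pan-Tompkins-style detector: zero-phase 5--20 Hz band-pass, squared
#' derivative, 150 ms moving-window integration, adaptive threshold, and a
#' 250 ms refractory period.  Robust to the widened / inverted QRS morphology
#' of ventricular ectopic beats (the squared derivative is polarity-blind).
#'
#' @param ecg ECG sample vector.
#' @param fs sampling rate in Hz.
#' @param refractory minimum peak separation in seconds.
#' @return strictly increasing integer vector of 1-based R-peak sample
#'   indices; a flat signal yields an empty vector.
#' @export
detect_r_peaks <- function(ecg, fs, refractory = 0.25) {
  if (fs <= 0) stop_pulsebp("fs must be positive")
  if (length(ecg) < 2 * fs)
    stop_pulsebp("need at least 2 s of ECG signal")
  if (stats::sd(ecg) == 0) return(integer(0))
  band <- bandpass(ecg, fs, 5, 20)
  env <- moving_mean(c(diff(band), 0)^2, round(0.15 * fs))
  thr <- 0.2 * as.numeric(stats::quantile(env, 0.99))
  if (thr <= 0) return(integer(0))
  above <- env > thr
  if (!any(above)) return(integer(0))
  # contiguous supra-threshold regions -> one candidate each
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- integer(0)
  for (k in which(runs$values)) {
    seg <- starts[k]:ends[k]
    centre <- seg[which.max(env[seg])]
    w0 <- max(1L, centre - round(0.1 * fs))
    w1 <- min(length(ecg), centre + round(0.1 * fs))
    cand <- c(cand, w0 - 1L + which.max(abs(band[w0:w1])))
  }
  cand <- sort(unique(cand))
  # refractory: keep the stronger of any pair closer than the refractory gap
  keep <- integer(0)
  for (c0 in cand) {
    if (length(keep) && c0 - keep[length(keep)] < refractory * fs) {
      if (abs(band[c0]) > abs(band[keep[length(keep)]]))
        keep[length(keep)] <- c0
    } else keep <- c(keep, c0)
  }
  keep
}

#' Locate PPG fiducial points for each beat
#'
#' For each R-peak with an admissible PPG pulse in the transit-time search
#' window, locates the five pulse landmarks on a 10 Hz low-passed copy of the
#' PPG: `F` (foot: last local minimum before the upstroke), `M` (peak of the
#' first derivative on the upstroke), `P` (pulse peak), `M'` (minimum of the
#' first derivative on the descending edge) and `F'` (foot of the next pulse,
#' or the end of the decay for the final beat).  Beats whose window contains
#' no admissible pulse, or whose landmarks violate the ordering
#' `r < F <= M <= P <= M' <= F'`, are skipped; the skip count is reported in
#' the `"skipped"` attribute.
#'
#' @param ppg PPG sample vector (same sampling grid as the ECG).
#' @param r_peaks R-peak sample indices from [detect_r_peaks()].
#' @param fs sampling rate in Hz.
#' @param min_ptt,max_ptt admissible R-to-foot delay range in seconds.
#' @return data frame (class `beat_fiducials`) with columns `beat_index`,
#'   `r_idx`, `f_idx`, `m_idx`, `p_idx`, `mprime_idx`, `fprime_idx`.
#' @export
locate_ppg_fiducials <- function(ppg, r_peaks, fs,
                                 min_ptt = 0.05, max_ptt = 0.5) {
  if (fs <= 0) stop_pulsebp("fs must be positive")
  if (length(r_peaks) < 1) stop_pulsebp("need at least one R-peak")
  n <- length(ppg)
  x <- lowpass(ppg, fs, 10)
  d <- central_diff(x)
  nb <- length(r_peaks)
  M <- F_ <- P <- rep(NA_integer_, nb)
  # minimum admissible upstroke slope: rejects windows holding no real pulse
  d_gate <- 0.02 * max(d)

  for (k in seq_len(nb)) {
    r <- r_peaks[k]
    lo <- r + floor(min_ptt * fs)
    hi <- min(n, r + round(0.9 * fs))
    if (k < nb) hi <- min(hi, r_peaks[k + 1] + floor(min_ptt * fs))
    if (hi - lo < 3) next
    m <- lo - 1L + which.max(d[lo:hi])
    if (d[m] <= 0 || d[m] <= d_gate) next
    tol <- 0.01 * d[m]
    # foot: walk back from the max-slope point to the last non-positive slope
    j <- m - 1L
    while (j > r && d[j] > tol) j <- j - 1L
    if (j <= r) next
    w <- max(r + 1L, j - 3L):min(j + 3L, m - 1L)
    # refine on the raw signal: the filtered copy blurs the foot corner
    f <- w[max(which(ppg[w] == min(ppg[w])))]  # last index attaining the min
    if (f - r < floor(min_ptt * fs) || f - r > ceiling(max_ptt * fs)) next
    # peak: first non-positive slope after the max-slope point
    j <- m + 1L
    jmax <- min(n - 1L, hi + round(0.5 * fs))
    while (j < jmax && d[j] > tol) j <- j + 1L
    w <- max(m, j - 3L):min(j + 3L, n)
    p <- w[which.max(ppg[w])]  # refine the peak on the raw signal
    if (p <= m) next
    M[k] <- m; F_[k] <- f; P[k] <- p
  }

  med_rr <- if (nb > 1) stats::median(diff(r_peaks)) else round(0.8 * fs)
  rows <- vector("list", nb)
  skipped <- 0L
  for (k in seq_len(nb)) {
    if (is.na(M[k])) { skipped <- skipped + 1L; next }
    # end foot: the next beat's foot when available, else end of the decay
    fp <- NA_integer_
    if (k < nb && !is.na(F_[k + 1]) && F_[k + 1] > P[k]) {
      fp <- F_[k + 1]
    } else {
      hi <- min(n, P[k] + round(1.5 * med_rr))
      if (hi > P[k] + 2) {
        # first raw-signal minimum after the peak (end of the decay)
        fp <- P[k] + which.min(ppg[(P[k] + 1):hi])
      }
    }
    if (is.na(fp) || fp <= P[k] + 1) { skipped <- skipped + 1L; next }
    mp <- P[k] + which.min(d[(P[k] + 1):fp])
    ok <- r_peaks[k] < F_[k] && F_[k] <= M[k] && M[k] <= P[k] &&
      P[k] <= mp && mp <= fp
    if (!ok) { skipped <- skipped + 1L; next }
    rows[[k]] <- data.frame(beat_index = k, r_idx = r_peaks[k],
                            f_idx = F_[k], m_idx = M[k], p_idx = P[k],
                            mprime_idx = mp, fprime_idx = fp)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(beat_index = integer(0), r_idx = integer(0),
                      f_idx = integer(0), m_idx = integer(0),
                      p_idx = integer(0), mprime_idx = integer(0),
                      fprime_idx = integer(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("beat_fiducials", "data.frame")
  out
}

#' Delimit arterial-pressure cycles
#'
#' Each paired beat owns the half-open IBP cycle bounded by the first
#' diastolic trough within 0.6 s after its R-peak and the next trough.
#' Beats with no such pair of troughs are skipped.
#'
#' @param ibp arterial pressure sample vector (mmHg).
#' @param r_peaks R-peak sample indices.
#' @param fs sampling rate in Hz.
#' @return data frame with columns `beat_index`, `start_idx`, `end_idx`
#'   (half-open cycle `[start_idx, end_idx)` in 1-based indices).
#' @export
detect_ibp_cycles <- function(ibp, r_peaks, fs) {
  if (length(r_peaks) < 2) stop_pulsebp("need at least two R-peaks")
  if (stats::sd(ibp) == 0)
    return(data.frame(beat_index = integer(0), start_idx = integer(0),
                      end_idx = integer(0)))
  x <- lowpass(ibp, fs, 10)
  n <- length(x)
  idx <- 2:(n - 1)
  tr <- idx[x[idx] < x[idx - 1] & x[idx] <= x[idx + 1]]
  # collapse trough clusters closer than 250 ms, keeping the deepest
  if (length(tr) > 1) {
    keep <- integer(0)
    for (t in tr) {
      if (length(keep) && t - keep[length(keep)] < 0.25 * fs) {
        if (x[t] < x[keep[length(keep)]]) keep[length(keep)] <- t
      } else keep <- c(keep, t)
    }
    tr <- keep
  }
  # refine each trough to the raw-signal minimum nearby (the low-pass blurs
  # the diastolic corner by a few samples)
  hw <- round(0.08 * fs)
  tr <- vapply(tr, function(t) {
    w <- max(1L, t - hw):min(n, t + hw)
    w[which.min(ibp[w])]
  }, integer(1))
  tr <- sort(unique(tr))
  rows <- lapply(seq_along(r_peaks), function(k) {
    r <- r_peaks[k]
    s <- tr[tr > r & tr <= r + round(0.6 * fs)]
    if (!length(s)) return(NULL)
    s <- s[1]
    e <- tr[tr > s]
    if (!length(e)) return(NULL)
    data.frame(beat_index = k, start_idx = s, end_idx = e[1])
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(beat_index = integer(0), start_idx = integer(0),
                      end_idx = integer(0))
  rownames(out) <- NULL
  out
}

#' PPG energy quality filter
#'
#' Per-beat PPG energy is `E_b = sum((x_i - mean_b)^2)` over the beat's
#' segment `[F, F')`.  A beat is excluded when its energy deviates from the
#' record's mean energy by more than `k_sd` standard deviations (sample SD,
#' computed once over all beats; the rule is single-pass, not iterated).
#'
#' @param ppg PPG sample vector.
#' @param beats a `beat_fiducials` data frame.
#' @param k_sd exclusion threshold in SD units (default 2).
#' @return list with elements `kept` and `excluded` (disjoint subsets of
#'   `beats` whose union is the input) and `energy` (per input beat).
#' @export
ppg_quality_filter <- function(ppg, beats, k_sd = 2) {
  if (nrow(beats) < 3)
    stop_pulsebp("insufficient beats for quality statistics")
  energy <- vapply(seq_len(nrow(beats)), function(i) {
    seg <- ppg[beats$f_idx[i]:(beats$fprime_idx[i] - 1L)]
    sum((seg - mean(seg))^2)
  }, numeric(1))
  mu <- mean(energy)
  sdv <- stats::sd(energy)
  out <- abs(energy - mu) > k_sd * sdv
  list(kept = beats[!out, , drop = FALSE],
       excluded = beats[out, , drop = FALSE],
       energy = energy)
}
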