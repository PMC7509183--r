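#' Simulator configuration
#'
#' Parameters of the synthetic arrhythmic-waveform generator.  The generator
#' emulates the statistical structure of beat-to-beat blood pressure during
#' arrhythmias: sinus beats follow the base heart rate with small timing
#' jitter; premature ventricular contractions (PVCs) arrive early (coupling
#' interval 0.6 of the sinus interval), carry a reduced stroke amplitude and
#' are followed by a compensatory pause; supraventricular beats occur in runs
#' of shortened intervals.  Per-beat systolic pressure follows
#' `SBP_i = a0 + a1 * RR_{i-1} + a2 * stroke_i + N(0, noise_sd_bp)`,
#' diastolic pressure is an affine function of systolic
#' (`DBP_i = 0.55 * SBP_i + 10 + N(0, noise_sd_bp/2)`), and the R-to-PPG-foot
#' transit time follows `ptt_i = b0 - b1 * SBP_i` plus small noise, clipped to
#' \[0.05, 0.5\] s.
#'
#' @param duration record length in seconds (the rendered record may be
#'   slightly longer so the final cardiac cycle closes).
#' @param fs sampling rate in Hz.
#' @param base_hr sinus heart rate in beats per minute (42--140).
#' @param pvc_probability,svt_run_probability per-beat probability that the
#'   next event is a PVC (with compensatory pause) or the start of a
#'   supraventricular run.
#' @param a0,a1,a2 systolic pressure rule coefficients (mmHg, mmHg/s, mmHg).
#' @param b0,b1 transit-time rule coefficients (s, s/mmHg).
#' @param noise_sd_bp beat-to-beat pressure noise SD in mmHg.
#' @param noise_sd_signal additive waveform noise SD, relative to each
#'   channel's pulse amplitude.
#' @param artifact_fraction fraction of beats whose PPG pulse amplitude is
#'   multiplied by 5 (motion-artifact stand-in that trips the energy filter).
#' @param hr_jitter_sd relative SD of sinus inter-beat interval jitter.
#' @param stroke_jitter_sd SD of the per-beat stroke-amplitude jitter
#'   (relative; ectopic beat classes use proportionally larger jitter).
#' @param ptt_noise_sd transit-time noise SD in seconds.
#' @param seed integer RNG seed; identical configurations give bit-identical
#'   schedules and records.
#' @return a `sim_config` list.
#' @export
sim_config <- function(duration = 60, fs = 250, base_hr = 75,
                       pvc_probability = 0.08, svt_run_probability = 0.05,
                       a0 = 60, a1 = 25, a2 = 35,
                       b0 = 0.35, b1 = 0.0015,
                       noise_sd_bp = 2, noise_sd_signal = 0.02,
                       artifact_fraction = 0, hr_jitter_sd = 0.03,
                       stroke_jitter_sd = 0.02, ptt_noise_sd = 0.003,
                       seed = 1L) {
  cfg <- list(duration = duration, fs = fs, base_hr = base_hr,
              pvc_probability = pvc_probability,
              svt_run_probability = svt_run_probability,
              a0 = a0, a1 = a1, a2 = a2, b0 = b0, b1 = b1,
              noise_sd_bp = noise_sd_bp, noise_sd_signal = noise_sd_signal,
              artifact_fraction = artifact_fraction,
              hr_jitter_sd = hr_jitter_sd, stroke_jitter_sd = stroke_jitter_sd,
              ptt_noise_sd = ptt_noise_sd,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$fs <= 0) stop_pulsebp("fs must be positive")
  if (cfg$duration <= 0) stop_pulsebp("duration must be positive")
  probs <- c(cfg$pvc_probability, cfg$svt_run_probability,
             cfg$artifact_fraction)
  if (any(probs < 0 | probs > 1))
    stop_pulsebp("probabilities must lie in [0, 1]")
  if (cfg$noise_sd_bp < 0 || cfg$noise_sd_signal < 0)
    stop_pulsebp("noise SDs must be non-negative")
  if (cfg$base_hr < 42 || cfg$base_hr > 140)
    stop_pulsebp("base_hr outside the supported 42-140 bpm range ",
                 "(inter-beat intervals must stay in [0.25, 2] s)")
  invisible(cfg)
}

#' Generate a beat schedule
#'
#' Draws beat times, rhythm labels, per-beat stroke amplitudes, true
#' systolic/diastolic pressures and true R-to-PPG-foot transit times under
#' the rules documented in [sim_config()].  Deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @return a `beat_schedule` data frame with columns `beat_time` (s),
#'   `beat_type` (`"sinus"`, `"ventricular"`, `"supraventricular"`),
#'   `true_sbp`, `true_dbp` (mmHg), `true_ptt` (s) and `stroke_scale`.
#' @export
make_beat_schedule <- function(config) {
  validate_sim_config(config)
  rr <- 60 / config$base_hr
  t_end <- config$duration - 0.5 * rr
  if (config$duration / rr < 3)
    stop_pulsebp("duration too short to contain at least 3 beats")
  with_seed(config$seed, {
    times <- numeric(0); types <- character(0); strokes <- numeric(0)
    add_beat <- function(t, type, stroke) {
      times <<- c(times, t); types <<- c(types, type)
      strokes <<- c(strokes, stroke)
    }
    t <- 0.25 * rr
    sj <- config$stroke_jitter_sd
    add_beat(t, "sinus", 1 + stats::rnorm(1, 0, sj))
    repeat {
      u <- stats::runif(1)
      if (u < config$pvc_probability) {
        # premature ventricular beat + compensatory pause (pair sums to 2 RR)
        t_pvc <- t + 0.6 * rr
        t_next <- t + 2 * rr
        if (t_next > t_end) break
        add_beat(t_pvc, "ventricular", 0.45 + stats::rnorm(1, 0, 2.5 * sj))
        add_beat(t_next, "sinus", 1.05 + stats::rnorm(1, 0, sj))
        t <- t_next
      } else if (u < config$pvc_probability + config$svt_run_probability) {
        k <- 3L + stats::rgeom(1, 0.4)
        ok <- TRUE
        for (j in seq_len(k)) {
          t <- t + 0.6 * rr
          if (t > t_end) { ok <- FALSE; break }
          add_beat(t, "supraventricular", 0.75 + stats::rnorm(1, 0, 1.5 * sj))
        }
        if (!ok) break
      } else {
        t <- t + rr * (1 + stats::rnorm(1, 0, config$hr_jitter_sd))
        if (t > t_end) break
        add_beat(t, "sinus", 1 + stats::rnorm(1, 0, sj))
      }
    }
    n <- length(times)
    if (n < 3) stop_pulsebp("duration too short to contain at least 3 beats")
    rr_prev <- c(rr, diff(times))
    sbp <- config$a0 + config$a1 * rr_prev + config$a2 * strokes +
      stats::rnorm(n, 0, config$noise_sd_bp)
    dbp <- 0.55 * sbp + 10 + stats::rnorm(n, 0, config$noise_sd_bp / 2)
    ptt <- config$b0 - config$b1 * sbp + stats::rnorm(n, 0, config$ptt_noise_sd)
    ptt <- pmin(pmax(ptt, 0.05), 0.5)
    sched <- data.frame(beat_time = times, beat_type = types,
                        true_sbp = sbp, true_dbp = dbp, true_ptt = ptt,
                        stroke_scale = pmax(strokes, 0.1),
                        stringsAsFactors = FALSE)
    validate_beat_schedule(sched)
    class(sched) <- c("beat_schedule", "data.frame")
    sched
  })
}

validate_beat_schedule <- function(s) {
  if (any(diff(s$beat_time) <= 0))
    stop_pulsebp("beat times must be strictly increasing")
  ibi <- diff(s$beat_time)
  if (any(ibi < 0.25 - 1e-9 | ibi > 2 + 1e-9))
    stop_pulsebp("inter-beat interval outside [0.25, 2] s")
  if (any(!is.finite(s$true_sbp)) || any(!is.finite(s$true_dbp)) ||
      any(s$true_sbp <= 0) || any(s$true_dbp <= 0))
    stop_pulsebp("blood pressures must be finite and positive")
  if (any(s$true_sbp <= s$true_dbp))
    stop_pulsebp("true_sbp must exceed true_dbp for every beat")
  if (any(s$true_ptt < 0.05 | s$true_ptt > 0.5))
    stop_pulsebp("true_ptt outside [0.05, 0.5] s")
  invisible(s)
}

# Log-normal-shaped lobe: zero at tau = 0, mode at tau = peak_at.
lognormal_lobe <- function(tau, peak_at, shape) {
  m <- peak_at
  out <- numeric(length(tau))
  pos <- tau > 0
  out[pos] <- exp(-(log(tau[pos] / m))^2 / (2 * shape^2))
  out
}

# One PPG pulse on [0, n_samp): raised-cosine upstroke (crisp foot, peak
# exactly at the end of the upstroke), raised-cosine decay back to 0 at the
# next foot, plus a small log-normal dicrotic lobe on the descent.
ppg_pulse_shape <- function(n_samp, fs, upstroke_s) {
  j <- 0:(n_samp - 1)
  k_up <- min(max(2L, round(upstroke_s * fs)), n_samp - 2L)
  shape <- numeric(n_samp)
  up <- j <= k_up
  shape[up] <- 0.5 * (1 - cos(pi * j[up] / k_up))
  down <- 0.5 * (1 + cos(pi * (j[!up] - k_up) / (n_samp - 1 - k_up)))
  tau_d <- (j[!up] - k_up) / fs
  dic <- lognormal_lobe(tau_d, 0.45 * (n_samp - 1 - k_up) / fs, 0.35)
  shape[!up] <- down * (1 + 0.12 * dic)
  shape
}

qrs_template <- function(fs, ventricular = FALSE) {
  width <- if (ventricular) 0.18 else 0.08
  half <- round(width / 2 * fs)
  off <- seq(-half, half)
  tau <- off / fs
  main <- ifelse(abs(tau) <= width / 4,
                 cos(pi * tau / (width / 2))^2, 0)
  side <- 0.25 * ifelse(abs(abs(tau) - width * 0.35) <= width * 0.12,
                        cos(pi * (abs(tau) - width * 0.35) / (width * 0.24))^2, 0)
  shape <- main - side
  if (ventricular) shape <- -1.1 * shape
  list(offsets = off, shape = shape)
}

#' Render synthetic ECG / PPG / IBP waveforms from a beat schedule
#'
#' The ECG is a narrow biphasic QRS template at each beat time (widened and
#' inverted for ventricular beats).  The PPG is a positive-baseline (1.0 a.u.)
#' pulse per beat whose foot falls exactly at `beat_time + true_ptt`, built
#' from two log-normal-shaped lobes (systolic plus a small dicrotic lobe) with
#' amplitude proportional to `stroke_scale`; the upstroke occupies about 30%
#' of the beat interval.  The arterial pressure channel is a smooth
#' piecewise-cosine pulse per cycle spanning exactly
#' \[`true_dbp`, `true_sbp`\].  Gaussian noise is added at
#' `noise_sd_signal` (relative to each channel's pulse amplitude), and for
#' `artifact_fraction` of beats the PPG pulse amplitude is multiplied by 5.
#'
#' @param schedule a [make_beat_schedule()] result.
#' @param config the [sim_config()] used to build it.
#' @param patient_id identifier stored in the record.
#' @return list with elements `record` (a [waveform_record()]) and `truth`,
#'   a data frame of per-beat ground truth: `beat_time`, `beat_type`,
#'   `true_sbp`, `true_dbp`, `true_ptt`, `r_idx`, `f_idx`, `m_idx`, `p_idx`
#'   (1-based sample indices) and `artifact` flag.
#' @export
render_record <- function(schedule, config, patient_id = "sim") {
  if (nrow(schedule) == 0) stop_pulsebp("empty beat schedule")
  fs <- config$fs
  times <- schedule$beat_time
  n_beats <- length(times)
  rr_med <- if (n_beats > 1) stats::median(diff(times)) else 60 / config$base_hr
  n_samp <- max(round(config$duration * fs),
                ceiling((times[n_beats] + rr_med + 0.25) * fs) + 1)
  ecg <- numeric(n_samp)
  ppg <- rep(1.0, n_samp)
  ibp <- numeric(n_samp)

  with_seed(config$seed + 1L, {
    artifact <- stats::runif(n_beats) < config$artifact_fraction

    # --- ECG ---
    r_idx <- round(times * fs) + 1L
    if (any(diff(r_idx) < 1))
      stop_pulsebp("overlapping beats after template placement")
    for (i in seq_len(n_beats)) {
      tpl <- qrs_template(fs, schedule$beat_type[i] == "ventricular")
      idx <- r_idx[i] + tpl$offsets
      keep <- idx >= 1 & idx <= n_samp
      ecg[idx[keep]] <- ecg[idx[keep]] + tpl$shape[keep]
    }

    # --- PPG ---
    f_idx <- round((times + schedule$true_ptt) * fs) + 1L
    if (any(diff(f_idx) < 2))
      stop_pulsebp("overlapping PPG pulses after template placement")
    p_idx <- m_idx <- integer(n_beats)
    for (i in seq_len(n_beats)) {
      seg_end <- if (i < n_beats) f_idx[i + 1] - 1L
                 else min(n_samp, f_idx[i] + round(rr_med * fs))
      L <- seg_end - f_idx[i] + 1L
      if (L < 4) stop_pulsebp("overlapping beats after template placement")
      interval <- L / fs
      shape <- ppg_pulse_shape(L, fs, 0.3 * interval)
      amp <- schedule$stroke_scale[i] * if (artifact[i]) 5 else 1
      seg <- f_idx[i]:seg_end
      ppg[seg] <- 1.0 + amp * shape
      p_idx[i] <- f_idx[i] - 1L + which.max(shape)
      m_idx[i] <- f_idx[i] - 1L + which.max(diff(shape))
    }

    # --- IBP ---
    # Each cycle starts at a one-sample end-diastolic nadir holding exactly
    # its own DBP; the diastolic runoff decays to a floor slightly above the
    # adjacent DBPs, so every nadir is a unique strict local minimum and the
    # per-cycle extrema are exactly (true_dbp, true_sbp).
    ibp_delay <- 0.2
    s_idx <- round((times + ibp_delay) * fs) + 1L
    cyc_end <- c(s_idx[-1], min(n_samp, s_idx[n_beats] + round(rr_med * fs)))
    dbp <- schedule$true_dbp
    sbp <- schedule$true_sbp
    ibp[seq_len(s_idx[1])] <- dbp[1] + 0.08 * (sbp[1] - dbp[1])
    for (i in seq_len(n_beats)) {
      s0 <- s_idx[i]; s1 <- min(cyc_end[i], n_samp)
      L <- s1 - s0
      if (L < 3) next
      pp <- sbp[i] - dbp[i]
      floor_i <- max(dbp[i], if (i < n_beats) dbp[i + 1] else dbp[i]) +
        0.04 * pp
      k_up <- max(1L, round(0.3 * L))
      j <- 0:(L - 1)
      up <- j <= k_up
      v <- numeric(L)
      v[up] <- dbp[i] + pp * 0.5 * (1 - cos(pi * j[up] / k_up))
      v[!up] <- floor_i + (sbp[i] - floor_i) *
        0.5 * (1 + cos(pi * (j[!up] - k_up) / (L - 1 - k_up)))
      ibp[s0 + j] <- v
    }
    tail_start <- min(cyc_end[n_beats], n_samp)
    if (tail_start < n_samp)
      ibp[tail_start:n_samp] <- dbp[n_beats]

    # --- noise ---
    if (config$noise_sd_signal > 0) {
      pp <- mean(schedule$true_sbp - schedule$true_dbp)
      ecg <- ecg + stats::rnorm(n_samp, 0, config$noise_sd_signal)
      ppg <- ppg + stats::rnorm(n_samp, 0, config$noise_sd_signal)
      ibp <- ibp + stats::rnorm(n_samp, 0, config$noise_sd_signal * pp)
    }

    record <- waveform_record(ecg, ppg, ibp, fs = fs, patient_id = patient_id)
    truth <- data.frame(beat_index = seq_len(n_beats),
                        beat_time = times,
                        beat_type = schedule$beat_type,
                        true_sbp = schedule$true_sbp,
                        true_dbp = schedule$true_dbp,
                        true_ptt = schedule$true_ptt,
                        r_idx = r_idx, f_idx = f_idx,
                        m_idx = m_idx, p_idx = p_idx,
                        artifact = artifact,
                        stringsAsFactors = FALSE)
    list(record = record, truth = truth)
  })
}

#' Simulate a complete synthetic record
#'
#' Convenience wrapper: [make_beat_schedule()] followed by [render_record()].
#'
#' @inheritParams render_record
#' @param config a [sim_config()].
#' @return list with `record`, `truth` and `schedule`.
#' @export
simulate_record <- function(config, patient_id = "sim") {
  schedule <- make_beat_schedule(config)
  out <- render_record(schedule, config, patient_id = patient_id)
  out$schedule <- schedule
  out
}

#' Simulate a feature-level cohort with a known pressure rule
#'
#' Generates per-beat feature tables for `n_patients` synthetic patients in
#' which systolic pressure is a known linear function of the R-to-derivative-
#' peak transit time, `SBP = intercept + slope * PTTrm + N(0, noise_sd)`, and
#' the remaining fourteen features are independent physiological-range
#' nuisance draws.  Used to benchmark the regression and feature-importance
#' machinery against a ground-truth generative rule.
#'
#' @param n_patients,n_beats cohort dimensions.
#' @param intercept,slope,noise_sd pressure rule (mmHg, mmHg/s, mmHg).
#' @param seed RNG seed.
#' @return list of per-patient feature data frames (one row per beat, the 15
#'   feature columns plus `ref_sbp`, `ref_dbp`, `beat_type`, `quality_pass`).
#' @export
simulate_feature_cohort <- function(n_patients = 10, n_beats = 500,
                                    intercept = 150, slope = -200,
                                    noise_sd = 3, seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n_patients), function(p) {
      pttrm <- stats::runif(n_beats, 0.10, 0.30)
      sbp <- intercept + slope * pttrm + stats::rnorm(n_beats, 0, noise_sd)
      dbp <- 0.55 * sbp + 10 + stats::rnorm(n_beats, 0, noise_sd / 2)
      df <- data.frame(
        PTTrf = pttrm - stats::runif(n_beats, 0.03, 0.05),
        PTTrm = pttrm,
        PTTrp = pttrm + stats::runif(n_beats, 0.05, 0.10),
        AT = stats::runif(n_beats, 0.15, 0.35),
        AS = stats::runif(n_beats, 2, 8),
        FAS = stats::runif(n_beats, 2, 8),
        SYSAREA = stats::runif(n_beats, 10, 60),
        DT = stats::runif(n_beats, 0.3, 0.7),
        DS = stats::runif(n_beats, 1, 4),
        FDS = stats::runif(n_beats, 1, 4),
        DIAAREA = stats::runif(n_beats, 20, 120),
        PIR = stats::runif(n_beats, 1.2, 2.5),
        PW = stats::runif(n_beats, 0.15, 0.45),
        HR = stats::runif(n_beats, 0.5, 1.2),
        K = stats::runif(n_beats, 0.3, 0.6),
        ref_sbp = sbp, ref_dbp = dbp,
        beat_type = "sinus", quality_pass = TRUE,
        stringsAsFactors = FALSE)
      attr(df, "patient_id") <- sprintf("synth%02d", p)
      df
    })
  })
}
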