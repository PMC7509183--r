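#' Pulse transit times for one beat
#'
#' Delays from the ECG R-peak to the PPG foot (`PTTrf`), to the peak of the
#' first derivative of the PPG (`PTTrm`) and to the PPG peak (`PTTrp`).
#'
#' @param fid one-row `beat_fiducials` entry (or list with `r_idx`, `f_idx`,
#'   `m_idx`, `p_idx`).
#' @param fs sampling rate in Hz.
#' @return list with `PTTrf`, `PTTrm`, `PTTrp` in seconds.
#' @export
compute_ptts <- function(fid, fs) {
  if (!(fid$r_idx < fid$f_idx && fid$f_idx <= fid$m_idx &&
        fid$m_idx <= fid$p_idx))
    stop_pulsebp("fiducial ordering violated: need r < F <= M <= P")
  if (fid$f_idx == fid$r_idx) stop_pulsebp("degenerate beat: F equals R")
  list(PTTrf = (fid$f_idx - fid$r_idx) / fs,
       PTTrm = (fid$m_idx - fid$r_idx) / fs,
       PTTrp = (fid$p_idx - fid$r_idx) / fs)
}

#' Ascending-edge features for one beat
#'
#' `AT` is the foot-to-peak time; `AS = (I(P) - I(F)) / AT`;
#' `FAS = (I(M) - I(F)) / T_FM` where `T_FM` is the foot-to-M time;
#' `SYSAREA = sum_{i=F..P} (I_i - I_F)` with a trapezoidal end-correction
#' (intensity x samples; no division by fs, so the value converges to
#' fs times the continuous area under the edge).
#'
#' @param ppg PPG sample vector.
#' @param fid one-row fiducial entry.
#' @param fs sampling rate in Hz.
#' @return list with `AT`, `AS`, `FAS`, `SYSAREA` and logical `degenerate`.
#' @export
compute_ascending <- function(ppg, fid, fs) {
  if (!(fid$f_idx < fid$m_idx && fid$m_idx < fid$p_idx))
    stop_pulsebp("need F < M < P on the ascending edge")
  at <- (fid$p_idx - fid$f_idx) / fs
  if (at <= 0) stop_pulsebp("zero ascending time")
  i_f <- ppg[fid$f_idx]; i_p <- ppg[fid$p_idx]; i_m <- ppg[fid$m_idx]
  t_fm <- (fid$m_idx - fid$f_idx) / fs
  list(AT = at,
       AS = (i_p - i_f) / at,
       FAS = (i_m - i_f) / t_fm,
       SYSAREA = sum(ppg[fid$f_idx:fid$p_idx] - i_f) - (i_p - i_f) / 2,
       degenerate = (i_p - i_f) <= 0)
}

#' Descending-edge features for one beat
#'
#' `DT` is the peak-to-end-foot time; `DS = (I(P) - I(F')) / DT`;
#' `FDS = (I(M') - I(F')) / T_M'F'` where `T_M'F'` is the M'-to-end-foot
#' time; `DIAAREA = sum_{i=P..F'} (I_i - I_F')` with the same trapezoidal
#' end-correction as the ascending area.
#'
#' @inheritParams compute_ascending
#' @return list with `DT`, `DS`, `FDS`, `DIAAREA` and logical `degenerate`.
#' @export
compute_descending <- function(ppg, fid, fs) {
  if (!(fid$p_idx < fid$mprime_idx && fid$mprime_idx < fid$fprime_idx))
    stop_pulsebp("need P < M' < F' on the descending edge")
  dt <- (fid$fprime_idx - fid$p_idx) / fs
  if (dt <= 0) stop_pulsebp("zero descending time")
  i_p <- ppg[fid$p_idx]; i_fp <- ppg[fid$fprime_idx]
  i_mp <- ppg[fid$mprime_idx]
  t_mf <- (fid$fprime_idx - fid$mprime_idx) / fs
  list(DT = dt,
       DS = (i_p - i_fp) / dt,
       FDS = (i_mp - i_fp) / t_mf,
       DIAAREA = sum(ppg[fid$p_idx:fid$fprime_idx] - i_fp) - (i_p - i_fp) / 2,
       degenerate = (i_p - i_fp) <= 0)
}

#' Ratio, width, rate and shape features for one beat
#'
#' `PIR = I(P)/I(F)` on the raw (baseline-preserving) PPG; `PW` is the
#' M-to-M' time; `HR` is the interval between this beat's PPG peak and the
#' previous beat's (seconds, the literal peak-to-peak definition); `K` is the
#' pulse characteristic value `(mean - min) / (max - min)` over the cycle
#' `[F, F')`.
#'
#' @param ppg PPG sample vector used for shape features (`K`).
#' @param fid,prev_fid fiducial entries for this and the previous beat;
#'   `prev_fid = NULL` marks the first beat of a record (HR undefined).
#' @param fs sampling rate in Hz.
#' @param ppg_raw unfiltered PPG for the intensity ratio (defaults to `ppg`).
#' @return list with `PIR`, `PW`, `HR` (`NA` on the first beat) and `K`.
#' @export
compute_scalar_features <- function(ppg, fid, prev_fid, fs, ppg_raw = ppg) {
  i_f <- ppg_raw[fid$f_idx]
  if (i_f <= 0) stop_pulsebp("PIR undefined on non-positive baseline")
  cyc <- ppg[fid$f_idx:(fid$fprime_idx - 1L)]
  rng <- max(cyc) - min(cyc)
  list(PIR = ppg_raw[fid$p_idx] / i_f,
       PW = (fid$mprime_idx - fid$m_idx) / fs,
       HR = if (is.null(prev_fid)) NA_real_
            else (fid$p_idx - prev_fid$p_idx) / fs,
       K = if (rng > 0) (mean(cyc) - min(cyc)) / rng else NA_real_)
}

#' Build the per-beat feature table
#'
#' Combines fiducials, paired pressure cycles and rhythm labels into one row
#' per cardiac cycle carrying the 15 features, the reference SBP/DBP from the
#' invasive pressure cycle, the beat label and the quality flag.  The first
#' beat (undefined HR) and degenerate beats (zero-amplitude edges, undefined
#' K, non-monotone landmarks) are dropped; the dropped count is reported in
#' the `"dropped"` attribute.
#'
#' @param record a [waveform_record()].
#' @param beats a `beat_fiducials` data frame.
#' @param cycles data frame from [detect_ibp_cycles()].
#' @param labels optional character vector of rhythm labels aligned with
#'   `beats$beat_index`; defaults to `"unknown"`.
#' @param quality_pass optional logical vector aligned with `beats` rows
#'   (from [ppg_quality_filter()]); defaults to all `TRUE`.
#' @return data frame with the 19 canonical columns plus `beat_index` and
#'   `beat_time_s`.
#' @export
build_feature_table <- function(record, beats, cycles, labels = NULL,
                                quality_pass = NULL) {
  if (nrow(beats) == 0) stop_pulsebp("empty beat list")
  fs <- record$fs
  ppg_f <- lowpass(record$ppg, fs, 10)
  if (is.null(quality_pass)) quality_pass <- rep(TRUE, nrow(beats))
  cyc_by_beat <- cycles[match(beats$beat_index, cycles$beat_index), ,
                        drop = FALSE]
  rows <- vector("list", nrow(beats))
  dropped <- 0L
  for (i in seq_len(nrow(beats))) {
    fid <- beats[i, ]
    cyc <- cyc_by_beat[i, ]
    prev <- if (i > 1 &&
                beats$beat_index[i - 1] == beats$beat_index[i] - 1L)
      beats[i - 1, ] else NULL
    if (is.na(cyc$start_idx) || is.null(prev)) { dropped <- dropped + 1L; next }
    res <- tryCatch({
      ptts <- compute_ptts(fid, fs)
      asc <- compute_ascending(ppg_f, fid, fs)
      dsc <- compute_descending(ppg_f, fid, fs)
      sca <- compute_scalar_features(ppg_f, fid, prev, fs,
                                     ppg_raw = record$ppg)
      if (asc$degenerate || dsc$degenerate || is.na(sca$K)) NULL
      else {
        bp <- reference_bp_per_cycle(
          record$ibp[cyc$start_idx:(cyc$end_idx - 1L)])
        data.frame(PTTrf = ptts$PTTrf, PTTrm = ptts$PTTrm, PTTrp = ptts$PTTrp,
                   AT = asc$AT, AS = asc$AS, FAS = asc$FAS,
                   SYSAREA = asc$SYSAREA,
                   DT = dsc$DT, DS = dsc$DS, FDS = dsc$FDS,
                   DIAAREA = dsc$DIAAREA,
                   PIR = sca$PIR, PW = sca$PW, HR = sca$HR, K = sca$K,
                   ref_sbp = bp$sbp, ref_dbp = bp$dbp,
                   beat_type = if (is.null(labels)) "unknown"
                               else labels[i],
                   quality_pass = quality_pass[i],
                   beat_index = fid$beat_index,
                   beat_time_s = (fid$r_idx - 1) / fs,
                   stringsAsFactors = FALSE)
      }
    }, error = function(e) NULL)
    if (is.null(res)) { dropped <- dropped + 1L; next }
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop_pulsebp("no valid beats after feature extraction")
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Full feature-extraction chain for one record
#'
#' Runs R-peak detection, PPG fiducial location, pressure-cycle delimitation,
#' the PPG energy quality filter and [build_feature_table()] in sequence.
#' Quality-failing beats are kept in the table with `quality_pass = FALSE`.
#'
#' @param record a [waveform_record()].
#' @param beat_labels optional data frame with `time_s` and `beat_type`
#'   columns (e.g. simulator ground truth); each detected beat takes the
#'   label of the nearest entry within `label_tol` seconds.
#' @param quality_k energy-filter threshold in SD units.
#' @param label_tol label-matching tolerance in seconds.
#' @return the feature table (see [build_feature_table()]).
#' @export
extract_beat_features <- function(record, beat_labels = NULL, quality_k = 2,
                                  label_tol = 0.15) {
  fs <- record$fs
  r_peaks <- detect_r_peaks(record$ecg, fs)
  if (length(r_peaks) < 3) stop_pulsebp("fewer than 3 beats detected")
  fids <- locate_ppg_fiducials(record$ppg, r_peaks, fs)
  if (nrow(fids) < 3) stop_pulsebp("fewer than 3 beats with PPG fiducials")
  cycles <- detect_ibp_cycles(record$ibp, r_peaks, fs)
  qf <- ppg_quality_filter(record$ppg, fids, k_sd = quality_k)
  qpass <- !(fids$beat_index %in% qf$excluded$beat_index)
  labels <- NULL
  if (!is.null(beat_labels)) {
    t_beat <- (fids$r_idx - 1) / fs
    labels <- vapply(t_beat, function(tb) {
      d <- abs(beat_labels$time_s - tb)
      if (min(d) <= label_tol) beat_labels$beat_type[which.min(d)]
      else "unknown"
    }, character(1))
  }
  build_feature_table(record, fids, cycles, labels = labels,
                      quality_pass = qpass)
}
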