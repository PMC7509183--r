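#' Reference blood pressures for one cycle
#'
#' Reference systolic and diastolic pressures are the maximum and minimum of
#' the invasive arterial waveform over the half-open cardiac cycle.
#'
#' @param ibp_cycle numeric vector of pressure samples (mmHg) for one cycle.
#' @return list with `sbp`, `dbp` (mmHg) and logical `degenerate`
#'   (`sbp == dbp`).
#' @export
reference_bp_per_cycle <- function(ibp_cycle) {
  if (length(ibp_cycle) == 0) stop_pulsebp("empty IBP cycle")
  if (length(ibp_cycle) < 3)
    stop_pulsebp("IBP cycle must contain at least 3 samples")
  sbp <- max(ibp_cycle)
  dbp <- min(ibp_cycle)
  list(sbp = sbp, dbp = dbp, degenerate = sbp == dbp)
}

#' Beat-to-beat pressure change by beat type
#'
#' For each beat, the pressure change is the absolute difference between its
#' pressure and that of its nearest sinus beat (nearest in time, preferring
#' the preceding beat on exact ties; for a sinus beat the nearest *other*
#' sinus beat is used).  Changes are aggregated per rhythm type as
#' mean +/- sample SD, plus a pooled overall row.
#'
#' @param rows data frame with `beat_type`, `ref_sbp`, `ref_dbp` and
#'   optionally `beat_time_s` (row order is used when absent).
#' @return data frame with columns `beat_type`, `n`, `sbp_change_mean`,
#'   `sbp_change_sd`, `dbp_change_mean`, `dbp_change_sd`; the last row is
#'   `"overall"`.
#' @export
bp_change_vs_nearest_sinus <- function(rows) {
  n <- nrow(rows)
  t <- if ("beat_time_s" %in% names(rows)) rows$beat_time_s else seq_len(n)
  sinus <- which(rows$beat_type == "sinus")
  if (!length(sinus)) stop_pulsebp("no sinus beats present")
  d_sbp <- d_dbp <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cand <- if (rows$beat_type[i] == "sinus") setdiff(sinus, i) else sinus
    if (!length(cand)) next
    dist <- abs(t[cand] - t[i])
    best <- min(dist)
    hits <- cand[dist == best]
    j <- if (any(hits < i)) max(hits[hits < i]) else min(hits)
    d_sbp[i] <- abs(rows$ref_sbp[i] - rows$ref_sbp[j])
    d_dbp[i] <- abs(rows$ref_dbp[i] - rows$ref_dbp[j])
  }
  summarise <- function(type, idx) {
    data.frame(beat_type = type, n = length(idx),
               sbp_change_mean = mean(d_sbp[idx], na.rm = TRUE),
               sbp_change_sd = stats::sd(d_sbp[idx][!is.na(d_sbp[idx])]),
               dbp_change_mean = mean(d_dbp[idx], na.rm = TRUE),
               dbp_change_sd = stats::sd(d_dbp[idx][!is.na(d_dbp[idx])]),
               stringsAsFactors = FALSE)
  }
  types <- unique(rows$beat_type)
  out <- do.call(rbind, lapply(types, function(ty)
    summarise(ty, which(rows$beat_type == ty))))
  out <- rbind(out, summarise("overall", seq_len(n)))
  rownames(out) <- NULL
  stopifnot(out$n[nrow(out)] == sum(out$n[-nrow(out)]))
  out
}
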