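#' Synchronized waveform record
#'
#' Container for synchronous single-lead ECG, finger PPG and invasive
#' arterial pressure (IBP) sample arrays at a common sampling rate.
#'
#' @param ecg,ppg,ibp equal-length numeric sample vectors (arbitrary units
#'   for ECG/PPG, mmHg for IBP).
#' @param fs sampling rate in Hz.
#' @param patient_id record identifier.
#' @param t0 time of the first sample in seconds.
#' @return a `waveform_record` object.
#' @export
waveform_record <- function(ecg, ppg, ibp, fs, patient_id = "anon", t0 = 0) {
  n <- length(ecg)
  if (n == 0 || length(ppg) != n || length(ibp) != n)
    stop_pulsebp("ecg, ppg and ibp must be equal-length, non-empty vectors")
  if (fs <= 0) stop_pulsebp("fs must be positive")
  for (ch in c("ecg", "ppg", "ibp")) {
    x <- get(ch)
    bad <- which(!is.finite(x))
    if (length(bad))
      stop_pulsebp("non-finite sample in channel ", ch, " at index ", bad[1])
  }
  structure(list(patient_id = as.character(patient_id), fs = fs, t0 = t0,
                 ecg = as.numeric(ecg), ppg = as.numeric(ppg),
                 ibp = as.numeric(ibp)),
            class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record '%s': %d samples @ %g Hz (%.1f s)>\n",
              x$patient_id, length(x$ecg), x$fs, length(x$ecg) / x$fs))
  invisible(x)
}

record_channels <- c("ecg", "ppg", "ibp")

#' Write a waveform record
#'
#' CSV format: comment header lines `# fs=<Hz>`, `# patient_id=<id>`,
#' `# t0=<s>` followed by columns `time_s, ecg, ppg, ibp`.  WFDB format:
#' a text `.hea` header plus a format-16 (little-endian int16) interleaved
#' `.dat` file, one signal per channel with per-channel gain.
#'
#' @param record a [waveform_record()].
#' @param path output path; for WFDB, the record name without extension.
#' @param format `"csv"` or `"wfdb"`.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "csv") write_record_csv(record, path)
  else write_record_wfdb(record, path)
  invisible(path)
}

#' Read a waveform record
#'
#' @param path file path (CSV) or WFDB record name (with or without `.hea`).
#' @param format `"csv"` or `"wfdb"`.
#' @return a validated [waveform_record()]; channels are resolved by name,
#'   not by column position.
#' @export
read_record <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "csv") read_record_csv(path) else read_record_wfdb(path)
}

write_record_csv <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%.10g", record$fs),
               sprintf("# patient_id=%s", record$patient_id),
               sprintf("# t0=%.10g", record$t0)), con)
  n <- length(record$ecg)
  df <- data.frame(time_s = record$t0 + (seq_len(n) - 1) / record$fs,
                   ecg = record$ecg, ppg = record$ppg, ibp = record$ibp)
  utils::write.csv(df, con, row.names = FALSE)
}

read_record_csv <- function(path) {
  if (!file.exists(path)) stop_pulsebp("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key, default = NULL) {
    hit <- grep(paste0("^#\\s*", key, "="), hdr, value = TRUE)
    if (!length(hit)) return(default)
    sub(paste0("^#\\s*", key, "="), "", hit[1])
  }
  fs <- as.numeric(get_field("fs"))
  if (!length(fs) || is.na(fs)) stop_pulsebp("CSV header must declare fs")
  pid <- get_field("patient_id", "anon")
  t0 <- as.numeric(get_field("t0", "0"))
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  for (ch in record_channels)
    if (!ch %in% names(df)) stop_pulsebp("channel ", ch, " not found")
  waveform_record(df$ecg, df$ppg, df$ibp, fs = fs, patient_id = pid, t0 = t0)
}

# Per-channel WFDB gains: ECG/PPG stored at 1/2000 unit resolution, pressure
# at 1/100 mmHg.  int16 range allows |ecg|,|ppg| < 16 and ibp < 327 mmHg.
wfdb_gains <- c(ecg = 2000, ppg = 2000, ibp = 100)
wfdb_units <- c(ecg = "mV", ppg = "au", ibp = "mmHg")

write_record_wfdb <- function(record, path) {
  name <- basename(path)
  n <- length(record$ecg)
  dig <- lapply(record_channels, function(ch) {
    v <- round(record[[ch]] * wfdb_gains[[ch]])
    if (any(abs(v) > 32767))
      stop_pulsebp("channel ", ch, " out of int16 range at WFDB gain")
    as.integer(v)
  })
  names(dig) <- record_channels
  sig_lines <- vapply(record_channels, function(ch) {
    d <- dig[[ch]]
    chk <- sum(as.double(d)) %% 65536
    if (chk > 32767) chk <- chk - 65536
    sprintf("%s.dat 16 %g(0)/%s 16 0 %d %d 0 %s",
            name, wfdb_gains[[ch]], wfdb_units[[ch]], d[1], as.integer(chk), ch)
  }, character(1))
  writeLines(c(sprintf("%s %d %.10g %d", name, length(record_channels),
                       record$fs, n),
               sig_lines,
               sprintf("# patient_id=%s", record$patient_id)),
             paste0(path, ".hea"))
  inter <- integer(n * 3)
  for (k in seq_along(record_channels)) inter[seq(k, by = 3, length.out = n)] <-
    dig[[record_channels[k]]]
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(inter, con, size = 2, endian = "little")
}

read_record_wfdb <- function(path) {
  path <- sub("\\.hea$", "", path)
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) stop_pulsebp("file not found: ", hea)
  lines <- readLines(hea)
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2]); fs <- as.numeric(top[3]); n <- as.integer(top[4])
  sig <- lines[2:(1 + nsig)]
  pid <- "anon"
  pid_line <- grep("^#\\s*patient_id=", lines, value = TRUE)
  if (length(pid_line)) pid <- sub("^#\\s*patient_id=", "", pid_line[1])
  meta <- lapply(sig, function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    if (f[2] != "16") stop_pulsebp("only WFDB format 16 is supported")
    gain_spec <- f[3]
    gain <- as.numeric(sub("\\(.*$", "", gain_spec))
    baseline <- if (grepl("\\(", gain_spec))
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_spec)) else 0
    list(gain = gain, baseline = baseline, desc = f[length(f)])
  })
  descs <- vapply(meta, `[[`, character(1), "desc")
  for (ch in record_channels)
    if (!ch %in% descs) stop_pulsebp("channel ", ch, " not found")
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  raw <- readBin(con, integer(), n = n * nsig, size = 2, endian = "little",
                 signed = TRUE)
  chans <- lapply(seq_len(nsig), function(k) {
    m <- meta[[k]]
    (raw[seq(k, by = nsig, length.out = n)] - m$baseline) / m$gain
  })
  names(chans) <- descs
  waveform_record(chans$ecg, chans$ppg, chans$ibp, fs = fs, patient_id = pid)
}

#' Canonical feature-column names
#'
#' The fifteen per-beat features, in their fixed column order.
#' @return character vector of length 15.
#' @export
feature_names <- function() {
  c("PTTrf", "PTTrm", "PTTrp", "AT", "AS", "FAS", "SYSAREA",
    "DT", "DS", "FDS", "DIAAREA", "PIR", "PW", "HR", "K")
}

feature_table_columns <- function() {
  c(feature_names(), "ref_sbp", "ref_dbp", "beat_type", "quality_pass")
}

#' Write a per-beat feature table to CSV
#'
#' One row per cardiac cycle; the 15 feature columns followed by `ref_sbp`,
#' `ref_dbp`, `beat_type` and `quality_pass` (19 columns).
#'
#' @param rows a data frame of beat feature rows.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(rows, path) {
  if (is.null(rows) || nrow(rows) == 0)
    stop_pulsebp("feature table is empty")
  missing <- setdiff(feature_table_columns(), names(rows))
  if (length(missing))
    stop_pulsebp("feature table lacks columns: ",
                 paste(missing, collapse = ", "))
  utils::write.csv(rows[, feature_table_columns()], path, row.names = FALSE)
  invisible(path)
}

#' Read a per-beat feature table from CSV
#'
#' @param path CSV path written by [write_feature_table()].
#' @return data frame with the 19 canonical columns.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_pulsebp("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(feature_table_columns(), names(df))
  if (length(missing))
    stop_pulsebp("feature table lacks columns: ",
                 paste(missing, collapse = ", "))
  df$quality_pass <- as.logical(df$quality_pass)
  df
}

#' Write simulator ground truth to a sidecar CSV
#'
#' @param truth the `truth` data frame from [render_record()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- data.frame(beat_time_s = truth$beat_time, type = truth$beat_type,
                    sbp = truth$true_sbp, dbp = truth$true_dbp,
                    ptt_s = truth$true_ptt, artifact_flag = truth$artifact)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
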