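#' @name io_formats
#' @title On-disk formats
#' @description
#' Sessions are stored as EDF (European Data Format: ASCII header, 16-bit
#' little-endian samples, physical range fixed at +/-500 uV) with a TSV
#' event table (`onset_s`, `code`), and subject tables as CSV. Readers
#' validate strictly and fail with messages naming the offending field.
NULL

.edf_pad <- function(x, width) formatC(as.character(x), width = width, flag = "-")

EDF_PHYS_MIN <- -500
EDF_PHYS_MAX <- 500

#' Write a session to EDF
#'
#' One-second data records; the final record is zero-padded, so a reader
#' may return up to `fs - 1` trailing padding samples. Samples are quantised
#' to 16 bits over a fixed +/-500 uV physical range.
#'
#' @param session An `eeg_session`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(session, path) {
  stopifnot(inherits(session, "eeg_session"))
  sig <- session$signal
  fs <- as.integer(session$fs)
  ns <- nrow(sig)
  n_rec <- ceiling(ncol(sig) / fs)
  if (ncol(sig) < n_rec * fs)
    sig <- cbind(sig, matrix(0, ns, n_rec * fs - ncol(sig)))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8), .edf_pad("X", 80), .edf_pad("X", 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (1 + ns), 8), .edf_pad("", 44),
    .edf_pad(n_rec, 8), .edf_pad(1, 8), .edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  per_sig <- function(vals, width)
    writeChar(paste0(vapply(vals, .edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  per_sig(session$channel_labels, 16)
  per_sig(rep("", ns), 80)
  per_sig(rep("uV", ns), 8)
  per_sig(rep(EDF_PHYS_MIN, ns), 8)
  per_sig(rep(EDF_PHYS_MAX, ns), 8)
  per_sig(rep(-32768L, ns), 8)
  per_sig(rep(32767L, ns), 8)
  per_sig(rep("", ns), 80)
  per_sig(rep(fs, ns), 8)
  per_sig(rep("", ns), 32)

  scale <- (EDF_PHYS_MAX - EDF_PHYS_MIN) / (32767 - (-32768))
  dig <- round((pmin(pmax(sig, EDF_PHYS_MIN), EDF_PHYS_MAX) - EDF_PHYS_MIN) / scale) - 32768
  storage.mode(dig) <- "integer"
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return An `eeg_session` with an empty event table.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes (recomputed below)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rds <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rds(16); rds(80); rds(8)
  pmin_ <- as.numeric(rds(8)); pmax_ <- as.numeric(rds(8))
  dmin <- as.numeric(rds(8)); dmax <- as.numeric(rds(8))
  rds(80)
  spr <- as.integer(rds(8))
  rds(32)
  if (length(unique(spr)) != 1)
    stop("mixed per-signal sampling rates are not supported")
  fs <- spr[1] / rec_dur
  sig <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2,
                   endian = "little", signed = TRUE)
    block <- matrix(raw, nrow = spr[1])     # samples x signals
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    sig[, cols] <- t(block)
  }
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  sig <- sig * scale + (pmin_ - dmin * scale)
  eeg_session(sig, fs, labels,
              data.frame(onset_s = numeric(0), code = character(0)))
}

#' Write / read the event table
#'
#' Tab-separated, columns `onset_s` (seconds from recording start, 6
#' decimals) and `code` (RED/ORANGE/GREEN).
#'
#' @param events data.frame with `onset_s`, `code`.
#' @param path File path.
#' @return `path` invisibly / the validated event data.frame.
#' @export
write_events_tsv <- function(events, path) {
  out <- data.frame(onset_s = sprintf("%.6f", events$onset_s), code = events$code)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  if (!file.exists(path)) stop("events file not found: ", path)
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("onset_s", "code") %in% names(ev)))
    stop("events file must have columns onset_s and code")
  bad <- setdiff(unique(ev$code), c("RED", "ORANGE", "GREEN"))
  if (length(bad))
    stop("unknown event code(s) ", paste(bad, collapse = ", "),
         "; allowed codes are RED, ORANGE, GREEN")
  if (is.unsorted(ev$onset_s)) stop("events must be sorted by onset_s")
  ev
}

#' Read a session (EDF + events)
#'
#' @param edf_path EDF file.
#' @param events_path Events TSV.
#' @param require_channels Channel labels that must be present (default the
#'   32-channel montage); a missing label is a structured error naming it.
#' @return An `eeg_session`; any channel labelled "EMG" is carried but
#'   flagged non-EEG by the epoching stage.
#' @export
read_session <- function(edf_path, events_path,
                         require_channels = montage_channels()) {
  ses <- read_edf(edf_path)
  missing <- setdiff(require_channels, ses$channel_labels)
  if (length(missing))
    stop("required channel label(s) missing from EDF: ",
         paste(missing, collapse = ", "))
  ses$events <- read_events_tsv(events_path)
  ses
}

.subject_schema <- c("subject_id", paste0("K", 1:7), paste0("V", 1:7),
                     "age", "gender", "education_years",
                     "freq_manual", "freq_sport", "freq_music",
                     "freq_spare1", "freq_spare2")

#' Write / read the subject table
#'
#' CSV with one row per subject: 14 MIQ-RS answers (K1..K7, V1..V7, each in
#' 1..7), age, gender, education_years and five 6-point (0..5) frequency
#' ratings. The reader validates ranges row by row and reports the subject
#' and field of the first violation.
#'
#' @param records Subject data.frame following the schema.
#' @param path CSV path.
#' @return `path` invisibly / the validated data.frame.
#' @export
write_subjects_csv <- function(records, path) {
  stopifnot(all(.subject_schema %in% names(records)))
  utils::write.csv(records[.subject_schema], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_subjects_csv
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) stop("subject table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.subject_schema, names(tab))
  if (length(miss)) stop("subject table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(tab$subject_id[duplicated(tab$subject_id)]), collapse = ", "))
  check_range <- function(cols, lo, hi) {
    for (cl in cols) {
      bad <- which(!is.finite(tab[[cl]]) | tab[[cl]] < lo | tab[[cl]] > hi)
      if (length(bad))
        stop(sprintf("subject %s: field %s value %s outside %d..%d",
                     tab$subject_id[bad[1]], cl, tab[[cl]][bad[1]], lo, hi))
    }
  }
  check_range(c(paste0("K", 1:7), paste0("V", 1:7)), 1, 7)
  check_range(grep("^freq_", .subject_schema, value = TRUE), 0, 5)
  tab
}
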