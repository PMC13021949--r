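#' Write an ECG record as a WFDB header/signal pair
#'
#' Emits a minimal but valid WFDB record: a text header (`<id>.hea`) and a
#' format-16 signal file (`<id>.dat`, 16-bit two's-complement little-endian
#' integers, frames interleaved across channels). Samples are quantized as
#' `round(mV * gain) + baseline`; with the default gain of 1000 ADC units/mV
#' a signal already quantized to 1 uV resolution round-trips bit-identically.
#'
#' @param record an [ecg_record].
#' @param dir output directory (created if needed).
#' @param gain ADC units per mV (one value for all channels).
#' @param baseline ADC value corresponding to 0 mV.
#' @return Invisibly, the path to the header file.
#' @seealso [read_record()]
#' @export
write_wfdb <- function(record, dir, gain = 1000, baseline = 0) {
  stopifnot(inherits(record, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nsig <- nrow(record$signal); nsamp <- ncol(record$signal)
  adc <- round(record$signal * gain) + baseline
  if (any(adc > 32767 | adc < -32768))
    stop("signal exceeds the 16-bit ADC range at gain ", gain)
  storage.mode(adc) <- "integer"
  datname <- paste0(record$record_id, ".dat")
  # per-signal checksum: 16-bit signed sum of samples
  cksum <- apply(adc, 1, function(v) {
    s <- sum(as.numeric(v)) %% 65536
    if (s > 32767) s - 65536 else s
  })
  hdr <- c(sprintf("%s %d %g %d", record$record_id, nsig, record$fs, nsamp),
           sprintf("%s 16 %g(%d)/mV 16 0 %d %d 0 %s",
                   datname, gain, baseline, adc[, 1], as.integer(cksum),
                   record$lead_names))
  writeLines(hdr, file.path(dir, paste0(record$record_id, ".hea")))
  con <- file(file.path(dir, datname), "wb")
  on.exit(close(con))
  writeBin(as.integer(as.vector(adc)), con, size = 2, endian = "little")
  invisible(file.path(dir, paste0(record$record_id, ".hea")))
}

parse_gain_spec <- function(s) {
  # "1000(0)/mV" | "1000/mV" | "1000"
  m <- regmatches(s, regexec("^([0-9eE.+-]+)(\\(([-0-9]+)\\))?(/(.*))?$", s))[[1]]
  if (length(m) == 0 || !nzchar(m[2]))
    stop("cannot parse gain specification '", s, "'")
  list(gain = as.numeric(m[2]),
       baseline = if (nzchar(m[4])) as.numeric(m[4]) else 0,
       units = if (nzchar(m[6])) m[6] else "mV")
}

#' Read a WFDB record
#'
#' Parses a WFDB header and its format-16 signal file, converts samples to mV
#' via `(adc - baseline) / gain`, and normalizes channel descriptions to the
#' canonical 12-lead names (channel order preserved from the file). Only
#' format 16 with all signals in one `.dat` file is supported — the dialect
#' the package's own writer emits.
#'
#' @param path path to the record: with or without the `.hea` extension.
#' @param dialect signal-file dialect; only `"wfdb"` is supported.
#' @return an [ecg_record] (labels and demographics are not stored in WFDB
#'   headers; attach them from a label table, see [read_label_table()]).
#' @export
read_record <- function(path, dialect = "wfdb") {
  dialect <- match.arg(dialect, "wfdb")
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea))
    stop("cannot read WFDB header: file not found: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec_fields <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec_fields) < 4)
    stop("corrupt WFDB header (record line): ", hea)
  record_id <- rec_fields[1]
  nsig <- as.integer(rec_fields[2])
  fs <- as.numeric(rec_fields[3])
  nsamp <- as.integer(rec_fields[4])
  if (is.na(nsig) || nsig < 1) stop("corrupt WFDB header (no signals): ", hea)
  if (length(lines) < 1 + nsig)
    stop("corrupt WFDB header (expected ", nsig, " signal lines): ", hea)
  sig <- lapply(lines[2:(1 + nsig)], function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(f) < 9)
      stop("corrupt WFDB signal line: '", l, "'")
    g <- parse_gain_spec(f[3])
    list(file = f[1], fmt = f[2], gain = g$gain, baseline = g$baseline,
         units = g$units, cksum = as.numeric(f[7]),
         desc = paste(f[9:length(f)], collapse = " "))
  })
  fmts <- unique(vapply(sig, `[[`, "", "fmt"))
  if (!identical(fmts, "16"))
    stop("unsupported WFDB signal format(s): ", paste(fmts, collapse = ", "),
         " (only format 16 is supported)")
  datfiles <- unique(vapply(sig, `[[`, "", "file"))
  if (length(datfiles) != 1)
    stop("multi-file WFDB records are not supported: ", hea)
  datpath <- file.path(dirname(hea), datfiles)
  if (!file.exists(datpath))
    stop("cannot read WFDB signal file: file not found: ", datpath)
  con <- file(datpath, "rb")
  on.exit(close(con))
  raw_int <- readBin(con, "integer", n = nsig * nsamp, size = 2,
                     signed = TRUE, endian = "little")
  if (length(raw_int) != nsig * nsamp)
    stop("corrupt WFDB signal file (expected ", nsig * nsamp,
         " samples, got ", length(raw_int), "): ", datpath)
  adc <- matrix(raw_int, nrow = nsig)          # frames are columns
  for (i in seq_len(nsig)) {
    s <- sum(as.numeric(adc[i, ])) %% 65536
    if (s > 32767) s <- s - 65536
    if (is.finite(sig[[i]]$cksum) && s != sig[[i]]$cksum)
      warning("checksum mismatch on channel ", i, " of ", record_id)
  }
  mv <- adc
  for (i in seq_len(nsig))
    mv[i, ] <- (adc[i, ] - sig[[i]]$baseline) / sig[[i]]$gain
  leads <- normalize_lead_names(vapply(sig, `[[`, "", "desc"))
  ecg_record(mv, fs = fs, lead_names = leads, record_id = record_id)
}

#' Write a label table for a set of records
#'
#' Tab-separated table with one row per record: `record_id`, `patient_id`,
#' `codes` (pipe-separated `code:likelihood` pairs), `age`, `sex`,
#' `validated`, `split`.
#'
#' @param records list of [ecg_record]s.
#' @param path output file.
#' @param split optional character vector (recycled) of split assignments.
#' @return Invisibly, the data frame written.
#' @export
write_label_table <- function(records, path, split = NA_character_) {
  codes <- vapply(records, function(r) {
    if (is.null(r$labels)) "" else
      paste(sprintf("%s:%g", names(r$labels), r$labels), collapse = "|")
  }, "")
  df <- data.frame(record_id = vapply(records, `[[`, "", "record_id"),
                   patient_id = vapply(records, `[[`, "", "patient_id"),
                   codes = codes,
                   age = vapply(records, `[[`, 0, "age"),
                   sex = vapply(records, `[[`, "", "sex"),
                   validated = vapply(records, `[[`, TRUE, "validated"),
                   split = rep_len(split, length(records)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read a label table
#'
#' @param path file written by [write_label_table()].
#' @return data frame with a `labels` list-column of named likelihood vectors
#'   in addition to the raw `codes` strings.
#' @export
read_label_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(record_id = "character",
                                         patient_id = "character",
                                         codes = "character"))
  df$labels <- lapply(df$codes, function(s) {
    if (!nzchar(s)) return(NULL)
    parts <- strsplit(strsplit(s, "|", fixed = TRUE)[[1]], ":", fixed = TRUE)
    stats::setNames(vapply(parts, function(p) as.numeric(p[2]), 0),
                    vapply(parts, `[[`, "", 1))
  })
  df
}

#' Load a cohort directory (WFDB records + label table)
#'
#' @param dir directory containing `manifest.tsv` (a label table, possibly
#'   with extra columns) and one WFDB record per `record_id`.
#' @param validated_only drop records not validated by a human rater.
#' @return list with `records` (list of [ecg_record]s with labels and
#'   demographics attached) and `manifest` (the label-table data frame).
#' @export
load_cohort <- function(dir, validated_only = FALSE) {
  man_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(man_path))
    stop("no manifest.tsv in ", dir)
  man <- read_label_table(man_path)
  if (validated_only) man <- man[man$validated, , drop = FALSE]
  records <- lapply(seq_len(nrow(man)), function(i) {
    r <- read_record(file.path(dir, man$record_id[i]))
    r$patient_id <- man$patient_id[i]
    r$labels <- man$labels[[i]]
    r$age <- man$age[i]
    r$sex <- man$sex[i]
    r$validated <- man$validated[i]
    r
  })
  list(records = records, manifest = man)
}
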