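# Minimal WFDB support: header (.hea) parsing and 16-bit (format 16,
# little-endian, sample-interleaved) signal files, the layout PhysioNet
# 12-lead resting ECGs use. Physical units are reconstructed as
# (adc - baseline) / gain millivolts.

#' Read a record-metadata table
#'
#' The metadata dialect is a CSV with columns `record_id`, `patient_id`,
#' `age`, `sex`, `rhythm_labels` and `superclass_labels`; the two label
#' columns hold semicolon-joined sets (empty string = empty set).
#'
#' @param path path to the metadata CSV.
#' @return A data.frame with one row per record.
#' @export
read_metadata_csv <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  meta <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(record_id = "character",
                                         patient_id = "character"))
  need <- c("record_id", "patient_id", "age", "sex",
            "rhythm_labels", "superclass_labels")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata CSV missing column(s): ", paste(miss, collapse = ", "))
  meta$age <- suppressWarnings(as.numeric(meta$age))
  meta$sex[!meta$sex %in% c("male", "female")] <- NA_character_
  meta
}

split_labels <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0)
  else strsplit(x, ";", fixed = TRUE)[[1]]
}

apply_metadata <- function(record, metadata) {
  row <- metadata[metadata$record_id == record$record_id, , drop = FALSE]
  if (nrow(row) == 0L) return(record)
  row <- row[1L, ]
  record$patient_id <- row$patient_id
  record$age <- row$age
  record$sex <- row$sex
  record$rhythm_labels <- split_labels(row$rhythm_labels)
  record$superclass_labels <- split_labels(row$superclass_labels)
  record
}

parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty WFDB header: ", hea_path)
  top <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  if (length(top) < 3L) stop("malformed WFDB record line in ", hea_path)
  rec <- list(record_name = top[[1]],
              nsig = as.integer(top[[2]]),
              fs = as.numeric(top[[3]]),
              nsamp = if (length(top) >= 4L) as.integer(top[[4]]) else NA_integer_)
  if (length(lines) < 1L + rec$nsig)
    stop("WFDB header declares ", rec$nsig, " signals but lists fewer")
  sig <- lapply(lines[1L + seq_len(rec$nsig)], function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(f) < 2L) stop("malformed WFDB signal line: ", l)
    fmt <- sub("x[0-9]+$", "", f[[2]])     # strip samples-per-frame suffix
    gain_spec <- if (length(f) >= 3L) f[[3]] else "200"
    gain_num <- sub("\\(.*", "", sub("/.*", "", gain_spec))
    baseline <- if (grepl("\\(", gain_spec))
      as.numeric(sub(".*\\((-?[0-9]+)\\).*", "\\1", gain_spec)) else
      if (length(f) >= 5L) as.numeric(f[[5]]) else 0
    list(file = f[[1]], fmt = fmt,
         gain = {g <- as.numeric(gain_num); if (is.na(g) || g == 0) 200 else g},
         baseline = if (is.na(baseline)) 0 else baseline,
         description = if (length(f) >= 9L)
           paste(f[9:length(f)], collapse = " ") else NA_character_)
  })
  rec$signals <- sig
  rec
}

#' Read a WFDB record
#'
#' Reads a WFDB header/signal pair (format 16 only) into an [ecg_record()].
#' Lead names are taken from the signal description field when present,
#' otherwise leads are assumed to follow the standard 12-lead order. When a
#' metadata table is supplied, patient id, age, sex and labels are joined on
#' `record_id`; records absent from the table stay readable but unlabelled.
#'
#' @param path path to the record, with or without the `.hea` extension.
#' @param metadata optional data.frame from [read_metadata_csv()].
#' @return An [ecg_record()].
#' @export
read_wfdb_record <- function(path, metadata = NULL) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("WFDB header not found: ", hea)
  h <- parse_wfdb_header(hea)
  fmts <- unique(vapply(h$signals, `[[`, "", "fmt"))
  if (!identical(fmts, "16"))
    stop("unsupported WFDB signal format(s) ", paste(fmts, collapse = ","),
         " in ", hea, " (only format 16 is supported)")
  dat_files <- unique(vapply(h$signals, `[[`, "", "file"))
  if (length(dat_files) != 1L)
    stop("multi-file WFDB records are not supported: ", hea)
  dat <- file.path(dirname(hea), dat_files)
  if (!file.exists(dat)) stop("WFDB signal file not found: ", dat)
  n_int <- file.info(dat)$size / 2L
  raw <- readBin(dat, what = "integer", size = 2L, n = n_int,
                 signed = TRUE, endian = "little")
  if (length(raw) %% h$nsig != 0L)
    stop("corrupt WFDB signal file (length not a multiple of nsig): ", dat)
  adc <- matrix(raw, nrow = h$nsig)          # interleaved by sample
  mv <- adc
  for (i in seq_len(h$nsig)) {
    s <- h$signals[[i]]
    mv[i, ] <- (adc[i, ] - s$baseline) / s$gain
  }
  leads <- vapply(h$signals, `[[`, "", "description")
  if (anyNA(leads)) leads <- LEAD_VOCABULARY[seq_len(h$nsig)]
  rec <- ecg_record(record_id = h$record_name,
                    patient_id = h$record_name,
                    fs = h$fs, lead_names = leads, samples = mv)
  if (!is.null(metadata)) rec <- apply_metadata(rec, metadata)
  rec
}

#' Write a record as a WFDB header/signal pair
#'
#' Quantises to 16-bit integers with the given gain (ADC units per mV);
#' round-trip error through [read_wfdb_record()] is at most 1/(2 gain) mV.
#'
#' @param record an [ecg_record()].
#' @param dir output directory (created if needed).
#' @param gain ADC units per millivolt.
#' @return The header path, invisibly.
#' @export
write_wfdb_record <- function(record, dir, gain = 1000) {
  stopifnot(inherits(record, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  name <- record$record_id
  adc <- round(record$samples * gain)
  if (any(abs(adc) > 32767))
    stop("signal exceeds 16-bit range at gain ", gain)
  hea <- file.path(dir, paste0(name, ".hea"))
  datname <- paste0(name, ".dat")
  lines <- c(sprintf("%s %d %g %d", name, nrow(adc), record$fs, ncol(adc)),
             sprintf("%s 16 %g/mV 16 0 %d 0 0 %s", datname, gain,
                     as.integer(adc[, 1]), record$lead_names))
  writeLines(lines, hea)
  writeBin(as.integer(adc), file.path(dir, datname), size = 2L,
           endian = "little")
  invisible(hea)
}

#' Read a delimited-text ECG record
#'
#' CSV fallback format: one column per lead, header row of lead names,
#' values in millivolts; the sampling frequency is not stored in the file
#' and must be supplied.
#'
#' @param path path to the CSV.
#' @param fs sampling frequency in Hz.
#' @param record_id record identifier; defaults to the file stem.
#' @param metadata optional data.frame from [read_metadata_csv()].
#' @return An [ecg_record()].
#' @export
read_ecg_csv <- function(path, fs, record_id = NULL, metadata = NULL) {
  if (!file.exists(path)) stop("ECG CSV not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(record_id))
    record_id <- sub("\\.[^.]*$", "", basename(path))
  rec <- ecg_record(record_id = record_id, patient_id = record_id, fs = fs,
                    lead_names = names(x), samples = t(as.matrix(x)))
  if (!is.null(metadata)) rec <- apply_metadata(rec, metadata)
  rec
}
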