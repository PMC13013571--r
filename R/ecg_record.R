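#' @keywords internal
"_PACKAGE"

# Standard 12-lead vocabulary; stored order of a record may be any subset.
LEAD_VOCABULARY <- c("I", "II", "III", "aVR", "aVL", "aVF",
                     "V1", "V2", "V3", "V4", "V5", "V6")

#' Construct a multi-lead ECG record
#'
#' An `ecg_record` bundles a leads-by-time sample matrix (millivolts) with
#' its sampling frequency and the patient/label metadata used downstream by
#' the cohort pipeline. Age and sex may be missing (`NA`), never sentinel
#' numbers.
#'
#' @param record_id character scalar identifying the recording.
#' @param patient_id character scalar identifying the patient.
#' @param fs sampling frequency in Hz (positive).
#' @param lead_names character vector of unique lead names drawn from the
#'   standard 12-lead vocabulary (I, II, III, aVR, aVL, aVF, V1--V6).
#' @param samples numeric matrix, one row per lead, columns are samples (mV).
#' @param age patient age in years (nonnegative) or `NA`.
#' @param sex `"male"`, `"female"` or `NA`.
#' @param rhythm_labels character vector of rhythm statements (e.g. `"SR"`,
#'   `"AFIB"`); may be empty.
#' @param superclass_labels character vector of diagnostic superclass labels;
#'   may be empty.
#'
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(record_id, patient_id, fs, lead_names, samples,
                       age = NA_real_, sex = NA_character_,
                       rhythm_labels = character(0),
                       superclass_labels = character(0)) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = length(lead_names))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (nrow(samples) != length(lead_names))
    stop("samples must have exactly one row per lead name (",
         nrow(samples), " rows vs ", length(lead_names), " leads)")
  if (ncol(samples) < 2L)
    stop("each lead must contain at least 2 samples")
  if (anyDuplicated(lead_names))
    stop("lead names must be unique")
  bad <- setdiff(lead_names, LEAD_VOCABULARY)
  if (length(bad))
    stop("lead names outside the 12-lead vocabulary: ",
         paste(bad, collapse = ", "))
  if (!is.na(age) && age < 0) stop("age must be nonnegative or NA")
  if (!is.na(sex) && !sex %in% c("male", "female"))
    stop("sex must be 'male', 'female' or NA")
  structure(list(
    record_id = as.character(record_id),
    patient_id = as.character(patient_id),
    fs = as.numeric(fs),
    lead_names = as.character(lead_names),
    samples = samples,
    age = as.numeric(age),
    sex = as.character(sex),
    rhythm_labels = unique(as.character(rhythm_labels)),
    superclass_labels = unique(as.character(superclass_labels))
  ), class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s> patient %s, %d lead(s) x %d samples @ %g Hz\n",
              x$record_id, x$patient_id, nrow(x$samples), ncol(x$samples),
              x$fs))
  cat("  leads:  ", paste(x$lead_names, collapse = " "), "\n")
  cat("  rhythm: ", if (length(x$rhythm_labels))
    paste(x$rhythm_labels, collapse = ";") else "(none)", "\n")
  invisible(x)
}

#' Extract a single lead from a record
#'
#' @param record an [ecg_record()].
#' @param lead lead name to extract.
#'
#' @return A list with `samples` (numeric vector, mV) and `fs` (Hz).
#' @export
select_lead <- function(record, lead) {
  stopifnot(inherits(record, "ecg_record"))
  i <- match(lead, record$lead_names)
  if (is.na(i))
    stop("lead '", lead, "' not present; available leads: ",
         paste(record$lead_names, collapse = ", "))
  list(samples = record$samples[i, ], fs = record$fs)
}

#' Downsample a record by integer decimation
#'
#' Keeps every `factor`-th sample starting at the first, with no filtering
#' and no interpolation: 500 Hz to 125 Hz is exact decimation by 4. Selected
#' samples are bit-identical to the input.
#'
#' @param record an [ecg_record()].
#' @param factor positive integer decimation factor.
#'
#' @return An [ecg_record()] with fs divided by `factor` and
#'   `ceiling(n / factor)` samples per lead.
#' @export
downsample <- function(record, factor) {
  stopifnot(inherits(record, "ecg_record"))
  if (length(factor) != 1L || is.na(factor) || factor < 1 ||
      factor != as.integer(factor))
    stop("factor must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(record)
  idx <- seq(1L, ncol(record$samples), by = factor)
  out <- record
  out$samples <- record$samples[, idx, drop = FALSE]
  out$fs <- record$fs / factor
  out
}
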