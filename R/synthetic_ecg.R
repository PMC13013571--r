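# Synthetic multi-lead ECG generator. Each beat is a sum of five Gaussian
# bumps (P, Q, R, S, T) placed relative to the R peak; RR intervals come
# from a truncated normal; sinusoidal baseline wander and white noise are
# added on top. Twelve leads are fixed linear mixtures of two latent
# morphology sources plus lead-specific noise — enough to exercise per-lead
# code paths without a torso model. Analytic ground truth (R-peak times,
# class label) is returned with every record.

default_wave_params <- function() {
  data.frame(wave = c("P", "Q", "R", "S", "T"),
             amp = c(0.15, -0.10, 1.00, -0.15, 0.30),      # mV
             offset = c(-0.16, -0.025, 0, 0.025, 0.30),    # s relative to R
             width = c(0.020, 0.008, 0.010, 0.008, 0.040), # Gaussian sd, s
             stringsAsFactors = FALSE)
}

# Second latent source: broader, P/T-dominant morphology so leads are not
# simple rescalings of each other.
alt_wave_params <- function() {
  w <- default_wave_params()
  w$amp <- c(0.10, -0.05, 0.60, -0.25, 0.40)
  w$width <- w$width * 1.4
  w
}

# fixed 12 x 2 mixing of the two latent sources, one row per lead in
# standard order I, II, III, aVR, aVL, aVF, V1..V6
lead_mixing_matrix <- function() {
  m <- matrix(c(
    0.6, 0.3,   1.0, 0.0,   0.4, 0.5,  -0.8, -0.2,
    0.3, 0.4,   0.7, 0.2,  -0.3, 0.8,   0.2, 0.9,
    0.5, 0.7,   0.8, 0.4,   0.9, 0.2,   1.0, 0.1),
    ncol = 2, byrow = TRUE)
  rownames(m) <- LEAD_VOCABULARY
  m
}

#' Parameters of the synthetic ECG generator
#'
#' @param fs sampling frequency in Hz (>= 125; 500 matches the source
#'   registry this generator emulates).
#' @param duration record length in seconds (>= 5; 10 is the standard).
#' @param mean_rr mean RR interval in seconds.
#' @param rr_sd RR-interval standard deviation in seconds (>= 0); intervals
#'   are floored at 0.3 s.
#' @param wave_params data.frame with columns `wave`, `amp` (mV), `offset`
#'   (s relative to the R peak) and `width` (Gaussian sd, s).
#' @param baseline_amp baseline-wander amplitude in mV.
#' @param baseline_freq baseline-wander frequency in Hz.
#' @param noise_sd additive white-noise standard deviation in mV.
#' @param class_effect named multiplicative perturbations applied to wave
#'   parameters for case-class records, names like `"P_amp"` or
#'   `"P_width"`; `NULL` means no class difference.
#' @param seed integer seed.
#' @return A list of class `synthetic_ecg_params`.
#' @export
synthetic_ecg_params <- function(fs = 500, duration = 10, mean_rr = 0.8,
                                 rr_sd = 0.05,
                                 wave_params = default_wave_params(),
                                 baseline_amp = 0.05, baseline_freq = 0.33,
                                 noise_sd = 0.02, class_effect = NULL,
                                 seed = 1L) {
  if (fs < 125) stop("fs must be at least 125 Hz")
  if (duration < 5) stop("duration must be at least 5 s")
  if (rr_sd < 0) stop("rr_sd must be nonnegative")
  if (mean_rr <= 0) stop("mean_rr must be positive")
  if (any(wave_params$width <= 0)) stop("wave widths must be positive")
  structure(list(fs = fs, duration = duration, mean_rr = mean_rr,
                 rr_sd = rr_sd, wave_params = wave_params,
                 baseline_amp = baseline_amp, baseline_freq = baseline_freq,
                 noise_sd = noise_sd, class_effect = class_effect,
                 seed = as.integer(seed)),
            class = "synthetic_ecg_params")
}

#' Graded P-wave class effect
#'
#' The default case/control morphology difference: a multiplicative
#' enlargement of the P wave, the physiologically plausible correlate of
#' atrial remodelling. `strength` interpolates linearly from no effect
#' (`0`) to amplitude x2.0 / width x1.6 (`1`, the strong fixture at which
#' the feature-classifier pipeline separates the classes cleanly on
#' default-noise records).
#'
#' @param strength effect magnitude in \[0, 1\].
#' @return A named multiplier vector for
#'   [synthetic_ecg_params()]`$class_effect`, or `NULL` when `strength = 0`.
#' @export
paf_class_effect <- function(strength = 1) {
  stopifnot(strength >= 0)
  if (strength == 0) return(NULL)
  c(P_amp = 1 + 1.0 * strength, P_width = 1 + 0.6 * strength)
}

apply_class_effect <- function(wave_params, class_effect) {
  if (is.null(class_effect) || !length(class_effect)) return(wave_params)
  for (nm in names(class_effect)) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !parts[1] %in% wave_params$wave ||
        !parts[2] %in% c("amp", "offset", "width"))
      stop("malformed class_effect name: ", nm,
           " (expected <wave>_<amp|offset|width>)")
    i <- match(parts[1], wave_params$wave)
    wave_params[i, parts[2]] <- wave_params[i, parts[2]] * class_effect[[nm]]
  }
  wave_params
}

beat_train <- function(t, r_times, wave_params) {
  s <- numeric(length(t))
  for (w in seq_len(nrow(wave_params)))
    for (rt in r_times)
      s <- s + wave_params$amp[w] *
        exp(-((t - (rt + wave_params$offset[w]))^2) /
              (2 * wave_params$width[w]^2))
  s
}

#' Generate one synthetic 12-lead ECG record
#'
#' @param params a [synthetic_ecg_params()]; the class perturbation in
#'   `params$class_effect` is applied iff `label == "case"`.
#' @param record_id,patient_id identifiers stored in the record.
#' @param label `"case"` or `"control"` (morphology class).
#' @param age,sex,rhythm_labels,superclass_labels metadata stored in the
#'   record.
#' @return A list with `record` (an [ecg_record()]), `r_peak_times`
#'   (seconds), `r_peak_indices` (1-based samples) and `label`.
#' @export
generate_ecg <- function(params, record_id = "synth001",
                         patient_id = record_id, label = "control",
                         age = NA_real_, sex = NA_character_,
                         rhythm_labels = "SR",
                         superclass_labels = character(0)) {
  stopifnot(inherits(params, "synthetic_ecg_params"))
  set.seed(params$seed)
  waves <- if (identical(label, "case"))
    apply_class_effect(params$wave_params, params$class_effect)
  else params$wave_params

  r_times <- 0.35
  repeat {
    rr <- if (params$rr_sd > 0)
      max(0.3, stats::rnorm(1, params$mean_rr, params$rr_sd))
    else params$mean_rr
    nxt <- r_times[length(r_times)] + rr
    if (nxt > params$duration - 0.05) break
    r_times <- c(r_times, nxt)
  }

  n <- round(params$duration * params$fs)
  t <- (seq_len(n) - 1) / params$fs
  s1 <- beat_train(t, r_times, waves)
  s2 <- beat_train(t, r_times, apply_class_effect(
    alt_wave_params(), if (identical(label, "case")) params$class_effect else NULL))
  wander <- params$baseline_amp * sin(2 * pi * params$baseline_freq * t)
  mix <- lead_mixing_matrix()
  samples <- mix %*% rbind(s1, s2)
  samples <- samples + matrix(wander, nrow(mix), n, byrow = TRUE)
  if (params$noise_sd > 0)
    samples <- samples + matrix(stats::rnorm(length(samples), 0,
                                             params$noise_sd),
                                nrow(mix), n)
  rec <- ecg_record(record_id = record_id, patient_id = patient_id,
                    fs = params$fs, lead_names = rownames(mix),
                    samples = samples, age = age, sex = sex,
                    rhythm_labels = rhythm_labels,
                    superclass_labels = superclass_labels)
  list(record = rec, r_peak_times = r_times,
       r_peak_indices = round(r_times * params$fs) + 1L, label = label)
}

#' Generate a labelled synthetic registry
#'
#' Case patients receive class-perturbed SR records plus one dummy
#' AFIB-labelled record (so the cohort pipeline recognises them); control
#' patients receive SR records with demographics stratum-matched (same sex,
#' same age decade) to the case patients by cycling, which guarantees a
#' balanced matched cohort. Optional extra patients carry a comorbidity
#' superclass (destined for test group 1) or nothing (test group 2). Case
#' ages are uniform over 40--89 and sexes balanced. Deterministic given
#' `params$seed`.
#'
#' @param n_case_patients,n_control_patients patient counts (>= 1).
#' @param records_per_patient SR records generated per patient.
#' @param params a [synthetic_ecg_params()] shared by all records.
#' @param n_comorbid_patients extra non-case patients with a comorbidity
#'   superclass.
#' @param n_healthy_patients extra non-case healthy patients.
#' @return A list with `records` (list of [ecg_record()]), `metadata`
#'   (registry data.frame in the [read_metadata_csv()] dialect), `labels`
#'   (named character vector record_id -> class) and `truth` (planted
#'   counts and ground-truth R-peak indices per record).
#' @export
generate_registry <- function(n_case_patients, n_control_patients,
                              records_per_patient = 1,
                              params = synthetic_ecg_params(),
                              n_comorbid_patients = 0,
                              n_healthy_patients = 0) {
  stopifnot(n_case_patients >= 1, n_control_patients >= 1,
            records_per_patient >= 1)
  set.seed(params$seed)
  total <- (n_case_patients + n_control_patients + n_comorbid_patients +
              n_healthy_patients) * (records_per_patient + 1L)
  seeds <- sample.int(2^30, total)
  seed_i <- 0L
  next_seed <- function() { seed_i <<- seed_i + 1L; seeds[seed_i] }

  case_age <- sample(40:89, n_case_patients, replace = TRUE)
  case_sex <- rep(c("male", "female"), length.out = n_case_patients)

  records <- list(); meta <- list(); labels <- character(0); rp <- list()
  add_record <- function(pid, rid, label, age, sex, rhythm, super) {
    p <- params; p$seed <- next_seed()
    g <- generate_ecg(p, record_id = rid, patient_id = pid, label = label,
                      age = age, sex = sex, rhythm_labels = rhythm,
                      superclass_labels = super)
    records[[rid]] <<- g$record
    labels[[rid]] <<- label
    rp[[rid]] <<- g$r_peak_indices
    meta[[length(meta) + 1L]] <<- data.frame(
      record_id = rid, patient_id = pid, age = age, sex = sex,
      rhythm_labels = paste(rhythm, collapse = ";"),
      superclass_labels = paste(super, collapse = ";"),
      stringsAsFactors = FALSE)
  }

  pid_counter <- 0L
  new_pid <- function(prefix) {
    pid_counter <<- pid_counter + 1L
    sprintf("%s%03d", prefix, pid_counter)
  }

  for (i in seq_len(n_case_patients)) {
    pid <- new_pid("case")
    add_record(pid, paste0(pid, "_afib"), "case", case_age[i], case_sex[i],
               "AFIB", character(0))
    for (r in seq_len(records_per_patient))
      add_record(pid, sprintf("%s_sr%02d", pid, r), "case",
                 case_age[i], case_sex[i], "SR", character(0))
  }
  for (i in seq_len(n_control_patients)) {
    pid <- new_pid("ctrl")
    j <- ((i - 1L) %% n_case_patients) + 1L   # cycle case strata
    age <- sample(seq(floor(case_age[j] / 10) * 10,
                      floor(case_age[j] / 10) * 10 + 9), 1)
    for (r in seq_len(records_per_patient))
      add_record(pid, sprintf("%s_sr%02d", pid, r), "control",
                 age, case_sex[j], "SR", character(0))
  }
  if (n_comorbid_patients > 0)
    for (i in seq_len(n_comorbid_patients)) {
      pid <- new_pid("como")
      add_record(pid, paste0(pid, "_sr01"), "control",
                 sample(40:89, 1), sample(c("male", "female"), 1),
                 "SR", "MI")
    }
  if (n_healthy_patients > 0)
    for (i in seq_len(n_healthy_patients)) {
      pid <- new_pid("hlth")
      add_record(pid, paste0(pid, "_sr01"), "control",
                 sample(40:89, 1), sample(c("male", "female"), 1),
                 "SR", character(0))
    }

  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  list(records = records, metadata = metadata, labels = labels,
       truth = list(n_case_patients = n_case_patients,
                    n_control_patients = n_control_patients,
                    n_comorbid_patients = n_comorbid_patients,
                    n_healthy_patients = n_healthy_patients,
                    records_per_patient = records_per_patient,
                    r_peak_indices = rp))
}
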