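# Case/control cohort construction from a labelled record registry.
# Cases: sinus-rhythm records of patients who also have an AFIB record.
# Controls: age- and sex-matched sinus-rhythm records of patients with no
# AFIB record and no comorbidity superclass. Leftover records form the
# comorbidity (group 1) and healthy (group 2) test groups.

meta_has_label <- function(column, label) {
  vapply(column, function(x) label %in% split_labels(x), logical(1),
         USE.NAMES = FALSE)
}

decade_band <- function(age) {
  b <- floor(age / 10) * 10
  ifelse(is.na(b) | b < 20 | b > 80, NA_real_, b)
}

#' Select case records from a labelled registry
#'
#' A patient qualifies as a case when they have at least one AFIB-labelled
#' record and at least one SR-labelled record; all of their SR records are
#' selected (the AFIB records themselves never are).
#'
#' @param metadata data.frame in the [read_metadata_csv()] dialect.
#' @return The subset of `metadata` rows forming the case record set.
#' @export
select_cases <- function(metadata) {
  afib <- meta_has_label(metadata$rhythm_labels, "AFIB")
  sr <- meta_has_label(metadata$rhythm_labels, "SR")
  qualifying <- intersect(unique(metadata$patient_id[afib]),
                          unique(metadata$patient_id[sr]))
  metadata[sr & metadata$patient_id %in% qualifying, , drop = FALSE]
}

control_eligible <- function(metadata, case_patients) {
  sr <- meta_has_label(metadata$rhythm_labels, "SR")
  afib_patients <- unique(metadata$patient_id[
    meta_has_label(metadata$rhythm_labels, "AFIB")])
  comorbid_patients <- unique(metadata$patient_id[
    nzchar(metadata$superclass_labels) & !is.na(metadata$superclass_labels)])
  metadata[sr &
           !metadata$patient_id %in% afib_patients &
           !metadata$patient_id %in% comorbid_patients &
           !metadata$patient_id %in% case_patients, , drop = FALSE]
}

#' Match control records to case records by sex and age decade
#'
#' One control record per case record, drawn without replacement from the
#' eligible pool, matched on sex and decade age band (20--29 ... 80--89;
#' ages outside those bands are rejected with a warning). Within a stratum,
#' candidates with the smallest absolute age difference are preferred and
#' ties are resolved by a seeded draw; a second record from an
#' already-used control patient is only taken when the stratum would
#' otherwise be exhausted. Unmatched cases are reported, not fatal.
#'
#' @param cases case record rows (from [select_cases()]).
#' @param pool control-eligible record rows.
#' @param seed integer seed making the matching reproducible.
#' @return A list with `controls` (matched rows plus `matched_case_id`),
#'   and `unmatched` (case record ids that found no control).
#' @export
match_controls <- function(cases, pool, seed = 1L) {
  set.seed(seed)
  drop_case <- is.na(decade_band(cases$age)) | is.na(cases$sex)
  if (any(drop_case))
    warning("case record(s) outside the 20-89 decade bands or missing ",
            "demographics rejected: ",
            paste(cases$record_id[drop_case], collapse = ", "))
  cases <- cases[!drop_case, , drop = FALSE]
  pool <- pool[!is.na(decade_band(pool$age)) & !is.na(pool$sex), , drop = FALSE]
  pool <- pool[order(pool$patient_id, pool$record_id), , drop = FALSE]
  used_record <- logical(nrow(pool))
  used_patient <- character(0)
  picks <- integer(0)
  matched_case <- character(0)
  unmatched <- character(0)
  for (i in seq_len(nrow(cases))) {
    stratum <- which(!used_record &
                     pool$sex == cases$sex[i] &
                     decade_band(pool$age) == decade_band(cases$age[i]))
    if (!length(stratum)) { unmatched <- c(unmatched, cases$record_id[i]); next }
    fresh <- stratum[!pool$patient_id[stratum] %in% used_patient]
    cand <- if (length(fresh)) fresh else stratum
    dist <- abs(pool$age[cand] - cases$age[i])
    cand <- cand[dist == min(dist)]
    pick <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
    used_record[pick] <- TRUE
    used_patient <- union(used_patient, pool$patient_id[pick])
    picks <- c(picks, pick)
    matched_case <- c(matched_case, cases$record_id[i])
  }
  controls <- pool[picks, , drop = FALSE]
  controls$matched_case_id <- matched_case
  rownames(controls) <- NULL
  list(controls = controls, unmatched = unmatched)
}

#' Build the comorbidity and healthy test groups
#'
#' From all records outside the training cohort: test group 1 holds the SR
#' records of non-case patients with at least one comorbidity superclass
#' (on any of their records); test group 2 the SR records of non-case
#' patients with none that were not used as matched controls. The groups
#' are disjoint from each other and from the cohort.
#'
#' @param metadata full registry metadata.
#' @param cohort_record_ids record ids already used in the training cohort.
#' @return A list with data.frames `test_group_1` and `test_group_2`.
#' @export
build_test_groups <- function(metadata, cohort_record_ids = character(0)) {
  case_patients <- unique(select_cases(metadata)$patient_id)
  afib_patients <- unique(metadata$patient_id[
    meta_has_label(metadata$rhythm_labels, "AFIB")])
  sr <- meta_has_label(metadata$rhythm_labels, "SR")
  comorbid_patients <- unique(metadata$patient_id[
    nzchar(metadata$superclass_labels) & !is.na(metadata$superclass_labels)])
  eligible <- sr &
    !metadata$patient_id %in% case_patients &
    !metadata$patient_id %in% afib_patients &
    !metadata$record_id %in% cohort_record_ids
  g1 <- metadata[eligible & metadata$patient_id %in% comorbid_patients, ,
                 drop = FALSE]
  g2 <- metadata[eligible & !metadata$patient_id %in% comorbid_patients, ,
                 drop = FALSE]
  list(test_group_1 = g1, test_group_2 = g2)
}

#' Run the full cohort construction
#'
#' Chains [select_cases()], [match_controls()] and [build_test_groups()]
#' and returns a cohort manifest plus CONSORT-style counts. Re-running with
#' the same seed reproduces the identical cohort.
#'
#' @param metadata registry metadata (see [read_metadata_csv()]).
#' @param seed matching seed.
#' @return A list with `cases`, `controls`, `unmatched`, `test_group_1`,
#'   `test_group_2`, `manifest` (record_id, patient_id, arm,
#'   matched_case_id) and `counts`.
#' @export
build_cohort <- function(metadata, seed = 1L) {
  cases <- select_cases(metadata)
  pool <- control_eligible(metadata, unique(cases$patient_id))
  m <- match_controls(cases, pool, seed = seed)
  cohort_ids <- c(cases$record_id, m$controls$record_id)
  tg <- build_test_groups(metadata, cohort_ids)
  manifest <- rbind(
    data.frame(record_id = cases$record_id, patient_id = cases$patient_id,
               arm = "case", matched_case_id = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(record_id = m$controls$record_id,
               patient_id = m$controls$patient_id,
               arm = "control", matched_case_id = m$controls$matched_case_id,
               stringsAsFactors = FALSE))
  counts <- c(case_patients = length(unique(cases$patient_id)),
              case_records = nrow(cases),
              control_records = nrow(m$controls),
              cohort_records = nrow(manifest),
              cohort_patients = length(unique(manifest$patient_id)),
              unmatched_cases = length(m$unmatched),
              test_group_1 = nrow(tg$test_group_1),
              test_group_2 = nrow(tg$test_group_2))
  list(cases = cases, controls = m$controls, unmatched = m$unmatched,
       test_group_1 = tg$test_group_1, test_group_2 = tg$test_group_2,
       manifest = manifest, counts = counts)
}
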