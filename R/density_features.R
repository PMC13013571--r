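# Attractor density features: normalised histograms of the projected point
# cloud over concentric annuli (r density) and angular wedges (theta
# density) about the projection origin — the image of any constant signal,
# which makes rotation of the theta profile meaningful across records.

density_profile <- function(kind, edges, densities) {
  structure(list(kind = kind, bin_count = length(densities),
                 bin_edges = edges, densities = densities),
            class = "density_profile")
}

#' Radial (annulus) density of an attractor
#'
#' Bin edges are uniform over \[0, max radius\] of this cloud (per-record
#' scaling removes residual amplitude dependence, or pass `r_max` for a
#' fixed global scale); bins are half-open \[low, high) with the maximal
#' point included in the top bin. Densities are counts divided by the total
#' point count, so they sum to 1.
#'
#' @param points two-column matrix of (u, v) coordinates, or an
#'   `attractor_projection`.
#' @param bins number of annuli (positive integer).
#' @param r_max optional fixed outer radius; defaults to the cloud maximum.
#' @return A `density_profile` with `kind = "radial"`.
#' @export
radial_density <- function(points, bins, r_max = NULL) {
  pts <- as_points(points)
  if (bins < 1 || bins != as.integer(bins))
    stop("bins must be a positive integer")
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  if (is.null(r_max)) r_max <- max(r)
  if (r_max <= 0) stop("zero-radius point cloud: no radial extent")
  idx <- pmin(floor(r / r_max * bins) + 1L, bins)
  density_profile("radial",
                  edges = seq(0, r_max, length.out = bins + 1L),
                  densities = tabulate(idx, nbins = bins) / length(r))
}

#' Angular (wedge) density of an attractor
#'
#' Angles theta = atan2(v, u) are mapped to \[0, 2 pi) and counted in
#' `bins` uniform wedges; points exactly at the origin fall in wedge 1.
#' Densities sum to 1.
#'
#' @inheritParams radial_density
#' @param bins number of wedges (positive integer).
#' @return A `density_profile` with `kind = "angular"`.
#' @export
angular_density <- function(points, bins) {
  pts <- as_points(points)
  if (bins < 1 || bins != as.integer(bins))
    stop("bins must be a positive integer")
  theta <- atan2(pts[, 2], pts[, 1]) %% (2 * pi)
  idx <- pmin(floor(theta / (2 * pi) * bins) + 1L, bins)
  density_profile("angular",
                  edges = seq(0, 2 * pi, length.out = bins + 1L),
                  densities = tabulate(idx, nbins = bins) / length(theta))
}

as_points <- function(points) {
  if (inherits(points, "attractor_projection")) points <- points$points
  if (!is.matrix(points) || ncol(points) != 2L)
    stop("points must be a two-column (u, v) matrix")
  if (nrow(points) < 1L) stop("empty point cloud")
  points
}

#' Attractor density feature vector for one record and lead
#'
#' Runs the full reconstruction for a single lead: R-peak detection, average
#' cycle length, min-max amplitude normalisation, delay embedding at
#' tau = round(L/N), symmetric projection k, then the requested density
#' profile(s). With `feature_kind = "both"` the theta block precedes the r
#' block. Preprocessing failures (too few beats, flat signal) propagate as
#' errors so the caller can exclude the record.
#'
#' @param record an [ecg_record()].
#' @param lead lead name to analyse.
#' @param N embedding dimension, 3--9.
#' @param k projection index.
#' @param theta_bins wedges for the theta density (default 60, the
#'   resolution used with KNN models; trees use 100).
#' @param r_bins annuli for the r density (default 20 for KNN; trees use 40).
#' @param feature_kind `"theta"`, `"r"` or `"both"`.
#' @param L_samples optional precomputed average cycle length in samples
#'   (e.g. from a reference lead); by default it is estimated from the
#'   analysed lead itself.
#' @return A named numeric feature vector (`theta_001`..., `r_001`...),
#'   with attributes `record_id` and `patient_id`.
#' @export
feature_vector <- function(record, lead, N = 3, k = 1,
                           theta_bins = 60, r_bins = 20,
                           feature_kind = c("theta", "r", "both"),
                           L_samples = NULL) {
  feature_kind <- match.arg(feature_kind)
  ch <- select_lead(record, lead)
  if (is.null(L_samples)) {
    peaks <- detect_r_peaks(ch$samples, ch$fs)
    L_samples <- average_cycle_length(peaks, ch$fs)$L_samples
  }
  x <- normalize_amplitude(ch$samples)
  tau <- embedding_delay(L_samples, N)
  att <- project_attractor(delay_embed(x, N, tau), k)
  out <- numeric(0)
  if (feature_kind %in% c("theta", "both")) {
    th <- angular_density(att, theta_bins)$densities
    names(th) <- sprintf("theta_%03d", seq_len(theta_bins))
    out <- c(out, th)
  }
  if (feature_kind %in% c("r", "both")) {
    rr <- radial_density(att, r_bins)$densities
    names(rr) <- sprintf("r_%03d", seq_len(r_bins))
    out <- c(out, rr)
  }
  attr(out, "record_id") <- record$record_id
  attr(out, "patient_id") <- record$patient_id
  out
}

#' Build a per-record feature table from labelled records
#'
#' Applies [feature_vector()] to every record and assembles the feature
#' table consumed by the cross-validation harness. Records on which
#' preprocessing fails are dropped with a warning naming them.
#'
#' @param records list of [ecg_record()] objects.
#' @param labels character vector (`"case"` / `"control"`), one per record.
#' @inheritParams feature_vector
#' @param downsample_factor integer decimation applied before analysis
#'   (4 converts 500 Hz records to 125 Hz).
#' @return A data.frame with columns `record_id`, `patient_id`, `label`,
#'   `age`, `sex`, then one column per feature; attribute `feature_names`
#'   lists the feature columns.
#' @export
build_feature_table <- function(records, labels, lead = "II", N = 3, k = 1,
                                theta_bins = 60, r_bins = 20,
                                feature_kind = "theta",
                                downsample_factor = 1) {
  stopifnot(length(records) == length(labels))
  rows <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- downsample(records[[i]], downsample_factor)
    fv <- tryCatch(
      feature_vector(rec, lead, N, k, theta_bins, r_bins, feature_kind),
      error = function(e) {
        warning("record ", rec$record_id, " excluded: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(fv)) next
    rows[[i]] <- data.frame(record_id = rec$record_id,
                            patient_id = rec$patient_id,
                            label = labels[[i]],
                            age = rec$age, sex = rec$sex,
                            t(as.numeric(fv)), stringsAsFactors = FALSE)
    names(rows[[i]])[-(1:5)] <- names(fv)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no record survived feature extraction")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  feature_table(tab)
}

#' Mark a data.frame as a feature table
#'
#' Validates the layout expected by the harness: metadata columns
#' `record_id`, `patient_id`, `label` (plus optional `age`, `sex`), all
#' remaining columns numeric features, record ids unique.
#'
#' @param df a data.frame.
#' @return The validated data.frame with class `feature_table` and
#'   attribute `feature_names`.
#' @export
feature_table <- function(df) {
  need <- c("record_id", "patient_id", "label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("feature table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$record_id)) stop("record_id values must be unique")
  if (any(is.na(df$patient_id) | !nzchar(df$patient_id)))
    stop("every row needs a patient_id")
  bad <- setdiff(unique(df$label), c("case", "control"))
  if (length(bad))
    stop("labels must be 'case'/'control'; found: ", paste(bad, collapse = ", "))
  feats <- setdiff(names(df), c(need, "age", "sex"))
  if (!length(feats)) stop("feature table has no feature columns")
  if (!all(vapply(df[feats], is.numeric, logical(1))))
    stop("feature columns must all be numeric")
  attr(df, "feature_names") <- feats
  class(df) <- unique(c("feature_table", class(df)))
  df
}

feature_matrix <- function(table) {
  as.matrix(table[, attr(table, "feature_names"), drop = FALSE])
}
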