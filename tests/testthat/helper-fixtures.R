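# Shared fixture builders. Everything is generated in code at test time;
# expensive objects are cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# tiny record with known samples, bypassing the generator
tiny_record <- function(samples = rbind(sin(seq(0, 20, length.out = 1000)),
                                        cos(seq(0, 20, length.out = 1000))),
                        leads = c("I", "II"), fs = 100,
                        record_id = "rec1", patient_id = "pat1") {
  ecg_record(record_id, patient_id, fs, leads, samples)
}

# two well-separated Gaussian blobs, one record per patient
toy_feature_table <- function(n_per_class = 5, separation = 10, sd = 0.5,
                              n_features = 3, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- matrix(stats::rnorm(n * n_features, sd = sd), n, n_features)
  X[seq_len(n_per_class), 1] <- X[seq_len(n_per_class), 1] + separation
  df <- data.frame(record_id = sprintf("r%02d", seq_len(n)),
                   patient_id = sprintf("p%02d", seq_len(n)),
                   label = rep(c("case", "control"), each = n_per_class),
                   age = sample(40:80, n, replace = TRUE),
                   sex = rep(c("male", "female"), length.out = n),
                   X, stringsAsFactors = FALSE)
  names(df)[-(1:5)] <- sprintf("f%02d", seq_len(n_features))
  feature_table(df)
}

# registries and feature tables used by several files (built once)
registry_at_strength <- function(strength, seed = 11) {
  cached(sprintf("registry_%s_%d", strength, seed), function() {
    generate_registry(40, 40, 1,
                      synthetic_ecg_params(seed = seed,
                                           class_effect = paf_class_effect(strength)))
  })
}

theta_table_at_strength <- function(strength, seed = 11) {
  cached(sprintf("theta_tab_%s_%d", strength, seed), function() {
    reg <- registry_at_strength(strength, seed)
    sr <- !grepl("_afib", names(reg$records))
    build_feature_table(reg$records[sr], reg$labels[sr],
                        lead = "II", downsample_factor = 4)
  })
}

# explicit-loop projection oracle: forms each delay vector and each dot
# product one element at a time
brute_force_projection <- function(signal, N, tau, k) {
  basis <- projection_basis(N, k)
  M <- length(signal) - (N - 1) * tau
  pts <- matrix(NA_real_, M, 2)
  for (t in seq_len(M)) {
    vec <- numeric(N)
    for (j in 0:(N - 1)) vec[j + 1] <- signal[t + j * tau]
    u <- 0; v <- 0
    for (j in seq_len(N)) {
      u <- u + vec[j] * basis$u[j]
      v <- v + vec[j] * basis$v[j]
    }
    pts[t, ] <- c(u, v)
  }
  pts
}

# nearest-neighbour loop excluding the held-out patient, independent of the
# harness implementation
brute_force_lopo_1nn <- function(table, metric = "euclidean") {
  X <- as.matrix(table[, attr(table, "feature_names")])
  preds <- character(nrow(table))
  for (i in seq_len(nrow(table))) {
    best <- Inf; best_j <- NA
    for (j in seq_len(nrow(table))) {
      if (table$patient_id[j] == table$patient_id[i]) next
      d <- switch(metric,
                  euclidean = sqrt(sum((X[i, ] - X[j, ])^2)),
                  cityblock = sum(abs(X[i, ] - X[j, ])),
                  chebychev = max(abs(X[i, ] - X[j, ])))
      if (d < best) { best <- d; best_j <- j }
    }
    preds[i] <- table$label[best_j]
  }
  preds
}
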