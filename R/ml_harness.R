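# Classification harness: leave-one-patient-out cross-validation of KNN and
# decision-tree models, Bayesian hyperparameter search over the published
# search space, demographic feature normalisation, stratified accuracy
# reporting and misclassification analysis. The positive class is "case"
# (the PAF arm) everywhere.

#' Model configuration
#'
#' Represents one point of the hyperparameter search space: a KNN model has
#' a categorical distance metric (ten choices) and an odd neighbour count
#' in 1..99; a decision tree has a minimum leaf size in 1..182 (Gini
#' splits, no depth limit, cp = 0 — leaf size is the only tuned parameter).
#'
#' @param model `"knn"` or `"tree"`.
#' @param knn_metric distance metric (see [pairwise_distances()]).
#' @param knn_neighbors odd integer 1..99.
#' @param tree_min_leaf integer 1..182.
#' @param seed integer seed recorded with the configuration.
#' @return A list of class `model_config`.
#' @export
model_config <- function(model = c("knn", "tree"), knn_metric = "euclidean",
                         knn_neighbors = 1, tree_min_leaf = 1, seed = 1L) {
  model <- match.arg(model)
  if (model == "knn") {
    knn_metric <- match.arg(knn_metric, KNN_METRICS)
    if (!knn_neighbors %in% seq(1, 99, by = 2))
      stop("knn_neighbors must be an odd integer in 1..99")
  } else {
    if (!tree_min_leaf %in% 1:182)
      stop("tree_min_leaf must be an integer in 1..182")
  }
  structure(list(model = model, knn_metric = knn_metric,
                 knn_neighbors = as.integer(knn_neighbors),
                 tree_min_leaf = as.integer(tree_min_leaf),
                 seed = as.integer(seed)),
            class = "model_config")
}

config_key <- function(config) {
  if (config$model == "knn")
    sprintf("knn/%s/%d", config$knn_metric, config$knn_neighbors)
  else
    sprintf("tree/%d", config$tree_min_leaf)
}

fit_predict <- function(train_x, train_y, test_x, config) {
  if (config$model == "knn") {
    knn_predict(train_x, train_y, test_x,
                k_neighbors = config$knn_neighbors,
                metric = config$knn_metric)
  } else {
    df <- data.frame(label = factor(train_y, levels = c("case", "control")),
                     train_x, check.names = FALSE)
    fit <- rpart::rpart(label ~ ., data = df, method = "class",
                        control = rpart::rpart.control(
                          minbucket = config$tree_min_leaf,
                          minsplit = 2L * config$tree_min_leaf,
                          cp = 0, xval = 0))
    as.character(predict(fit,
                         newdata = as.data.frame(test_x, check.names = FALSE),
                         type = "class"))
  }
}

#' Leave-one-patient-out cross-validation
#'
#' One fold per unique patient: every record of the held-out patient is
#' scored by a model trained on all other patients' records, so no training
#' row ever shares a patient with a scored row. Overall metrics come from
#' the pooled per-record predictions.
#'
#' @param table a [feature_table()] containing both labels and at least two
#'   patients.
#' @param config a [model_config()].
#' @return A list of class `cv_result`: `predictions` (data.frame with
#'   record_id, patient_id, truth, predicted), `confusion` (TP, FN, FP, TN
#'   with case = positive), `accuracy`, `sensitivity`, `specificity` and
#'   `TNR` (an alias of specificity).
#' @export
leave_one_patient_out_cv <- function(table, config) {
  table <- feature_table(as.data.frame(table))
  if (length(unique(table$label)) < 2L)
    stop("both labels must be present for cross-validation")
  patients <- unique(table$patient_id)
  if (length(patients) < 2L) stop("need at least 2 patients")
  X <- feature_matrix(table)
  preds <- character(nrow(table))
  for (p in patients) {
    test_i <- which(table$patient_id == p)
    train_i <- which(table$patient_id != p)
    preds[test_i] <- fit_predict(X[train_i, , drop = FALSE],
                                 table$label[train_i],
                                 X[test_i, , drop = FALSE], config)
  }
  cv_result(data.frame(record_id = table$record_id,
                       patient_id = table$patient_id,
                       truth = table$label, predicted = preds,
                       stringsAsFactors = FALSE))
}

cv_result <- function(predictions) {
  tp <- sum(predictions$truth == "case" & predictions$predicted == "case")
  fn <- sum(predictions$truth == "case" & predictions$predicted == "control")
  fp <- sum(predictions$truth == "control" & predictions$predicted == "case")
  tn <- sum(predictions$truth == "control" & predictions$predicted == "control")
  m <- confusion_metrics(tp, fn, fp, tn)
  structure(list(predictions = predictions,
                 confusion = c(TP = tp, FN = fn, FP = fp, TN = tn),
                 accuracy = m$accuracy, sensitivity = m$sensitivity,
                 specificity = m$specificity, TNR = m$specificity),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d records: TP %d FN %d FP %d TN %d\n",
              nrow(x$predictions), x$confusion["TP"], x$confusion["FN"],
              x$confusion["FP"], x$confusion["TN"]))
  cat(sprintf("  accuracy %.1f%%  sensitivity %s  specificity %s\n",
              100 * x$accuracy,
              ifelse(is.na(x$sensitivity), "NA",
                     sprintf("%.1f%%", 100 * x$sensitivity)),
              ifelse(is.na(x$specificity), "NA",
                     sprintf("%.1f%%", 100 * x$specificity))))
  invisible(x)
}

#' Metrics from a confusion matrix
#'
#' Accuracy = (TP+TN)/total, sensitivity = TP/(TP+FN), specificity (= TNR)
#' = TN/(TN+FP), with case as the positive class. A ratio with a zero
#' denominator is reported as `NA` (missing), never as zero.
#'
#' @param TP,FN,FP,TN nonnegative counts (total > 0).
#' @return A list with `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(TP, FN, FP, TN) {
  counts <- c(TP, FN, FP, TN)
  if (any(counts < 0)) stop("counts must be nonnegative")
  total <- sum(counts)
  if (total == 0) stop("confusion matrix is empty")
  list(accuracy = (TP + TN) / total,
       sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
       specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_)
}

knn_search_space <- function() {
  g <- expand.grid(knn_metric = KNN_METRICS,
                   knn_neighbors = seq(1L, 99L, by = 2L),
                   stringsAsFactors = FALSE)
  g[order(match(g$knn_metric, KNN_METRICS), g$knn_neighbors), , drop = FALSE]
}

tree_search_space <- function() data.frame(tree_min_leaf = 1:182)

space_config <- function(model, row, seed) {
  if (model == "knn")
    model_config("knn", knn_metric = row$knn_metric,
                 knn_neighbors = row$knn_neighbors, seed = seed)
  else
    model_config("tree", tree_min_leaf = row$tree_min_leaf, seed = seed)
}

# Expected improvement from a random-forest surrogate: predictive mean and
# spread taken across the individual trees.
rf_expected_improvement <- function(fit, candidates, best) {
  pred <- predict(fit, candidates, predict.all = TRUE)$individual
  mu <- rowMeans(pred)
  sd <- apply(pred, 1, stats::sd)
  z <- ifelse(sd > 0, (mu - best) / sd, 0)
  ei <- ifelse(sd > 0, (mu - best) * stats::pnorm(z) + sd * stats::dnorm(z),
               pmax(mu - best, 0))
  ei
}

#' Bayesian hyperparameter optimisation
#'
#' Sequential model-based search over the hyperparameter space of
#' [model_config()]: an initial seeded random design, then an
#' expected-improvement acquisition over the unvisited configurations using
#' a random-forest surrogate of leave-one-patient-out accuracy. The whole
#' run is deterministic given `seed`. For spaces small enough to enumerate,
#' `exhaustive = TRUE` evaluates every configuration instead.
#'
#' @param table a [feature_table()].
#' @param model `"knn"` or `"tree"`.
#' @param n_iterations total configurations to evaluate (>= 1).
#' @param seed integer seed for the search.
#' @param exhaustive evaluate the full space (ignores `n_iterations`).
#' @param space optional data.frame restricting the search space
#'   (columns as in the full space for `model`).
#' @return A list of class `bayes_opt_result`: `best_config`,
#'   `best_accuracy`, `optima` (all visited configurations achieving the
#'   best accuracy, in visit order) and `history` (data.frame of visited
#'   configurations and accuracies).
#' @export
bayesian_optimize <- function(table, model = c("knn", "tree"),
                              n_iterations = 30, seed = 1L,
                              exhaustive = FALSE, space = NULL) {
  model <- match.arg(model)
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (nrow(table) == 0L) stop("empty feature table")
  if (is.null(space))
    space <- if (model == "knn") knn_search_space() else tree_search_space()
  n_space <- nrow(space)
  evaluate <- function(i) {
    cfg <- space_config(model, space[i, , drop = FALSE], seed)
    leave_one_patient_out_cv(table, cfg)$accuracy
  }
  set.seed(seed)
  if (exhaustive || n_iterations >= n_space) {
    visited <- seq_len(n_space)
    acc <- vapply(visited, evaluate, numeric(1))
  } else {
    n0 <- min(max(2L, min(10L, n_iterations)), n_space)
    visited <- sample.int(n_space, n0)
    acc <- vapply(visited, evaluate, numeric(1))
    enc <- as.data.frame(lapply(space, function(col)
      if (is.character(col)) factor(col) else as.numeric(col)))
    while (length(visited) < n_iterations) {
      remaining <- setdiff(seq_len(n_space), visited)
      # few unique response values are expected early in the search;
      # randomForest warns about that, harmlessly
      fit <- suppressWarnings(randomForest::randomForest(
        x = enc[visited, , drop = FALSE], y = acc, ntree = 100))
      ei <- rf_expected_improvement(fit, enc[remaining, , drop = FALSE],
                                    max(acc))
      nxt <- remaining[which.max(ei)]
      visited <- c(visited, nxt)
      acc <- c(acc, evaluate(nxt))
    }
  }
  best <- max(acc)
  opt_idx <- visited[acc == best]
  optima <- lapply(opt_idx, function(i)
    space_config(model, space[i, , drop = FALSE], seed))
  history <- cbind(space[visited, , drop = FALSE], accuracy = acc)
  rownames(history) <- NULL
  structure(list(best_config = optima[[1]], best_accuracy = best,
                 optima = optima, history = history),
            class = "bayes_opt_result")
}

#' Consensus hyperparameters across lead/dimension/projection combinations
#'
#' When several configurations tie for the best accuracy within a
#' combination, the modal configuration across all combinations is taken;
#' if that mode is not among the optimal options of the queried
#' combination, the first entry of that combination's optimal list is used
#' instead.
#'
#' @param per_combination_optima list of entries, each a list with `lead`,
#'   `N`, `k` and `optima` (nonempty list of [model_config()]s).
#' @param query index of the combination the consensus is resolved for.
#' @return A [model_config()].
#' @export
select_consensus_hyperparameters <- function(per_combination_optima,
                                             query = 1L) {
  if (!length(per_combination_optima)) stop("empty optima list")
  all_keys <- unlist(lapply(per_combination_optima, function(e) {
    if (!length(e$optima)) stop("every combination needs a nonempty optima set")
    vapply(e$optima, config_key, "")
  }))
  counts <- table(factor(all_keys, levels = unique(all_keys)))
  mode_key <- names(counts)[which.max(counts)]
  entry <- per_combination_optima[[query]]
  keys <- vapply(entry$optima, config_key, "")
  if (mode_key %in% keys) entry$optima[[match(mode_key, keys)]]
  else entry$optima[[1]]
}

#' Demographic normalisation parameters
#'
#' Age is mapped affinely from the table's age range onto
#' \[Age1, Age1 + Age2\]; sex becomes a single numeric feature, Sex1 for
#' male and Sex2 for female. The defaults are the optimised values reported
#' for this feature scale (density features have small magnitudes, so the
#' demographic features are scaled to match rather than dominate).
#'
#' @param Age1 offset of the normalised age range.
#' @param Age2 width of the normalised age range.
#' @param Sex1 numeric code for male.
#' @param Sex2 numeric code for female.
#' @return A list of class `demographic_normalization`.
#' @export
demographic_normalization <- function(Age1 = 0.0103, Age2 = 0.9983,
                                      Sex1 = 0.0486, Sex2 = 0.0317) {
  structure(list(Age1 = Age1, Age2 = Age2, Sex1 = Sex1, Sex2 = Sex2),
            class = "demographic_normalization")
}

#' Append normalised demographic features to a feature table
#'
#' @param table a [feature_table()] whose rows all carry age and sex.
#' @param params a [demographic_normalization()].
#' @return The table with two extra feature columns `age_feature` and
#'   `sex_feature`.
#' @export
append_demographics <- function(table,
                                params = demographic_normalization()) {
  stopifnot(inherits(params, "demographic_normalization"))
  df <- as.data.frame(table)
  missing_rows <- df$record_id[is.na(df$age) | is.na(df$sex)]
  if (length(missing_rows))
    stop("missing demographics for record(s): ",
         paste(missing_rows, collapse = ", "))
  rng <- range(df$age)
  scaled <- if (rng[2] > rng[1]) (df$age - rng[1]) / (rng[2] - rng[1]) else 0
  df$age_feature <- params$Age1 + params$Age2 * scaled
  df$sex_feature <- ifelse(df$sex == "male", params$Sex1, params$Sex2)
  feature_table(df)
}

default_age_bands <- function() {
  list(breaks = c(-Inf, 50, 60, 70, 80, 90),
       labels = c("<50", "50-59", "60-69", "70-79", "80-89"))
}

#' Accuracy stratified by age band and sex
#'
#' Cross-tabulates per-record correctness over age bands and sexes,
#' including per-band, per-sex and overall margins. Count-weighted pooling
#' of the strata reproduces the overall accuracy exactly; empty strata are
#' reported with `n = 0` and missing accuracy.
#'
#' @param result a `cv_result` from [leave_one_patient_out_cv()].
#' @param table the [feature_table()] the result was computed from (source
#'   of age and sex).
#' @param age_bands list with `breaks` and `labels` as in the default:
#'   bands <50, 50--59, 60--69, 70--79, 80--89.
#' @return A data.frame with columns `age_band`, `sex`, `n`, `n_correct`,
#'   `accuracy`; margin rows use `"all"`.
#' @export
stratified_report <- function(result, table, age_bands = default_age_bands()) {
  df <- merge(result$predictions,
              as.data.frame(table)[, c("record_id", "age", "sex")],
              by = "record_id", sort = FALSE)
  if (anyNA(df$age) || anyNA(df$sex))
    stop("stratified_report needs age and sex for every record")
  df$correct <- df$truth == df$predicted
  df$band <- cut(df$age, breaks = age_bands$breaks,
                 labels = age_bands$labels, right = FALSE)
  bands <- c(age_bands$labels, "all")
  sexes <- c("male", "female", "all")
  out <- expand.grid(age_band = bands, sex = sexes,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stat <- function(sel) c(n = sum(sel), n_correct = sum(df$correct[sel]))
  cells <- t(apply(out, 1, function(row) {
    sel <- (row[["age_band"]] == "all" |
              (!is.na(df$band) & df$band == row[["age_band"]])) &
           (row[["sex"]] == "all" | df$sex == row[["sex"]])
    stat(sel)
  }))
  out$n <- as.integer(cells[, "n"])
  out$n_correct <- as.integer(cells[, "n_correct"])
  out$accuracy <- ifelse(out$n > 0, out$n_correct / out$n, NA_real_)
  out
}

#' Consistently misclassified records across configurations
#'
#' A record is flagged when it is predicted wrongly in at least
#' `ceiling(threshold * n)` of its n classifications (12 of 16 qualifies at
#' threshold 0.75). Flagged controls are tagged false positives, flagged
#' cases false negatives.
#'
#' @param predictions named list: record_id -> character vector of
#'   predicted labels across configurations.
#' @param truth named character vector: record_id -> true label.
#' @param threshold fraction in (0, 1].
#' @return A data.frame with `record_id`, `n_predictions`, `n_wrong`,
#'   `flagged` and `type` (`"false_positive"` / `"false_negative"` for
#'   flagged records, `NA` otherwise).
#' @export
misclassification_analysis <- function(predictions, truth, threshold = 0.75) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  ids <- names(predictions)
  if (is.null(ids) || anyNA(match(ids, names(truth))))
    stop("every prediction list entry needs a truth label")
  n_pred <- vapply(predictions, length, integer(1))
  if (any(n_pred < 1L)) stop("every record needs at least one prediction")
  n_wrong <- vapply(ids, function(id)
    sum(predictions[[id]] != truth[[id]]), integer(1))
  flagged <- n_wrong >= ceiling(threshold * n_pred)
  data.frame(record_id = ids, n_predictions = n_pred, n_wrong = n_wrong,
             flagged = flagged,
             type = ifelse(!flagged, NA_character_,
                           ifelse(truth[ids] == "control",
                                  "false_positive", "false_negative")),
             row.names = NULL, stringsAsFactors = FALSE)
}
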