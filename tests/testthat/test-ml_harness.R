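test_that("confusion metrics reproduce printed-table arithmetic", {
  m <- confusion_metrics(16, 7, 0, 23)
  expect_equal(m$accuracy, 39 / 46)
  expect_equal(round(100 * m$accuracy, 1), 84.8)
  f <- confusion_metrics(11, 9, 0, 20)
  expect_equal(f$accuracy, 31 / 40)
  expect_equal(round(100 * f$accuracy, 1), 77.5)
  deg <- confusion_metrics(0, 0, 0, 10)
  expect_equal(deg$accuracy, 1)
  expect_true(is.na(deg$sensitivity))
  expect_equal(deg$specificity, 1)
  expect_error(confusion_metrics(0, 0, 0, 0), "empty")
})

test_that("LOPO makes one fold per patient and scores every record", {
  df <- data.frame(record_id = sprintf("r%d", 1:5),
                   patient_id = c("a", "a", "b", "c", "c"),
                   label = c("case", "case", "control", "case", "control"),
                   f1 = c(5, 5.2, -5, 5.1, -4.5), f2 = rnorm(5),
                   stringsAsFactors = FALSE)
  cv <- leave_one_patient_out_cv(feature_table(df), model_config("knn"))
  expect_equal(nrow(cv$predictions), 5)
  expect_setequal(cv$predictions$record_id, df$record_id)
  expect_equal(sum(cv$confusion), 5)
})

test_that("perfectly separable blobs give accuracy 1 with 1-NN", {
  tab <- toy_feature_table(n_per_class = 6, separation = 20)
  cv <- leave_one_patient_out_cv(tab, model_config("knn", knn_neighbors = 1))
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$sensitivity, 1)
  expect_equal(cv$specificity, 1)
  # and a tree with leaf size 1 also separates them
  cvt <- leave_one_patient_out_cv(tab, model_config("tree", tree_min_leaf = 1))
  expect_equal(cvt$accuracy, 1)
})

test_that("LOPO predictions equal a hand-rolled nearest-neighbour loop", {
  set.seed(99)
  df <- data.frame(record_id = sprintf("r%d", 1:8),
                   patient_id = c("a", "a", "b", "c", "d", "d", "e", "f"),
                   label = sample(c("case", "control"), 8, replace = TRUE,
                                  prob = c(0.5, 0.5)),
                   f1 = rnorm(8), f2 = rnorm(8), f3 = rnorm(8),
                   stringsAsFactors = FALSE)
  df$label[1:2] <- "case"; df$label[3] <- "control"  # both classes present
  tab <- feature_table(df)
  for (metric in c("euclidean", "cityblock", "chebychev")) {
    cv <- leave_one_patient_out_cv(
      tab, model_config("knn", knn_metric = metric, knn_neighbors = 1))
    expect_equal(cv$predictions$predicted, brute_force_lopo_1nn(tab, metric),
                 info = metric)
  }
})

test_that("no training row ever shares a patient with a scored row", {
  # each patient has two identical records; the nearest *other* patient
  # always carries the opposite label, so patient-leakage would score 100%
  # and a correct LOPO split must score 0%
  base <- seq(0, 35, by = 5)
  df <- data.frame(record_id = sprintf("r%d", 1:16),
                   patient_id = rep(sprintf("p%d", 1:8), each = 2),
                   label = rep(rep(c("case", "control"), 4), each = 2),
                   f1 = rep(base, each = 2),
                   stringsAsFactors = FALSE)
  cv <- leave_one_patient_out_cv(feature_table(df),
                                 model_config("knn", knn_neighbors = 1))
  expect_equal(cv$accuracy, 0)
})

test_that("all ten KNN metrics produce valid predictions", {
  tab <- toy_feature_table(n_per_class = 5, separation = 8, n_features = 4)
  for (metric in c("cityblock", "chebychev", "correlation", "cosine",
                   "euclidean", "hamming", "jaccard", "minkowski",
                   "seuclidean", "spearman")) {
    cv <- leave_one_patient_out_cv(
      tab, model_config("knn", knn_metric = metric, knn_neighbors = 3))
    expect_true(all(cv$predictions$predicted %in% c("case", "control")),
                info = metric)
  }
})

test_that("balanced tables satisfy accuracy == (sens + spec)/2", {
  for (seed in c(1, 7, 31)) {
    tab <- toy_feature_table(n_per_class = 8, separation = 1.5, sd = 1,
                             seed = seed)
    cv <- leave_one_patient_out_cv(tab,
                                   model_config("knn", knn_neighbors = 3))
    expect_equal(cv$accuracy, (cv$sensitivity + cv$specificity) / 2)
  }
})

test_that("search over a restricted space matches exhaustive evaluation", {
  tab <- toy_feature_table(n_per_class = 6, separation = 2, sd = 2, seed = 3)
  space <- data.frame(knn_metric = c("euclidean", "chebychev"),
                      knn_neighbors = c(1L, 5L), stringsAsFactors = FALSE)
  accs <- vapply(1:2, function(i) {
    cfg <- model_config("knn", knn_metric = space$knn_metric[i],
                        knn_neighbors = space$knn_neighbors[i])
    leave_one_patient_out_cv(tab, cfg)$accuracy
  }, numeric(1))
  bo <- bayesian_optimize(tab, "knn", seed = 4, exhaustive = TRUE,
                          space = space)
  expect_equal(bo$best_accuracy, max(accs))
  expect_equal(bo$best_config$knn_metric,
               space$knn_metric[which.max(accs)])
})

test_that("optimisation is deterministic and finds a separating config", {
  tab <- toy_feature_table(n_per_class = 5, separation = 15)
  b1 <- bayesian_optimize(tab, "tree", n_iterations = 12, seed = 21)
  b2 <- bayesian_optimize(tab, "tree", n_iterations = 12, seed = 21)
  expect_identical(b1$history, b2$history)
  expect_identical(b1$best_config, b2$best_config)
  expect_equal(b1$best_accuracy, 1)
  bknn <- bayesian_optimize(tab, "knn", n_iterations = 15, seed = 22)
  expect_equal(bknn$best_accuracy, 1)
})

test_that("consensus hyperparameters follow the mode-then-first rule", {
  A <- model_config("knn", knn_metric = "euclidean", knn_neighbors = 3)
  B <- model_config("knn", knn_metric = "cosine", knn_neighbors = 7)
  C <- model_config("tree", tree_min_leaf = 4)
  combos <- function(...) lapply(list(...), function(o)
    list(lead = "II", N = 3, k = 1, optima = o))
  expect_identical(
    select_consensus_hyperparameters(combos(list(A), list(A), list(A, B)),
                                     query = 3), A)
  expect_identical(
    select_consensus_hyperparameters(combos(list(A), list(A), list(B)),
                                     query = 3), B)
  expect_identical(select_consensus_hyperparameters(combos(list(C))), C)
})

test_that("demographic features map onto the documented ranges", {
  tab <- toy_feature_table(n_per_class = 5)
  out <- append_demographics(tab)   # optimised defaults
  expect_equal(min(out$age_feature[out$age == min(out$age)]), 0.0103)
  expect_equal(max(out$age_feature), 0.0103 + 0.9983 *
                 (max(tab$age) - min(tab$age)) / (max(tab$age) - min(tab$age)))
  expect_equal(unique(out$sex_feature[out$sex == "male"]), 0.0486)
  expect_equal(unique(out$sex_feature[out$sex == "female"]), 0.0317)
  plain <- append_demographics(tab, demographic_normalization(0, 1, 1, 0))
  expect_equal(plain$age_feature,
               (tab$age - min(tab$age)) / (max(tab$age) - min(tab$age)))
  expect_true("age_feature" %in% attr(out, "feature_names"))
  tab$age[2] <- NA
  expect_error(append_demographics(feature_table(as.data.frame(tab))),
               tab$record_id[2])
})

test_that("stratified accuracies pool exactly to the overall accuracy", {
  tab <- toy_feature_table(n_per_class = 12, separation = 1.2, sd = 1,
                           seed = 5)
  cv <- leave_one_patient_out_cv(tab, model_config("knn", knn_neighbors = 3))
  rep <- stratified_report(cv, tab)
  overall <- rep[rep$age_band == "all" & rep$sex == "all", ]
  expect_equal(overall$accuracy, cv$accuracy)
  bands <- rep[rep$age_band != "all" & rep$sex == "all" & rep$n > 0, ]
  expect_equal(sum(bands$accuracy * bands$n) / sum(bands$n), cv$accuracy)
  sexes <- rep[rep$age_band == "all" & rep$sex != "all", ]
  expect_equal(sum(sexes$n_correct), overall$n_correct)
  # recount oracle: per-stratum accuracy equals a direct recount
  merged <- merge(cv$predictions, as.data.frame(tab)[, c("record_id", "age", "sex")])
  sel <- merged$sex == "male" & merged$age >= 60 & merged$age < 70
  cell <- rep[rep$age_band == "60-69" & rep$sex == "male", ]
  expect_equal(cell$n, sum(sel))
  if (cell$n > 0)
    expect_equal(cell$accuracy,
                 mean(merged$truth[sel] == merged$predicted[sel]))
})

test_that("misclassification flags at the 12-of-16 boundary", {
  mk <- function(n_wrong, truth) {
    wrong <- if (truth == "case") "control" else "case"
    c(rep(wrong, n_wrong), rep(truth, 16 - n_wrong))
  }
  preds <- list(a = mk(12, "case"), b = mk(11, "case"), c = mk(16, "control"))
  truth <- c(a = "case", b = "case", c = "control")
  out <- misclassification_analysis(preds, truth, threshold = 0.75)
  expect_true(out$flagged[out$record_id == "a"])
  expect_false(out$flagged[out$record_id == "b"])
  expect_equal(out$type[out$record_id == "a"], "false_negative")
  expect_equal(out$type[out$record_id == "c"], "false_positive")
  expect_error(misclassification_analysis(preds, truth, 0), "threshold")
})
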