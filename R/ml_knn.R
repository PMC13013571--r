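# K-nearest-neighbour classification over the ten distance metrics of the
# hyperparameter search space. Metrics needing extra parameters default to
# exponent 3 (minkowski) and per-feature training-set standard deviation
# (seuclidean); zero-variance features are dropped from seuclidean rather
# than producing infinite weights.

KNN_METRICS <- c("cityblock", "chebychev", "correlation", "cosine",
                 "euclidean", "hamming", "jaccard", "minkowski",
                 "seuclidean", "spearman")

row_rank <- function(X) t(apply(X, 1, rank))

#' Distances from query rows to reference rows
#'
#' @param X reference matrix (rows = observations).
#' @param Y query matrix with the same columns.
#' @param metric one of cityblock, chebychev, correlation, cosine,
#'   euclidean, hamming, jaccard, minkowski, seuclidean, spearman.
#' @param minkowski_p exponent for the minkowski metric.
#' @param seuclidean_scale per-feature scale for seuclidean; defaults to the
#'   per-feature standard deviation of `X`.
#' @return A `nrow(Y)` x `nrow(X)` matrix of distances.
#' @export
pairwise_distances <- function(X, Y, metric = "euclidean", minkowski_p = 3,
                               seuclidean_scale = NULL) {
  metric <- match.arg(metric, KNN_METRICS)
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(ncol(X) == ncol(Y))
  if (metric == "seuclidean") {
    s <- if (is.null(seuclidean_scale)) apply(X, 2, stats::sd) else seuclidean_scale
    keep <- s > 0
    if (!any(keep)) stop("seuclidean: all features have zero variance")
    X <- sweep(X[, keep, drop = FALSE], 2, s[keep], "/")
    Y <- sweep(Y[, keep, drop = FALSE], 2, s[keep], "/")
    metric <- "euclidean"
  }
  if (metric == "spearman") {
    X <- row_rank(X); Y <- row_rank(Y)
    metric <- "correlation"
  }
  n <- nrow(X); m <- nrow(Y)
  D <- matrix(0, m, n)
  if (metric == "correlation") {
    Xc <- X - rowMeans(X); Yc <- Y - rowMeans(Y)
    nx <- sqrt(rowSums(Xc^2)); ny <- sqrt(rowSums(Yc^2))
    num <- tcrossprod(Yc, Xc)
    den <- outer(ny, nx)
    C <- ifelse(den > 0, num / den, 0)
    D <- 1 - C
  } else if (metric == "cosine") {
    nx <- sqrt(rowSums(X^2)); ny <- sqrt(rowSums(Y^2))
    num <- tcrossprod(Y, X)
    den <- outer(ny, nx)
    D <- 1 - ifelse(den > 0, num / den, 0)
  } else {
    for (i in seq_len(m)) {
      d <- abs(sweep(X, 2, Y[i, ]))    # |x_j - y| per reference row
      D[i, ] <- switch(metric,
        cityblock = rowSums(d),
        chebychev = apply(d, 1, max),
        euclidean = sqrt(rowSums(d^2)),
        minkowski = rowSums(d^minkowski_p)^(1 / minkowski_p),
        hamming   = rowMeans(d != 0),
        jaccard   = {
          nz <- sweep(X != 0, 2, Y[i, ] != 0, "|")
          denom <- rowSums(nz)
          ifelse(denom > 0, rowSums(d != 0 & nz) / denom, 0)
        })
    }
  }
  D
}

#' KNN prediction with patient-aware training data
#'
#' Majority vote over the `k_neighbors` nearest training rows; neighbour
#' ties are resolved by training-row order (stable sort) and vote ties are
#' broken toward `"control"` (the lower-false-positive preference; only
#' reachable through distance degeneracy since `k_neighbors` is odd).
#'
#' @param train_x,train_y training features and labels.
#' @param test_x query features.
#' @param k_neighbors odd neighbour count.
#' @param metric distance metric name.
#' @param minkowski_p minkowski exponent.
#' @param tie_break label returned on a split vote.
#' @return Character vector of predicted labels.
#' @export
knn_predict <- function(train_x, train_y, test_x, k_neighbors = 1,
                        metric = "euclidean", minkowski_p = 3,
                        tie_break = "control") {
  k <- min(k_neighbors, nrow(train_x))
  D <- pairwise_distances(train_x, test_x, metric, minkowski_p)
  apply(D, 1, function(drow) {
    nb <- train_y[order(drow)[seq_len(k)]]
    tab <- table(nb)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L && tie_break %in% top) tie_break else top[[1]]
  })
}
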