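# Symmetric projection attractor reconstruction: Takens delay embedding of
# a single channel, followed by a harmonic 2D projection orthogonal to the
# (1,...,1) diagonal, which cancels constant baseline offsets exactly.

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Embedding delay from the average cycle length
#'
#' The N delay coordinates are spaced L/N apart (one third of a cycle for
#' the classical N = 3 embedding), rounded half-away-from-zero to the
#' nearest sample with a floor of 1.
#'
#' @param L_samples average cycle length in samples (positive).
#' @param N embedding dimension, 3--9.
#' @return Integer delay tau in samples.
#' @export
embedding_delay <- function(L_samples, N) {
  check_dimension(N)
  if (L_samples < N)
    stop("cycle too short for dimension: L = ", L_samples, " < N = ", N)
  max(1L, as.integer(round_half_away(L_samples / N)))
}

check_dimension <- function(N) {
  if (length(N) != 1L || is.na(N) || N != as.integer(N) || N < 3 || N > 9)
    stop("embedding dimension N must be an integer in 3..9")
  invisible(as.integer(N))
}

#' Valid projection indices for a dimension
#'
#' @param N embedding dimension, 3--9.
#' @return Integer vector `1:floor((N-1)/2)`. Across N = 3..9 the (N, k)
#'   pairs number 16 in total.
#' @export
valid_projections <- function(N) {
  check_dimension(N)
  seq_len((N - 1) %/% 2)
}

#' Takens delay embedding
#'
#' Row t of the embedding is (x(t), x(t + tau), ..., x(t + (N-1) tau));
#' every entry is an exact copy of a signal sample (no interpolation), and
#' all M = length - (N-1) tau rows are kept.
#'
#' @param signal numeric vector.
#' @param N embedding dimension, 3--9.
#' @param tau delay in samples (positive integer).
#' @return A list of class `delay_embedding` with `vectors` (M x N matrix),
#'   `N` and `tau`.
#' @export
delay_embed <- function(signal, N, tau) {
  N <- check_dimension(N)
  if (tau < 1 || tau != as.integer(tau)) stop("tau must be a positive integer")
  tau <- as.integer(tau)
  M <- length(signal) - (N - 1L) * tau
  if (M < 1L)
    stop("signal too short: need length > (N-1)*tau = ", (N - 1L) * tau)
  vectors <- vapply(0:(N - 1L),
                    function(j) signal[(1L + j * tau):(M + j * tau)],
                    numeric(M))
  if (M == 1L) vectors <- matrix(vectors, nrow = 1L)
  structure(list(vectors = vectors, N = N, tau = tau),
            class = "delay_embedding")
}

#' Orthonormal harmonic projection basis
#'
#' The k-th symmetric projection of an N-dimensional embedding is spanned by
#' u_j = sqrt(2/N) cos(2 pi k j / N) and v_j = sqrt(2/N) sin(2 pi k j / N),
#' j = 0..N-1. Both vectors are orthonormal and exactly orthogonal to
#' (1,...,1), so constant offsets of the signal project to the origin.
#'
#' @param N embedding dimension, 3--9.
#' @param k projection index, `1 <= k <= floor((N-1)/2)`.
#' @return A list with unit-norm weight vectors `u` and `v` of length N.
#' @export
projection_basis <- function(N, k) {
  N <- check_dimension(N)
  if (!k %in% valid_projections(N))
    stop("invalid projection k = ", k, " for N = ", N,
         "; valid: ", paste(valid_projections(N), collapse = ", "))
  j <- 0:(N - 1)
  ang <- 2 * pi * k * j / N
  list(u = sqrt(2 / N) * cos(ang), v = sqrt(2 / N) * sin(ang))
}

#' Project a delay embedding to a 2D attractor
#'
#' @param embedding a [delay_embed()] result.
#' @param k projection index, `1 <= k <= floor((N-1)/2)`.
#' @return A list of class `attractor_projection` with `points` (M x 2
#'   matrix of (u, v) coordinates), `N` and `k`.
#' @export
project_attractor <- function(embedding, k) {
  stopifnot(inherits(embedding, "delay_embedding"))
  basis <- projection_basis(embedding$N, k)
  pts <- embedding$vectors %*% cbind(u = basis$u, v = basis$v)
  structure(list(points = pts, N = embedding$N, k = as.integer(k)),
            class = "attractor_projection")
}
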