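#' Delay-coordinate embedding of a scalar time series
#'
#' Reconstructs an attractor from a single observed variable by lagged
#' coordinates: point `k` of the reconstruction is
#' `(x[k], x[k + lag], ..., x[k + (dim - 1) * lag])`. By Takens' theorem the
#' reconstruction is topologically equivalent to the attractor of the full
#' (unobserved) system, which is what licenses comparing reconstructions
#' built from different variables of the same system.
#'
#' For series of ~10 samples the default `dim = 2`, `lag = 1` keeps the
#' number of reconstructed points as large as possible; the TEP score needs
#' at least three of them.
#'
#' @param x Numeric vector, the scalar series (length `T >= (dim-1)*lag + 3`).
#' @param dim Embedding dimension `E` (positive integer).
#' @param lag Delay `tau` in sample steps (positive integer).
#' @param standardize If `TRUE`, z-score the series (mean 0, sd 1) before
#'   embedding. Off by default; recommended when comparing variables whose
#'   measurement scales differ (e.g. expression of different genes).
#' @param name Optional identifier carried along for labelling.
#'
#' @return A `tep_embedding`: a numeric matrix with one reconstructed point
#'   per row (`T - (dim-1)*lag` rows, `dim` columns) and attributes
#'   `source_name`, `dim`, `lag`, `standardize`.
#'
#' @examples
#' delay_embed(c(1, 2, 3, 4, 5), dim = 2, lag = 1)
#' @export
delay_embed <- function(x, dim = 2, lag = 1, standardize = FALSE, name = NULL) {
  if (!is.numeric(x)) abort("`x` must be a numeric vector.")
  if (anyNA(x) || any(!is.finite(x))) {
    abort("`x` contains missing or non-finite values; the score is undefined on them.")
  }
  dim <- check_count(dim, "dim")
  lag <- check_count(lag, "lag")
  t_len <- length(x)
  t_min <- (dim - 1L) * lag + 3L
  if (t_len < t_min) {
    abort(sprintf(
      "insufficient points: series of length %d cannot be embedded with dim = %d, lag = %d (need at least %d).",
      t_len, dim, lag, t_min
    ))
  }
  if (isTRUE(standardize)) {
    s <- sd(x)
    if (s == 0) abort("constant series: cannot standardize a zero-variance series.")
    x <- (x - mean(x)) / s
  }
  n <- t_len - (dim - 1L) * lag
  pts <- vapply(seq_len(dim) - 1L, function(k) x[seq_len(n) + k * lag], numeric(n))
  pts <- matrix(pts, nrow = n, ncol = dim)
  structure(
    pts,
    source_name = name,
    embedding_dim = dim,
    lag = lag,
    standardize = isTRUE(standardize),
    class = c("tep_embedding", "matrix", "array")
  )
}

#' @export
print.tep_embedding <- function(x, ...) {
  nm <- attr(x, "source_name")
  cat(sprintf(
    "<tep_embedding%s: %d points in %d dimensions (lag %d%s)>\n",
    if (is.null(nm)) "" else paste0(" of ", nm),
    nrow(x), attr(x, "embedding_dim"), attr(x, "lag"),
    if (attr(x, "standardize")) ", standardized" else ""
  ))
  print(unclass(head(x, 6)))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Euclidean distance matrix of a reconstructed attractor
#'
#' All inter-point Euclidean distances of an embedding: the raw material of
#' the TEP score, in which causal prediction is judged by whether the two
#' reconstructions' distance matrices agree up to one common scale.
#'
#' @param embedding A `tep_embedding` (or plain matrix of points in rows)
#'   with at least 3 points.
#' @return A symmetric `n x n` numeric matrix with zero diagonal.
#' @examples
#' pairwise_distances(delay_embed(c(0, 3, 4, 0), dim = 2))
#' @export
pairwise_distances <- function(embedding) {
  if (nrow(embedding) < 3) {
    abort("insufficient points: need at least 3 embedded points for distance comparison.")
  }
  as.matrix(dist(unclass(embedding), method = "euclidean"))
}

check_count <- function(x, what) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 1 || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single positive integer.", what))
  }
  as.integer(x)
}
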