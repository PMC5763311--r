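#' Scale ratio and TEP relative errors of two distance matrices
#'
#' Given the inter-point distance matrices `d` (reconstruction of the
#' predictor/effect variable) and `D` (reconstruction of the predicted/cause
#' variable), computes the similarity scale `gamma = d[1,2] / D[1,2]` from a
#' reference pair of points and the relative prediction errors
#' `eps[i,j] = |d[i,j] - gamma * D[i,j]| / (gamma * D[i,j])` for all
#' `i = 3..n`, `j < i`. If the two reconstructions were exactly similar
#' figures -- the ideal of topologically equivalent positions -- every error
#' would be zero.
#'
#' @param d,D Symmetric `n x n` distance matrices (`n >= 3`) from
#'   [pairwise_distances()]; `d` belongs to the predictor attractor, `D` to
#'   the predicted one.
#' @param reference_pair `"first"` (default): the scale is set by the first
#'   two points in temporal order. `"farthest"`: use the pair with maximal
#'   `D` distance, a more robust alternative when the first two points are
#'   close.
#' @param skip_degenerate If `TRUE`, pairs with `D[i,j] == 0` (coincident
#'   points on the predicted attractor) are skipped and the score averages
#'   renormalize over the remaining pairs; if `FALSE` (default) they raise an
#'   error so data problems surface.
#'
#' @return A list with `gamma` (positive scalar) and `rel_errors`, an
#'   `n x n` matrix filled for rows `i >= 3`, columns `j < i` (NA elsewhere).
#' @examples
#' e <- delay_embed(c(0.4, 0.91, 0.3, 0.79, 0.62), dim = 2)
#' tep_relative_errors(pairwise_distances(e), pairwise_distances(e))$gamma
#' @export
tep_relative_errors <- function(d, D,
                                reference_pair = c("first", "farthest"),
                                skip_degenerate = FALSE) {
  reference_pair <- match.arg(reference_pair)
  n <- nrow(d)
  if (!is.matrix(d) || !is.matrix(D) || any(dim(d) != dim(D)) || n != ncol(d)) {
    abort("`d` and `D` must be square matrices of equal size.")
  }
  if (n < 3) abort("insufficient points: need n >= 3 for relative errors.")

  if (reference_pair == "first") {
    ref <- c(1L, 2L)
  } else {
    ref <- which(D == max(D), arr.ind = TRUE)[1, , drop = TRUE]
  }
  d_ref <- d[ref[1], ref[2]]
  D_ref <- D[ref[1], ref[2]]
  if (d_ref == 0 || D_ref == 0) {
    abort(sprintf(
      "degenerate reference pair: zero distance between points %d and %d (d = %g, D = %g).",
      ref[1], ref[2], d_ref, D_ref
    ))
  }
  gamma <- d_ref / D_ref

  rel <- matrix(NA_real_, n, n)
  low <- lower.tri(rel) & row(rel) >= 3
  bad <- low & D == 0
  if (any(bad)) {
    if (!skip_degenerate) {
      ij <- which(bad, arr.ind = TRUE)[1, , drop = TRUE]
      abort(sprintf(
        "coincident points on target attractor: D[%d,%d] = 0 (use `skip_degenerate` to drop such pairs).",
        ij[1], ij[2]
      ))
    }
    low <- low & !bad
  }
  rel[low] <- abs(d[low] - gamma * D[low]) / (gamma * D[low])
  list(gamma = gamma, rel_errors = rel)
}

#' TEP score from a matrix of relative errors
#'
#' Collapses the relative errors into one bounded score:
#' `score = 1/(n-1) * sum_{i=3}^{n} mean_{j<i} exp(-eps[i,j])`.
#' Each error is passed through `exp(-eps)` so the score lies in (0, 1];
#' because the outer sum has `n - 2` terms but is divided by `n - 1`, the
#' attainable maximum is `(n - 2)/(n - 1)`, reached exactly when all errors
#' vanish. Larger score = smaller prediction errors = stronger evidence that
#' the predicted variable causes the predictor variable.
#'
#' @param rel_errors `n x n` matrix as returned by [tep_relative_errors()]
#'   (entries for `i >= 3`, `j < i`; NAs elsewhere and for skipped pairs).
#' @param n Number of embedded points used for error estimation.
#' @return A single numeric score in `(0, (n-2)/(n-1)]`.
#' @examples
#' tep_score(matrix(c(NA, NA, 0, NA, NA, 0, NA, NA, NA), 3, 3, byrow = TRUE), n = 3)
#' @export
tep_score <- function(rel_errors, n) {
  n <- check_count(n, "n")
  if (n < 3) abort("insufficient points: the score needs n >= 3.")
  if (nrow(rel_errors) < n || ncol(rel_errors) < n) {
    abort("`rel_errors` is smaller than `n`.")
  }
  total <- 0
  for (i in 3:n) {
    row_i <- rel_errors[i, seq_len(i - 1)]
    if (all(is.na(row_i))) {
      abort(sprintf("all error terms for point %d are missing; cannot renormalize.", i))
    }
    total <- total + mean(exp(-row_i), na.rm = TRUE)
  }
  total / (n - 1)
}

#' Directed TEP causality score for one ordered pair of series
#'
#' Scores the directed claim "`y` causes `x`". Under prediction-based
#' causality the effect's history carries an imprint of the cause, so the
#' claim is tested by using the reconstruction of `x` (the predictor) to
#' predict the points of the reconstruction of `y`: `d` is the distance
#' matrix of `x`'s embedding, `D` that of `y`'s, and the score aggregates
#' the relative errors `|d - gamma D| / (gamma D)`. The measure is
#' asymmetric: `causal_score(x, y)` and `causal_score(y, x)` differ in
#' general, which is what makes it directional.
#'
#' @param x Numeric vector: the putative effect (its embedding is the
#'   predictor attractor).
#' @param y Numeric vector of the same length: the putative cause.
#' @inheritParams delay_embed
#' @inheritParams tep_relative_errors
#'
#' @return A `tep_result` with elements `score`, `gamma`, `rel_errors`,
#'   `n` (embedded points used), `n_time` (raw time points) and `config`.
#'   `tidy()` returns the per-pair errors, `glance()` a one-row summary.
#'
#' @examples
#' sim <- simulate_logistic_uni(10)
#' causal_score(sim$X, sim$Y)$score # "Y causes X": true influence
#' causal_score(sim$Y, sim$X)$score # "X causes Y": absent influence
#' @export
causal_score <- function(x, y, dim = 2, lag = 1, standardize = FALSE,
                         reference_pair = c("first", "farthest"),
                         skip_degenerate = FALSE) {
  if (length(x) != length(y)) abort("`x` and `y` must have the same length.")
  reference_pair <- match.arg(reference_pair)
  mx <- delay_embed(x, dim = dim, lag = lag, standardize = standardize)
  my <- delay_embed(y, dim = dim, lag = lag, standardize = standardize)
  score_embeddings(mx, my,
    n_time = length(x), dim = dim, lag = lag, standardize = standardize,
    reference_pair = reference_pair, skip_degenerate = skip_degenerate
  )
}

score_embeddings <- function(mx, my, n_time, dim, lag, standardize,
                             reference_pair, skip_degenerate) {
  re <- tep_relative_errors(
    pairwise_distances(mx), pairwise_distances(my),
    reference_pair = reference_pair, skip_degenerate = skip_degenerate
  )
  n <- nrow(mx)
  structure(
    list(
      score = tep_score(re$rel_errors, n),
      gamma = re$gamma,
      rel_errors = re$rel_errors,
      n = n,
      n_time = n_time,
      config = list(
        dim = dim, lag = lag, standardize = standardize,
        reference_pair = reference_pair, skip_degenerate = skip_degenerate
      )
    ),
    class = "tep_result"
  )
}

#' @export
print.tep_result <- function(x, ...) {
  cat(sprintf(
    "<tep_result: score %.6f (max %.6f), gamma %.6f, n = %d embedded points>\n",
    x$score, (x$n - 2) / (x$n - 1), x$gamma, x$n
  ))
  invisible(x)
}

#' @rdname causal_score
#' @param x_result A `tep_result`.
#' @param ... Unused.
#' @export
tidy.tep_result <- function(x, ...) {
  rel <- x$rel_errors
  idx <- which(!is.na(rel), arr.ind = TRUE)
  tibble::tibble(
    i = as.integer(idx[, 1]),
    j = as.integer(idx[, 2]),
    rel_error = rel[idx]
  ) |>
    dplyr::arrange(.data$i, .data$j)
}

#' @rdname causal_score
#' @export
glance.tep_result <- function(x, ...) {
  tibble::tibble(
    score = x$score,
    score_max = (x$n - 2) / (x$n - 1),
    gamma = x$gamma,
    n = x$n,
    n_time = x$n_time
  )
}

#' Leave-one-out TEP scores
#'
#' Diagnostic for the stability of [causal_score()] on very short series:
#' each embedded point is deleted in turn from both reconstructions and the
#' score recomputed on the remaining `n - 1` points. A score that collapses
#' when one point is removed is being carried by that point.
#'
#' @inheritParams causal_score
#' @return A tibble with one row per left-out point index (`left_out`,
#'   `score`); the headline full-data statistic remains [causal_score()],
#'   and `mean(loo_scores(...)$score)` gives the leave-one-out average.
#' @examples
#' sim <- simulate_logistic(8)
#' loo <- loo_scores(sim$X, sim$Y)
#' mean(loo$score)
#' @export
loo_scores <- function(x, y, dim = 2, lag = 1, standardize = FALSE,
                       reference_pair = c("first", "farthest"),
                       skip_degenerate = FALSE) {
  if (length(x) != length(y)) abort("`x` and `y` must have the same length.")
  reference_pair <- match.arg(reference_pair)
  mx <- delay_embed(x, dim = dim, lag = lag, standardize = standardize)
  my <- delay_embed(y, dim = dim, lag = lag, standardize = standardize)
  n <- nrow(mx)
  if (n < 4) abort("insufficient points: leave-one-out needs at least 4 embedded points.")
  scores <- vapply(seq_len(n), function(k) {
    score_embeddings(
      mx[-k, , drop = FALSE], my[-k, , drop = FALSE],
      n_time = length(x), dim = dim, lag = lag, standardize = standardize,
      reference_pair = reference_pair, skip_degenerate = skip_degenerate
    )$score
  }, numeric(1))
  tibble::tibble(left_out = seq_len(n), score = scores)
}
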