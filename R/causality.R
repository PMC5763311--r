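#' All-pairs directed TEP causality matrix
#'
#' Scores every ordered pair of variables in a multivariate time-series
#' table: entry (row A, column B) is the TEP score for the claim
#' "A causes B" (rows cause columns). For `G` variables this yields
#' `G * (G - 1)` directed scores; the diagonal is undefined. Each variable
#' is embedded once and all pairwise distance matrices are reused across
#' pairs, so the all-pairs sweep costs little more than the embeddings.
#'
#' @param data The observed series: a data frame / tibble with one row per
#'   time point and one numeric column per variable (an optional `time`
#'   column is ignored for scoring), or a numeric matrix with variables in
#'   columns. At least 2 variables and enough time points to embed.
#' @inheritParams causal_score
#'
#' @return A `tep_cm`: list with `names` (variable identifiers), `scores`
#'   (`G x G` matrix, `NA` diagonal, rows cause columns), `n`, `n_time`, and
#'   `config`. Pairs whose score is undefined (degenerate geometry) are `NA`
#'   with one summarizing warning. `tidy()` returns a tibble of
#'   `(from, to, score)`; `glance()` a one-row summary; `autoplot()` a
#'   heatmap.
#'
#' @examples
#' sim <- simulate_logistic(10)
#' cm <- tep_causality(sim)
#' tidy(cm)
#' @export
tep_causality <- function(data, dim = 2, lag = 1, standardize = FALSE,
                          reference_pair = c("first", "farthest"),
                          skip_degenerate = FALSE) {
  reference_pair <- match.arg(reference_pair)
  ts <- as_series_matrix(data)
  g <- ncol(ts$values)
  if (g < 2) abort("need at least 2 variables to score causality.")

  emb <- lapply(seq_len(g), function(i) {
    delay_embed(ts$values[, i],
      dim = dim, lag = lag, standardize = standardize,
      name = ts$names[i]
    )
  })
  dmat <- lapply(emb, pairwise_distances)
  n <- nrow(emb[[1]])

  scores <- matrix(NA_real_, g, g, dimnames = list(ts$names, ts$names))
  failures <- character()
  for (a in seq_len(g)) {
    for (b in seq_len(g)) {
      if (a == b) next
      # "a causes b": predictor = effect b (d), predicted = cause a (D)
      res <- tryCatch(
        {
          re <- tep_relative_errors(dmat[[b]], dmat[[a]],
            reference_pair = reference_pair,
            skip_degenerate = skip_degenerate
          )
          tep_score(re$rel_errors, n)
        },
        error = function(e) {
          failures <<- c(failures, sprintf("%s -> %s (%s)", ts$names[a], ts$names[b], conditionMessage(e)))
          NA_real_
        }
      )
      scores[a, b] <- res
    }
  }
  if (length(failures) > 0) {
    warn(sprintf(
      "%d pair(s) could not be scored and are marked missing: %s",
      length(failures), paste(head(failures, 5), collapse = "; ")
    ))
  }
  structure(
    list(
      names = ts$names,
      scores = scores,
      n = n,
      n_time = nrow(ts$values),
      config = list(
        dim = dim, lag = lag, standardize = standardize,
        reference_pair = reference_pair, skip_degenerate = skip_degenerate
      )
    ),
    class = "tep_cm"
  )
}

#' @export
print.tep_cm <- function(x, ...) {
  g <- length(x$names)
  cat(sprintf(
    "<tep_cm: %d variables, %d directed scores (rows cause columns), n = %d embedded points>\n",
    g, sum(!is.na(x$scores)), x$n
  ))
  print(round(x$scores[seq_len(min(g, 6)), seq_len(min(g, 6))], 4))
  if (g > 6) cat("...\n")
  invisible(x)
}

#' @rdname tep_causality
#' @param x A `tep_cm`.
#' @param ... Unused.
#' @export
tidy.tep_cm <- function(x, ...) {
  tibble::tibble(
    from = rep(x$names, times = length(x$names)),
    to = rep(x$names, each = length(x$names)),
    score = as.vector(x$scores)
  ) |>
    dplyr::filter(.data$from != .data$to) |>
    dplyr::arrange(.data$from, .data$to)
}

#' @rdname tep_causality
#' @export
glance.tep_cm <- function(x, ...) {
  off <- x$scores[row(x$scores) != col(x$scores)]
  tibble::tibble(
    n_vars = length(x$names),
    n_time = x$n_time,
    n_embedded = x$n,
    n_scores = sum(!is.na(off)),
    n_missing = sum(is.na(off)),
    score_min = suppressWarnings(min(off, na.rm = TRUE)),
    score_max = suppressWarnings(max(off, na.rm = TRUE))
  )
}

#' @rdname tep_causality
#' @param object A `tep_cm`.
#' @export
autoplot.tep_cm <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$to, y = .data$from, fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_discrete(limits = rev(object$names)) +
    ggplot2::scale_x_discrete(limits = object$names, position = "top") +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(
      x = "effect (column)", y = "cause (row)", fill = "TEP score",
      title = "Directed TEP causality scores (rows cause columns)"
    ) +
    ggplot2::theme_minimal()
}

# Coerce the accepted in-memory representations (tibble/data.frame with an
# optional `time` column, or numeric matrix with variables in columns) to a
# validated list(names, times, values[T x G]).
as_series_matrix <- function(data) {
  if (inherits(data, "tep_cm")) abort("`data` is already a causality matrix.")
  if (is.matrix(data)) {
    values <- data
    nms <- colnames(values) %||% paste0("V", seq_len(ncol(values)))
    times <- seq_len(nrow(values))
  } else if (is.data.frame(data)) {
    df <- data
    if ("time" %in% names(df)) {
      times <- df[["time"]]
      df <- df[setdiff(names(df), "time")]
    } else {
      times <- seq_len(nrow(df))
    }
    if (!all(vapply(df, is.numeric, logical(1)))) {
      abort("all variable columns must be numeric.")
    }
    values <- as.matrix(df)
    nms <- names(df)
  } else {
    abort("`data` must be a data frame or a numeric matrix (time in rows).")
  }
  if (anyDuplicated(nms)) abort("variable names must be unique.")
  if (anyNA(values) || any(!is.finite(values))) {
    abort("missing or non-finite values in the series; with ~10 samples imputation would dominate the result, so none is attempted.")
  }
  if (nrow(values) < 3) abort("need at least 3 time points.")
  list(names = nms, times = times, values = values)
}
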