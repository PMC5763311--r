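#' ROC curve and AUC of a causality matrix against a known network
#'
#' Every ordered pair of distinct variables is one ranking instance, labelled
#' positive when the directed edge is in the ground-truth network. Instances
#' are ranked by TEP score (higher = stronger evidence) and summarized by
#' the ROC curve and its area. The AUC equals the Mann-Whitney U statistic
#' with ties counted half -- relevant here because very short series produce
#' tied scores.
#'
#' @param scores A `tep_cm` from [tep_causality()], or a tibble with columns
#'   `from`, `to`, `score` covering ordered pairs.
#' @param truth Directed ground-truth edges: tibble/data frame with columns
#'   `from`, `to` (e.g. [five_species_truth()], a `grn_sim$network`, or
#'   [read_edges()]).
#'
#' @return A `tep_roc`: list with `fpr`, `tpr` (curve from (0,0) to (1,1)),
#'   `auc`, `n_positive`, `n_negative`. `tidy()` gives the curve points,
#'   `glance()` the AUC row, `autoplot()` the curve.
#'
#' @examples
#' sim <- simulate_five_species(15, seed = 1)
#' r <- tep_roc(tep_causality(sim), five_species_truth())
#' r$auc
#' @export
tep_roc <- function(scores, truth) {
  inst <- roc_instances(scores, truth)
  n_pos <- sum(inst$label == 1)
  n_neg <- sum(inst$label == 0)
  r <- pROC::roc(
    response = inst$label, predictor = inst$score,
    levels = c(0, 1), direction = "<", quiet = TRUE
  )
  curve <- tibble::tibble(fpr = 1 - r$specificities, tpr = r$sensitivities) |>
    dplyr::arrange(.data$fpr, .data$tpr)
  structure(
    list(
      fpr = curve$fpr,
      tpr = curve$tpr,
      auc = as.numeric(pROC::auc(r)),
      n_positive = n_pos,
      n_negative = n_neg
    ),
    class = "tep_roc"
  )
}

roc_instances <- function(scores, truth) {
  if (inherits(scores, "tep_cm")) scores <- tidy(scores)
  if (!all(c("from", "to", "score") %in% names(scores))) {
    abort("`scores` must be a tep_cm or a tibble with columns from, to, score.")
  }
  if (!all(c("from", "to") %in% names(truth))) {
    abort("`truth` must have columns `from` and `to`.")
  }
  vars <- unique(c(scores$from, scores$to))
  unknown <- setdiff(unique(c(truth$from, truth$to)), vars)
  if (length(unknown) > 0) {
    abort(sprintf(
      "edge list names unknown to the score matrix: %s",
      paste(unknown, collapse = ", ")
    ))
  }
  edge_key <- paste(truth$from, truth$to, sep = "\r")
  inst <- scores |>
    dplyr::filter(.data$from != .data$to) |>
    dplyr::mutate(label = as.integer(paste(.data$from, .data$to, sep = "\r") %in% edge_key))
  n_missing <- sum(is.na(inst$score))
  if (n_missing > 0) {
    warn(sprintf("%d instance(s) with missing scores excluded from the ROC.", n_missing))
    inst <- dplyr::filter(inst, !is.na(.data$score))
  }
  if (length(unique(inst$label)) < 2) {
    abort("single-class truth: need at least one true edge and one non-edge.")
  }
  inst
}

#' @export
print.tep_roc <- function(x, ...) {
  cat(sprintf(
    "<tep_roc: AUC %.6f over %d positives / %d negatives>\n",
    x$auc, x$n_positive, x$n_negative
  ))
  invisible(x)
}

#' @rdname tep_roc
#' @param x A `tep_roc`.
#' @param ... Unused.
#' @export
tidy.tep_roc <- function(x, ...) {
  tibble::tibble(fpr = x$fpr, tpr = x$tpr)
}

#' @rdname tep_roc
#' @export
glance.tep_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_positive = x$n_positive, n_negative = x$n_negative)
}

#' @rdname tep_roc
#' @param object A `tep_roc`.
#' @export
autoplot.tep_roc <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("ROC of directed TEP scores (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Binary causal calls from a score matrix
#'
#' Turns the continuous directed scores into 0/1 calls, either by a fixed
#' score threshold or by taking the top-ranked pairs. ROC/AUC (threshold
#' free) is the primary evaluation; calls are a convenience for reporting a
#' concrete network.
#'
#' @param scores A `tep_cm` or a `(from, to, score)` tibble.
#' @param threshold Call an edge when `score >= threshold`.
#' @param top_k Alternative to `threshold`: call exactly the `top_k`
#'   highest-scoring ordered pairs (ties broken by pair order).
#' @return A tibble `(from, to, score, call)`; missing scores yield `NA`
#'   calls.
#' @examples
#' sim <- simulate_logistic(10)
#' tep_detect(tep_causality(sim), threshold = 0.45)
#' @export
tep_detect <- function(scores, threshold = NULL, top_k = NULL) {
  if (inherits(scores, "tep_cm")) scores <- tidy(scores)
  if (is.null(threshold) == is.null(top_k)) {
    abort("supply exactly one of `threshold` or `top_k`.")
  }
  scores <- dplyr::filter(scores, .data$from != .data$to)
  if (!is.null(threshold)) {
    dplyr::mutate(scores, call = .data$score >= threshold)
  } else {
    top_k <- check_count(top_k, "top_k")
    ord <- order(scores$score, decreasing = TRUE, na.last = TRUE)
    call <- rep(FALSE, nrow(scores))
    call[ord[seq_len(min(top_k, sum(!is.na(scores$score))))]] <- TRUE
    call[is.na(scores$score)] <- NA
    dplyr::mutate(scores, call = call)
  }
}

#' Compare several causality matrices against one ground truth
#'
#' One ROC/AUC per labelled score matrix, collected in a table sorted by
#' AUC -- the shape of a benchmark summary across methods or noise levels.
#'
#' @param runs Named list of `tep_cm` objects (or `(from, to, score)`
#'   tibbles); names are the run labels.
#' @param truth Directed ground-truth edges (`from`, `to`).
#' @return A tibble `(label, auc, n_positive, n_negative)` sorted by
#'   decreasing AUC.
#' @examples
#' sim <- simulate_five_species(15, seed = 1)
#' cm <- tep_causality(sim)
#' tep_benchmark(list(fit = cm), five_species_truth())
#' @export
tep_benchmark <- function(runs, truth) {
  if (!is.list(runs) || length(runs) == 0) abort("`runs` must be a non-empty list.")
  labels <- names(runs) %||% as.character(seq_along(runs))
  if (any(labels == "")) abort("every element of `runs` must be named.")
  purrr::map2(runs, labels, function(cm, label) {
    g <- glance(tep_roc(cm, truth))
    dplyr::bind_cols(tibble::tibble(label = label), g)
  }) |>
    purrr::list_rbind() |>
    dplyr::arrange(dplyr::desc(.data$auc))
}
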