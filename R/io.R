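#' Read and write multivariate time-series tables
#'
#' On disk the convention is gene-expression style: one row per variable,
#' first column the variable name, remaining columns the time points, with a
#' header row of time labels (`orientation = "variables"`). Tables with time
#' in rows and one column per variable (first column the time label) are
#' read with `orientation = "time"`. TSV and CSV dialects are supported and
#' sniffed from the file when `delim` is `NULL`. In memory the package uses
#' the tidy layout: a tibble with a `time` column and one numeric column per
#' variable.
#'
#' @param path File path.
#' @param delim Field delimiter; `NULL` (default) sniffs `","` vs tab.
#' @param orientation `"variables"` (variables in rows, the default) or
#'   `"time"` (time in rows).
#' @return `read_timeseries()`: a tibble (`time`, one column per variable).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_timeseries(simulate_logistic(5), f)
#' read_timeseries(f)
#' @export
read_timeseries <- function(path, delim = NULL, orientation = c("variables", "time")) {
  orientation <- match.arg(orientation)
  delim <- delim %||% sniff_delim(path)
  raw <- suppressWarnings(readr::read_delim(path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(readr::col_character(), .default = readr::col_double())
  ))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "parse error at line %d, column %d: expected %s, got '%s'.",
      probs$row[1], probs$col[1], probs$expected[1], probs$actual[1]
    ))
  }
  if (ncol(raw) < 2) abort("need at least one value column.")
  if (anyNA(raw)) {
    bad <- which(rowSums(is.na(raw)) > 0)[1]
    abort(sprintf("missing value at line %d (ragged row or empty cell).", bad + 1L))
  }
  if (orientation == "variables") {
    nms <- raw[[1]]
    dup <- nms[duplicated(nms)]
    if (length(dup) > 0) {
      abort(sprintf(
        "duplicate name '%s' at line %d.",
        dup[1], which(nms == dup[1])[2] + 1L
      ))
    }
    values <- t(as.matrix(raw[-1]))
    out <- tibble::as_tibble(as.data.frame(values), .name_repair = "minimal")
    names(out) <- nms
    time <- suppressWarnings(as.numeric(names(raw)[-1]))
    if (anyNA(time)) time <- seq_len(nrow(out))
    dplyr::bind_cols(tibble::tibble(time = time), out)
  } else {
    nms <- names(raw)[-1]
    dup <- nms[duplicated(nms)]
    if (length(dup) > 0) abort(sprintf("duplicate name '%s' in header.", dup[1]))
    out <- raw
    names(out)[1] <- "time"
    out
  }
}

#' @rdname read_timeseries
#' @param data Tibble with a `time` column (optional) and numeric variable
#'   columns, as produced by the simulators.
#' @return `write_timeseries()`: `path`, invisibly.
#' @export
write_timeseries <- function(data, path, delim = NULL,
                             orientation = c("variables", "time")) {
  orientation <- match.arg(orientation)
  delim <- delim %||% sniff_delim_path(path)
  ts <- as_series_matrix(data)
  if (orientation == "variables") {
    out <- as.data.frame(t(ts$values))
    names(out) <- as.character(ts$times)
    out <- cbind(data.frame(name = ts$names), out)
  } else {
    out <- as.data.frame(ts$values)
    names(out) <- ts$names
    out <- cbind(data.frame(time = ts$times), out)
  }
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Read and write directed edge lists
#'
#' Two-column delimited text (source, target), one directed edge per line;
#' lines starting with `#` are comments. A header is optional and detected
#' when the first data line equals `from`/`to`.
#'
#' @param path File path.
#' @return `read_edges()`: tibble of directed edges (`from`, `to`).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_edges(five_species_truth(), f)
#' nrow(read_edges(f))
#' @export
read_edges <- function(path) {
  lines <- readr::read_lines(path)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble::tibble(from = character(), to = character()))
  }
  delim <- if (grepl("\t", lines[1])) "\t" else if (grepl(",", lines[1])) "," else "[[:space:]]+"
  parts <- strsplit(lines, delim)
  bad <- which(vapply(parts, length, integer(1)) != 2)
  if (length(bad) > 0) {
    abort(sprintf("edge line %d does not have exactly two fields: '%s'", bad[1], lines[bad[1]]))
  }
  edges <- tibble::tibble(
    from = vapply(parts, `[[`, character(1), 1),
    to = vapply(parts, `[[`, character(1), 2)
  )
  if (identical(unname(tolower(unlist(edges[1, ]))), c("from", "to"))) edges <- edges[-1, ]
  edges
}

#' @rdname read_edges
#' @param edges Tibble/data frame of directed edges with columns `from`, `to`.
#' @return `write_edges()`: `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  readr::write_delim(edges[c("from", "to")], path, delim = "\t")
  invisible(path)
}

#' Read and write causality score matrices
#'
#' Scores are stored as a TSV matrix with the same variable ordering on rows
#' (causes) and columns (effects), 12 significant digits, `NA` on the
#' diagonal and for unscored pairs.
#'
#' @param scores A `tep_cm` from [tep_causality()].
#' @param path File path.
#' @return `write_scores()`: `path` invisibly; `read_scores()`: a `tep_cm`
#'   (with unknown scoring config).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_scores(tep_causality(simulate_logistic(10)), f)
#' read_scores(f)
#' @export
write_scores <- function(scores, path) {
  if (!inherits(scores, "tep_cm")) abort("`scores` must be a tep_cm.")
  m <- signif(scores$scores, 12)
  out <- cbind(
    data.frame(name = scores$names),
    as.data.frame(m, optional = TRUE)
  )
  readr::write_delim(out, path, delim = "\t")
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  nms <- raw[[1]]
  m <- as.matrix(raw[-1])
  dimnames(m) <- list(nms, names(raw)[-1])
  if (!identical(nms, colnames(m))) abort("row and column names of the score matrix differ.")
  structure(
    list(names = nms, scores = m, n = NA_integer_, n_time = NA_integer_, config = NULL),
    class = "tep_cm"
  )
}

#' Write ROC results as JSON
#'
#' Serializes a [tep_roc()] result (fpr/tpr arrays, AUC, class counts) to
#' JSON with 6 significant digits.
#'
#' @param roc A `tep_roc`.
#' @param path File path.
#' @return `path`, invisibly.
#' @examples
#' r <- tep_roc(tep_causality(simulate_five_species(15, seed = 1)), five_species_truth())
#' write_roc(r, tempfile(fileext = ".json"))
#' @export
write_roc <- function(roc, path) {
  if (!inherits(roc, "tep_roc")) abort("`roc` must be a tep_roc.")
  jsonlite::write_json(
    list(
      fpr = signif(roc$fpr, 6), tpr = signif(roc$tpr, 6),
      auc = signif(roc$auc, 6),
      n_positive = roc$n_positive, n_negative = roc$n_negative
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

sniff_delim <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  if (length(first) == 0) abort("empty file.")
  if (grepl("\t", first[1])) "\t" else if (grepl(",", first[1])) "," else "\t"
}

sniff_delim_path <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}
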