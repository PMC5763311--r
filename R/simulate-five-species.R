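#' Five-species coupled map benchmark
#'
#' Iterates a five-variable coupled difference system in which species
#' Y1, Y2, Y3 influence one another and all three drive Y4 and Y5, while
#' Y4 and Y5 influence nothing. Each update is
#' `Y_i(t+1) = Y_i(t) * (growth[i] + sum_j coupling[i, j] * Y_j(t))`,
#' with `coupling[i, i]` the self-limitation term. The default coefficients
#' are the benchmark's published values (see [five_species_params()]); the
#' implied 12 directed interactions are returned by [five_species_truth()].
#'
#' @param n_steps Number of time points to return (>= 3).
#' @param init Numeric vector of 5 initial values in (0, 1); if `NULL`,
#'   drawn uniformly from (0.2, 0.8) using `seed`.
#' @param seed Integer seed used only when `init` is `NULL`.
#' @param params List with elements `growth` (length 5) and `coupling`
#'   (5 x 5), as from [five_species_params()].
#' @param burn_in Steps iterated and discarded before recording (default 0).
#'
#' @return A tibble with columns `time`, `Y1` .. `Y5`.
#' @examples
#' simulate_five_species(15, seed = 1)
#' @export
simulate_five_species <- function(n_steps, init = NULL, seed = NULL,
                                  params = five_species_params(), burn_in = 0) {
  n_steps <- check_count(n_steps, "n_steps")
  if (n_steps < 3) abort("`n_steps` must be at least 3.")
  if (is.null(init)) {
    if (!is.null(seed)) set.seed(seed)
    init <- runif(5, 0.2, 0.8)
  }
  if (length(init) != 5 || any(init < 0) || any(init >= 1)) {
    abort("`init` must be 5 values in [0, 1).")
  }
  growth <- params$growth
  cpl <- params$coupling
  total <- n_steps + burn_in
  y <- matrix(0, total, 5)
  y[1, ] <- init
  for (t in seq_len(total - 1)) {
    y[t + 1, ] <- y[t, ] * (growth + as.vector(cpl %*% y[t, ]))
    if (any(!is.finite(y[t + 1, ])) || max(abs(y[t + 1, ])) > 1e3) {
      abort(sprintf("divergent trajectory at step %d.", t + 1))
    }
  }
  y <- y[seq.int(burn_in + 1, total), , drop = FALSE]
  out <- tibble::as_tibble(as.data.frame(y))
  names(out) <- paste0("Y", 1:5)
  dplyr::bind_cols(tibble::tibble(time = seq_len(n_steps)), out)
}

#' @rdname simulate_five_species
#' @return `five_species_params()`: list with the published `growth` rates
#'   and signed `coupling` matrix (`coupling[i, j]` multiplies `Y_j` in
#'   `Y_i`'s update).
#' @export
five_species_params <- function() {
  coupling <- rbind(
    c(-4,     -2,     -0.4,   0,    0),
    c(-0.3,   -3.1,   -0.93,  0,    0),
    c(0.636,  0.636,  -2.12,  0,    0),
    c(-0.111, -0.011, 0.131,  -3.8, 0),
    c(-0.082, -0.111, -0.125, 0,    -4.1)
  )
  dimnames(coupling) <- list(paste0("Y", 1:5), paste0("Y", 1:5))
  list(growth = c(4, 3.1, 2.12, 3.8, 4.1), coupling = coupling)
}

#' Ground-truth directed network of the five-species benchmark
#'
#' The 12 directed influences implied by the nonzero off-diagonal coupling
#' coefficients: Y1, Y2, Y3 are mutually coupled and each drives Y4 and Y5;
#' Y4 and Y5 drive nothing.
#'
#' @return A tibble of directed edges with columns `from`, `to`.
#' @examples
#' five_species_truth()
#' @export
five_species_truth <- function() {
  cpl <- five_species_params()$coupling
  idx <- which(cpl != 0 & row(cpl) != col(cpl), arr.ind = TRUE)
  # coupling[i, j] != 0 means Y_j appears in Y_i's update: edge Y_j -> Y_i
  tibble::tibble(
    from = paste0("Y", idx[, "col"]),
    to = paste0("Y", idx[, "row"])
  ) |>
    dplyr::arrange(.data$from, .data$to)
}
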