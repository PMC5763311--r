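#' Synthetic gene regulatory network expression data
#'
#' Generates a short time-course expression matrix from a random directed
#' regulatory network whose node dynamics follow Michaelis-Menten/Hill
#' kinetics, emulating the kind of in-silico benchmark used to validate
#' network-inference methods on ~10 time points. Gene `i` obeys
#' \deqn{dx_i/dt = m_i \prod_{r \in reg(i)} h_r(x_r) - \delta x_i}
#' where an activator contributes `x_r^h / (K^h + x_r^h)` and a repressor
#' `K^h / (K^h + x_r^h)`; genes without regulators relax to their basal
#' level `m_i / delta`. The system is integrated with fixed-step RK4 from a
#' random positive initial state (a post-perturbation snapshot), sampled at
#' `n_timepoints` equally spaced times over two relaxation times
#' `2 / degradation_rate`, and measurement noise is added with [add_noise()].
#'
#' Three independent seeds make topology, kinetics/initial state, and noise
#' separately reproducible.
#'
#' @param n_genes Number of genes `G` (>= 2).
#' @param n_timepoints Number of sampled time points (default 10, >= 3).
#' @param noise_level Additive measurement-noise scale as a fraction of each
#'   gene's temporal standard deviation (benchmark levels: 0, 0.1, 0.2).
#' @param topology_seed,dynamics_seed,noise_seed Integer seeds.
#' @param hill_coefficient Hill exponent `h` (default 2).
#' @param degradation_rate First-order decay `delta` in 1/time (default 1).
#' @param mean_in_degree Expected number of regulators per gene (default 1.5).
#' @param n_integration_steps Fixed RK4 steps over the integration window.
#' @param adjacency Optional signed adjacency matrix (`[source, target]`,
#'   entries -1/0/1, zero diagonal) to use instead of sampling a topology;
#'   the per-edge Hill constants still come from `topology_seed`, so two runs
#'   differing only in `adjacency` are directly comparable (in-silico
#'   intervention).
#'
#' @return A `grn_sim`: list with `expression` (tibble: `time` plus one
#'   numeric column per gene), `network` (tibble of directed edges `from`,
#'   `to`, `sign`), and `params`.
#' @examples
#' sim <- simulate_grn(n_genes = 10, topology_seed = 1, dynamics_seed = 2, noise_seed = 3)
#' sim$network
#' @export
simulate_grn <- function(n_genes = 20, n_timepoints = 10, noise_level = 0,
                         topology_seed = 1, dynamics_seed = 2, noise_seed = 3,
                         hill_coefficient = 2, degradation_rate = 1,
                         mean_in_degree = 1.5, n_integration_steps = 200,
                         adjacency = NULL) {
  n_genes <- check_count(n_genes, "n_genes")
  n_timepoints <- check_count(n_timepoints, "n_timepoints")
  if (n_genes < 2) abort("`n_genes` must be at least 2.")
  if (n_timepoints < 3) abort("`n_timepoints` must be at least 3.")
  if (noise_level < 0) abort("`noise_level` must be non-negative.")
  genes <- sprintf("g%03d", seq_len(n_genes))

  # -- topology: directed Erdos-Renyi with expected in-degree, signed edges.
  # Hill constants are drawn before the adjacency so that supplying an
  # edited `adjacency` leaves all kinetic constants unchanged.
  set.seed(topology_seed)
  k_half <- matrix(runif(n_genes^2, 0.3, 1), n_genes, n_genes)
  if (is.null(adjacency)) {
    p_edge <- min(1, mean_in_degree / (n_genes - 1))
    adj <- matrix(0L, n_genes, n_genes, dimnames = list(genes, genes)) # [source, target]
    for (tgt in seq_len(n_genes)) {
      for (src in seq_len(n_genes)) {
        if (src != tgt && runif(1) < p_edge) {
          adj[src, tgt] <- sample(c(1L, -1L), 1)
        }
      }
    }
  } else {
    if (!is.matrix(adjacency) || any(dim(adjacency) != n_genes) ||
      any(!adjacency %in% c(-1L, 0L, 1L)) || any(diag(adjacency) != 0)) {
      abort("`adjacency` must be an n_genes x n_genes matrix with entries -1/0/1 and zero diagonal.")
    }
    adj <- adjacency
    storage.mode(adj) <- "integer"
    dimnames(adj) <- list(genes, genes)
  }

  # -- kinetics and initial state
  set.seed(dynamics_seed)
  m_max <- runif(n_genes, 0.5, 1.5)
  x0 <- runif(n_genes, 0.1, 1)

  regulators <- lapply(seq_len(n_genes), function(tgt) which(adj[, tgt] != 0L))
  h <- hill_coefficient
  deriv <- function(t, x, parms) {
    dx <- numeric(n_genes)
    for (tgt in seq_len(n_genes)) {
      act <- 1
      for (src in regulators[[tgt]]) {
        hill <- x[src]^h / (k_half[src, tgt]^h + x[src]^h)
        act <- act * if (adj[src, tgt] == 1L) hill else 1 - hill
      }
      dx[tgt] <- m_max[tgt] * act - degradation_rate * x[tgt]
    }
    list(dx)
  }

  t_max <- 2 / degradation_rate
  grid <- seq(0, t_max, length.out = n_integration_steps + 1)
  sol <- deSolve::ode(y = x0, times = grid, func = deriv, parms = NULL, method = "rk4")
  states <- unname(sol[, -1, drop = FALSE])
  if (any(!is.finite(states))) {
    bad <- which(!is.finite(states), arr.ind = TRUE)[1, ]
    abort(sprintf("non-finite state for gene %s at integration step %d.", genes[bad[2]], bad[1]))
  }

  keep <- round(seq(1, nrow(states), length.out = n_timepoints))
  expr <- tibble::as_tibble(as.data.frame(states[keep, , drop = FALSE]))
  names(expr) <- genes
  expr <- dplyr::bind_cols(tibble::tibble(time = grid[keep]), expr)
  expr <- add_noise(expr, level = noise_level, seed = noise_seed)

  edges <- which(adj != 0L, arr.ind = TRUE)
  network <- tibble::tibble(
    from = genes[edges[, 1]],
    to = genes[edges[, 2]],
    sign = adj[edges]
  ) |>
    dplyr::arrange(.data$from, .data$to)

  structure(
    list(
      expression = expr,
      network = network,
      params = list(
        n_genes = n_genes, n_timepoints = n_timepoints, noise_level = noise_level,
        topology_seed = topology_seed, dynamics_seed = dynamics_seed,
        noise_seed = noise_seed, hill_coefficient = hill_coefficient,
        degradation_rate = degradation_rate, mean_in_degree = mean_in_degree,
        n_integration_steps = n_integration_steps, m_max = m_max, x0 = x0,
        k_half = k_half, adjacency = adj
      )
    ),
    class = "grn_sim"
  )
}

#' @export
print.grn_sim <- function(x, ...) {
  cat(sprintf(
    "<grn_sim: %d genes, %d time points, %d directed edges, noise level %g>\n",
    x$params$n_genes, x$params$n_timepoints, nrow(x$network), x$params$noise_level
  ))
  invisible(x)
}

#' Additive measurement noise scaled to each variable
#'
#' Adds independent Gaussian noise to every observation with standard
#' deviation `level` times that variable's temporal standard deviation, the
#' common reading of a unitless "noise level" for expression benchmarks.
#' `level = 0` returns the input unchanged.
#'
#' @param data Tibble/data frame with one row per time point (optional
#'   `time` column is passed through untouched) or numeric matrix.
#' @param level Non-negative noise scale.
#' @param seed Optional integer seed for reproducibility.
#' @return Object of the same shape as `data` with noise added.
#' @examples
#' add_noise(simulate_logistic(10), level = 0.1, seed = 1)
#' @export
add_noise <- function(data, level, seed = NULL) {
  if (level < 0) abort("`level` must be non-negative.")
  if (level == 0) {
    return(data)
  }
  if (!is.null(seed)) set.seed(seed)
  is_df <- is.data.frame(data)
  if (is_df) {
    keep_time <- "time" %in% names(data)
    vars <- setdiff(names(data), "time")
    values <- as.matrix(data[vars])
  } else {
    values <- data
  }
  sds <- apply(values, 2, sd)
  noise <- matrix(rnorm(length(values)), nrow(values)) *
    rep(level * sds, each = nrow(values))
  noisy <- values + noise
  if (!is_df) {
    return(noisy)
  }
  out <- tibble::as_tibble(as.data.frame(noisy))
  names(out) <- vars
  if (keep_time) out <- dplyr::bind_cols(data["time"], out)
  out
}
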