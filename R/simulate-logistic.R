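#' Coupled logistic map benchmark
#'
#' Iterates the two-species coupled logistic difference system
#' \deqn{X(t+1) = X(t) [r_x - r_x X(t) - \beta_{xy} Y(t)]}
#' \deqn{Y(t+1) = Y(t) [r_y - r_y Y(t) - \beta_{yx} X(t)]}
#' whose chaotic regime is a standard testbed for directional causality
#' detection: with both couplings nonzero each variable drives the other;
#' `simulate_logistic_uni()` forces `beta_yx = 0` so that Y drives X but X
#' has no influence on Y. Defaults are the benchmark's stated parameters and
#' initial conditions.
#'
#' @param n_steps Number of time points to return (>= 3), including the
#'   initial condition.
#' @param r_x,r_y Intrinsic growth rates.
#' @param beta_xy Coupling strength of Y on X (appears in X's update).
#' @param beta_yx Coupling strength of X on Y.
#' @param x0,y0 Initial values in (0, 1).
#' @param burn_in Steps iterated and discarded before recording (default 0:
#'   the benchmark records from the given initial condition).
#'
#' @return A tibble with columns `time`, `X`, `Y` (one row per time point).
#' @examples
#' simulate_logistic(10)
#' @export
simulate_logistic <- function(n_steps, r_x = 3.8, r_y = 3.5,
                              beta_xy = 0.02, beta_yx = 0.1,
                              x0 = 0.4, y0 = 0.2, burn_in = 0) {
  n_steps <- check_count(n_steps, "n_steps")
  if (n_steps < 3) abort("`n_steps` must be at least 3.")
  total <- n_steps + burn_in
  x <- y <- numeric(total)
  x[1] <- x0
  y[1] <- y0
  for (t in seq_len(total - 1)) {
    x[t + 1] <- x[t] * (r_x - r_x * x[t] - beta_xy * y[t])
    y[t + 1] <- y[t] * (r_y - r_y * y[t] - beta_yx * x[t])
    # once the state leaves the attractor's basin the quadratic term makes
    # the magnitude grow without bound, so a modest cap detects divergence
    if (!all(is.finite(c(x[t + 1], y[t + 1]))) || max(abs(c(x[t + 1], y[t + 1]))) > 1e3) {
      abort(sprintf("divergent trajectory at step %d.", t + 1))
    }
  }
  keep <- seq.int(burn_in + 1, total)
  tibble::tibble(time = seq_len(n_steps), X = x[keep], Y = y[keep])
}

#' @rdname simulate_logistic
#' @export
simulate_logistic_uni <- function(n_steps, r_x = 3.8, r_y = 3.5,
                                  beta_xy = 0.02, x0 = 0.4, y0 = 0.2,
                                  burn_in = 0) {
  simulate_logistic(n_steps,
    r_x = r_x, r_y = r_y, beta_xy = beta_xy, beta_yx = 0,
    x0 = x0, y0 = y0, burn_in = burn_in
  )
}
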