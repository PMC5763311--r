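# Naive, scalar-by-scalar oracles kept deliberately independent of the
# vectorized implementation they check.

oracle_embed <- function(x, E, tau) {
  n <- length(x) - (E - 1) * tau
  m <- matrix(0, n, E)
  for (k in seq_len(n)) {
    for (e in seq_len(E)) {
      m[k, e] <- x[k + (e - 1) * tau]
    }
  }
  m
}

oracle_dist <- function(points) {
  n <- nrow(points)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt(sum((points[i, ] - points[j, ])^2))
    }
  }
  d
}

# Literal transcription of the relative-error and score formulas:
# gamma = d12/D12; eps_ij = |d_ij - gamma D_ij| / (gamma D_ij), i >= 3, j < i;
# score = 1/(n-1) * sum_i mean_j exp(-eps_ij).
oracle_tep <- function(d, D) {
  n <- nrow(d)
  gamma <- d[1, 2] / D[1, 2]
  total <- 0
  eps <- matrix(NA_real_, n, n)
  for (i in 3:n) {
    inner <- 0
    for (j in 1:(i - 1)) {
      eps[i, j] <- abs(d[i, j] - gamma * D[i, j]) / (gamma * D[i, j])
      inner <- inner + 1 / exp(eps[i, j])
    }
    total <- total + inner / (i - 1)
  }
  list(gamma = gamma, rel_errors = eps, score = total / (n - 1))
}

oracle_score_pair <- function(x, y, E = 2, tau = 1) {
  mx <- oracle_embed(x, E, tau)
  my <- oracle_embed(y, E, tau)
  oracle_tep(oracle_dist(mx), oracle_dist(my))$score
}

# Mann-Whitney U statistic over all positive x negative pairs, half credit
# for ties, normalized to [0, 1].
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  u <- 0
  for (p in pos) {
    for (q in neg) {
      u <- u + (p > q) + 0.5 * (p == q)
    }
  }
  u / (length(pos) * length(neg))
}

# Random score table over G variables plus a random directed truth, for
# ROC cross-checks.
random_roc_case <- function(g, seed) {
  set.seed(seed)
  nms <- paste0("v", seq_len(g))
  grid <- expand.grid(from = nms, to = nms, stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, ]
  scores <- tibble::tibble(
    from = grid$from, to = grid$to,
    score = sample(round(runif(nrow(grid)), 2)) # rounding forces some ties
  )
  lab <- rbinom(nrow(grid), 1, 0.4)
  if (all(lab == 0)) lab[1] <- 1
  if (all(lab == 1)) lab[1] <- 0
  truth <- tibble::tibble(from = grid$from[lab == 1], to = grid$to[lab == 1])
  list(scores = scores, truth = truth, labels = lab)
}
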