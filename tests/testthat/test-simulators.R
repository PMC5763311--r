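test_that("the coupled logistic map reproduces hand-computed steps", {
  sim <- simulate_logistic(3)
  expect_equal(sim$X[2], 0.4 * (3.8 - 3.8 * 0.4 - 0.02 * 0.2)) # 0.9104
  expect_equal(sim$X[2], 0.9104)
  expect_equal(sim$Y[2], 0.2 * (3.5 - 3.5 * 0.2 - 0.1 * 0.4)) # 0.552
  expect_equal(sim$Y[2], 0.552)

  uni <- simulate_logistic_uni(3)
  expect_equal(uni$Y[2], 0.2 * (3.5 - 3.5 * 0.2)) # 0.56
  expect_equal(uni$Y[2], 0.56)
  expect_equal(uni$X[2], sim$X[2]) # X's update is unchanged
})

test_that("zero is a fixed point and decoupled maps iterate independently", {
  sim <- simulate_logistic(10, x0 = 0)
  expect_equal(sim$X, rep(0, 10))

  free <- simulate_logistic(10, beta_xy = 0, beta_yx = 0)
  x <- 0.4
  y <- 0.2
  for (t in 2:10) {
    x[t] <- x[t - 1] * 3.8 * (1 - x[t - 1])
    y[t] <- y[t - 1] * 3.5 * (1 - y[t - 1])
  }
  expect_equal(free$X, x, tolerance = 1e-14)
  expect_equal(free$Y, y, tolerance = 1e-14)
})

test_that("the default logistic trajectory stays inside (0,1) for 1000 steps", {
  sim <- simulate_logistic(1000)
  expect_true(all(sim$X > 0 & sim$X < 1))
  expect_true(all(sim$Y > 0 & sim$Y < 1))
})

test_that("in the unidirectional system Y is autonomous but X still listens to Y", {
  uni <- simulate_logistic_uni(12)
  free <- simulate_logistic(12, beta_xy = 0, beta_yx = 0)
  expect_equal(uni$Y, free$Y, tolerance = 1e-14)

  bumped <- simulate_logistic_uni(12, y0 = 0.25)
  expect_false(isTRUE(all.equal(uni$X[3], bumped$X[3])))
})

test_that("divergent trajectories are reported with the step index", {
  expect_error(simulate_logistic(60, x0 = 0.9999999, r_x = 4.2), "divergent trajectory at step")
})

test_that("the five-species map reproduces a hand substitution", {
  y <- c(0.5, 0.5, 0.5, 0.5, 0.5)
  sim <- simulate_five_species(3, init = y)
  expect_equal(sim$Y1[2], 0.5 * (4 - 4 * 0.5 - 2 * 0.5 - 0.4 * 0.5))
  expect_equal(sim$Y2[2], 0.5 * (3.1 - 0.3 * 0.5 - 3.1 * 0.5 - 0.93 * 0.5))
  expect_equal(sim$Y3[2], 0.5 * (2.12 + 0.636 * 0.5 + 0.636 * 0.5 - 2.12 * 0.5))
  expect_equal(sim$Y4[2], 0.5 * (3.8 - 0.111 * 0.5 - 0.011 * 0.5 + 0.131 * 0.5 - 3.8 * 0.5))
  expect_equal(sim$Y5[2], 0.5 * (4.1 - 0.082 * 0.5 - 0.111 * 0.5 - 0.125 * 0.5 - 4.1 * 0.5))
})

test_that("species 4 influences nothing: zeroing it leaves Y1..Y3 unchanged", {
  init <- c(0.4, 0.3, 0.6, 0.5, 0.45)
  base <- simulate_five_species(8, init = init)
  no4 <- simulate_five_species(8, init = replace(init, 4, 0))
  expect_equal(no4$Y4, rep(0, 8))
  expect_equal(no4$Y1, base$Y1, tolerance = 1e-14)
  expect_equal(no4$Y2, base$Y2, tolerance = 1e-14)
  expect_equal(no4$Y3, base$Y3, tolerance = 1e-14)
})

test_that("cutting the driver coefficients decouples Y4 and Y5 into plain logistic maps", {
  p <- five_species_params()
  p$coupling[4:5, 1:3] <- 0
  init <- c(0.4, 0.3, 0.6, 0.5, 0.45)
  sim <- simulate_five_species(5, init = init, params = p)
  y4 <- init[4]
  y5 <- init[5]
  for (t in 2:5) {
    y4[t] <- y4[t - 1] * (3.8 - 3.8 * y4[t - 1])
    y5[t] <- y5[t - 1] * (4.1 - 4.1 * y5[t - 1])
  }
  expect_equal(sim$Y4, y4, tolerance = 1e-12)
  expect_equal(sim$Y5, y5, tolerance = 1e-12)
})

test_that("the five-species ground truth lists exactly the 12 printed influences", {
  truth <- five_species_truth()
  expect_equal(nrow(truth), 12)
  expect_false(any(truth$from %in% c("Y4", "Y5")))
  key <- paste(truth$from, truth$to)
  expect_true("Y1 Y4" %in% key)
  expect_false("Y4 Y1" %in% key)
  # mutual coupling among Y1..Y3, drive onto Y4 and Y5
  for (a in c("Y1", "Y2", "Y3")) {
    for (b in setdiff(c("Y1", "Y2", "Y3", "Y4", "Y5"), a)) {
      expect_true(paste(a, b) %in% key)
    }
  }
})

test_that("the GRN generator is reproducible and the noise seed acts independently", {
  a <- simulate_grn(n_genes = 8, topology_seed = 5, dynamics_seed = 6, noise_seed = 7)
  b <- simulate_grn(n_genes = 8, topology_seed = 5, dynamics_seed = 6, noise_seed = 7)
  expect_identical(a$expression, b$expression)
  expect_identical(a$network, b$network)

  noisy1 <- simulate_grn(
    n_genes = 8, noise_level = 0.1,
    topology_seed = 5, dynamics_seed = 6, noise_seed = 7
  )
  noisy2 <- simulate_grn(
    n_genes = 8, noise_level = 0.1,
    topology_seed = 5, dynamics_seed = 6, noise_seed = 8
  )
  expect_false(identical(noisy1$expression, noisy2$expression))
  expect_identical(noisy1$network, noisy2$network)
})

test_that("the returned network is exactly the topology the integrator used", {
  sim <- simulate_grn(n_genes = 10, topology_seed = 11, dynamics_seed = 12, noise_seed = 13)
  adj <- sim$params$adjacency
  edges <- which(adj != 0, arr.ind = TRUE)
  expect_setequal(
    paste(rownames(adj)[edges[, 1]], colnames(adj)[edges[, 2]]),
    paste(sim$network$from, sim$network$to)
  )

  reachable_from <- function(adj, start) {
    seen <- start
    frontier <- start
    while (length(frontier) > 0) {
      nxt <- unique(unlist(lapply(frontier, function(s) which(adj[s, ] != 0))))
      frontier <- setdiff(nxt, seen)
      seen <- union(seen, frontier)
    }
    seen
  }

  # intervention: deleting a real edge changes its target (and only genes
  # downstream of the target can change)
  e <- which(adj != 0, arr.ind = TRUE)[1, ]
  adj2 <- adj
  adj2[e[1], e[2]] <- 0L
  sim2 <- simulate_grn(
    n_genes = 10, topology_seed = 11, dynamics_seed = 12, noise_seed = 13,
    adjacency = adj2
  )
  tgt <- e[2]
  genes <- names(sim$expression)[-1]
  expect_false(isTRUE(all.equal(sim$expression[[genes[tgt]]], sim2$expression[[genes[tgt]]])))
  frozen <- setdiff(seq_along(genes), reachable_from(adj, tgt))
  for (g in frozen) {
    expect_equal(sim2$expression[[genes[g]]], sim$expression[[genes[g]]], tolerance = 1e-12)
  }

  # intervention on a non-edge: nothing changes
  non <- which(adj == 0 & row(adj) != col(adj), arr.ind = TRUE)[1, ]
  adj3 <- adj
  adj3[non[1], non[2]] <- 0L # already zero; explicit no-op intervention
  sim3 <- simulate_grn(
    n_genes = 10, topology_seed = 11, dynamics_seed = 12, noise_seed = 13,
    adjacency = adj3
  )
  expect_equal(sim3$expression, sim$expression, tolerance = 1e-14)
})

test_that("without edges every gene relaxes along the closed-form solution", {
  sim <- simulate_grn(
    n_genes = 6, mean_in_degree = 0,
    topology_seed = 1, dynamics_seed = 2, noise_seed = 3
  )
  expect_equal(nrow(sim$network), 0)
  m <- sim$params$m_max
  x0 <- sim$params$x0
  t <- sim$expression$time
  for (g in seq_len(6)) {
    closed <- m[g] + (x0[g] - m[g]) * exp(-t)
    expect_equal(sim$expression[[g + 1]], closed, tolerance = 1e-7)
  }
})

test_that("additive noise has the advertised per-variable scale", {
  clean <- matrix(c(rnorm(1e5, sd = 2), rnorm(1e5, sd = 0.3)), ncol = 2)
  noisy <- add_noise(clean, level = 0.1, seed = 99)
  resid_sd <- apply(noisy - clean, 2, sd)
  expect_equal(resid_sd / apply(clean, 2, sd), c(0.1, 0.1), tolerance = 0.02)

  sim <- simulate_logistic(10)
  expect_identical(add_noise(sim, level = 0), sim)
  expect_identical(add_noise(sim, 0.1, seed = 4), add_noise(sim, 0.1, seed = 4))
})
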