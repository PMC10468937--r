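make_small_setup <- function(case = "C", m = 21L) {
  conn <- tiny_connectome()
  list(conn = conn, params = scenario_params(case), grid = a_grid(m),
       seed = seed_indicator(conn$parcellation))
}

test_that("initialization yields a healthy brain", {
  s <- make_small_setup()
  st <- initialize_state(s$params, s$conn$parcellation, s$conn$connectivity,
                         s$conn$proximity, s$grid)
  expect_equal(st$t, 0)
  expect_equal(st$u[, 1], rep(0.01, 3))
  expect_equal(sum(st$u[, 2:5]), 0)
  expect_equal(sum(st$tau), 0)
  A0 <- mean_malfunction(st$f, s$grid)
  expect_true(all(abs(A0 - A0[1]) < 1e-15))
  expect_lt(max(abs(A0 - 0.01)), 2 * s$grid$da)
  expect_equal(rowSums(st$f) * s$grid$da, rep(1, 3))

  # seeding active with an empty seed set is rejected
  parc0 <- parcellation(paste0("n", 1:3), c("a", "b", "b"))
  expect_error(
    initialize_state(s$params, parc0, s$conn$connectivity,
                     s$conn$proximity, s$grid),
    "seed set is empty")
})

test_that("a zero-dynamics configuration leaves the state unchanged", {
  s <- make_small_setup()
  p <- s$params
  p$alpha <- 0; p$C_tau <- 0; p$c <- 0
  p$sigma <- rep(0, 4); p$C_F <- 0
  p$C_G <- 0; p$C_S <- 0; p$C_T <- 0
  st <- initialize_state(p, s$conn$parcellation, s$conn$connectivity,
                         s$conn$proximity, s$grid)
  st2 <- sim_step(st, s$conn$connectivity, s$conn$proximity, p, s$seed,
                  s$grid, dt = 0.05)
  # uniform monomers: diffusion also contributes nothing
  expect_equal(st2$u, st$u, tolerance = 1e-14)
  expect_equal(st2$tau, st$tau)
  expect_equal(st2$f, st$f)
  expect_equal(st2$t, 0.05)
})

test_that("engine trajectory matches the monolithic method-of-lines oracle", {
  skip_if_not_installed("deSolve")
  s <- make_small_setup("C")
  orc <- monolithic_oracle(s$conn, s$params, s$grid, t_end = 2)
  traj <- run_simulation(
    sim_config(case = "C", t_end = 2, a_cells = 21L, sample_dt = 1),
    connectome = s$conn)
  st <- traj$final_state
  relLinf <- function(a, b) max(abs(a - b)) / max(abs(b))
  expect_lt(relLinf(st$u, orc$u), 1e-3)
  expect_lt(relLinf(st$tau, orc$tau), 1e-3)
  expect_lt(relLinf(st$f, orc$f), 1e-3)
})

test_that("symmetry: vertex-transitive graph with uniform data stays uniform", {
  # ring with uniform weights for both graphs, all nodes seeded
  n <- 6
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    W[i, i %% n + 1] <- 1
    W[i %% n + 1, i] <- 1
  }
  parc <- parcellation(paste0("n", 1:n), rep("all", n), seed_nodes = 1:n)
  conn <- list(parcellation = parc, connectivity = weighted_graph(W),
               proximity = weighted_graph(W))
  traj <- run_simulation(
    sim_config(case = "C", t_end = 3, a_cells = 16L, sample_dt = 1),
    connectome = conn)
  st <- traj$final_state
  expect_lt(max(abs(sweep(st$u, 2, st$u[1, ]))), 1e-12)
  expect_lt(max(abs(sweep(st$tau, 2, st$tau[1, ]))), 1e-12)
  expect_lt(max(abs(sweep(st$f, 2, st$f[1, ]))), 1e-12)
})

test_that("run invariants: positivity, monotone damage and aggregates, mass", {
  syn <- synthesize_connectome(12, 3, rng_seed = 2)
  traj <- run_simulation(
    sim_config(case = "C", t_end = 8, a_cells = 31L, sample_dt = 0.5,
               n_nodes = 12L, n_regions = 3L, rng_seed = 2L),
    connectome = syn)
  expect_true(all(traj$u_global >= 0))
  expect_true(all(traj$tau_global >= 0))
  expect_lt(traj$f_mass_drift, 1e-10)
  # A(x_m, t), plaques and tangles nondecreasing per node/compartment
  expect_true(all(diff(traj$A_node) >= -1e-12))
  expect_true(all(diff(traj$u_global[, 5]) >= -1e-14))
  expect_true(all(diff(traj$tau_global[, 5]) >= -1e-14))
  # sample times strictly increasing
  expect_true(all(diff(traj$times) > 0))
})

test_that("scenario nulls propagate through full runs", {
  syn <- synthesize_connectome(8, 3, rng_seed = 4)
  cfgA <- sim_config(case = "A", t_end = 4, a_cells = 16L, n_nodes = 8L,
                     n_regions = 3L, rng_seed = 4L)
  tA <- run_simulation(cfgA, connectome = syn)
  expect_equal(max(abs(tA$final_state$tau)), 0)
  expect_equal(max(tA$tau_global), 0)

  cfgE <- sim_config(case = "E", t_end = 4, a_cells = 16L, n_nodes = 8L,
                     n_regions = 3L, rng_seed = 4L)
  tE <- run_simulation(cfgE, connectome = syn)
  expect_equal(max(abs(tE$final_state$u[, 2:5])), 0)
  expect_equal(max(tE$u_global[, 2:5]), 0)
})

test_that("runs are deterministic given config and seed", {
  cfg <- sim_config(case = "B", t_end = 3, a_cells = 16L, n_nodes = 8L,
                    n_regions = 3L, rng_seed = 9L)
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  expect_identical(t1$final_state, t2$final_state)
  expect_identical(t1$A_global, t2$A_global)
  expect_identical(t1$meta$connectome_hash, t2$meta$connectome_hash)
})

test_that("operator splitting error shrinks with the step size", {
  skip_if_not_installed("deSolve")
  s <- make_small_setup("C", m = 16L)
  orc <- monolithic_oracle(s$conn, s$params, s$grid, t_end = 1)
  err <- sapply(c(1, 0.5), function(scale) {
    traj <- run_simulation(
      sim_config(case = "C", t_end = 1, a_cells = 16L, sample_dt = 1,
                 dt_scale = scale),
      connectome = s$conn)
    st <- traj$final_state
    max(abs(st$f - orc$f)) / max(abs(orc$f))
  })
  expect_lt(err[2], 0.75 * err[1])
})
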