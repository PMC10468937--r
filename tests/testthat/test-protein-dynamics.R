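test_that("coagulation gain matches hand expansions and brute-force enumeration", {
  expect_equal(coagulation_gain(rep(0, 5), 3), rep(0, 5))
  expect_equal(coagulation_gain(c(1, 0, 0, 0, 0), 2), c(0, 1, 0, 0, 0))
  expect_equal(coagulation_gain(c(1, 1, 1, 1, 0), 2), c(0, 1, 2, 3, 10))
  set.seed(21)
  for (k in 1:20) {
    conc <- runif(5, 0, 2)
    rate <- runif(1, 0, 5)
    expect_equal(coagulation_gain(conc, rate), gain_oracle(conc, rate),
                 tolerance = 1e-13)
  }
  # matrix form agrees with rowwise vector form
  u <- matrix(runif(20), 4, 5)
  expect_equal(coagulation_gain(u, 1.5),
               t(apply(u, 1, coagulation_gain, rate = 1.5)))
  expect_error(coagulation_gain(c(-1, 0, 0, 0, 0), 1), "nonnegative")
})

test_that("coagulation loss consumes soluble species by the full total", {
  expect_equal(coagulation_loss(c(2, 0, 0, 0, 0), 3), c(12, 0, 0, 0, 0))
  expect_equal(coagulation_loss(rep(0, 5), 1), rep(0, 5))
  # plaques contribute to the total but are themselves exempt
  expect_equal(coagulation_loss(c(1, 1, 1, 1, 1), 1), c(5, 5, 5, 5, 0))
  set.seed(22)
  for (k in 1:10) {
    conc <- runif(5)
    expect_equal(coagulation_loss(conc, 2), loss_oracle(conc, 2),
                 tolerance = 1e-13)
  }
})

test_that("the entorhinal seeding pulse has the Gamma shape", {
  expect_equal(tau_seed_source(0, 10), 0)
  expect_equal(tau_seed_source(10, 10), exp(-1))
  expect_equal(tau_seed_source(7, 7), exp(-1))
  expect_gt(tau_seed_source(10, 10), tau_seed_source(50, 10))
  expect_lt(tau_seed_source(1e6, 10), 1e-10)
  # maximum at t = lambda
  tt <- seq(0, 100, by = 0.1)
  expect_equal(tt[which.max(tau_seed_source(tt, 10))], 10)
})

test_that("amyloid-induced tau production is threshold-gated on oligomers", {
  expect_equal(abeta_induced_production(c(5, 0, 0, 0, 5), 10, 0.001), 0)
  expect_equal(abeta_induced_production(runif(5), 0, 0.001), 0)
  expect_equal(
    abeta_induced_production(c(0.5, 0.002, 0.001, 0.001, 0.9), 10, 0.001),
    0.03)
  # monomers and plaques do not count
  expect_equal(abeta_induced_production(c(9, 0.01, 0, 0, 9), 1, 0.001),
               abeta_induced_production(c(0, 0.01, 0, 0, 0), 1, 0.001))
})

test_that("amyloid RHS matches hand cases and the triple-loop oracle", {
  p <- scenario_params("C")
  # single node: no diffusion, alpha = 0 -> pure clearance of monomers
  p0 <- p; p0$alpha <- 0
  g1 <- weighted_graph(matrix(c(0, 1, 1, 0), 2, 2))
  u <- matrix(0, 2, 5); u[, 1] <- 0.3
  du <- abeta_rhs(u, g1, p0, production = rep(0, 2))
  expect_equal(du[, 1], rep(-p0$sigma[1] * 0.3 / p0$epsilon, 2))

  # zero state, zero production -> zero derivative
  expect_equal(abeta_rhs(matrix(0, 2, 5), g1, p, rep(0, 2)),
               matrix(0, 2, 5))

  # spatially uniform field on a connected graph: diffusion contributes 0,
  # so a single-node computation reproduces every node
  set.seed(31)
  W <- random_graph_matrix(5)
  gr <- weighted_graph(W)
  uu <- matrix(rep(runif(5), each = 5), 5, 5)
  du2 <- abeta_rhs(uu, gr, p, rep(0.2, 5))
  expect_equal(du2, abeta_rhs_oracle(uu, W, p, rep(0.2, 5)),
               tolerance = 1e-12)
  expect_equal(max(abs(sweep(du2, 2, du2[1, ]))), 0)

  for (n in c(3, 7, 10)) {
    W <- random_graph_matrix(n)
    u <- matrix(runif(n * 5), n, 5)
    prod <- runif(n)
    got <- abeta_rhs(u, weighted_graph(W), p, prod)
    want <- abeta_rhs_oracle(u, W, p, prod)
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-12)
  }
  expect_error(abeta_rhs(matrix(0, 3, 5), g1, p, rep(0, 3)), "nodes")
})

test_that("tau RHS matches hand cases and the triple-loop oracle", {
  p <- scenario_params("C")
  g1 <- weighted_graph(matrix(c(0, 1, 1, 0), 2, 2))

  # case A: no seeding, no induced production, zero tau -> identically zero
  pA <- scenario_params("A")
  expect_equal(tau_rhs(matrix(0, 2, 5), matrix(0, 2, 5), g1, pA,
                       t = 3, seed = c(1, 0)),
               matrix(0, 2, 5))

  # seed-node source at t = lambda: c * exp(-1)
  dtau <- tau_rhs(matrix(0, 2, 5), matrix(0, 2, 5), g1, p,
                  t = p$lambda, seed = c(1, 0))
  expect_equal(dtau[, 1], c(0.05 * exp(-1), 0))
  expect_equal(dtau[, 2:5], matrix(0, 2, 4))

  # production localized where oligomers exceed the threshold
  u <- matrix(0, 2, 5); u[2, 2] <- 0.1
  dtau2 <- tau_rhs(matrix(0, 2, 5), u, g1, p, t = 0, seed = c(0, 0))
  expect_equal(dtau2[, 1], c(0, p$C_tau * (0.1 - p$U_bar)))

  set.seed(33)
  for (n in c(4, 8)) {
    W <- random_graph_matrix(n)
    tau <- matrix(runif(n * 5), n, 5)
    u <- matrix(runif(n * 5, 0, 0.1), n, 5)
    seed <- as.numeric(runif(n) < 0.3)
    got <- tau_rhs(tau, u, weighted_graph(W), p, t = 2.5, seed = seed)
    want <- tau_rhs_oracle(tau, u, W, p, t = 2.5, seed = seed)
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-12)
  }
})

test_that("scenario nulls hold at the RHS level", {
  # alpha = 0 with no oligomers: compartments 2..5 stay identically zero
  pE <- scenario_params("E")
  g <- weighted_graph(matrix(c(0, 2, 2, 0), 2, 2))
  u <- matrix(0, 2, 5); u[, 1] <- runif(2)
  du <- abeta_rhs(u, g, pE, production = runif(2))
  expect_equal(du[, 2:5], matrix(0, 2, 4))

  # plaque and tangle equations are gain-only: derivatives never negative
  p <- scenario_params("C")
  set.seed(44)
  for (k in 1:10) {
    u <- matrix(runif(10), 2, 5)
    tau <- matrix(runif(10), 2, 5)
    expect_gte(min(abeta_rhs(u, g, p, runif(2))[, 5]), 0)
    expect_gte(min(tau_rhs(tau, u, g, p, t = 1, seed = c(1, 0))[, 5]), 0)
  }
})

test_that("pure diffusion conserves the pi-weighted mass in the RHS", {
  # alpha = sigma = F = 0: d/dt sum_m pi_m u_i(x_m) = 0 for each compartment
  p <- scenario_params("C")
  p$alpha <- 0
  p$sigma <- rep(0, 4)
  set.seed(55)
  W <- random_graph_matrix(6)
  g <- weighted_graph(W)
  u <- matrix(runif(30), 6, 5)
  du <- abeta_rhs(u, g, p, production = rep(0, 6))
  for (i in 1:4) expect_lt(abs(sum(g$pi * du[, i])), 1e-12)
})
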