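# Independent oracles: direct transcriptions of the model equations using
# plain loops, kept deliberately separate from the vectorised implementation.

# Graph Laplacian by double loop.
laplacian_oracle <- function(W, g) {
  n <- nrow(W)
  out <- numeric(n)
  for (m in seq_len(n)) {
    pim <- sum(W[m, ])
    acc <- 0
    for (j in seq_len(n)) acc <- acc + (g[m] - g[j]) * W[m, j]
    out[m] <- acc / pim
  }
  out
}

# Coagulation gain by brute-force enumeration of ordered index pairs.
gain_oracle <- function(conc, rate) {
  g <- numeric(5)
  for (i in 2:4) {
    for (j in seq_len(i - 1)) g[i] <- g[i] + conc[j] * conc[i - j]
  }
  for (j in 1:4) for (k in 1:4) {
    if (j + k >= 5) g[5] <- g[5] + conc[j] * conc[k]
  }
  rate / 2 * g
}

loss_oracle <- function(conc, rate) {
  l <- numeric(5)
  total <- sum(conc)
  for (i in 1:4) l[i] <- rate * conc[i] * total
  l
}

# Naive per-node transcription of the full amyloid right-hand side.
abeta_rhs_oracle <- function(u, W, params, production) {
  n <- nrow(u)
  du <- matrix(0, n, 5)
  for (m in seq_len(n)) {
    pim <- sum(W[m, ])
    lap <- numeric(4)
    for (i in 1:4) {
      for (j in seq_len(n)) lap[i] <- lap[i] + (u[m, i] - u[j, i]) * W[m, j]
      lap[i] <- lap[i] / pim
    }
    g <- gain_oracle(u[m, ], params$alpha)
    l <- loss_oracle(u[m, ], params$alpha)
    du[m, 1] <- -params$d[1] * lap[1] - l[1] - params$sigma[1] * u[m, 1] +
      production[m]
    for (i in 2:4)
      du[m, i] <- -params$d[i] * lap[i] + g[i] - l[i] -
        params$sigma[i] * u[m, i]
    du[m, 5] <- g[5]
  }
  du / params$epsilon
}

# Naive per-node transcription of the full tau right-hand side.
tau_rhs_oracle <- function(tau, u, W, params, t, seed) {
  n <- nrow(tau)
  dtau <- matrix(0, n, 5)
  s_t <- (t / params$lambda) * exp(-t / params$lambda)
  for (m in seq_len(n)) {
    pim <- sum(W[m, ])
    lap <- numeric(4)
    for (i in 1:4) {
      for (j in seq_len(n)) lap[i] <- lap[i] + (tau[m, i] - tau[j, i]) * W[m, j]
      lap[i] <- lap[i] / pim
    }
    g <- gain_oracle(tau[m, ], params$gamma)
    l <- loss_oracle(tau[m, ], params$gamma)
    olig <- u[m, 2] + u[m, 3] + u[m, 4]
    dtau[m, 1] <- -params$d_tilde[1] * lap[1] - l[1] +
      params$c * s_t * seed[m] +
      params$C_tau * max(olig - params$U_bar, 0)
    for (i in 2:4)
      dtau[m, i] <- -params$d_tilde[i] * lap[i] + g[i] - l[i]
    dtau[m, 5] <- g[5]
  }
  dtau
}

# Small random symmetric weight matrix with positive row sums.
random_graph_matrix <- function(n, density = 0.6) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < density) W[i, j] <- W[j, i] <- stats::runif(1, 0.1, 2)
  }
  # guarantee positive totals: chain backbone
  for (i in seq_len(n - 1)) if (W[i, i + 1] == 0) W[i, i + 1] <- W[i + 1, i] <- 0.5
  W
}

# Monolithic method-of-lines integration of the full coupled system with
# deSolve: every equation (proteins and the semi-discretised transport) is
# stacked into one state vector and integrated jointly, with the
# deterioration rate and production recomputed continuously -- independent
# of the engine's operator splitting.
monolithic_oracle <- function(connectome, params, grid, t_end, u01 = 0.01,
                              a0 = 0.01,
                              f0_width = max(0.03, 3 * grid$da),
                              times = NULL) {
  parc <- connectome$parcellation
  We <- connectome$connectivity$W
  Wf <- connectome$proximity$W
  n <- parc$n
  m <- grid$m
  seed <- as.numeric(seq_len(n) %in% parc$seed_nodes)
  f0 <- initial_density(grid, center = a0, width = f0_width)
  y0 <- c(rep(c(u01, 0, 0, 0, 0), each = n), rep(0, n * 5),
          rep(f0, each = n))
  idx_u <- 1:(5 * n)
  idx_tau <- (5 * n) + 1:(5 * n)
  idx_f <- (10 * n) + 1:(n * m)
  wq <- (params$mu0 + grid$centers) * (1 - grid$centers) * grid$da
  deriv <- function(t, y, parms) {
    u <- matrix(y[idx_u], n, 5)
    tau <- matrix(y[idx_tau], n, 5)
    f <- matrix(y[idx_f], n, m)
    Ff <- as.numeric(C_F_ <- params$C_F * (f %*% wq))
    du <- abeta_rhs_oracle(u, Wf, params, Ff)
    dtau <- tau_rhs_oracle(tau, u, We, params, t, seed)
    df <- matrix(0, n, m)
    for (node in seq_len(n)) {
      olig <- sum(u[node, 2:4])
      ts <- sum(tau[node, ])
      v <- numeric(m + 1)
      for (e in seq_len(m + 1)) {
        ae <- grid$interfaces[e]
        v[e] <- params$C_G *
          sum(pmax(grid$centers - ae, 0) * f[node, ]) * grid$da +
          params$C_S * (1 - ae) * max(olig - params$U_bar_abeta, 0) +
          params$C_T * (1 - ae) * max(ts - params$U_bar_tau, 0)
      }
      # MC-limited second-order upwind face values (semi-discrete)
      fn <- f[node, ]
      sl <- numeric(m)
      for (k in 2:(m - 1)) {
        a1 <- fn[k] - fn[k - 1]; b1 <- fn[k + 1] - fn[k]
        if (a1 * b1 > 0)
          sl[k] <- sign(a1) * min(2 * abs(a1), 2 * abs(b1),
                                  0.5 * abs(a1 + b1))
      }
      flux <- c(0, v[2:(m + 1)] * (fn + 0.5 * sl))  # zero inflow
      df[node, ] <- -(flux[2:(m + 1)] - flux[1:m]) / grid$da
    }
    list(c(as.numeric(du), as.numeric(dtau), as.numeric(df)))
  }
  if (is.null(times)) times <- c(0, t_end)
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-9, atol = 1e-11)
  last <- sol[nrow(sol), -1]
  list(u = matrix(last[idx_u], n, 5),
       tau = matrix(last[idx_tau], n, 5),
       f = matrix(last[idx_f], n, m),
       sol = sol)
}

# Tiny hand-made connectome: 3 nodes, triangle connectivity, path proximity,
# node 1 is the seed region.
tiny_connectome <- function() {
  We <- matrix(c(0, 1, 0.5,
                 1, 0, 1,
                 0.5, 1, 0), 3, 3)
  Wf <- matrix(c(0, 1, 0,
                 1, 0, 1,
                 0, 1, 0), 3, 3)
  parc <- parcellation(paste0("n", 1:3),
                       c("entorhinal", "other", "other"),
                       seed_nodes = 1L)
  list(parcellation = parc,
       connectivity = weighted_graph(We, paste0("n", 1:3)),
       proximity = weighted_graph(Wf, paste0("n", 1:3)))
}
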