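#' @name protein_dynamics
#' @title Smoluchowski coagulation terms for the five-compartment systems
#'
#' @description
#' Both proteins are tracked in five compartments per parcel: monomers,
#' dimers, short proto-oligomers, long oligomers, and the insoluble fifth
#' compartment (amyloid plaques, neurofibrillary tangles).  Binary
#' coalescence `P_j + P_k -> P_{j+k}` moves mass up the ladder; any merger
#' reaching length five or more lands in the insoluble pool, which neither
#' diffuses nor clears.
NULL

# Accepts a 5-vector (one node) or an N x 5 matrix; returns the same shape.
as_conc_matrix <- function(conc) {
  if (is.null(dim(conc))) {
    if (length(conc) != 5L)
      stop("concentration vector must have 5 compartments", call. = FALSE)
    matrix(conc, ncol = 5L)
  } else {
    if (ncol(conc) != 5L)
      stop("concentration matrix must have 5 columns", call. = FALSE)
    conc
  }
}

#' Coagulation gain terms
#'
#' Gain into compartment `i` from mergers of smaller polymers:
#' `gain_1 = 0`; `gain_i = (rate/2) * sum_{j=1}^{i-1} c_j c_{i-j}` for
#' `i = 2..4`; the insoluble pool gains
#' `(rate/2) * sum over ordered pairs j,k <= 4 with j+k >= 5 of c_j c_k`.
#'
#' @param conc nonnegative 5-vector or N x 5 matrix of concentrations.
#' @param rate coalescence probability (`alpha` for amyloid, `gamma` for
#'   tau).
#' @return same shape as `conc`.
#' @export
coagulation_gain <- function(conc, rate) {
  vec <- is.null(dim(conc))
  u <- as_conc_matrix(conc)
  if (any(u < 0) || rate < 0)
    stop("concentrations and rate must be nonnegative", call. = FALSE)
  h <- rate / 2
  g <- matrix(0, nrow(u), 5L)
  g[, 2L] <- h * u[, 1L]^2
  g[, 3L] <- h * 2 * u[, 1L] * u[, 2L]
  g[, 4L] <- h * (2 * u[, 1L] * u[, 3L] + u[, 2L]^2)
  g[, 5L] <- h * (2 * u[, 1L] * u[, 4L] + 2 * u[, 2L] * u[, 3L] +
                  2 * u[, 2L] * u[, 4L] + u[, 3L]^2 +
                  2 * u[, 3L] * u[, 4L] + u[, 4L]^2)
  if (vec) drop(g) else g
}

#' Coagulation loss terms
#'
#' Soluble compartments `i = 1..4` are consumed at
#' `rate * c_i * (c_1 + ... + c_5)`; the total includes the insoluble pool
#' (plaques and tangles keep scavenging soluble polymers), while the
#' insoluble compartment itself has no loss term.
#'
#' @inheritParams coagulation_gain
#' @return same shape as `conc`.
#' @export
coagulation_loss <- function(conc, rate) {
  vec <- is.null(dim(conc))
  u <- as_conc_matrix(conc)
  if (any(u < 0) || rate < 0)
    stop("concentrations and rate must be nonnegative", call. = FALSE)
  total <- rowSums(u)
  l <- rate * u * total
  l[, 5L] <- 0
  if (vec) drop(l) else l
}

#' Gamma-shaped entorhinal seeding pulse
#'
#' Time profile `s(t) = (t/lambda) * exp(-t/lambda)` of spontaneous
#' misfolded-tau monomer production in the seed region: it rises, peaks at
#' `t = lambda` (value `exp(-1)`) and decays as the pool of cleavable
#' physiological tau shrinks with neuronal loss.  The per-node source is
#' `c * s(t) * seed_indicator`.
#'
#' @param t time (vectorised).
#' @param lambda seeding time scale, > 0.
#' @return numeric, same length as `t`.
#' @export
tau_seed_source <- function(t, lambda) {
  stopifnot(lambda > 0)
  (t / lambda) * exp(-t / lambda)
}

#' Amyloid-oligomer-induced tau misfolding
#'
#' Production of misfolded tau monomers driven by toxic amyloid oligomers:
#' `C_tau * (u_2 + u_3 + u_4 - U_bar)^+`.  Only the soluble oligomeric
#' compartments 2..4 count; monomers and plaques are not toxic here, and
#' below the threshold `U_bar` no misfolding is induced.
#'
#' @param u nonnegative 5-vector or N x 5 matrix of amyloid concentrations.
#' @param C_tau production constant.
#' @param U_bar oligomer threshold.
#' @return scalar (vector input) or length-N vector.
#' @export
abeta_induced_production <- function(u, C_tau, U_bar) {
  u <- as_conc_matrix(u)
  drop(C_tau * pmax(u[, 2L] + u[, 3L] + u[, 4L] - U_bar, 0))
}

#' Time derivatives of the amyloid-beta system
#'
#' Assembles the right-hand side of the amyloid equations on the proximity
#' graph.  Monomers diffuse, aggregate, clear, and are produced at rate
#' `production` (the health-dependent source, see [amyloid_production()]);
#' oligomers additionally gain from coagulation; plaques only gain.  The
#' whole right-hand side is divided by the time-scale ratio `epsilon`, so
#' the integrator sees plain derivatives.
#'
#' @param u N x 5 amyloid concentrations.
#' @param proximity proximity-graph [weighted_graph()].
#' @param params [model_params()] with scenario constants set.
#' @param production length-N nonnegative vector of monomer production.
#' @return N x 5 matrix `du/dt`.
#' @export
abeta_rhs <- function(u, proximity, params, production) {
  if (nrow(u) != proximity$n)
    stop("state has ", nrow(u), " nodes but graph has ", proximity$n,
         call. = FALSE)
  gain <- coagulation_gain(u, params$alpha)
  loss <- coagulation_loss(u, params$alpha)
  lap <- proximity$L %*% u[, 1:4, drop = FALSE]
  du <- matrix(0, nrow(u), 5L)
  du[, 1L] <- -params$d[1L] * lap[, 1L] - loss[, 1L] -
    params$sigma[1L] * u[, 1L] + production
  for (i in 2:4)
    du[, i] <- -params$d[i] * lap[, i] + gain[, i] - loss[, i] -
      params$sigma[i] * u[, i]
  du[, 5L] <- gain[, 5L]
  du / params$epsilon
}

#' Time derivatives of the misfolded-tau system
#'
#' Assembles the right-hand side of the tau equations on the connectivity
#' graph.  Misfolded monomers diffuse along neural connections, aggregate,
#' and are produced by the Gamma-shaped entorhinal seeding pulse
#' (`c * s(t)` on the seed set) and by toxic amyloid oligomers
#' ([abeta_induced_production()]).  The tau system has no clearance term
#' and carries no `epsilon` factor: it evolves on the slow disease time
#' scale.
#'
#' @param tau N x 5 misfolded-tau concentrations.
#' @param u N x 5 amyloid concentrations (drives induced production).
#' @param connectivity connectivity-graph [weighted_graph()].
#' @param params [model_params()] with scenario constants set.
#' @param t current time.
#' @param seed length-N 0/1 indicator of the entorhinal seed set.
#' @return N x 5 matrix `dtau/dt`.
#' @export
tau_rhs <- function(tau, u, connectivity, params, t, seed) {
  if (nrow(tau) != connectivity$n)
    stop("state has ", nrow(tau), " nodes but graph has ", connectivity$n,
         call. = FALSE)
  gain <- coagulation_gain(tau, params$gamma)
  loss <- coagulation_loss(tau, params$gamma)
  lap <- connectivity$L %*% tau[, 1:4, drop = FALSE]
  dtau <- matrix(0, nrow(tau), 5L)
  dtau[, 1L] <- -params$d_tilde[1L] * lap[, 1L] - loss[, 1L] +
    params$c * tau_seed_source(t, params$lambda) * seed +
    abeta_induced_production(u, params$C_tau, params$U_bar)
  for (i in 2:4)
    dtau[, i] <- -params$d_tilde[i] * lap[, i] + gain[, i] - loss[, i]
  dtau[, 5L] <- gain[, 5L]
  dtau
}
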