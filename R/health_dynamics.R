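#' Uniform grid on the malfunction coordinate
#'
#' The per-neuron health state is a coordinate `a` on `[0, 1]` (0 = healthy,
#' 1 = dead).  Its probability density per parcel is discretised as cell
#' averages on `M` uniform cells.  The grid stores cell centres, interface
#' positions, and the precomputed prion-influence quadrature kernel
#' `K[k, e] = (a_k - a_e)^+ * da` used by [deterioration_rate()].
#'
#' @param n_cells number of cells `M` (at least 8; default 101).
#' @return object of class `adsim_agrid` with `m`, `da`, `centers`
#'   (length M), `interfaces` (length M + 1).
#' @export
a_grid <- function(n_cells = 101L) {
  m <- as.integer(n_cells)
  if (m < 8L) stop("need at least 8 cells on [0,1]", call. = FALSE)
  da <- 1 / m
  centers <- (seq_len(m) - 0.5) * da
  interfaces <- (0:m) * da
  K <- pmax(outer(centers, interfaces, "-"), 0) * da
  structure(list(m = m, da = da, centers = centers, interfaces = interfaces,
                 prion_kernel = K),
            class = "adsim_agrid")
}

#' Near-delta initial health density
#'
#' A healthy brain starts with (almost) all probability mass near `a = 0`:
#' a normalized triangular bump approximating a Dirac delta centred at a
#' small `center`, truncated at the domain boundary.
#'
#' @param grid an [a_grid()].
#' @param center bump centre `a0`, with `0 <= a0 < 0.1` (default 0.01).
#' @param width bump half-width; must be at least one cell (default three
#'   cells) so the spike is resolvable.
#' @return length-M density row with `sum(f) * da == 1`.
#' @export
initial_density <- function(grid, center = 0.01, width = 3 * grid$da) {
  stopifnot(inherits(grid, "adsim_agrid"))
  if (center < 0 || center >= 0.1)
    stop("center must satisfy 0 <= center < 0.1", call. = FALSE)
  if (width < grid$da)
    stop("width below one cell: the spike is unresolvable at this grid",
         call. = FALSE)
  f <- pmax(1 - abs(grid$centers - center) / width, 0)
  f / (sum(f) * grid$da)
}

#' Health-dependent amyloid monomer production
#'
#' Midpoint quadrature of
#' `F(f) = C_F * integral (mu0 + a) (1 - a) f(a) da`: a healthy parcel
#' (all mass at `a = 0`) produces at the baseline rate `C_F * mu0`,
#' malfunctioning neurons overproduce (`+ a` factor), and dead neurons
#' (`a = 1`) release nothing.
#'
#' @param f length-M density row, or N x M matrix of densities.
#' @param grid an [a_grid()].
#' @param C_F production constant.
#' @param mu0 healthy baseline rate.
#' @return scalar, or length-N vector for matrix input.
#' @export
amyloid_production <- function(f, grid, C_F, mu0) {
  w <- (mu0 + grid$centers) * (1 - grid$centers) * grid$da
  if (is.null(dim(f))) sum(f * w) * C_F else drop(C_F * (f %*% w))
}

#' Deterioration rate at cell interfaces
#'
#' The drift `v(a) >= 0` of the malfunction coordinate combines a
#' prion-like influence of already-malfunctioning neighbours in the same
#' parcel, `C_G * integral (b - a)^+ f(b) db`, with threshold-gated
#' toxicity of soluble amyloid oligomers (compartments 2..4) and of total
#' misfolded tau (compartments 1..5), each damped by `(1 - a)`.  Every term
#' vanishes at `a = 1`, so the flux out of the last cell is analytically
#' zero and probability mass is conserved.
#'
#' @param f length-M density row or N x M matrix.
#' @param grid an [a_grid()].
#' @param oligomer_sum per-node `u_2 + u_3 + u_4` (scalar or length N).
#' @param tau_sum per-node `tau_1 + ... + tau_5` (scalar or length N).
#' @param params [model_params()].
#' @return interface velocities: length `M + 1` vector or N x (M + 1)
#'   matrix.
#' @export
deterioration_rate <- function(f, grid, oligomer_sum, tau_sum, params) {
  vec <- is.null(dim(f))
  if (vec) f <- matrix(f, nrow = 1L)
  tox <- params$C_S * pmax(oligomer_sum - params$U_bar_abeta, 0) +
    params$C_T * pmax(tau_sum - params$U_bar_tau, 0)
  v <- params$C_G * (f %*% grid$prion_kernel) +
    outer(tox, 1 - grid$interfaces)
  if (vec) drop(v) else v
}

#' Conservative upwind transport step
#'
#' Advances each parcel's health density by one explicit step of a
#' conservative upwind scheme for `d_t f + d_a(v f) = 0` with `v >= 0`:
#' `f_k <- f_k - (dt/da) * (F_{k+1/2} - F_{k-1/2})` with the
#' slope-limited second-order upwind flux
#' `F_{k+1/2} = v_{k+1/2} * (f_k + (1 - nu)/2 * s_k)`, where `s_k` is the
#' monotonized-central (MC) limited slope of `f` in cell `k` and
#' `nu = v * dt / da` the local Courant number.  At `nu = 1` the flux reduces to plain first-order
#' upwind (exact single-cell shift for uniform `v`).  The inflow flux at
#' `a = 0` is zero and the outflow flux at `a = 1` vanishes because
#' `v(1) = 0`, so total mass is conserved to round-off; the limiter keeps
#' the update total-variation-diminishing and nonnegativity-preserving
#' under the CFL condition `dt * max(v) / da <= 1`.
#'
#' @param f length-M density row or N x M matrix.
#' @param v interface velocities (length M + 1 or N x (M + 1)), `v >= 0`.
#' @param dt time step.
#' @param grid an [a_grid()].
#' @return updated density, same shape as `f`.
#' @export
transport_step <- function(f, v, dt, grid) {
  vec <- is.null(dim(f))
  if (vec) {
    f <- matrix(f, nrow = 1L)
    v <- matrix(v, nrow = 1L)
  }
  m <- grid$m
  if (ncol(f) != m || ncol(v) != m + 1L)
    stop("density/velocity shapes do not match the grid", call. = FALSE)
  if (any(v < 0)) stop("transport requires v >= 0", call. = FALSE)
  cfl <- dt * max(v) / grid$da
  if (cfl > 1 + 1e-12)
    stop("CFL violation (", format(cfl), " > 1): reduce dt", call. = FALSE)
  d <- f[, 2:m, drop = FALSE] - f[, 1:(m - 1L), drop = FALSE]
  dm <- cbind(0, d)                       # f_k - f_{k-1} (ghost: zero slope)
  dp <- cbind(d, 0)                       # f_{k+1} - f_k
  s <- (sign(dm) == sign(dp)) * sign(dm) *
    pmin(2 * abs(dm), 2 * abs(dp), 0.5 * abs(dm + dp))
  vr <- v[, 2:(m + 1L), drop = FALSE]     # right-face velocity of each cell
  nu <- vr * (dt / grid$da)
  flux <- vr * (f + 0.5 * (1 - nu) * s)   # upwind face value, left cell
  inflow <- cbind(0, flux[, 1:(m - 1L), drop = FALSE])  # zero at a = 0
  out <- f - (dt / grid$da) * (flux - inflow)
  if (vec) drop(out) else out
}

#' Mean degree of malfunction
#'
#' Local disease burden `A(x_m, t) = integral a f(x_m, a, t) da` by
#' midpoint quadrature; lies in `[0, 1]` for a normalized density.
#'
#' @param f length-M density row or N x M matrix.
#' @param grid an [a_grid()].
#' @return scalar or length-N vector.
#' @export
mean_malfunction <- function(f, grid) {
  w <- grid$centers * grid$da
  if (is.null(dim(f))) sum(f * w) else drop(f %*% w)
}
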