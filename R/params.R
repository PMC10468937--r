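#' Model parameters
#'
#' Container for every rate constant, threshold and scale of the
#' amyloid-beta/tau network model.  Diffusion coefficients `d` (amyloid,
#' proximity graph), `d_tilde` (tau, connectivity graph) and clearance rates
#' `sigma` (amyloid only) are length-4 vectors indexed by compartment
#' 1..4 (monomer, dimer, short proto-oligomer, long oligomer): the fifth
#' compartment — plaques and tangles — neither diffuses nor clears, so no
#' fifth coefficient exists.
#'
#' The three scenario constants `alpha` (amyloid coalescence probability),
#' `C_tau` (amyloid-oligomer-driven tau misfolding) and `c` (entorhinal tau
#' seeding amplitude) have no silent defaults: a run must name a scenario
#' case or set them explicitly.
#'
#' @param epsilon time-scale ratio between the fast amyloid kinetics and the
#'   slow disease progression (dimensionless, > 0).
#' @param alpha,C_tau,c scenario constants (see [scenario_params()]).
#' @param gamma tau coalescence probability.
#' @param lambda time scale of the Gamma-shaped entorhinal seeding pulse.
#' @param U_bar amyloid-oligomer threshold below which no tau misfolding is
#'   induced.
#' @param d,d_tilde,sigma length-4 compartment-indexed coefficient vectors,
#'   nonincreasing in compartment (longer oligomers move slower).
#' @param C_G prion-like propagation constant in the deterioration rate.
#' @param C_S,C_T amyloid and tau toxicity constants.
#' @param U_bar_abeta,U_bar_tau toxicity thresholds.
#' @param C_F,mu0 amyloid production constant and healthy baseline rate.
#' @return object of class `adsim_params`.
#' @export
model_params <- function(epsilon, alpha = NA_real_, gamma, c = NA_real_,
                         C_tau = NA_real_, lambda, U_bar,
                         d, d_tilde, sigma,
                         C_G, C_S, C_T, U_bar_abeta, U_bar_tau, C_F, mu0) {
  p <- list(epsilon = epsilon, alpha = alpha, gamma = gamma, c = c,
            C_tau = C_tau, lambda = lambda, U_bar = U_bar,
            d = d, d_tilde = d_tilde, sigma = sigma,
            C_G = C_G, C_S = C_S, C_T = C_T,
            U_bar_abeta = U_bar_abeta, U_bar_tau = U_bar_tau,
            C_F = C_F, mu0 = mu0)
  validate_params(p)
  structure(p, class = "adsim_params")
}

validate_params <- function(p, require_scenario = FALSE) {
  scal <- c("epsilon", "gamma", "lambda", "U_bar", "C_G", "C_S", "C_T",
            "U_bar_abeta", "U_bar_tau", "C_F", "mu0")
  for (k in scal) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("parameter '", k, "' must be a nonnegative number", call. = FALSE)
  }
  if (p$epsilon <= 0) stop("parameter 'epsilon' must be > 0", call. = FALSE)
  if (p$lambda <= 0) stop("parameter 'lambda' must be > 0", call. = FALSE)
  for (k in c("d", "d_tilde", "sigma")) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 4L || any(!is.finite(v)) || any(v < 0))
      stop("parameter '", k, "' must be 4 nonnegative numbers", call. = FALSE)
  }
  for (k in c("d", "d_tilde")) {
    if (any(diff(p[[k]]) > 1e-12))
      stop("parameter '", k, "' must be nonincreasing in compartment",
           call. = FALSE)
  }
  for (k in c("alpha", "C_tau", "c")) {
    v <- p[[k]]
    if (!is.na(v) && (!is.finite(v) || v < 0))
      stop("parameter '", k, "' must be nonnegative", call. = FALSE)
    if (require_scenario && is.na(v))
      stop("scenario constant '", k, "' is unset: name a case or set ",
           "alpha, C_tau and c explicitly", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.adsim_params <- function(x, ...) {
  cat("<adsim_params>\n")
  cat("  epsilon =", x$epsilon, " gamma =", x$gamma, " lambda =", x$lambda,
      "\n  alpha =", x$alpha, " C_tau =", x$C_tau, " c =", x$c,
      "\n  d = d_tilde = 1/i? ", isTRUE(all.equal(x$d, 1 / (1:4))),
      " sigma[1..4] =", paste(signif(x$sigma, 3), collapse = " "), "\n")
  invisible(x)
}

#' Fixed parameter defaults
#'
#' Returns the fixed parameter set used throughout the simulation study:
#' compartment-dependent diffusion and clearance `d_i = d~_i = sigma_i =
#' 1/i`, time-scale ratio `epsilon = 0.1`, tau coalescence `gamma = 4`,
#' seeding time scale `lambda = 10`, misfolding threshold `U_bar = 0.001`,
#' prion propagation `C_G = 0.1`, toxicities `C_S = C_T = 0.01` with
#' thresholds `0.001`, production `C_F = 10` with healthy baseline
#' `mu0 = 0.01`.  The scenario constants `alpha`, `C_tau`, `c` are left
#' unset (`NA`) until a scenario is applied.
#'
#' @return an [model_params()] object.
#' @export
default_params <- function() {
  model_params(
    epsilon = 0.1,
    gamma = 4,
    lambda = 10,
    U_bar = 0.001,
    d = 1 / (1:4),
    d_tilde = 1 / (1:4),
    sigma = 1 / (1:4),
    C_G = 0.1,
    C_S = 0.01,
    C_T = 0.01,
    U_bar_abeta = 0.001,
    U_bar_tau = 0.001,
    C_F = 10,
    mu0 = 0.01
  )
}

.scenario_table <- list(
  A = c(alpha = 10, C_tau = 0,  c = 0),
  B = c(alpha = 10, C_tau = 0,  c = 0.05),
  C = c(alpha = 10, C_tau = 10, c = 0.05),
  D = c(alpha = 10, C_tau = 10, c = 0),
  E = c(alpha = 0,  C_tau = 10, c = 0.05)
)

#' Scenario presets
#'
#' The five simulated cases differ only in the three constants controlling
#' amyloid agglomeration (`alpha`), amyloid-driven tau misfolding (`C_tau`)
#' and entorhinal tau seeding (`c`):
#'
#' | case | alpha | C_tau | c    | interpretation |
#' |------|-------|-------|------|----------------|
#' | A    | 10    | 0     | 0    | no tau sources: simplified amyloid cascade |
#' | B    | 10    | 0     | 0.05 | tau seeding only |
#' | C    | 10    | 10    | 0.05 | full synergy |
#' | D    | 10    | 10    | 0    | amyloid-driven tau, no seeding |
#' | E    | 0     | 10    | 0.05 | amyloid aggregation inhibited (drug-like) |
#'
#' @param case one of `"A".."E"`.
#' @return an [model_params()] object: the [default_params()] with the
#'   case's `alpha`, `C_tau`, `c` filled in.
#' @export
scenario_params <- function(case) {
  case <- as.character(case)
  if (length(case) != 1L || !case %in% names(.scenario_table))
    stop("unknown scenario case '", case, "' (expected A, B, C, D or E)",
         call. = FALSE)
  p <- default_params()
  s <- .scenario_table[[case]]
  p$alpha <- unname(s["alpha"])
  p$C_tau <- unname(s["C_tau"])
  p$c <- unname(s["c"])
  p
}

# Configuration keys, their defaults, and validation -------------------------

.config_defaults <- function() {
  list(
    case = "C",
    alpha = NULL, C_tau = NULL, c = NULL,   # explicit overrides of the case
    epsilon = NULL, gamma = NULL, lambda = NULL, U_bar = NULL,
    C_G = NULL, C_S = NULL, C_T = NULL,
    U_bar_abeta = NULL, U_bar_tau = NULL, C_F = NULL, mu0 = NULL,
    d = NULL, d_tilde = NULL, sigma = NULL,
    t_end = 50, u01 = 0.01, sample_dt = 0.5, dt_scale = 1,
    a_cells = 101L, a0 = 0.01, f0_width = 0.03,
    connectome = "synthetic", parcels = NULL,
    graph_format = "edge-list-csv", dialect = "strict",
    n_nodes = 64L, n_regions = 8L, rng_seed = 1L, k_nn = 4L
  )
}

#' Assemble a full run configuration
#'
#' Merges user settings over the documented defaults and validates them.
#' Scenario constants come from `case` (default `"C"`) unless `alpha`,
#' `C_tau` and `c` are all given explicitly.
#'
#' @param ... configuration keys (see [load_config()] for the full list).
#' @return list of class `adsim_config` with an `$params` element holding
#'   the resolved [model_params()].
#' @export
sim_config <- function(...) {
  user <- list(...)
  if (length(user) == 1L && is.list(user[[1]]) && is.null(names(user)))
    user <- user[[1]]
  defaults <- .config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- defaults
  for (k in names(user)) cfg[[k]] <- user[[k]]

  explicit <- !vapply(cfg[c("alpha", "C_tau", "c")], is.null, logical(1))
  if (all(explicit)) {
    p <- default_params()
    p$alpha <- cfg$alpha; p$C_tau <- cfg$C_tau; p$c <- cfg$c
  } else if (any(explicit)) {
    stop("set all three of alpha, C_tau, c explicitly, or name a case",
         call. = FALSE)
  } else {
    p <- scenario_params(cfg$case)
  }
  for (k in c("epsilon", "gamma", "lambda", "U_bar", "C_G", "C_S", "C_T",
              "U_bar_abeta", "U_bar_tau", "C_F", "mu0", "d", "d_tilde",
              "sigma")) {
    if (!is.null(cfg[[k]])) p[[k]] <- cfg[[k]]
  }
  validate_params(p, require_scenario = TRUE)

  if (!is.numeric(cfg$t_end) || cfg$t_end <= 0)
    stop("invalid value for key 't_end'", call. = FALSE)
  if (!is.numeric(cfg$u01) || cfg$u01 < 0)
    stop("invalid value for key 'u01'", call. = FALSE)
  if (!is.numeric(cfg$sample_dt) || cfg$sample_dt <= 0)
    stop("invalid value for key 'sample_dt'", call. = FALSE)
  if (!is.numeric(cfg$dt_scale) || cfg$dt_scale <= 0 || cfg$dt_scale > 1)
    stop("invalid value for key 'dt_scale' (use 0 < dt_scale <= 1)",
         call. = FALSE)
  if (cfg$a_cells < 8L)
    stop("invalid value for key 'a_cells' (need at least 8)", call. = FALSE)
  if (cfg$a0 < 0 || cfg$a0 >= 0.1)
    stop("invalid value for key 'a0' (need 0 <= a0 < 0.1)", call. = FALSE)

  cfg$params <- p
  structure(cfg, class = "adsim_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys take the documented defaults
#' (scenario case C, horizon `t_end = 50`, uniform initial amyloid monomer
#' level `u01 = 0.01`, 101 malfunction cells, synthetic 64-node /
#' 8-region connectome).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return an `adsim_config` (see [sim_config()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  sim_config(raw)
}

#' Write a run configuration to YAML
#'
#' Writes the resolved configuration (explicit defaults included) so that
#' reloading the file reproduces identical parameters.
#'
#' @param config an `adsim_config`.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "adsim_config"))
  out <- unclass(config)
  out$params <- NULL
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}
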