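#' Global burden of a compartment
#'
#' Average concentration over all parcels, `(1/N) * sum_m value(x_m)`
#' (all parcels are assumed to have the same volume).
#'
#' @param state an `adsim_state`.
#' @param compartment compartment index 1..5.
#' @param species `"abeta"` or `"tau"`.
#' @return scalar.
#' @export
global_burden <- function(state, compartment, species = c("abeta", "tau")) {
  species <- match.arg(species)
  x <- if (species == "abeta") state$u else state$tau
  mean(x[, compartment])
}

#' Regional burden of a compartment
#'
#' Average concentration over the parcels of one region,
#' `(1/r_j) * sum_{m in R_j} value(x_m)`.
#'
#' @param state an `adsim_state`.
#' @param parc [parcellation()].
#' @param region region name (or index into `parc$regions`).
#' @param compartment compartment index 1..5.
#' @param species `"abeta"` or `"tau"`.
#' @return scalar.
#' @export
regional_burden <- function(state, parc, region, compartment,
                            species = c("abeta", "tau")) {
  species <- match.arg(species)
  if (is.numeric(region)) region <- parc$regions[region]
  if (!region %in% parc$regions)
    stop("unknown region '", region, "'", call. = FALSE)
  members <- which(parc$region_of == region)
  if (!length(members)) stop("region '", region, "' is empty", call. = FALSE)
  x <- if (species == "abeta") state$u else state$tau
  mean(x[members, compartment])
}

#' Damage time series
#'
#' Extracts the per-node, per-region and global mean degree of malfunction
#' from a trajectory.  Each series is nondecreasing in time (the
#' deterioration rate is nonnegative) and bounded in `[0, 1]`.
#'
#' @param traj an `adsim_trajectory`.
#' @param parc parcellation (defaults to the trajectory's own).
#' @return list of class `adsim_damage`: `times`, `A_node`, `A_regional`,
#'   `A_global`.
#' @export
damage_series <- function(traj, parc = traj$parcellation) {
  n_reg <- length(parc$regions)
  reg_idx <- as.integer(parc$region_of)
  r_sizes <- tabulate(reg_idx, nbins = n_reg)
  A_reg <- t(apply(traj$A_node, 1L,
                   function(a) rowsum(a, reg_idx)[, 1L] / r_sizes))
  if (n_reg == 1L) A_reg <- matrix(A_reg, ncol = 1L)
  colnames(A_reg) <- parc$regions
  structure(list(times = traj$times, A_node = traj$A_node,
                 A_regional = A_reg, A_global = rowMeans(traj$A_node)),
            class = "adsim_damage")
}

#' Tidy export of burden and damage series
#'
#' Writes one long CSV with columns `time, species, compartment, region,
#' value`: global and regional burdens for both proteins (species `abeta`,
#' `tau`; compartments 1..5) and the damage series (species `damage`,
#' compartment `NA`).  `region` is `"global"` for whole-brain rows.
#'
#' @param traj an `adsim_trajectory`.
#' @param path output path.
#' @return the data frame that was written, invisibly.
#' @export
export_csv <- function(traj, path) {
  times <- traj$times
  regions <- traj$parcellation$regions
  rows <- list()
  for (sp in c("abeta", "tau")) {
    glob <- if (sp == "abeta") traj$u_global else traj$tau_global
    regm <- if (sp == "abeta") traj$u_regional else traj$tau_regional
    for (i in 1:5) {
      rows[[length(rows) + 1L]] <- data.frame(
        time = times, species = sp, compartment = i, region = "global",
        value = glob[, i])
      for (r in seq_along(regions))
        rows[[length(rows) + 1L]] <- data.frame(
          time = times, species = sp, compartment = i, region = regions[r],
          value = regm[, r, i])
    }
  }
  rows[[length(rows) + 1L]] <- data.frame(
    time = times, species = "damage", compartment = NA_integer_,
    region = "global", value = traj$A_global)
  for (r in seq_along(regions))
    rows[[length(rows) + 1L]] <- data.frame(
      time = times, species = "damage", compartment = NA_integer_,
      region = regions[r], value = traj$A_regional[, r])
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Peak time of a sampled series
#'
#' Argmax over samples, deterministic with ties broken toward the earlier
#' time.
#'
#' @param times sample times.
#' @param values series values.
#' @return the time of the first maximum.
#' @export
peak_time <- function(times, values) {
  stopifnot(length(times) == length(values))
  times[which.max(values)]
}

#' Summarise a trajectory
#'
#' Peak times and peak values of every global compartment curve, the final
#' global damage, final per-region damage, and final plaque/tangle burdens.
#'
#' @param traj an `adsim_trajectory`.
#' @return list suitable for JSON export.
#' @export
trajectory_summary <- function(traj) {
  tm <- traj$times
  S <- length(tm)
  peaks <- function(mat) lapply(1:5, function(i)
    list(time = peak_time(tm, mat[, i]), value = max(mat[, i])))
  list(
    case = traj$meta$case,
    t_end = traj$meta$t_end,
    abeta_peaks = peaks(traj$u_global),
    tau_peaks = peaks(traj$tau_global),
    final_plaque_burden = traj$u_global[S, 5L],
    final_tangle_burden = traj$tau_global[S, 5L],
    final_damage_global = traj$A_global[S],
    final_damage_regional = as.list(stats::setNames(
      traj$A_regional[S, ], traj$parcellation$regions))
  )
}

#' Run the five-scenario campaign on one connectome
#'
#' Runs the cases (default all of A..E) on a common connectome and
#' configuration, so trajectories are directly comparable.
#'
#' @param cases character vector of case labels.
#' @param config base configuration (case field is overridden per run).
#' @param connectome optional prebuilt connectome shared by all runs;
#'   defaults to one synthetic connectome built from the configuration.
#' @return named list of `adsim_trajectory` objects.
#' @export
compare_cases <- function(cases = c("A", "B", "C", "D", "E"),
                          config = sim_config(), connectome = NULL) {
  if (!inherits(config, "adsim_config")) config <- sim_config(config)
  if (is.null(connectome))
    connectome <- synthesize_connectome(config$n_nodes, config$n_regions,
                                        config$rng_seed, k_nn = config$k_nn)
  out <- list()
  for (cs in cases) {
    cfg <- unclass(config)
    cfg$case <- cs
    cfg$alpha <- cfg$C_tau <- cfg$c <- NULL
    cfg$params <- NULL
    out[[cs]] <- run_simulation(sim_config(cfg), connectome = connectome)
  }
  out
}
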