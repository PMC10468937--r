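#' Weighted graph on a brain parcellation
#'
#' Constructs the basic graph container used for both the connectivity graph
#' (white-matter fibre strengths, on which misfolded tau spreads) and the
#' proximity graph (distance-derived weights between spatially neighbouring
#' parcels, on which extracellular amyloid-beta diffuses).
#'
#' The container stores the symmetric nonnegative weight matrix `W`, the
#' per-node weight totals `pi = rowSums(W)` (all strictly positive: an
#' isolated parcel has no defined diffusion operator), and the row-normalised
#' Laplacian matrix `L = I - diag(1/pi) %*% W`, so that `L %*% g` evaluates
#' the weighted graph Laplacian of a nodal field `g`.
#'
#' @param weights symmetric N x N numeric matrix of nonnegative edge weights
#'   with zero diagonal.
#' @param node_ids optional character vector of node identifiers.
#' @return an object of class `adsim_graph` with elements `n`, `W`, `pi`,
#'   `L`, `node_ids`.
#' @export
weighted_graph <- function(weights, node_ids = NULL) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (n < 1L || ncol(weights) != n)
    stop("weights must be a square matrix", call. = FALSE)
  if (any(!is.finite(weights)))
    stop("weights must be finite", call. = FALSE)
  if (any(weights < 0))
    stop("weights must be nonnegative", call. = FALSE)
  if (any(diag(weights) != 0))
    stop("self-loops are not allowed (nonzero diagonal)", call. = FALSE)
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 1e-12)))
    stop("weight matrix must be symmetric", call. = FALSE)
  weights <- (weights + t(weights)) / 2  # exact symmetry to round-off
  pi_m <- rowSums(weights)
  if (any(pi_m <= 0)) {
    bad <- which(pi_m <= 0)
    ids <- if (is.null(node_ids)) bad else node_ids[bad]
    stop("node(s) with zero total weight (isolated): ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  if (is.null(node_ids)) node_ids <- as.character(seq_len(n))
  L <- diag(n) - weights / pi_m  # rowwise division: diag(1/pi) %*% W
  structure(
    list(n = n, W = weights, pi = pi_m, L = L, node_ids = node_ids),
    class = "adsim_graph"
  )
}

#' @export
print.adsim_graph <- function(x, ...) {
  cat("<adsim_graph> ", x$n, " nodes, ",
      sum(x$W[upper.tri(x$W)] > 0), " undirected edges\n", sep = "")
  invisible(x)
}

#' Apply the weighted graph Laplacian
#'
#' Evaluates `(Lap g)(x_m) = (1/pi_m) * sum_j (g(x_m) - g(x_j)) * w_mj`.
#' This operator is positive semidefinite; diffusion terms therefore enter
#' the model equations with a leading minus sign.
#'
#' @param graph an [weighted_graph()] object.
#' @param g numeric vector of length N, or an N x k matrix of nodal fields
#'   (one field per column).
#' @return object of the same shape as `g`.
#' @export
laplacian_apply <- function(graph, g) {
  stopifnot(inherits(graph, "adsim_graph"))
  vec <- is.null(dim(g))
  if (vec) g <- matrix(g, ncol = 1L)
  if (nrow(g) != graph$n)
    stop("field length ", nrow(g), " does not match node count ", graph$n,
         call. = FALSE)
  out <- graph$L %*% g
  if (vec) drop(out) else out
}

#' Parcellation of the brain network
#'
#' Groups graph vertices (parcels) into named regions and records which
#' vertices belong to the tau seeding set (the entorhinal cortex under Braak
#' staging).
#'
#' @param node_ids character vector of N parcel identifiers.
#' @param region_of factor or character vector of length N mapping each node
#'   to its region.
#' @param seed_nodes integer indices of the seed vertices (may be empty).
#' @param coords optional N x 3 matrix of parcel coordinates.
#' @return object of class `adsim_parcellation`.
#' @export
parcellation <- function(node_ids, region_of, seed_nodes = integer(0),
                         coords = NULL) {
  n <- length(node_ids)
  region_of <- as.factor(region_of)
  if (length(region_of) != n)
    stop("region_of must have one entry per node", call. = FALSE)
  if (anyNA(region_of))
    stop("every node must belong to exactly one region", call. = FALSE)
  seed_nodes <- sort(unique(as.integer(seed_nodes)))
  if (length(seed_nodes) && (min(seed_nodes) < 1L || max(seed_nodes) > n))
    stop("seed node indices out of range", call. = FALSE)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 3L)
      stop("coords must be an N x 3 matrix", call. = FALSE)
  }
  structure(
    list(node_ids = as.character(node_ids), region_of = region_of,
         regions = levels(region_of), seed_nodes = seed_nodes,
         coords = coords, n = n),
    class = "adsim_parcellation"
  )
}

#' @export
print.adsim_parcellation <- function(x, ...) {
  cat("<adsim_parcellation> ", x$n, " nodes, ", length(x$regions),
      " regions, ", length(x$seed_nodes), " seed nodes\n", sep = "")
  invisible(x)
}

#' Indicator of the tau seeding set
#'
#' @param parc an [parcellation()] object.
#' @return numeric 0/1 vector, 1 exactly on the seed vertices.
#' @export
seed_indicator <- function(parc) {
  stopifnot(inherits(parc, "adsim_parcellation"))
  ind <- numeric(parc$n)
  ind[parc$seed_nodes] <- 1
  ind
}

#' Read a connectome graph from file
#'
#' Supports an undirected edge-list CSV (header `node_i,node_j,weight`,
#' 1-based node ids) and GraphML with a numeric `weight` edge attribute.
#' Each undirected edge should be stored once; with `dialect = "strict"`
#' a duplicate `(i,j)`/`(j,i)` pair must carry the same weight, with
#' `dialect = "sum"` duplicates are accumulated.
#'
#' @param path file path.
#' @param fmt `"edge-list-csv"` or `"graphml"`.
#' @param dialect duplicate-edge policy, `"strict"` (default) or `"sum"`.
#' @param n_nodes optional total node count (edge lists cannot represent
#'   trailing nodes with no edges; such nodes are rejected anyway since
#'   every node needs positive total weight).
#' @return an [weighted_graph()].
#' @export
load_graph <- function(path, fmt = c("edge-list-csv", "graphml"),
                       dialect = c("strict", "sum"), n_nodes = NULL) {
  fmt <- match.arg(fmt)
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (fmt == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
    w <- igraph::E(g)$weight
    if (is.null(w)) stop("GraphML file lacks a 'weight' edge attribute",
                         call. = FALSE)
    W <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight",
                                               sparse = FALSE))
    ids <- igraph::V(g)$name
    if (is.null(ids)) ids <- as.character(seq_len(nrow(W)))
    return(weighted_graph(W, node_ids = ids))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("node_i", "node_j", "weight")
  if (!all(need %in% names(df)))
    stop("edge list must have header node_i,node_j,weight", call. = FALSE)
  for (col in need) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      stop("malformed value in column '", col, "' at data line ", bad[1L],
           call. = FALSE)
  }
  i <- as.integer(df$node_i); j <- as.integer(df$node_j)
  w <- as.numeric(df$weight)
  if (any(w < 0)) stop("negative edge weight at data line ",
                       which(w < 0)[1L], call. = FALSE)
  if (any(i == j)) stop("self-loop at data line ", which(i == j)[1L],
                        call. = FALSE)
  n <- if (is.null(n_nodes)) max(i, j) else as.integer(n_nodes)
  W <- matrix(0, n, n)
  for (r in seq_along(i)) {
    a <- i[r]; b <- j[r]
    if (W[a, b] != 0) {
      if (dialect == "strict" && W[a, b] != w[r])
        stop("conflicting duplicate weights for edge (", a, ",", b,
             ") at data line ", r, " under dialect='strict'", call. = FALSE)
      if (dialect == "sum") {
        W[a, b] <- W[a, b] + w[r]; W[b, a] <- W[a, b]
      }
    } else {
      W[a, b] <- w[r]; W[b, a] <- w[r]
    }
  }
  weighted_graph(W)
}

#' Read a parcel table
#'
#' CSV with header `node_id,region,seed` and optional `x,y,z` coordinate
#' columns; `seed` is 0/1 and flags the entorhinal seed vertices.
#'
#' @param path file path.
#' @return an [parcellation()].
#' @export
load_parcellation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("node_id", "region", "seed")
  if (!all(need %in% names(df)))
    stop("parcel table must have header node_id,region,seed[,x,y,z]",
         call. = FALSE)
  if (!all(df$seed %in% c(0L, 1L)))
    stop("seed column must contain only 0 or 1", call. = FALSE)
  coords <- if (all(c("x", "y", "z") %in% names(df)))
    as.matrix(df[, c("x", "y", "z")]) else NULL
  parcellation(df$node_id, df$region, which(df$seed == 1L), coords)
}

# FNV-1a over serialized bytes; provenance fingerprint for run logs.
content_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Generate a synthetic connectome
#'
#' Builds a stand-in for a dMRI-derived connectome for testing and
#' simulation studies: parcels are scattered in 3D around region centres on
#' a sphere, two bilateral "entorhinal" regions are flagged as the tau
#' seeding set, the proximity graph links k nearest neighbours with inverse
#' distance weights (symmetrised by max), and the connectivity graph draws
#' heavy-tailed (log-normal) weights with denser intra-region wiring,
#' distance-decaying inter-region wiring, and stronger seed-incident edges.
#' Both graphs are guaranteed connected (nearest-pair bridges are added if
#' needed).  The entorhinal regions receive fewer parcels than the others,
#' reflecting the small anatomical size of the entorhinal cortex.
#'
#' @param n_nodes total number of parcels (at least `2 * n_regions`).
#' @param n_regions number of regions, at least 3 (two entorhinal seed
#'   regions plus at least one other).
#' @param rng_seed integer seed; output is deterministic given the seed.
#' @param k_nn neighbours per node in the proximity graph (default 4).
#' @return list with elements `parcellation`, `connectivity`, `proximity`.
#' @export
synthesize_connectome <- function(n_nodes, n_regions, rng_seed, k_nn = 4L) {
  if (n_regions < 3L)
    stop("need at least 3 regions (two seed regions plus one other)",
         call. = FALSE)
  if (n_nodes < 2L * n_regions)
    stop("need n_nodes >= 2 * n_regions", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(rng_seed))

  # Region centres: two mirrored entorhinal centres low on the sphere,
  # remaining centres spread by golden-angle spiral.
  centres <- matrix(0, n_regions, 3)
  centres[1, ] <- c(-0.45, 0.15, -0.35)
  centres[2, ] <- c(0.45, 0.15, -0.35)
  n_other <- n_regions - 2L
  gold <- pi * (3 - sqrt(5))
  for (r in seq_len(n_other)) {
    z <- 1 - 2 * (r - 0.5) / n_other
    rad <- sqrt(max(0, 1 - z^2))
    th <- gold * r
    centres[r + 2L, ] <- c(rad * cos(th), rad * sin(th), z)
  }

  # Seed regions are small (entorhinal cortex is a small structure).
  base <- n_nodes %/% n_regions
  seed_sz <- max(2L, base %/% 2L)
  rest <- n_nodes - 2L * seed_sz
  sizes <- rep(rest %/% n_other, n_other)
  sizes[seq_len(rest %% n_other)] <- sizes[seq_len(rest %% n_other)] + 1L
  sizes <- c(seed_sz, seed_sz, sizes)

  region_names <- c("entorhinal_L", "entorhinal_R",
                    paste0("region_", seq_len(n_other) + 2L))
  region_of <- rep(region_names, times = sizes)
  coords <- matrix(0, n_nodes, 3)
  idx <- 0L
  for (r in seq_len(n_regions)) {
    for (s in seq_len(sizes[r])) {
      idx <- idx + 1L
      coords[idx, ] <- centres[r, ] + stats::rnorm(3, sd = 0.12)
    }
  }
  node_ids <- paste0("n", seq_len(n_nodes))
  seed_nodes <- which(region_of %in% c("entorhinal_L", "entorhinal_R"))
  parc <- parcellation(node_ids, factor(region_of, levels = region_names),
                       seed_nodes, coords)

  D <- as.matrix(stats::dist(coords))
  D[D < 1e-6] <- 1e-6

  # Proximity graph: k nearest neighbours, w = 1/d, symmetrised by max.
  Wf <- matrix(0, n_nodes, n_nodes)
  for (m in seq_len(n_nodes)) {
    nb <- order(D[m, ])[2:(k_nn + 1L)]
    Wf[m, nb] <- 1 / D[m, nb]
  }
  Wf <- pmax(Wf, t(Wf))
  Wf <- bridge_components(Wf, D)

  # Connectivity graph: heavy-tailed weights; denser within regions,
  # distance-decaying between regions, boosted on seed-incident edges.
  We <- matrix(0, n_nodes, n_nodes)
  seed_flag <- seq_len(n_nodes) %in% seed_nodes
  for (m in seq_len(n_nodes - 1L)) {
    for (j in (m + 1L):n_nodes) {
      same <- region_of[m] == region_of[j]
      p <- if (same) 0.85 else 0.35 * exp(-D[m, j] / 0.8)
      if (stats::runif(1) < p) {
        w <- exp(stats::rnorm(1, mean = 0, sd = 0.8))
        if (same) w <- 2 * w
        if (seed_flag[m] || seed_flag[j]) w <- 1.5 * w
        We[m, j] <- w
        We[j, m] <- w
      }
    }
  }
  We <- bridge_components(We, D)

  list(parcellation = parc,
       connectivity = weighted_graph(We, node_ids),
       proximity = weighted_graph(Wf, node_ids))
}

# Connect graph components by adding the nearest inter-component pair with
# an inverse-distance weight until a single component remains.
bridge_components <- function(W, D) {
  repeat {
    comp <- graph_components(W)
    if (max(comp) == 1L) return(W)
    in1 <- comp == 1L
    sub <- D[in1, !in1, drop = FALSE]
    k <- arrayInd(which.min(sub), dim(sub))
    a <- which(in1)[k[1]]
    b <- which(!in1)[k[2]]
    W[a, b] <- 1 / D[a, b]
    W[b, a] <- W[a, b]
  }
}

graph_components <- function(W) {
  n <- nrow(W)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      stack <- c(stack, which(W[v, ] > 0 & comp == 0L))
    }
  }
  comp
}
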