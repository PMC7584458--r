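#' Seed specification
#'
#' Describes where and how toxic (or healthy) protein is introduced on top
#' of the healthy baseline state. "Percent" seeding follows the model's unit
#' concentration scale: a p% seed is the absolute concentration p/100 (a 5%
#' toxic A-beta seed sets `ut` up by 0.05).
#'
#' @param species One of `"u"`, `"ut"`, `"v"`, `"vt"`.
#' @param amount Non-negative concentration added (default) or assigned
#'   (`mode = "set"`).
#' @param nodes Integer node indices, or
#' @param region Region-label substring (matched case-insensitively), or
#' @param where Coordinate predicate `function(x, y, z)` as in
#'   [nodes_where()]. Exactly one selector must be given.
#' @param mode `"add"` or `"set"`.
#' @return An object of class `seed_spec` (a single seed; pass a list of
#'   them to [initial_condition()]).
#' @export
#' @examples
#' seed_spec("ut", 0.05, where = function(x, y, z) x <= 4)
seed_spec <- function(species, amount, nodes = NULL, region = NULL,
                      where = NULL, mode = c("add", "set")) {
  mode <- match.arg(mode)
  stopifnot(species %in% c("u", "ut", "v", "vt"),
            is.numeric(amount), length(amount) == 1L, amount >= 0)
  sel <- c(!is.null(nodes), !is.null(region), !is.null(where))
  if (sum(sel) != 1L) {
    stop("give exactly one of nodes=, region=, where= to select seed nodes")
  }
  structure(list(species = species, amount = amount, nodes = nodes,
                 region = region, where = where, mode = mode),
            class = "seed_spec")
}

# resolve a seed_spec to node indices on a graph
resolve_seed_nodes <- function(seed, graph) {
  idx <- if (!is.null(seed$nodes)) {
    as.integer(seed$nodes)
  } else if (!is.null(seed$region)) {
    which(grepl(tolower(seed$region), tolower(graph$nodes$label), fixed = TRUE))
  } else {
    nodes_where(graph, seed$where)
  }
  if (length(idx) == 0L) {
    stop("seed selector resolves to no nodes",
         if (!is.null(seed$region)) paste0(" (region ", deparse(seed$region), ")"))
  }
  if (any(idx < 1L | idx > nrow(graph$nodes))) {
    stop("seed node indices out of range")
  }
  idx
}

#' Healthy-plus-seeds initial condition
#'
#' Sets every node to its local healthy stationary state
#' `(a0/a1, 0, b0/b1, 0)` with zero damage, then applies the seeds in order
#' (additively by default).
#'
#' @param graph A [connectome()] graph.
#' @param params A [kinetic_params()] object or per-node parameter matrix
#'   from [resolve_regional()].
#' @param seeds A [seed_spec()] or list of them (empty list: unperturbed
#'   healthy state).
#' @return A `state_vector`: list of numeric per-node vectors
#'   `u, ut, v, vt, q`.
#' @export
initial_condition <- function(graph, params, seeds = list()) {
  stopifnot(inherits(graph, "connectome"))
  n <- nrow(graph$nodes)
  np <- as_node_params(params, n)
  state <- list(u = as.numeric(np[, "a0"] / np[, "a1"]), ut = rep(0, n),
                v = as.numeric(np[, "b0"] / np[, "b1"]), vt = rep(0, n),
                q = rep(0, n))
  if (inherits(seeds, "seed_spec")) seeds <- list(seeds)
  for (seed in seeds) {
    idx <- resolve_seed_nodes(seed, graph)
    if (seed$mode == "add") {
      state[[seed$species]][idx] <- state[[seed$species]][idx] + seed$amount
    } else {
      state[[seed$species]][idx] <- seed$amount
    }
  }
  structure(state, class = "state_vector")
}

# pack/unpack the 5V state for deSolve
pack_state <- function(s) c(s$u, s$ut, s$v, s$vt, s$q)
unpack_state <- function(y, n) {
  list(u = y[seq_len(n)], ut = y[n + seq_len(n)], v = y[2L * n + seq_len(n)],
       vt = y[3L * n + seq_len(n)], q = y[4L * n + seq_len(n)])
}

#' Network right-hand side
#'
#' Time derivative of the full 5V-dimensional network system: per node the
#' homogeneous kinetics plus graph-Laplacian transport for each species,
#' and the damage law
#' `dq_j/dt = (k1 ut_j + k2 vt_j + k3 ut_j vt_j + k4 sum_k A_jk q_k)(1 - q_j)`
#' with the `n/l`-weighted damage adjacency `A`. At a spatially homogeneous
#' state the concentration derivatives reduce to the homogeneous kinetics
#' at every node (the Laplacian annihilates constants).
#'
#' @param graph A [connectome()] graph.
#' @param params [kinetic_params()] or per-node matrix.
#' @param damage A [damage_params()] object (or NULL for zero damage rates).
#' @param state A `state_vector` as from [initial_condition()].
#' @return A `state_vector` of derivatives.
#' @export
network_rhs <- function(graph, params, damage, state) {
  n <- nrow(graph$nodes)
  np <- as_node_params(params, n)
  ops <- .make_network_ops(graph, np, damage)
  unpack_state(ops$deriv(pack_state(state)), n)
}

# Precompute sparse operators and return a fast derivative closure.
.make_network_ops <- function(graph, np, damage) {
  n <- nrow(graph$nodes)
  L0 <- graph_laplacian(graph, 1)
  Lu <- np[, "rho_u"][1] * L0; Lut <- np[, "rho_ut"][1] * L0
  Lv <- np[, "rho_v"][1] * L0; Lvt <- np[, "rho_vt"][1] * L0
  # per-species rho is spatially uniform (spec: per-species, global scale);
  # guard against silently ignoring a per-node rho override
  for (f in .diff_fields) {
    if (length(unique(np[, f])) != 1L) {
      stop("per-node diffusivity overrides are not supported (field ", f, ")")
    }
  }
  A <- if (is.null(damage) || damage$k4 == 0) NULL else damage_adjacency(graph)
  k <- if (is.null(damage)) damage_params(0, 0, 0, 0) else damage
  col <- function(f) as.numeric(np[, f])
  a0 <- col("a0"); a1 <- col("a1"); a2 <- col("a2"); a1t <- col("a1t")
  b0 <- col("b0"); b1 <- col("b1"); b2 <- col("b2"); b1t <- col("b1t")
  b3 <- col("b3")
  deriv <- function(y) {
    u <- y[seq_len(n)]; ut <- y[n + seq_len(n)]
    v <- y[2L * n + seq_len(n)]; vt <- y[3L * n + seq_len(n)]
    q <- y[4L * n + seq_len(n)]
    uvt <- ut * v * vt
    du <- as.numeric(-(Lu %*% u)) + a0 - a1 * u - a2 * u * ut
    dut <- as.numeric(-(Lut %*% ut)) - a1t * ut + a2 * u * ut
    dv <- as.numeric(-(Lv %*% v)) + b0 - b1 * v - b2 * v * vt - b3 * uvt
    dvt <- as.numeric(-(Lvt %*% vt)) - b1t * vt + b2 * v * vt + b3 * uvt
    drive <- k$k1 * ut + k$k2 * vt + k$k3 * ut * vt
    if (!is.null(A)) drive <- drive + k$k4 * as.numeric(A %*% q)
    dq <- drive * (1 - q)
    c(du, dut, dv, dvt, dq)
  }
  list(deriv = deriv, n = n)
}

#' Integrate the network model
#'
#' Solves the coupled 5V-dimensional system (four species plus damage) with
#' a stiff BDF-class integrator (`deSolve`'s sparse-Jacobian `lsodes` by
#' default, the analogue of the CVODE/KLU setup used for connectome-scale
#' runs), from a seeded initial condition on a user output grid.
#'
#' @param graph A [connectome()] graph.
#' @param params [kinetic_params()] or per-node parameter matrix.
#' @param init A `state_vector` from [initial_condition()].
#' @param times Increasing numeric output grid (first entry is the initial
#'   time).
#' @param damage Optional [damage_params()]; NULL freezes damage at zero.
#' @param method deSolve method, default `"lsodes"`.
#' @param rtol,atol Solver tolerances.
#' @return An object of class `trajectory`: list with `times`, per-species
#'   matrices `u, ut, v, vt, q` (time x node), and `meta` (parameters,
#'   solver settings, diagnostics).
#' @export
#' @examples
#' g <- cubic_lattice(4, 1, 1)
#' p <- preset_params("primary_table1")
#' ic <- initial_condition(g, p, seed_spec("ut", 0.05, nodes = 1))
#' tr <- simulate_network(g, p, ic, times = seq(0, 5, by = 1))
simulate_network <- function(graph, params, init, times,
                             damage = NULL, method = "lsodes",
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(graph, "connectome"), length(times) >= 2L,
            all(diff(times) > 0))
  n <- nrow(graph$nodes)
  np <- as_node_params(params, n)
  ops <- .make_network_ops(graph, np, damage)
  y0 <- pack_state(init)
  stopifnot(length(y0) == 5L * n)
  func <- function(t, y, parms) list(ops$deriv(y))
  sol <- deSolve::ode(y = y0, times = times, func = func, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  diagn <- attributes(sol)[c("istate", "rstate")]
  if (attr(sol, "istate")[1] < 0) {
    stop("stiff integration failed (istate = ", attr(sol, "istate")[1],
         "); see deSolve diagnostics")
  }
  y <- unname(sol[, -1, drop = FALSE])
  take <- function(k) y[, (k - 1L) * n + seq_len(n), drop = FALSE]
  conc_min <- min(y[, seq_len(4L * n)])
  if (conc_min < -1e-6) {
    stop("negative concentration excursion beyond tolerance: min = ", conc_min)
  }
  structure(
    list(times = sol[, 1], u = take(1), ut = take(2), v = take(3),
         vt = take(4), q = take(5),
         meta = list(n_nodes = n, params = np, damage = damage,
                     method = method, rtol = rtol, atol = atol,
                     diagnostics = diagn)),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d nodes, %d output times in [%g, %g]\n",
              x$meta$n_nodes, length(x$times), x$times[1],
              x$times[length(x$times)]))
  invisible(x)
}

#' State at a stored output time
#'
#' @param traj A `trajectory`.
#' @param i Time index (default: last).
#' @return A `state_vector` (per-node u, ut, v, vt, q).
#' @export
trajectory_state <- function(traj, i = length(traj$times)) {
  structure(list(u = traj$u[i, ], ut = traj$ut[i, ], v = traj$v[i, ],
                 vt = traj$vt[i, ], q = traj$q[i, ]),
            class = "state_vector")
}

#' Tidy data.frame view of a trajectory
#'
#' @param x A `trajectory`.
#' @param ... Unused.
#' @return A long data.frame with columns time, node, u, ut, v, vt, q.
#' @export
as.data.frame.trajectory <- function(x, ...) {
  nt <- length(x$times); n <- x$meta$n_nodes
  data.frame(time = rep(x$times, times = n),
             node = rep(seq_len(n), each = nt),
             u = as.vector(x$u), ut = as.vector(x$ut),
             v = as.vector(x$v), vt = as.vector(x$vt),
             q = as.vector(x$q))
}

#' Integrate the homogeneous (single-node) kinetics
#'
#' Identical to [simulate_network()] on a one-node graph; serves as the
#' network cross-check oracle for homogeneity preservation.
#'
#' @param p A [kinetic_params()] object.
#' @param init Length-4 state `(u, ut, v, vt)` or length-5 including damage.
#' @param times Output time grid.
#' @param damage Optional [damage_params()] (the non-local term vanishes on
#'   a single node).
#' @param ... Passed to [simulate_network()].
#' @return A `trajectory` with one node.
#' @export
homogeneous_simulate <- function(p, init, times, damage = NULL, ...) {
  g1 <- connectome(data.frame(label = "node"),
                   data.frame(from = integer(0), to = integer(0),
                              n = numeric(0), l = numeric(0)))
  q0 <- if (length(init) >= 5L) init[[5]] else 0
  s0 <- structure(list(u = init[[1]], ut = init[[2]], v = init[[3]],
                       vt = init[[4]], q = q0), class = "state_vector")
  simulate_network(g1, p, s0, times, damage = damage, ...)
}
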