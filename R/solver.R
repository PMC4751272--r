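# Vertex-centered finite-volume discretization of the cable equation on
# neuron graphs and networks, and the surrounding solver machinery.

REGION_CODE <- c("axon" = 0L, "soma" = 1L,
                 "dendrite-basal" = 2L, "dendrite-apical" = 2L)

#' Build a compartment mesh
#'
#' Derives the finite-volume quantities from a morphology: the control
#' volume of vertex `i` spans the halves of all incident edges, so its
#' axial length is `l_i = 1/2 sum ||e||`, its lateral membrane area
#' `2 pi a_i l_i` and capacitance `C_i = c_m 2 pi a_i l_i`.  The axial
#' conductance of edge (i, j) follows the trapezoidal integral over the
#' piecewise-tubular resistivity,
#' `G_ij = 2 pi / (r_c (a_i^-2 + a_j^-2) ||e_ij||)`.
#' Coordinates and radii arrive in micrometres (the file convention) and
#' are converted to SI metres here.  The solve ordering (reversed
#' Cuthill-McKee) is computed once at build time.
#'
#' @param geometry A [neuron_graph()] or [network_geometry()].
#' @param r_c Specific cytosol resistance, Ohm m.
#' @param c_m Specific membrane capacitance, F m^-2.
#' @return Object of class `compartment_mesh`.
#' @export
build_mesh <- function(geometry, r_c = 1.5, c_m = 1e-2) {
  cells <- if (inherits(geometry, "neuron_graph")) list(geometry)
           else if (inherits(geometry, "network_geometry")) geometry$cells
           else abort("geometry must be a neuron_graph or network_geometry")
  if (length(cells) == 0) abort("cannot build a mesh from an empty network")

  offset <- 0L
  vtabs <- list(); etabs <- list()
  for (ci in seq_along(cells)) {
    g <- cells[[ci]]
    v <- g$vertices
    e <- graph_edges(g)
    if (any(e$length <= 0)) abort("zero-length edge in morphology")
    len_m <- e$length * 1e-6
    a_m <- v$radius * 1e-6
    l_half <- numeric(nrow(v))
    for (k in seq_len(nrow(e))) {
      l_half[e$parent[k]] <- l_half[e$parent[k]] + len_m[k] / 2
      l_half[e$child[k]] <- l_half[e$child[k]] + len_m[k] / 2
    }
    area <- 2 * pi * a_m * l_half
    G <- 2 * pi / (r_c * (a_m[e$parent]^-2 + a_m[e$child]^-2) * len_m)
    vtabs[[ci]] <- tibble(
      index = offset + v$id, cell = ci, vid = v$id,
      x = v$x, y = v$y, z = v$z, radius = v$radius,
      region = v$region, region_code = unname(REGION_CODE[v$region]),
      l_m = l_half, area = area, Cm = c_m * area,
      vol = pi * a_m^2 * l_half,
      is_root = is.na(v$parent))
    etabs[[ci]] <- tibble(
      cell = ci, edge_local = e$edge,
      i = offset + e$parent, j = offset + e$child,
      length_m = len_m, G = G)
    offset <- offset + nrow(v)
  }
  vertices <- dplyr::bind_rows(vtabs)
  edges <- dplyr::bind_rows(etabs)

  n <- nrow(vertices)
  sumG <- numeric(n)
  for (k in seq_len(nrow(edges))) {
    sumG[edges$i[k]] <- sumG[edges$i[k]] + edges$G[k]
    sumG[edges$j[k]] <- sumG[edges$j[k]] + edges$G[k]
  }

  mesh <- structure(list(vertices = vertices, edges = edges, sumG = sumG,
                         r_c = r_c, c_m = c_m, n = n),
                    class = "compartment_mesh")
  mesh$order <- cuthill_mckee_order(mesh)
  mesh$pos <- integer(n); mesh$pos[mesh$order] <- seq_len(n)
  sup <- rep(NA_integer_, n); g_sup <- numeric(n)
  pi_ <- mesh$pos[edges$i]; pj <- mesh$pos[edges$j]
  lo <- pmin(pi_, pj); hi <- pmax(pi_, pj)
  if (anyDuplicated(lo) > 0) {
    abort("ordering violates the one-superdiagonal property (non-tree geometry?)")
  }
  sup[lo] <- hi; g_sup[lo] <- edges$G
  mesh$sup <- sup
  mesh$g_sup <- g_sup
  mesh
}

#' @export
print.compartment_mesh <- function(x, ...) {
  cat(sprintf("<compartment_mesh> %d vertices, %d edges, %d cell(s)\n",
              x$n, nrow(x$edges), max(x$vertices$cell)))
  cat(sprintf("  r_c = %g Ohm m, c_m = %g F/m^2, total area %.3g m^2\n",
              x$r_c, x$c_m, sum(x$vertices$area)))
  invisible(x)
}

#' Cuthill-McKee solve ordering
#'
#' Breadth-first (Cuthill-McKee) ordering of the mesh adjacency, visited
#' neighbours sorted by degree, computed per connected component and then
#' reversed.  On a tree the reversed order places every vertex before its
#' BFS parent, so each matrix row has at most one non-zero entry strictly
#' right of the diagonal -- the structure that lets the sparse LU run
#' without fill in linear time.  Components occupy consecutive index
#' blocks.  A non-tree component triggers a warning (plain reversed CMK is
#' returned; the one-superdiagonal property may fail).
#'
#' @param mesh A [compartment_mesh()], or a list with `n` and an edge
#'   tibble `edges` having columns `i`, `j`.
#' @return Integer permutation: `order[k]` is the vertex at solve
#'   position `k`.
#' @export
cuthill_mckee_order <- function(mesh) {
  n <- mesh$n
  edges <- mesh$edges
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    adj[[edges$i[k]]] <- c(adj[[edges$i[k]]], edges$j[k])
    adj[[edges$j[k]]] <- c(adj[[edges$j[k]]], edges$i[k])
  }
  deg <- lengths(adj)
  visited <- logical(n)
  order <- integer(0)
  non_tree <- FALSE
  for (comp_start in seq_len(n)) {
    if (visited[comp_start]) next
    # component via BFS; start at its minimum-degree vertex
    comp <- comp_start
    frontier <- comp_start
    seen <- logical(n); seen[comp_start] <- TRUE
    while (length(frontier) > 0) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[!seen[nxt]]
      seen[nxt] <- TRUE
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    n_edges_comp <- sum(edges$i %in% comp)
    if (n_edges_comp != length(comp) - 1) non_tree <- TRUE
    start <- comp[order(deg[comp], comp)][1]
    # Cuthill-McKee BFS
    cm <- integer(0)
    queue <- start
    visited[start] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      cm <- c(cm, v)
      nb <- adj[[v]]
      nb <- nb[!visited[nb]]
      nb <- nb[order(deg[nb], nb)]
      visited[nb] <- TRUE
      queue <- c(queue, nb)
    }
    order <- c(order, rev(cm))
  }
  if (non_tree) {
    warn(paste("mesh contains a non-tree component; Cuthill-McKee ordering",
               "returned but the one-superdiagonal property may fail"))
  }
  order
}

#' Verify the one-superdiagonal property of an ordering
#'
#' @param mesh A [compartment_mesh()] (or list with `n`, `edges`).
#' @param order Permutation as returned by [cuthill_mckee_order()].
#' @return `TRUE` if under `order` every row of the adjacency has at most
#'   one neighbour with a larger position.
#' @export
has_one_superdiagonal <- function(mesh, order) {
  pos <- integer(mesh$n); pos[order] <- seq_len(mesh$n)
  lo <- pmin(pos[mesh$edges$i], pos[mesh$edges$j])
  anyDuplicated(lo) == 0
}

#' Mechanism bundle for the solver
#'
#' Gathers the membrane machinery handed to [step()] / [simulate()]:
#' Hodgkin-Huxley channels and the calibrated leak (per-region
#' parameters), optionally the calcium system (VDCC + NCX/PMCA pumps +
#' calibrated leak + AMPA-fraction influx).  Each mechanism follows the
#' explicit contract: its inner states are advanced before a time step
#' using only the previous step's solution, and it reports an
#' outward-positive current density at that solution.
#'
#' @param membrane A [membrane_spec()].
#' @param calcium A [calcium_spec()] or `NULL` to simulate voltage only.
#' @param hh,leak Logical switches (both off yields a purely passive or
#'   even mechanism-free membrane, useful for conservation tests).
#' @param E_l Optional per-region leak reversals
#'   (`c(axon=, soma=, dendrite=)`, V); default calibrated via
#'   [calibrate_leak_reversal()].
#' @return List of class `mechanism_set`.
#' @export
mechanisms <- function(membrane = membrane_spec(), calcium = NULL,
                       hh = TRUE, leak = TRUE, E_l = NULL) {
  if (is.null(E_l)) {
    E_l <- if (leak) {
      vapply(c("axon", "soma", "dendrite"),
             function(r) calibrate_leak_reversal(membrane, r), numeric(1))
    } else c(axon = 0, soma = 0, dendrite = 0)
  }
  structure(list(membrane = membrane, calcium = calcium,
                 hh = hh, leak = leak, E_l = E_l),
            class = "mechanism_set")
}

#' Initial simulation state
#'
#' Membrane potential set globally to `V0` (default the resting
#' potential), HH gates at their steady state for `V0`, calcium at its
#' resting concentration with VDCC gates equilibrated at `V0`.
#'
#' @param mesh A [compartment_mesh()].
#' @param mech A [mechanisms()] bundle.
#' @param V0 Initial potential, V.
#' @return List of class `cable_state` with per-vertex vectors in mesh
#'   (global) vertex order and the current time `t` (s).
#' @export
cable_state <- function(mesh, mech = mechanisms(), V0 = NULL) {
  if (is.null(V0)) V0 <- mech$membrane$V_r
  n <- mesh$n
  g0 <- hh_steady((V0 - mech$membrane$V_r) * 1e3)
  st <- list(V = rep(V0, n), n = rep(g0$n, n), m = rep(g0$m, n),
             h = rep(g0$h, n), t = 0)
  if (!is.null(mech$calcium)) {
    vg <- vdcc_steady(V0, mech$calcium)
    st$ca <- rep(mech$calcium$ca_rest, n)
    st$vdcc_m <- rep(vg$m_inf, n)
    st$vdcc_h <- rep(vg$h_inf, n)
  }
  structure(st, class = "cable_state")
}

# ---- kernel marshalling -----------------------------------------------

# membrane list for the kernel, region-coded vectors (axon, soma, dendrite)
kernel_membrane <- function(mech) {
  ms <- mech$membrane
  ord <- c("axon", "soma", "dendrite")
  list(hh_on = mech$hh, leak_on = mech$leak,
       g_K = unname(ms$g_K[ord]), g_Na = unname(ms$g_Na[ord]),
       g_l = unname(ms$g_l[ord]), E_l = unname(mech$E_l[ord]),
       E_K = ms$E_K, E_Na = ms$E_Na, V_r = ms$V_r, c_T = ms$c_T)
}

kernel_calcium <- function(mech, mesh) {
  if (is.null(mech$calcium)) return(list(on = FALSE))
  cs <- mech$calcium
  ord <- mesh$order
  # axial diffusive conductance: same trapezoidal integral with 1/D_ca
  a_m <- mesh$vertices$radius * 1e-6
  gc <- 2 * pi * cs$D_ca /
    ((a_m[mesh$edges$i]^-2 + a_m[mesh$edges$j]^-2) * mesh$edges$length_m)
  sum_gc <- numeric(mesh$n)
  for (k in seq_len(nrow(mesh$edges))) {
    sum_gc[mesh$edges$i[k]] <- sum_gc[mesh$edges$i[k]] + gc[k]
    sum_gc[mesh$edges$j[k]] <- sum_gc[mesh$edges$j[k]] + gc[k]
  }
  pi_ <- mesh$pos[mesh$edges$i]; pj <- mesh$pos[mesh$edges$j]
  lo <- pmin(pi_, pj)
  gc_sup <- numeric(mesh$n); gc_sup[lo] <- gc
  list(on = TRUE, vol = mesh$vertices$vol[ord], gc_sup = gc_sup,
       sum_gc = sum_gc[ord], ca_ext = cs$ca_ext,
       temperature = cs$temperature,
       P = cs$vdcc$P, z_m = cs$vdcc$z_m, V12_m = cs$vdcc$V12_m,
       tau_m = cs$vdcc$tau_m, p_m = cs$vdcc$p_m, z_h = cs$vdcc$z_h,
       V12_h = cs$vdcc$V12_h, tau_h = cs$vdcc$tau_h,
       ncx_f = cs$ncx$f_max, ncx_K = cs$ncx$K,
       pmca_f = cs$pmca$f_max, pmca_K = cs$pmca$K,
       leak = calibrate_calcium_leak(cs, mech$membrane$V_r),
       ampa_frac = cs$ampa_ca_fraction)
}

kernel_mesh <- function(mesh) {
  ord <- mesh$order
  list(sup = ifelse(is.na(mesh$sup), -1L, as.integer(mesh$sup - 1L)),
       g_sup = mesh$g_sup,
       Cm = mesh$vertices$Cm[ord], area = mesh$vertices$area[ord],
       sumG = mesh$sumG[ord],
       region = mesh$vertices$region_code[ord])
}

# synapse location -> global vertex index (control volume containing the
# offset point: parent half for offset <= 0.5, child half otherwise)
synapse_vertex <- function(mesh, cell, edge_local, offset) {
  key <- paste(mesh$edges$cell, mesh$edges$edge_local)
  idx <- match(paste(cell, edge_local), key)
  if (anyNA(idx)) abort("synapse references a missing edge")
  ifelse(offset <= 0.5, mesh$edges$i[idx], mesh$edges$j[idx])
}

global_vertex <- function(mesh, cell, vid) {
  key <- paste(mesh$vertices$cell, mesh$vertices$vid)
  idx <- match(paste(cell, vid), key)
  if (anyNA(idx)) abort("reference to a missing vertex")
  mesh$vertices$index[idx]
}

kernel_synapses <- function(mesh, synapses) {
  empty_p <- list(vertex = integer(0), onset = numeric(0), tau = numeric(0),
                  gmax = numeric(0), erev = numeric(0))
  empty_i <- list(pre_vertex = integer(0), post_vertex = integer(0),
                  gmax = numeric(0), tau1 = numeric(0), tau2 = numeric(0),
                  erev = numeric(0), vth = numeric(0), norm = numeric(0),
                  active = logical(0), events = list())
  if (is.null(synapses) || nrow(synapses) == 0) {
    return(list(primary = empty_p, inter = empty_i,
                primary_rows = integer(0), inter_rows = integer(0)))
  }
  pr <- which(synapses$kind == "primary")
  ir <- which(synapses$kind == "interconnecting")
  p <- empty_p; i <- empty_i
  if (length(pr) > 0) {
    s <- synapses[pr, ]
    if (anyNA(s$t_onset) || anyNA(s$tau)) {
      abort("primary synapses need a sampled activation pattern (sample_pattern)")
    }
    gv <- synapse_vertex(mesh, s$cell, s$edge, s$offset)
    p <- list(vertex = as.integer(mesh$pos[gv] - 1L),
              onset = s$t_onset * 1e-3, tau = s$tau * 1e-3,
              gmax = s$g_max * 1e-9, erev = s$e_rev * 1e-3)
  }
  if (length(ir) > 0) {
    s <- synapses[ir, ]
    gv_post <- synapse_vertex(mesh, s$cell, s$edge, s$offset)
    gv_pre <- global_vertex(mesh, s$pre_cell, s$pre_vertex)
    timing <- biexp_timing(s$tau1, s$tau2)
    i <- list(pre_vertex = as.integer(mesh$pos[gv_pre] - 1L),
              post_vertex = as.integer(mesh$pos[gv_post] - 1L),
              gmax = s$g_max * 1e-9, tau1 = s$tau1 * 1e-3,
              tau2 = s$tau2 * 1e-3, erev = s$e_rev * 1e-3,
              vth = s$v_th * 1e-3, norm = timing$n,
              active = s$active,
              events = lapply(s$activations, function(ev) ev * 1e-3))
  }
  list(primary = p, inter = i, primary_rows = pr, inter_rows = ir)
}

kernel_injections <- function(mesh, injections) {
  if (is.null(injections) || nrow(injections) == 0) {
    return(list(vertex = integer(0), amp = numeric(0), t0 = numeric(0),
                t1 = numeric(0)))
  }
  gv <- global_vertex(mesh, injections$cell, injections$vertex)
  list(vertex = as.integer(mesh$pos[gv] - 1L),
       amp = injections$amp * 1e-9,          # nA -> A
       t0 = injections$t0 * 1e-3, t1 = injections$t1 * 1e-3)
}

state_to_kernel <- function(state, mesh) {
  ord <- mesh$order
  ks <- list(V = state$V[ord], n = state$n[ord], m = state$m[ord],
             h = state$h[ord], t = state$t)
  if (!is.null(state$ca)) {
    ks$ca <- state$ca[ord]; ks$vdcc_m <- state$vdcc_m[ord]
    ks$vdcc_h <- state$vdcc_h[ord]
  }
  ks
}

state_from_kernel <- function(ks, mesh, template) {
  inv <- mesh$order
  st <- template
  st$V <- numeric(mesh$n); st$V[inv] <- ks$V
  st$n <- numeric(mesh$n); st$n[inv] <- ks$n
  st$m <- numeric(mesh$n); st$m[inv] <- ks$m
  st$h <- numeric(mesh$n); st$h[inv] <- ks$h
  if (!is.null(template$ca)) {
    st$ca <- numeric(mesh$n); st$ca[inv] <- ks$ca
    st$vdcc_m <- numeric(mesh$n); st$vdcc_m[inv] <- ks$vdcc_m
    st$vdcc_h <- numeric(mesh$n); st$vdcc_h[inv] <- ks$vdcc_h
  }
  st$t <- ks$t
  st
}

#' CFL-motivated time-step estimate
#'
#' The explicit (radial) part of the scheme is stable while
#' `dt <= C_i / G_mem,i` at every vertex, with `G_mem,i` the present total
#' membrane conductance (channels at current gate states plus synapses
#' active at `state$t`).  The estimate returns
#' `min(dt_max, safety * min_i C_i/G_mem,i)`: the more transmembrane
#' conductance, the smaller the step.
#'
#' @param mesh A [compartment_mesh()].
#' @param mech A [mechanisms()] bundle.
#' @param state A [cable_state()].
#' @param synapses Optional synapse set.
#' @param dt_max Upper bound, s.
#' @param safety Safety factor in (0, 1].
#' @return Time step, s.
#' @export
estimate_time_step <- function(mesh, mech, state, synapses = NULL,
                               dt_max = 1e-4, safety = 0.5) {
  stopifnot(safety > 0, safety <= 1)
  g <- membrane_conductance(mesh, mech, state, synapses)
  pos <- g > 0
  if (!any(pos)) return(dt_max)
  min(dt_max, safety * min(mesh$vertices$Cm[pos] / g[pos]))
}

# total membrane conductance per vertex (S), global order
membrane_conductance <- function(mesh, mech, state, synapses = NULL) {
  ms <- mech$membrane
  rc <- mesh$vertices$region_code + 1L  # 1 axon, 2 soma, 3 dendrite
  ord3 <- c("axon", "soma", "dendrite")
  g_dens <- numeric(mesh$n)
  if (mech$hh) {
    g_dens <- g_dens + ms$c_T * (unname(ms$g_K[ord3])[rc] * state$n^4 +
                                 unname(ms$g_Na[ord3])[rc] * state$m^3 * state$h)
  }
  if (mech$leak) g_dens <- g_dens + ms$c_T * unname(ms$g_l[ord3])[rc]
  g <- g_dens * mesh$vertices$area
  if (!is.null(synapses) && nrow(synapses) > 0) {
    t_ms <- state$t * 1e3
    pr <- synapses$kind == "primary" & !is.na(synapses$t_onset)
    if (any(pr)) {
      s <- synapses[pr, ]
      gs <- alpha_conductance(t_ms, s$t_onset, s$tau, s$g_max) * 1e-9
      gv <- synapse_vertex(mesh, s$cell, s$edge, s$offset)
      for (k in seq_along(gv)) g[gv[k]] <- g[gv[k]] + gs[k]
    }
    ir <- which(synapses$kind == "interconnecting")
    for (k in ir) {
      ev <- synapses$activations[[k]]
      if (length(ev) == 0) next
      gs <- sum(biexp_conductance(t_ms - ev, synapses$tau1[k],
                                  synapses$tau2[k], synapses$g_max[k])) * 1e-9
      gv <- synapse_vertex(mesh, synapses$cell[k], synapses$edge[k],
                           synapses$offset[k])
      g[gv] <- g[gv] + gs
    }
  }
  g
}

#' Advance the simulation by one time step
#'
#' One step of the mixed scheme: inner states and synapse activations are
#' updated explicitly from the state at time `t` (so presynaptic events
#' take effect one step later), then the voltage system
#' `(C_m/dt + axial Laplacian) V_new = (C_m/dt) V_old - I_mem(V_old)` is
#' solved by the ordered sparse LU, followed by the species systems.
#' Composing `step()` calls reproduces [simulate()] exactly.
#'
#' @param state A [cable_state()].
#' @param mesh A [compartment_mesh()].
#' @param mech A [mechanisms()] bundle.
#' @param synapses Optional synapse set.
#' @param dt Time step, s (take it from [estimate_time_step()]).
#' @param injections Optional injection tibble
#'   (`cell`, `vertex`, `amp` nA, `t0`, `t1` ms).
#' @return List with the advanced `state` and the (possibly updated)
#'   `synapses`.
#' @export
step <- function(state, mesh, mech, synapses = NULL, dt,
                 injections = NULL) {
  stopifnot(dt > 0)
  ksyn <- kernel_synapses(mesh, synapses)
  out <- cable_kernel(kernel_mesh(mesh), kernel_membrane(mech),
                      kernel_calcium(mech, mesh), ksyn$primary, ksyn$inter,
                      kernel_injections(mesh, injections),
                      state_to_kernel(state, mesh),
                      t_end = state$t + dt, dt_max = dt, safety = 1,
                      dt_fixed = dt, record_dt = 0,
                      probes = integer(0), max_steps = 1L,
                      record_dt_history = FALSE)
  new_state <- state_from_kernel(out$state, mesh, state)
  if (!is.null(synapses) && length(ksyn$inter_rows) > 0) {
    synapses$active[ksyn$inter_rows] <- out$active
    synapses$activations[ksyn$inter_rows] <-
      lapply(out$events, function(ev) ev * 1e3)
  }
  list(state = new_state, synapses = synapses)
}

#' Simulation configuration
#'
#' @param geometry A [neuron_graph()] or [network_geometry()].
#' @param mech A [mechanisms()] bundle.
#' @param synapses Optional synapse set.
#' @param duration Simulated time, ms.
#' @param dt_max Largest admissible step, s (accuracy cap; the CFL
#'   estimate can only shrink it).
#' @param safety CFL safety factor in (0, 1].
#' @param record_dt Probe sampling interval, ms.
#' @param probes `"soma"` (all somata), `"all"`, or a tibble
#'   (`cell`, `vertex`).
#' @param injections Optional tibble (`cell`, `vertex`, `amp` nA, `t0`,
#'   `t1` ms).
#' @param r_c,c_m Cable constants (see [build_mesh()]).
#' @param V0 Initial potential, V (default rest).
#' @param max_steps Step-count guard.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(geometry, mech = mechanisms(), synapses = NULL,
                              duration = 20, dt_max = 2e-5, safety = 0.5,
                              record_dt = 0.1, probes = "soma",
                              injections = NULL, r_c = 1.5, c_m = 1e-2,
                              V0 = NULL, max_steps = 2e7) {
  stopifnot(duration >= 0, dt_max > 0, safety > 0, safety <= 1)
  structure(list(geometry = geometry, mech = mech, synapses = synapses,
                 duration = duration, dt_max = dt_max, safety = safety,
                 record_dt = record_dt, probes = probes,
                 injections = injections, r_c = r_c, c_m = c_m, V0 = V0,
                 max_steps = max_steps),
            class = "simulation_config")
}

#' Run a cable simulation
#'
#' Builds the mesh, initializes the state, runs the CFL-limited step loop
#' and records probe traces at a fixed output interval along with every
#' synapse activation event.
#'
#' @param config A [simulation_config()].
#' @param mesh Optionally a pre-built [build_mesh()] result for
#'   `config$geometry` (avoids rebuilding across runs).
#' @param state Optional initial [cable_state()].
#' @return Object of class `cable_result`: tibbles `traces` (time ms,
#'   cell, vertex, V mV, ca mM), `events` (synapse, time ms), the final
#'   `state`, the `dt_history` tibble and step count.
#' @export
simulate <- function(config, mesh = NULL, state = NULL) {
  if (is.null(mesh)) mesh <- build_mesh(config$geometry, config$r_c, config$c_m)
  mech <- config$mech
  if (is.null(state)) state <- cable_state(mesh, mech, V0 = config$V0)

  probes <- resolve_probes(mesh, config$probes)
  ksyn <- kernel_synapses(mesh, config$synapses)
  out <- cable_kernel(kernel_mesh(mesh), kernel_membrane(mech),
                      kernel_calcium(mech, mesh), ksyn$primary, ksyn$inter,
                      kernel_injections(mesh, config$injections),
                      state_to_kernel(state, mesh),
                      t_end = state$t + config$duration * 1e-3,
                      dt_max = config$dt_max, safety = config$safety,
                      dt_fixed = 0, record_dt = config$record_dt * 1e-3,
                      probes = as.integer(mesh$pos[probes$index] - 1L),
                      max_steps = as.integer(config$max_steps),
                      record_dt_history = TRUE)
  final <- state_from_kernel(out$state, mesh, state)
  if (final$t < state$t + config$duration * 1e-3 - 1e-12) {
    warn(sprintf("simulation stopped after max_steps = %d at t = %g ms",
                 out$steps, final$t * 1e3))
  }

  has_ca <- !is.null(state$ca)
  init_rows <- tibble(time = state$t * 1e3, cell = probes$cell,
                      vertex = probes$vid,
                      V = state$V[probes$index] * 1e3,
                      ca = if (has_ca) state$ca[probes$index] else NA_real_)
  traces <- if (length(out$times) > 0) {
    tibble(time = rep(out$times * 1e3, each = nrow(probes)),
           cell = rep(probes$cell, length(out$times)),
           vertex = rep(probes$vid, length(out$times)),
           V = as.vector(t(out$trace_V)) * 1e3,
           ca = if (has_ca) as.vector(t(out$trace_ca)) else NA_real_)
  } else init_rows[0, ]
  traces <- dplyr::bind_rows(init_rows, traces)

  synapses <- config$synapses
  if (!is.null(synapses) && length(ksyn$inter_rows) > 0) {
    synapses$active[ksyn$inter_rows] <- out$active
    synapses$activations[ksyn$inter_rows] <- lapply(out$events, function(e) e * 1e3)
  }
  events <- if (!is.null(synapses)) activation_events(synapses) else
    tibble(synapse = integer(0), time = numeric(0))

  structure(list(traces = traces, events = events, state = final,
                 synapses = synapses,
                 dt_history = tibble(t = out$dt_times * 1e3,
                                     dt = out$dt_history),
                 steps = out$steps, mesh = mesh, config = config),
            class = "cable_result")
}

resolve_probes <- function(mesh, probes) {
  v <- mesh$vertices
  if (identical(probes, "soma")) {
    p <- v[v$region == "soma", c("index", "cell", "vid")]
  } else if (identical(probes, "all")) {
    p <- v[, c("index", "cell", "vid")]
  } else {
    idx <- global_vertex(mesh, probes$cell, probes$vertex)
    p <- tibble(index = idx, cell = probes$cell, vid = probes$vertex)
  }
  p
}

#' @export
print.cable_result <- function(x, ...) {
  cat(sprintf("<cable_result> %d steps to t = %.3f ms; %d probe(s), %d synapse event(s)\n",
              x$steps, x$state$t * 1e3,
              length(unique(paste(x$traces$cell, x$traces$vertex))),
              nrow(x$events)))
  if (nrow(x$dt_history) > 0) {
    cat(sprintf("  dt range [%.3g, %.3g] s\n",
                min(x$dt_history$dt), max(x$dt_history$dt)))
  }
  invisible(x)
}

# ---- monolithic assembly & partitioned solve ---------------------------

#' Assemble the voltage linear system
#'
#' The implicit-axial system of one step,
#' `(diag(C_m/dt) + L) V_new = (C_m/dt) V_old - I_mem`, as an explicit
#' sparse symmetric matrix plus right-hand side, together with its
#' building blocks (edge list, diagonal mass) so that block-partitioned
#' additive storage can be reconstructed.  This is the reference route for
#' testing the tree solver and the substrate of [partitioned_solve()].
#'
#' @param mesh A [compartment_mesh()].
#' @param v Previous potential per vertex, V.
#' @param i_mem Outward membrane current per vertex, A (already integrated
#'   over the compartment area).
#' @param dt Time step, s.
#' @return List of class `cable_system`: `A` (dgCMatrix), `b`,
#'   `diag_mass`, `edges`, `order` (the Cuthill-McKee permutation).
#' @export
assemble_system <- function(mesh, v, i_mem, dt) {
  n <- mesh$n
  e <- mesh$edges
  A <- Matrix::sparseMatrix(
    i = c(seq_len(n), e$i, e$j), j = c(seq_len(n), e$j, e$i),
    x = c(mesh$vertices$Cm / dt + mesh$sumG, -e$G, -e$G),
    dims = c(n, n))
  structure(list(A = A, b = mesh$vertices$Cm / dt * v - i_mem,
                 diag_mass = mesh$vertices$Cm / dt,
                 edges = e[, c("i", "j", "G")], order = mesh$order),
            class = "cable_system")
}

#' Solve the voltage system with the ordered tree LU
#'
#' Direct O(n) solve of an [assemble_system()] system using the reversed
#' Cuthill-McKee ordering (at most one entry right of the diagonal per
#' row): one elimination sweep, one back-substitution.
#'
#' @param system A `cable_system`.
#' @param mesh The mesh the system was assembled on.
#' @return Solution vector (global vertex order).
#' @export
tree_solve_system <- function(system, mesh) {
  ord <- mesh$order
  dg <- (system$diag_mass + mesh$sumG)[ord]
  b <- system$b[ord]
  n <- length(b)
  sup <- ifelse(is.na(mesh$sup), -1L, as.integer(mesh$sup - 1L))
  x <- tree_solve_r(sup, mesh$g_sup, dg, b)
  out <- numeric(n); out[ord] <- x
  out
}

tree_solve_r <- function(sup, g_sup, dg, b) {
  n <- length(dg)
  for (k in seq_len(n)) {
    p <- sup[k] + 1L
    if (p > 0) {
      dg[p] <- dg[p] - g_sup[k]^2 / dg[k]
      b[p] <- b[p] + g_sup[k] * b[k] / dg[k]
    }
  }
  x <- numeric(n)
  for (k in rev(seq_len(n))) {
    p <- sup[k] + 1L
    x[k] <- (b[k] + if (p > 0) g_sup[k] * x[p] else 0) / dg[k]
  }
  x
}

#' Block-partitioned additive-correction solve
#'
#' Emulates (serially) the parallel solution of neurons cut across
#' processors.  The vertices are partitioned into blocks; block matrices
#' are stored additively -- each edge contributes to exactly one block
#' containing both endpoints, and the diagonal mass of a cut vertex is
#' split evenly across the blocks sharing it, so the global matrix equals
#' the sum of block matrices.  Each iteration splits the defect
#' additively across blocks, solves every block for a correction,
#' accumulates the corrections at the cutting points (partition-of-unity
#' weighted, which keeps the serial emulation stable; the exact solution
#' is a fixed point), and repeats until the defect norm has dropped by
#' `reduction_factor` in every block.  With no cut vertex the block
#' solves are exact and the iteration converges in one step; in the
#' mass-dominated regime of CFL-limited steps, cut cables typically need
#' well under fifteen iterations.
#'
#' @param system A `cable_system` from [assemble_system()].
#' @param blocks List of integer vertex-index vectors covering all
#'   vertices; vertices present in several blocks are the cut points.
#'   Every edge must have both endpoints inside at least one common block.
#' @param x0 Starting iterate (defaults to zeros).
#' @param reduction_factor Target relative defect reduction per block
#'   (1 returns `x0` untouched).
#' @param max_iter Iteration cap; exceeding it is an error reporting the
#'   defect history.
#' @return List: `solution`, `iterations`, `defect_history` (tibble
#'   iteration x block).
#' @export
partitioned_solve <- function(system, blocks, x0 = NULL,
                              reduction_factor = 1e-10, max_iter = 50) {
  n <- length(system$b)
  if (is.null(x0)) x0 <- numeric(n)
  multiplicity <- numeric(n)
  for (blk in blocks) multiplicity[blk] <- multiplicity[blk] + 1
  if (any(multiplicity == 0)) abort("blocks must cover every vertex")

  e <- system$edges
  owner <- rep(NA_integer_, nrow(e))
  for (bi in seq_along(blocks)) {
    inb <- e$i %in% blocks[[bi]] & e$j %in% blocks[[bi]]
    owner[is.na(owner) & inb] <- bi
  }
  if (anyNA(owner)) {
    abort("every edge needs both endpoints in a common block (cut at vertices, not edges)")
  }

  # additive block matrices over local indices
  Ak <- list(); lut <- list()
  for (bi in seq_along(blocks)) {
    blk <- blocks[[bi]]
    loc <- integer(n); loc[blk] <- seq_along(blk)
    mine <- which(owner == bi)
    # off-block-diagonal mass split across sharing blocks; edge Laplacian
    # contributions (diagonal + off-diagonal) assigned to the owning block
    diag_part <- system$diag_mass[blk] / multiplicity[blk]
    ii <- c(seq_along(blk), loc[e$i[mine]], loc[e$j[mine]],
            loc[e$i[mine]], loc[e$j[mine]])
    jj <- c(seq_along(blk), loc[e$j[mine]], loc[e$i[mine]],
            loc[e$i[mine]], loc[e$j[mine]])
    xx <- c(diag_part, -e$G[mine], -e$G[mine], e$G[mine], e$G[mine])
    Ak[[bi]] <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                     dims = c(length(blk), length(blk)))
    lut[[bi]] <- blk
  }

  x <- x0
  # The global defect b - A x is split additively across blocks (a cut
  # vertex's defect divided by its multiplicity); each block solves for a
  # correction, and corrections are accumulated at the cutting points with
  # the same partition-of-unity weights.  The exact solution is a fixed
  # point (zero defect -> zero corrections), no-cut partitions converge in
  # one exact step, and in the mass-dominated regime of CFL-limited time
  # steps cut cables take a handful of iterations.
  defects <- function() {
    d_glob <- system$b - as.numeric(system$A %*% x)
    vapply(blocks, function(blk) sqrt(sum(d_glob[blk]^2)), numeric(1))
  }
  d0 <- defects()
  hist <- list(d0)
  iter <- 0L
  repeat {
    d <- hist[[length(hist)]]
    if (all(d <= d0 * reduction_factor + 1e-300)) break
    if (iter >= max_iter) {
      h <- do.call(rbind, hist)
      abort(paste0("partitioned solve did not converge in ", max_iter,
                   " iterations; defect history:\n",
                   paste(apply(h, 1, function(r)
                     paste(signif(r, 3), collapse = " ")), collapse = "\n")))
    }
    r_glob <- system$b - as.numeric(system$A %*% x)
    corr <- numeric(n)
    for (bi in seq_along(blocks)) {
      blk <- lut[[bi]]
      ck <- as.numeric(Matrix::solve(Ak[[bi]], r_glob[blk] / multiplicity[blk]))
      corr[blk] <- corr[blk] + ck / multiplicity[blk]
    }
    x <- x + corr
    iter <- iter + 1L
    hist[[length(hist) + 1L]] <- defects()
  }
  list(solution = x, iterations = iter,
       defect_history = tibble(iteration = rep(seq_along(hist) - 1L,
                                               each = length(blocks)),
                               block = rep(seq_along(blocks), length(hist)),
                               defect = unlist(hist)))
}
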