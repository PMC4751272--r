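# Synthetic layered cortical networks: stylized parametric morphologies,
# distance-rule synaptogenesis gated by a cell-type connectivity matrix,
# and thalamic (primary) input placement.

#' Cell-type connectivity matrix
#'
#' Base synaptic conductances `gs(T1, T2)` in nS for allowed presynaptic
#' to postsynaptic cell-type pairs.  A pair absent from the table is
#' forbidden: no synapse is created (a forbidden lookup is an error, never
#' 0 nS).  The default is the neocortical table used by the network
#' studies (pyramidal L2/3, spiny stellate L4, pyramidal L5A/L5B).
#'
#' @param pairs Tibble with columns `pre`, `post`, `gs` (nS, > 0).
#' @return Tibble of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("pre", "post", "gs") %in% names(pairs)))
  if (any(pairs$gs <= 0)) abort("base conductances of allowed pairs must be > 0")
  class(pairs) <- c("connectivity_matrix", class(tibble::tibble()))
  pairs
}

#' @rdname connectivity_matrix
#' @export
default_connectivity <- function() {
  connectivity_matrix(tibble::tribble(
    ~pre,             ~post,            ~gs,
    "L2/3-pyramidal", "L2/3-pyramidal", 1.0,
    "L2/3-pyramidal", "L5A-pyramidal",  0.8,
    "L2/3-pyramidal", "L5B-pyramidal",  0.3,
    "L4-stellate",    "L2/3-pyramidal", 0.7,
    "L4-stellate",    "L4-stellate",    1.6,
    "L4-stellate",    "L5A-pyramidal",  0.6,
    "L5A-pyramidal",  "L2/3-pyramidal", 0.5,
    "L5A-pyramidal",  "L5A-pyramidal",  2.0,
    "L5B-pyramidal",  "L5B-pyramidal",  1.3))
}

#' Base conductance lookup
#'
#' @param conn A [connectivity_matrix()].
#' @param pre,post Cell-type labels (vectorized).
#' @return Base conductance(s) in nS, `NA` for forbidden pairs.
#' @export
conn_base <- function(conn, pre, post) {
  idx <- match(paste(pre, post), paste(conn$pre, conn$post))
  conn$gs[idx]
}

#' Distance-dependent synaptic conductance
#'
#' Maximal conductance of an interconnecting synapse grows linearly with
#' the postsynaptic site's path distance to the soma:
#' `g_max = (1 + 0.001 dsd) * gs(T1, T2)` with `dsd` in micrometres.
#'
#' @param base Base conductance `gs(T1, T2)`, nS (> 0; a forbidden-pair
#'   `NA` is rejected).
#' @param dsd Path distance of the postsynapse to the soma, micrometres.
#' @return Maximal conductance, nS.
#' @export
synaptic_conductance <- function(base, dsd) {
  if (any(is.na(base)) || any(base <= 0)) {
    abort("base conductance must be a positive allowed-pair value")
  }
  if (any(dsd < 0)) abort("distance to soma must be >= 0")
  (1 + 0.001 * dsd) * base
}

#' Network generator configuration
#'
#' @param layers Tibble with columns `cell_type`, `count`, `z_min`,
#'   `z_max` (layer depth slab, micrometres).  The default is a
#'   desk-scale four-type column with the composition ratio of the large
#'   network study (7:7:3:3 for L2/3, L4, L5A, L5B).
#' @param box_xy Lateral extents `c(x, y)`, micrometres.
#' @param dist_synapse Synapse creation distance threshold, micrometres.
#' @param thalamic Named vector of mean primary-synapse counts per cell
#'   for thalamically driven types.
#' @param edge_length Section resolution of the generated morphologies,
#'   micrometres.  The distance rule counts section pairs, so the fitted
#'   count-vs-distance exponent carries a finite-section bias of order
#'   `edge_length / dist_synapse`; keeping sections at about a fifth of
#'   the smallest probed distance holds that bias near 0.1.
#' @param min_separation Minimum distance between somata, micrometres.
#' @param seed Integer seed.
#' @return List of class `netgen_config`.
#' @export
netgen_config <- function(layers = NULL,
                          box_xy = c(100, 100),
                          dist_synapse = 3,
                          thalamic = c("L4-stellate" = 30,
                                       "L5B-pyramidal" = 25),
                          edge_length = 0.2,
                          min_separation = 12,
                          seed = 1L) {
  if (is.null(layers)) {
    layers <- tibble::tribble(
      ~cell_type,       ~count, ~z_min, ~z_max,
      "L2/3-pyramidal", 14L,    190,    280,
      "L4-stellate",    14L,    120,    190,
      "L5A-pyramidal",  6L,     60,     120,
      "L5B-pyramidal",  6L,     0,      60)
  }
  layers <- tibble::as_tibble(layers)
  stopifnot(dist_synapse > 0, all(layers$count >= 0), edge_length > 0)
  structure(list(layers = layers, box_xy = box_xy,
                 dist_synapse = dist_synapse, thalamic = thalamic,
                 edge_length = edge_length,
                 min_separation = min_separation, seed = seed),
            class = "netgen_config")
}

# ---- stylized parametric morphologies ---------------------------------
# Each type gets: a soma; basal (or stellate) dendrites in random lateral
# directions; pyramidal types an apical trunk ascending towards the upper
# layers; an axon descending briefly and then running vertically across
# the z-range of the layers its type may innervate (from the connectivity
# matrix), with two lateral collaterals inside that range.

type_morphology <- function(cell_type) {
  switch(cell_type,
    "L2/3-pyramidal" = list(n_basal = 3, basal_len = 90, apical_len = 80,
                            soma_radius = 8),
    "L4-stellate"    = list(n_basal = 4, basal_len = 80, apical_len = 0,
                            soma_radius = 7),
    "L5A-pyramidal"  = list(n_basal = 3, basal_len = 100, apical_len = 140,
                            soma_radius = 9),
    "L5B-pyramidal"  = list(n_basal = 3, basal_len = 100, apical_len = 160,
                            soma_radius = 9),
    list(n_basal = 3, basal_len = 90, apical_len = 0, soma_radius = 8))
}

# polyline helper: append a straight run of vertices from `from_id`
polyline <- function(rows, from_id, from_xyz, dir, len, radius, region,
                     next_id, n_seg = 4) {
  dir <- dir / sqrt(sum(dir^2))
  step_len <- len / n_seg
  ids <- next_id + seq_len(n_seg) - 1L
  seg <- tibble(
    id = ids,
    x = from_xyz[1] + dir[1] * step_len * seq_len(n_seg),
    y = from_xyz[2] + dir[2] * step_len * seq_len(n_seg),
    z = from_xyz[3] + dir[3] * step_len * seq_len(n_seg),
    radius = radius, region = region,
    parent = c(from_id, ids[-n_seg]))
  list(rows = c(rows, list(seg)), last_id = ids[n_seg],
       last_xyz = c(seg$x[n_seg], seg$y[n_seg], seg$z[n_seg]),
       next_id = next_id + n_seg)
}

# one stylized cell; all randomness from the caller's RNG stream
stylized_cell <- function(cell_type, soma_xyz, axon_z_range, box_xy,
                          edge_length) {
  mp <- type_morphology(cell_type)
  rows <- list(tibble(id = 1L, x = soma_xyz[1], y = soma_xyz[2],
                      z = soma_xyz[3], radius = mp$soma_radius,
                      region = "soma", parent = NA_integer_))
  next_id <- 2L

  for (b in seq_len(mp$n_basal)) {
    phi <- runif(1, 0, 2 * pi)
    tilt <- runif(1, -0.35, 0.1)    # mostly lateral, slight droop
    dir <- c(cos(phi), sin(phi), tilt)
    st <- polyline(rows, 1L, soma_xyz, dir, mp$basal_len, 1,
                   "dendrite-basal", next_id)
    rows <- st$rows; next_id <- st$next_id
  }

  if (mp$apical_len > 0) {
    jitter <- runif(2, -0.15, 0.15)
    st <- polyline(rows, 1L, soma_xyz, c(jitter, 1), mp$apical_len, 1.2,
                   "dendrite-apical", next_id)
    rows <- st$rows; next_id <- st$next_id
    # small apical tuft
    for (s in c(-1, 1)) {
      phi <- runif(1, 0, 2 * pi)
      st2 <- polyline(rows, st$last_id, st$last_xyz,
                      c(0.8 * cos(phi), 0.8 * sin(phi), 0.6),
                      mp$apical_len * 0.4, 1, "dendrite-apical", next_id)
      rows <- st2$rows; next_id <- st2$next_id
    }
  }

  # axon: drop from the soma to the innervation range, run across it,
  # two lateral collaterals at random depths inside the range
  z_lo <- axon_z_range[1]; z_hi <- axon_z_range[2]
  entry_z <- if (soma_xyz[3] > z_hi) z_hi else if (soma_xyz[3] < z_lo) z_lo
             else soma_xyz[3]
  cur_id <- 1L; cur <- soma_xyz
  if (abs(entry_z - soma_xyz[3]) > 1) {
    st <- polyline(rows, cur_id, cur,
                   c(runif(2, -0.25, 0.25), sign(entry_z - soma_xyz[3])),
                   abs(entry_z - soma_xyz[3]), 0.5, "axon", next_id)
    rows <- st$rows; next_id <- st$next_id; cur_id <- st$last_id; cur <- st$last_xyz
  }
  run <- (z_hi - z_lo)
  if (run > 1) {
    to_top <- z_hi - cur[3]
    dir_z <- if (to_top > run / 2) 1 else -1
    span <- if (dir_z > 0) z_hi - cur[3] else cur[3] - z_lo
    if (span > 1) {
      st <- polyline(rows, cur_id, cur, c(runif(2, -0.25, 0.25), dir_z),
                     span, 0.5, "axon", next_id, n_seg = 6)
      rows <- st$rows; next_id <- st$next_id
      trunk_last <- st$last_id
      # collaterals branch from trunk-interior vertices
      trunk <- rows[[length(rows)]]
      for (cb in 1:2) {
        k <- sample(nrow(trunk), 1)
        phi <- runif(1, 0, 2 * pi)
        st2 <- polyline(rows, trunk$id[k],
                        c(trunk$x[k], trunk$y[k], trunk$z[k]),
                        c(cos(phi), sin(phi), runif(1, -0.2, 0.2)),
                        runif(1, 60, 110), 0.5, "axon", next_id)
        rows <- st2$rows; next_id <- st2$next_id
      }
    }
  } else {
    # local axon
    phi <- runif(1, 0, 2 * pi)
    st <- polyline(rows, cur_id, cur, c(cos(phi), sin(phi), -0.1), 80, 0.5,
                   "axon", next_id)
    rows <- st$rows; next_id <- st$next_id
  }

  g <- neuron_graph(dplyr::bind_rows(rows), cell_type = cell_type)
  resample_edges(g, edge_length)
}

#' Generate a synthetic layered network
#'
#' Places each layer's somata uniformly in its depth slab (respecting a
#' minimum soma separation), grows a stylized parametric morphology per
#' cell (basal/stellate dendrites, apical trunks ascending towards upper
#' layers, descending axons spanning the layers the type innervates) and
#' returns the assembled geometry.  Deterministic for a fixed seed.
#'
#' @param config A [netgen_config()].
#' @return A [network_geometry()]; the configuration is attached as
#'   attribute `"config"`.
#' @export
generate_network <- function(config) {
  layers <- config$layers
  conn <- default_connectivity()
  withr_seed(config$seed, {
    cells <- list()
    placed <- matrix(numeric(0), ncol = 3)
    for (li in seq_len(nrow(layers))) {
      ct <- layers$cell_type[li]
      # innervation range: z-extent of layers this type projects to
      targets <- conn$post[conn$pre == ct]
      tz <- layers[layers$cell_type %in% targets, ]
      axon_range <- if (nrow(tz) > 0) c(min(tz$z_min), max(tz$z_max))
                    else c(layers$z_min[li], layers$z_max[li])
      cnt <- layers$count[li]
      for (ci in seq_len(cnt)) {
        for (attempt in 1:200) {
          pos <- c(runif(1, 0, config$box_xy[1]),
                   runif(1, 0, config$box_xy[2]),
                   runif(1, layers$z_min[li], layers$z_max[li]))
          ok <- nrow(placed) == 0 ||
            min(sqrt(colSums((t(placed) - pos)^2))) >= config$min_separation
          if (ok) break
          if (attempt == 200) {
            abort(sprintf(
              "box too small: cannot place %d %s somata at separation %g um",
              cnt, ct, config$min_separation))
          }
        }
        placed <- rbind(placed, pos)
        cells[[length(cells) + 1L]] <-
          stylized_cell(ct, pos, axon_range, config$box_xy,
                        config$edge_length)
      }
    }
  })
  z_all <- range(c(layers$z_min, layers$z_max, 0))
  bbox <- rbind(min = c(x = 0, y = 0, z = z_all[1]),
                max = c(x = config$box_xy[1], y = config$box_xy[2],
                        z = z_all[2]))
  net <- network_geometry(cells, bbox = bbox)
  attr(net, "config") <- config
  net
}

#' Create interconnecting synapses by the distance rule
#'
#' For every axon-section/dendrite-section pair of different cells whose
#' cell types form an allowed pair and whose minimum Euclidean distance
#' falls below `dist_synapse`, one interconnecting synapse is created at
#' the closest points (at most one per section pair).  The distance is
#' the true minimum between the two line segments, so the criterion is
#' robust to how finely the geometry is discretized.  The maximal
#' conductance applies the distance-to-soma rule
#' ([synaptic_conductance()]); kinetics default to a fast AMPA receptor
#' parameterization.
#'
#' @param net A [network_geometry()].
#' @param dist_synapse Creation distance threshold, micrometres.
#' @param conn A [connectivity_matrix()].
#' @param seed Reserved for API symmetry; the rule itself is
#'   deterministic.
#' @param tau1,tau2 Bi-exponential rise/decay constants, ms.
#' @param v_th Presynaptic activation threshold, mV.
#' @return A synapse set of interconnecting synapses (possibly empty).
#' @export
create_interconnecting_synapses <- function(net, dist_synapse,
                                            conn = default_connectivity(),
                                            seed = 1L, tau1 = 0.2,
                                            tau2 = 1.7, v_th = -10) {
  seg <- network_segments(net)
  ax <- seg[seg$compartment == "axon", ]
  de <- seg[seg$compartment == "dendrite", ]
  if (nrow(ax) == 0 || nrow(de) == 0) return(empty_synapse_set())

  pairs <- segment_pairs_within(
    as.matrix(ax[, c("x0", "y0", "z0")]), as.matrix(ax[, c("x1", "y1", "z1")]),
    as.matrix(de[, c("x0", "y0", "z0")]), as.matrix(de[, c("x1", "y1", "z1")]),
    dist_synapse)
  if (length(pairs$i) == 0) return(empty_synapse_set())

  cand <- tibble(
    pre_cell = ax$cell[pairs$i], pre_edge = ax$edge[pairs$i],
    pre_offset = pairs$offset_i,
    post_cell = de$cell[pairs$j], post_edge = de$edge[pairs$j],
    post_offset = pairs$offset_j, distance = pairs$distance)
  cand <- cand[cand$pre_cell != cand$post_cell, ]   # no autapses
  if (nrow(cand) == 0) return(empty_synapse_set())

  types <- vapply(net$cells, function(g) g$cell_type, character(1))
  cand$base <- conn_base(conn, types[cand$pre_cell], types[cand$post_cell])
  cand <- cand[!is.na(cand$base), ]
  if (nrow(cand) == 0) return(empty_synapse_set())

  # postsynaptic path distance to soma at the synapse location
  cand$dsd <- NA_real_
  for (cc in unique(cand$post_cell)) {
    g <- net$cells[[cc]]
    e <- graph_edges(g)
    dist_all <- path_distance_to_soma(g)$distance
    rows <- which(cand$post_cell == cc)
    eidx <- match(cand$post_edge[rows], e$edge)
    cand$dsd[rows] <- dist_all[e$parent[eidx]] +
      cand$post_offset[rows] * e$length[eidx]
  }

  # presynaptic vertex: segment endpoint nearest the closest point
  cand$pre_vertex <- NA_integer_
  for (cc in unique(cand$pre_cell)) {
    g <- net$cells[[cc]]
    e <- graph_edges(g)
    rows <- which(cand$pre_cell == cc)
    eidx <- match(cand$pre_edge[rows], e$edge)
    cand$pre_vertex[rows] <- ifelse(cand$pre_offset[rows] <= 0.5,
                                    e$parent[eidx], e$child[eidx])
  }

  off <- pmin(pmax(cand$post_offset, 0.01), 0.99)
  out <- new_synapse_set(tibble(
    kind = "interconnecting", cell = cand$post_cell, edge = cand$post_edge,
    offset = off,
    g_max = synaptic_conductance(cand$base, cand$dsd),
    tau1 = tau1, tau2 = tau2, e_rev = 0, v_th = v_th,
    pre_cell = cand$pre_cell, pre_vertex = as.integer(cand$pre_vertex)))
  out$distance <- cand$distance   # creation distance, for scaling analyses
  out
}

# all edges of a network as 3D segments with compartment labels
network_segments <- function(net) {
  purrr::imap_dfr(net$cells, function(g, ci) {
    e <- graph_edges(g)
    v <- g$vertices
    comp <- v$region[e$child]
    comp <- ifelse(comp %in% c("dendrite-basal", "dendrite-apical"),
                   "dendrite", comp)
    tibble(cell = ci, edge = e$edge, compartment = comp,
           x0 = v$x[e$parent], y0 = v$y[e$parent], z0 = v$z[e$parent],
           x1 = v$x[e$child], y1 = v$y[e$child], z1 = v$z[e$child])
  })
}

#' Place thalamic (primary) input synapses
#'
#' Distributes primary synapses on the dendrites of thalamically driven
#' cell types.  Per-cell counts are Poisson around the configured means
#' (the study prescribes averages, not exact counts); placement uses the
#' length-weighted edge distribution of [distribute_primary()].
#'
#' @param net A [network_geometry()].
#' @param seed Integer seed.
#' @param means Named vector of mean counts per cell by cell type.
#' @param g_max Maximal conductance per input, nS.
#' @return A synapse set of primary synapses (empty if no driven type is
#'   present).
#' @export
place_thalamic_inputs <- function(net, seed = 1L,
                                  means = c("L4-stellate" = 30,
                                            "L5B-pyramidal" = 25),
                                  g_max = 1.2) {
  types <- vapply(net$cells, function(g) g$cell_type, character(1))
  sets <- list()
  for (ci in seq_along(net$cells)) {
    if (!types[ci] %in% names(means)) next
    n_syn <- withr_seed(seed + 7919L * ci, rpois(1, means[[types[ci]]]))
    if (n_syn == 0) next
    sets[[length(sets) + 1L]] <-
      distribute_primary(net$cells[[ci]], n_syn, seed = seed + 104729L * ci,
                         g_max = g_max, cell = ci)
  }
  if (length(sets) == 0) return(empty_synapse_set())
  new_synapse_set(dplyr::bind_rows(sets))
}
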