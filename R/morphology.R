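#' @useDynLib cablenet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import tibble
#' @importFrom rlang abort warn .data
#' @importFrom stats rnorm runif rpois setNames approx coef lm
#' @importFrom utils head tail
NULL

REGIONS <- c("soma", "dendrite-basal", "dendrite-apical", "axon")

#' Construct a neuron morphology graph
#'
#' A `neuron_graph` is a tree of 3D points rooted at the soma.  Each vertex
#' carries a position in micrometres, a radius in micrometres and a region
#' label; each non-root vertex points to its parent.  This is the SWC view of
#' a neuron: the solver later wraps a tubular compartment of the vertex's
#' radius around every vertex.
#'
#' @param vertices Tibble/data frame with columns `id` (integer, contiguous
#'   from 1), `x`, `y`, `z` (micrometres), `radius` (micrometres, positive),
#'   `region` (one of `"soma"`, `"dendrite-basal"`, `"dendrite-apical"`,
#'   `"axon"`) and `parent` (id of the parent vertex, `NA` for the root).
#'   An optional `orig_id` column preserves ids of the source file.
#' @param cell_type Free-form label, e.g. `"L2/3-pyramidal"`.
#' @return An object of class `neuron_graph`.
#' @export
neuron_graph <- function(vertices, cell_type = "unknown") {
  vertices <- tibble::as_tibble(vertices)
  required <- c("id", "x", "y", "z", "radius", "region", "parent")
  missing_cols <- setdiff(required, names(vertices))
  if (length(missing_cols) > 0) {
    abort(paste0("neuron_graph vertices lack column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"orig_id" %in% names(vertices)) vertices$orig_id <- vertices$id
  g <- structure(list(vertices = vertices, cell_type = cell_type),
                 class = "neuron_graph")
  validate_neuron_graph(g)
}

#' @export
print.neuron_graph <- function(x, ...) {
  v <- x$vertices
  cat(sprintf("<neuron_graph> %s: %d vertices, %d edges\n",
              x$cell_type, nrow(v), sum(!is.na(v$parent))))
  counts <- table(v$region)
  cat("  regions:", paste(sprintf("%s=%d", names(counts), counts),
                          collapse = ", "), "\n")
  cat(sprintf("  total cable length: %.1f um\n", sum(graph_edges(x)$length)))
  invisible(x)
}

validate_neuron_graph <- function(g) {
  v <- g$vertices
  n <- nrow(v)
  if (n == 0) abort("neuron_graph has no vertices")
  if (!identical(as.integer(v$id), seq_len(n))) {
    abort("vertex ids must be contiguous 1..n")
  }
  if (any(v$radius <= 0)) abort("all radii must be positive")
  if (!all(v$region %in% REGIONS)) {
    abort(paste0("unknown region label(s): ",
                 paste(setdiff(unique(v$region), REGIONS), collapse = ", ")))
  }
  roots <- which(is.na(v$parent))
  if (length(roots) != 1) {
    abort(sprintf("graph must have exactly one root, found %d", length(roots)))
  }
  p <- v$parent
  bad <- !is.na(p) & (p < 1 | p > n)
  if (any(bad)) abort("parent references a missing vertex id")
  # cycle check: walk each vertex to the root; a tree with one root and one
  # parent per vertex can only fail by containing a cycle off the root
  depth <- rep(NA_integer_, n)
  depth[roots] <- 0L
  frontier <- roots
  while (length(frontier) > 0) {
    nxt <- which(!is.na(p) & p %in% frontier & is.na(depth))
    depth[nxt] <- 1L
    frontier <- nxt
  }
  if (anyNA(depth)) abort("graph contains a cycle or disconnected vertices")
  g$root <- roots
  g
}

#' Edge table of a neuron graph
#'
#' @param graph A [neuron_graph()].
#' @return Tibble with one row per edge: `parent`, `child`, `length`
#'   (micrometres, Euclidean).
#' @export
graph_edges <- function(graph) {
  v <- graph$vertices
  child <- which(!is.na(v$parent))
  parent <- v$parent[child]
  len <- sqrt((v$x[child] - v$x[parent])^2 +
              (v$y[child] - v$y[parent])^2 +
              (v$z[child] - v$z[parent])^2)
  tibble(edge = seq_along(child), parent = as.integer(parent),
         child = as.integer(child), length = len)
}

#' Read an SWC morphology file
#'
#' Parses the 7-column SWC dialect used by NeuroMorpho.org
#' (`id type x y z radius parent`, `#` comments).  Type codes are mapped
#' 1 to soma, 2 to axon, 3 to basal dendrite, 4 to apical dendrite; unknown
#' codes are labelled basal dendrite with a warning.  Vertex ids are
#' re-indexed contiguously; the original ids are kept in `orig_id`.
#' Multi-point somata are collapsed to a single root vertex at the soma
#' centroid whose radius preserves the soma membrane area
#' (`4 pi r^2 = sum 2 pi a_i l_i`).
#'
#' @param path Path to an SWC file.  Radii must be radii (not diameters) in
#'   micrometres; files declaring diameters are out of scope.
#' @param cell_type Label attached to the resulting graph.
#' @return A [neuron_graph()].
#' @export
read_swc <- function(path, cell_type = basename(path)) {
  raw <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  if (nrow(raw) == 0) abort("empty SWC file")
  if (any(raw$radius <= 0)) abort("SWC file contains non-positive radius")
  unknown <- !(raw$type %in% 1:4)
  if (any(unknown)) {
    warn(sprintf("%d vertices with unknown SWC type code; labelled dendrite-basal",
                 sum(unknown)))
  }
  region <- rep("dendrite-basal", nrow(raw))
  region[raw$type == 1] <- "soma"
  region[raw$type == 2] <- "axon"
  region[raw$type == 3] <- "dendrite-basal"
  region[raw$type == 4] <- "dendrite-apical"

  roots <- which(raw$parent == -1)
  if (length(roots) != 1) {
    abort(sprintf("SWC file must have exactly one root (parent -1), found %d",
                  length(roots)))
  }
  idx <- match(raw$parent, raw$id)
  missing_parent <- raw$parent != -1 & is.na(idx)
  if (any(missing_parent)) abort("SWC parent references a missing id")

  v <- tibble(id = seq_len(nrow(raw)), x = raw$x, y = raw$y, z = raw$z,
              radius = raw$radius, region = region,
              parent = ifelse(raw$parent == -1, NA_integer_, idx),
              orig_id = raw$id)

  soma_idx <- which(v$region == "soma")
  if (length(soma_idx) > 1) v <- collapse_soma(v, soma_idx)

  neuron_graph(v, cell_type = cell_type)
}

# Collapse a multi-point soma to one root vertex: centroid position,
# area-equivalent radius (sphere surface = summed tubular soma area).
collapse_soma <- function(v, soma_idx) {
  seg_len <- function(i, j) sqrt((v$x[i] - v$x[j])^2 + (v$y[i] - v$y[j])^2 +
                                 (v$z[i] - v$z[j])^2)
  area <- 0
  for (i in soma_idx) {
    p <- v$parent[i]
    if (!is.na(p) && p %in% soma_idx) {
      l <- seg_len(i, p)
      area <- area + 2 * pi * mean(c(v$radius[i], v$radius[p])) * l
    }
  }
  r_eq <- if (area > 0) sqrt(area / (4 * pi)) else max(v$radius[soma_idx])
  cx <- mean(v$x[soma_idx]); cy <- mean(v$y[soma_idx]); cz <- mean(v$z[soma_idx])

  keep <- setdiff(seq_len(nrow(v)), soma_idx)
  root_old <- soma_idx[is.na(v$parent[soma_idx])]
  new_id <- integer(nrow(v))
  new_id[keep] <- seq_along(keep) + 1L
  new_id[soma_idx] <- 1L

  out <- v[keep, ]
  out$id <- new_id[keep]
  out$parent <- ifelse(is.na(out$parent), NA_integer_, new_id[out$parent])
  root_row <- tibble(id = 1L, x = cx, y = cy, z = cz, radius = r_eq,
                     region = "soma", parent = NA_integer_,
                     orig_id = v$orig_id[root_old])
  dplyr::arrange(dplyr::bind_rows(root_row, out), .data$id)
}

#' Write a neuron graph to SWC
#'
#' Deterministic 7-column output with region labels mapped back to SWC type
#' codes.  `write_swc` followed by [read_swc()] is the identity on topology,
#' coordinates and radii (within printed precision).
#'
#' @param graph A [neuron_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(graph, path) {
  v <- graph$vertices
  type <- c("soma" = 1L, "axon" = 2L, "dendrite-basal" = 3L,
            "dendrite-apical" = 4L)[v$region]
  lines <- sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                   v$id, type, v$x, v$y, v$z, v$radius,
                   ifelse(is.na(v$parent), -1L, v$parent))
  writeLines(c("# SWC written by cablenet", lines), path)
  invisible(path)
}

#' Path distance from a vertex to the soma
#'
#' Sum of Euclidean edge lengths along the unique tree path from `vertex`
#' to the root, in micrometres.  This is the distance entering the
#' distance-dependent synaptic conductance rule.
#'
#' @param graph A [neuron_graph()].
#' @param vertex Vertex id(s); default all vertices.
#' @return Tibble with columns `vertex` and `distance` (micrometres).
#' @export
path_distance_to_soma <- function(graph, vertex = NULL) {
  v <- graph$vertices
  n <- nrow(v)
  if (is.null(vertex)) vertex <- seq_len(n)
  if (any(vertex < 1 | vertex > n)) abort("vertex id out of range")
  e <- graph_edges(graph)
  elen <- numeric(n)           # length of edge to parent, per child vertex
  elen[e$child] <- e$length
  dist <- numeric(n)
  # accumulate in a parent-before-child order
  ord <- order(vertex_depths(v$parent))
  for (i in ord) {
    p <- v$parent[i]
    if (!is.na(p)) dist[i] <- dist[p] + elen[i]
  }
  tibble(vertex = as.integer(vertex), distance = dist[vertex])
}

vertex_depths <- function(parent) {
  n <- length(parent)
  depth <- rep(0L, n)
  frontier <- which(is.na(parent))
  d <- 0L
  while (length(frontier) > 0) {
    d <- d + 1L
    frontier <- which(!is.na(parent) & parent %in% frontier)
    depth[frontier] <- d
  }
  depth
}

#' Generate deterministic test geometries
#'
#' Parametric fixtures covering the shapes the solver and synapse machinery
#' are exercised on: an unbranched soma+dendrite cable (optionally with an
#' axon), a symmetric binary dendritic tree, and a two-cell network with a
#' controlled axon-dendrite gap.
#'
#' @param kind `"ball_and_stick"`, `"binary_tree"` or `"two_cell"`.
#' @param ... Passed to [make_ball_and_stick()], [make_binary_tree()] or
#'   [make_two_cell()].
#' @return A [neuron_graph()] (`ball_and_stick`, `binary_tree`) or a
#'   [network_geometry()] (`two_cell`).
#' @export
make_fixture <- function(kind = c("ball_and_stick", "binary_tree", "two_cell"),
                         ...) {
  kind <- match.arg(kind)
  switch(kind,
         ball_and_stick = make_ball_and_stick(...),
         binary_tree = make_binary_tree(...),
         two_cell = make_two_cell(...))
}

#' @rdname make_fixture
#' @param n_seg Number of dendritic segments (vertices = `n_seg + 1`).
#' @param L Dendrite length, micrometres.
#' @param a Dendrite radius, micrometres.
#' @param soma_radius Soma radius, micrometres.
#' @param axon Optional list `list(n_seg=, L=, a=)` appending an axon to the
#'   soma (used by the spike-initiation studies).
#' @param region Region label for the dendrite.
#' @param cell_type Cell-type label.
#' @export
make_ball_and_stick <- function(n_seg = 100, L = 1000, a = 1,
                                soma_radius = 5, axon = NULL,
                                region = "dendrite-apical",
                                cell_type = "ball-and-stick") {
  stopifnot(n_seg >= 1)
  if (a <= 0 || soma_radius <= 0 || L <= 0) abort("non-physical fixture parameters")
  dx <- L / n_seg
  v <- tibble(
    id = seq_len(n_seg + 1L),
    x = c(0, seq_len(n_seg) * dx), y = 0, z = 0,
    radius = c(soma_radius, rep(a, n_seg)),
    region = c("soma", rep(region, n_seg)),
    parent = c(NA_integer_, seq_len(n_seg)))
  if (!is.null(axon)) {
    if (axon$a <= 0 || axon$L <= 0) abort("non-physical fixture parameters")
    dxa <- axon$L / axon$n_seg
    n0 <- nrow(v)
    va <- tibble(
      id = n0 + seq_len(axon$n_seg),
      x = -seq_len(axon$n_seg) * dxa, y = 0, z = 0,
      radius = axon$a, region = "axon",
      parent = c(1L, n0 + seq_len(axon$n_seg - 1L)))
    v <- dplyr::bind_rows(v, va)
  }
  neuron_graph(v, cell_type = cell_type)
}

#' @rdname make_fixture
#' @param depth Branching depth: a single trunk leaves the soma and then
#'   bifurcates `depth` times, giving `2^(depth+1) - 1` dendritic segments.
#' @param seg_len Length of each branch segment, micrometres.
#' @export
make_binary_tree <- function(depth = 4, seg_len = 20, a = 1, soma_radius = 5,
                             cell_type = "binary-tree") {
  if (a <= 0 || soma_radius <= 0 || seg_len <= 0) {
    abort("non-physical fixture parameters")
  }
  # soma at origin, trunk straight up, then repeated bifurcation in the plane
  rows <- list(
    tibble(id = 1L, x = 0, y = 0, z = 0, radius = soma_radius,
           region = "soma", parent = NA_integer_),
    tibble(id = 2L, x = 0, y = seg_len, z = 0, radius = a,
           region = "dendrite-basal", parent = 1L))
  frontier <- tibble(id = 2L, x = 0, y = seg_len, angle = pi / 2)
  next_id <- 3L
  for (d in seq_len(depth)) {
    spread <- pi / (2^(d + 1))
    new_frontier <- list()
    for (k in seq_len(nrow(frontier))) {
      par <- frontier[k, ]
      for (s in c(-1, 1)) {
        ang <- par$angle + s * spread
        row <- tibble(id = next_id,
                      x = par$x + seg_len * cos(ang),
                      y = par$y + seg_len * sin(ang), z = 0,
                      radius = a, region = "dendrite-basal",
                      parent = par$id)
        rows[[length(rows) + 1L]] <- row
        new_frontier[[length(new_frontier) + 1L]] <-
          tibble(id = next_id, x = row$x, y = row$y, angle = ang)
        next_id <- next_id + 1L
      }
    }
    frontier <- dplyr::bind_rows(new_frontier)
  }
  neuron_graph(dplyr::bind_rows(rows), cell_type = cell_type)
}

#' @rdname make_fixture
#' @param gap Closest axon-dendrite distance between the two cells,
#'   micrometres.
#' @param pre_type,post_type Cell-type labels for the presynaptic (axon
#'   donor) and postsynaptic cell.
#' @export
make_two_cell <- function(gap = 2, n_seg = 20, L = 100, a = 1,
                          soma_radius = 5,
                          pre_type = "L4-stellate",
                          post_type = "L2/3-pyramidal") {
  if (gap <= 0) abort("non-physical fixture parameters")
  # Cell A: soma at origin, dendrite along +x, axon along +y then bending to
  # run parallel to cell B's dendrite at distance `gap`.
  dx <- L / n_seg
  pre_dend <- tibble(id = 2L + 0:(n_seg - 1L),
                     x = seq_len(n_seg) * dx, y = 0, z = 0,
                     radius = a, region = "dendrite-basal",
                     parent = c(1L, 2L + 0:(n_seg - 2L)))
  n0 <- n_seg + 1L
  # axon: descends in -y, then runs along x at y = -50
  ax1 <- tibble(id = n0 + seq_len(n_seg),
                x = 0, y = -seq_len(n_seg) * dx, z = 0,
                radius = a / 2, region = "axon",
                parent = c(1L, n0 + seq_len(n_seg - 1L)))
  n1 <- n0 + n_seg
  ax2 <- tibble(id = n1 + seq_len(n_seg),
                x = seq_len(n_seg) * dx, y = -L, z = 0,
                radius = a / 2, region = "axon",
                parent = c(n1, n1 + seq_len(n_seg - 1L)))
  pre <- neuron_graph(dplyr::bind_rows(
    tibble(id = 1L, x = 0, y = 0, z = 0, radius = soma_radius,
           region = "soma", parent = NA_integer_),
    pre_dend, ax1, ax2), cell_type = pre_type)

  # Cell B: soma offset in z by `gap` below the end of A's axon run; its
  # dendrite runs along x at y = -L, z = gap, so the closest axon-dendrite
  # approach is exactly `gap`.
  post_dend <- tibble(id = 2L + 0:(n_seg - 1L),
                      x = seq_len(n_seg) * dx, y = -L, z = gap,
                      radius = a, region = "dendrite-basal",
                      parent = c(1L, 2L + 0:(n_seg - 2L)))
  post <- neuron_graph(dplyr::bind_rows(
    tibble(id = 1L, x = 0, y = -L, z = gap, radius = soma_radius,
           region = "soma", parent = NA_integer_),
    post_dend), cell_type = post_type)

  network_geometry(list(pre, post))
}

#' Bundle cells into a network geometry
#'
#' @param cells List of [neuron_graph()] objects.
#' @param bbox Optional 2x3 matrix (rows: min/max; columns x, y, z,
#'   micrometres).  Defaults to the bounding box of all vertices.
#' @return Object of class `network_geometry` with `cells` and `bbox`.
#'   Subset labels (cell type x compartment type) are reported by
#'   [subset_labels()].
#' @export
network_geometry <- function(cells, bbox = NULL) {
  stopifnot(is.list(cells))
  for (cell in cells) {
    if (!inherits(cell, "neuron_graph")) abort("cells must be neuron_graph objects")
  }
  if (is.null(bbox)) {
    if (length(cells) > 0) {
      all_v <- dplyr::bind_rows(lapply(cells, function(g) g$vertices[, c("x", "y", "z")]))
      bbox <- rbind(min = apply(all_v, 2, min), max = apply(all_v, 2, max))
    } else {
      bbox <- rbind(min = c(x = 0, y = 0, z = 0), max = c(x = 0, y = 0, z = 0))
    }
  }
  structure(list(cells = cells, bbox = bbox), class = "network_geometry")
}

#' @export
print.network_geometry <- function(x, ...) {
  cat(sprintf("<network_geometry> %d cells\n", length(x$cells)))
  if (length(x$cells) > 0) {
    types <- table(vapply(x$cells, function(g) g$cell_type, character(1)))
    cat("  types:", paste(sprintf("%s=%d", names(types), types),
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset labels of a network
#'
#' Every vertex and edge of a network belongs to exactly one subset named
#' `"<cell type>#<compartment type>"`, the identifier convention used to
#' address parts of a network in simulation setup.
#'
#' @param net A [network_geometry()].
#' @return Tibble with one row per (cell, vertex): `cell`, `vertex`,
#'   `label`.
#' @export
subset_labels <- function(net) {
  purrr::imap_dfr(net$cells, function(g, i) {
    comp <- ifelse(g$vertices$region %in% c("dendrite-basal", "dendrite-apical"),
                   "dendrite", g$vertices$region)
    tibble(cell = i, vertex = g$vertices$id,
           label = paste0(g$cell_type, "#", comp))
  })
}

#' Resample edges to a maximum length
#'
#' Splits every edge longer than `max_len` into equal sub-edges with
#' linearly interpolated positions and radii.  Total cable length per branch
#' is preserved exactly; this is the knob controlling compartment size (and
#' hence the resolution at which the synapse distance rule sees the
#' geometry).
#'
#' @param graph A [neuron_graph()].
#' @param max_len Maximum edge length, micrometres.
#' @return A [neuron_graph()] with the same shape and finer edges.
#' @export
resample_edges <- function(graph, max_len) {
  stopifnot(max_len > 0)
  v <- graph$vertices
  rows <- list(v)
  next_id <- nrow(v)
  new_parent <- v$parent
  e <- graph_edges(graph)
  for (k in seq_len(nrow(e))) {
    if (e$length[k] <= max_len) next
    nsub <- ceiling(e$length[k] / max_len)
    ci <- e$child[k]; pi_ <- e$parent[k]
    frac <- seq_len(nsub - 1) / nsub
    ids <- next_id + seq_len(nsub - 1)
    mid <- tibble(
      id = ids,
      x = v$x[pi_] + frac * (v$x[ci] - v$x[pi_]),
      y = v$y[pi_] + frac * (v$y[ci] - v$y[pi_]),
      z = v$z[pi_] + frac * (v$z[ci] - v$z[pi_]),
      radius = v$radius[pi_] + frac * (v$radius[ci] - v$radius[pi_]),
      region = v$region[ci],
      parent = c(pi_, ids[-length(ids)]))
    new_parent[ci] <- ids[length(ids)]
    rows[[length(rows) + 1L]] <- mid
    next_id <- next_id + nsub - 1L
  }
  out <- dplyr::bind_rows(rows)
  out$parent[seq_len(nrow(v))] <- new_parent
  # re-index contiguously (appended vertices already are)
  neuron_graph(out, cell_type = graph$cell_type)
}

#' Read/write the network exchange format
#'
#' A versioned JSON document standing in for simulator-specific grid
#' formats: cells (with vertex tables), bounding box and optional synapse
#' records.  Writers emit deterministic field order so identical inputs give
#' byte-identical files.
#'
#' @param net A [network_geometry()].
#' @param synapses Optional synapse tibble (see [distribute_primary()] /
#'   [create_interconnecting_synapses()]).
#' @param path Output path.
#' @return `path` invisibly for the writer; a list
#'   `list(network, synapses)` for the reader.
#' @export
write_network_json <- function(net, path, synapses = NULL) {
  doc <- list(
    format = "cablenet-network",
    version = 1L,
    bbox = unname(as.matrix(net$bbox)),
    cells = lapply(net$cells, function(g) {
      list(cell_type = g$cell_type,
           vertices = as.data.frame(g$vertices[, c("id", "x", "y", "z",
                                                   "radius", "region",
                                                   "parent")]))
    }),
    synapses = if (!is.null(synapses)) as.data.frame(synapses))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "cablenet-network")) {
    abort("not a cablenet network exchange document")
  }
  cells <- lapply(seq_len(nrow_or_len(doc$cells)), function(i) {
    entry <- if (is.data.frame(doc$cells)) {
      list(cell_type = doc$cells$cell_type[[i]],
           vertices = doc$cells$vertices[[i]])
    } else doc$cells[[i]]
    v <- tibble::as_tibble(entry$vertices)
    v$parent <- as.integer(v$parent)
    v$id <- as.integer(v$id)
    neuron_graph(v, cell_type = entry$cell_type)
  })
  bbox <- matrix(unlist(doc$bbox), nrow = 2)
  rownames(bbox) <- c("min", "max")
  syn <- if (!is.null(doc$synapses) && length(doc$synapses) > 0) {
    tibble::as_tibble(doc$synapses)
  }
  list(network = network_geometry(cells, bbox = bbox), synapses = syn)
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
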