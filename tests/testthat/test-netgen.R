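test_that("connectivity matrix encodes allowed pairs and forbids the rest", {
  conn <- default_connectivity()
  expect_equal(conn_base(conn, "L5A-pyramidal", "L5A-pyramidal"), 2.0)
  expect_equal(conn_base(conn, "L4-stellate", "L4-stellate"), 1.6)
  expect_true(is.na(conn_base(conn, "L5B-pyramidal", "L2/3-pyramidal")))
  expect_true(is.na(conn_base(conn, "L2/3-pyramidal", "L4-stellate")))
  expect_error(connectivity_matrix(tibble::tibble(pre = "a", post = "b",
                                                  gs = 0)), "> 0")
})

test_that("synaptic conductance applies the distance rule", {
  expect_equal(synaptic_conductance(1.0, 0), 1.0)
  expect_equal(synaptic_conductance(1.0, 100), 1.1)
  expect_equal(synaptic_conductance(c(2, 0.5), c(50, 200)),
               c(2 * 1.05, 0.5 * 1.2))
  expect_error(synaptic_conductance(NA_real_, 10), "allowed-pair")
  expect_error(synaptic_conductance(-1, 10), "allowed-pair")
})

test_that("network generation is deterministic, layered and bounded", {
  layers <- tibble::tribble(
    ~cell_type,       ~count, ~z_min, ~z_max,
    "L2/3-pyramidal", 3L,     190,    280,
    "L4-stellate",    3L,     120,    190,
    "L5A-pyramidal",  2L,     60,     120,
    "L5B-pyramidal",  2L,     0,      60)
  cfg <- netgen_config(layers = layers, box_xy = c(80, 80),
                       edge_length = 2, seed = 5)
  net <- generate_network(cfg)
  expect_equal(length(net$cells), 10)
  types <- vapply(net$cells, function(g) g$cell_type, character(1))
  expect_equal(as.vector(table(types)[c("L2/3-pyramidal", "L4-stellate",
                                        "L5A-pyramidal", "L5B-pyramidal")]),
               c(3L, 3L, 2L, 2L))
  # somata inside their layer slabs and the lateral box
  for (i in seq_along(net$cells)) {
    soma <- net$cells[[i]]$vertices[net$cells[[i]]$root, ]
    slab <- layers[layers$cell_type == types[i], ]
    expect_gte(soma$z, slab$z_min); expect_lte(soma$z, slab$z_max)
    expect_gte(soma$x, 0); expect_lte(soma$x, 80)
  }
  # subset labels partition all vertices into type x compartment groups
  lab <- subset_labels(net)
  expect_equal(nrow(lab), sum(vapply(net$cells,
                                     function(g) nrow(g$vertices), numeric(1))))
  expect_true(all(grepl("#", lab$label)))

  # empty network is legal
  empty <- generate_network(netgen_config(
    layers = dplyr::mutate(layers, count = 0L)))
  expect_equal(length(empty$cells), 0)

  # same seed twice: byte-identical JSON export
  net2 <- generate_network(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_network_json(net, f1); write_network_json(net2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # impossible separation constraint errors out
  expect_error(generate_network(netgen_config(layers = layers,
                                              box_xy = c(5, 5),
                                              min_separation = 50)),
               "box too small")
})

test_that("distance rule creates synapses only below threshold, on allowed pairs", {
  net <- make_two_cell(gap = 2)
  expect_equal(nrow(create_interconnecting_synapses(net, 1)), 0)
  syn <- create_interconnecting_synapses(net, 3)
  expect_gte(nrow(syn), 1)
  types <- vapply(net$cells, function(g) g$cell_type, character(1))
  conn <- default_connectivity()
  expect_true(all(!is.na(conn_base(conn, types[syn$pre_cell],
                                   types[syn$cell]))))
  # brute-force oracle: every qualifying pair distance really is < 3 um,
  # and the pre side is an axon edge, the post side a dendrite edge
  for (k in seq_len(nrow(syn))) {
    pre <- net$cells[[syn$pre_cell[k]]]
    post <- net$cells[[syn$cell[k]]]
    expect_equal(pre$vertices$region[syn$pre_vertex[k]], "axon")
    e <- graph_edges(post)
    child <- e$child[match(syn$edge[k], e$edge)]
    expect_true(post$vertices$region[child] %in%
                  c("dendrite-basal", "dendrite-apical"))
    expect_lt(syn$distance[k], 3)
  }
  # counts are non-decreasing in dist_synapse
  counts <- vapply(c(2.2, 3, 4, 6), function(d)
    nrow(create_interconnecting_synapses(net, d)), numeric(1))
  expect_true(all(diff(counts) >= 0))
  # conductances follow the distance-to-soma rule within bounds
  base <- conn_base(conn, types[syn$pre_cell[1]], types[syn$cell[1]])
  expect_true(all(syn$g_max >= base))
  expect_true(all(syn$g_max <= base * (1 + 0.001 * 400)))
})

test_that("forbidden pairs never receive synapses on a mixed network", {
  cfg <- netgen_config(layers = tibble::tribble(
    ~cell_type,       ~count, ~z_min, ~z_max,
    "L2/3-pyramidal", 4L,     100,    160,
    "L5B-pyramidal",  4L,     0,      60), box_xy = c(60, 60),
    edge_length = 1, seed = 3)
  net <- generate_network(cfg)
  syn <- create_interconnecting_synapses(net, 6)
  types <- vapply(net$cells, function(g) g$cell_type, character(1))
  conn <- default_connectivity()
  if (nrow(syn) > 0) {
    # exhaustive: every created pair is allowed; L5B -> L2/3 is forbidden
    expect_true(all(!is.na(conn_base(conn, types[syn$pre_cell],
                                     types[syn$cell]))))
    expect_false(any(types[syn$pre_cell] == "L5B-pyramidal" &
                       types[syn$cell] == "L2/3-pyramidal"))
  }
  succeed()
})

test_that("thalamic input counts are Poisson around the configured means", {
  layers <- tibble::tribble(
    ~cell_type,    ~count, ~z_min, ~z_max,
    "L4-stellate", 3L,     0,      80)
  net <- generate_network(netgen_config(layers = layers, box_xy = c(80, 80),
                                        edge_length = 4, seed = 2))
  totals <- vapply(1:100, function(s)
    nrow(place_thalamic_inputs(net, seed = s)), numeric(1))
  # mean 3 cells x 30 = 90; CLT bound at 4 sigma of the seed-mean
  expect_lt(abs(mean(totals) - 90), 4 * sqrt(90 / 100))
  # every synapse sits on a dendrite edge of its own cell
  syn <- place_thalamic_inputs(net, seed = 1)
  for (k in seq_len(nrow(syn))) {
    g <- net$cells[[syn$cell[k]]]
    e <- graph_edges(g)
    child <- e$child[match(syn$edge[k], e$edge)]
    expect_true(g$vertices$region[child] %in%
                  c("dendrite-basal", "dendrite-apical"))
  }
  # no driven types -> empty set, no error
  l2 <- tibble::tribble(~cell_type, ~count, ~z_min, ~z_max,
                        "L2/3-pyramidal", 2L, 0, 80)
  net2 <- generate_network(netgen_config(layers = l2, box_xy = c(80, 80),
                                         edge_length = 4, seed = 2))
  expect_equal(nrow(place_thalamic_inputs(net2, seed = 1)), 0)
})
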