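test_that("SWC reading maps types, re-indexes and validates structure", {
  swc <- tempfile(fileext = ".swc")
  writeLines(c("# comment",
               "1 1 0 0 0 5 -1",
               "2 3 10 0 0 1 1",
               "3 3 20 0 0 1 2"), swc)
  g <- read_swc(swc)
  expect_equal(nrow(g$vertices), 3)
  expect_equal(sum(!is.na(g$vertices$parent)), 2)
  expect_equal(g$root, 1L)
  expect_equal(g$vertices$region, c("soma", "dendrite-basal", "dendrite-basal"))

  # parent referencing a missing id
  writeLines(c("1 1 0 0 0 5 -1", "2 3 1 0 0 1 9"), swc)
  expect_error(read_swc(swc), "missing id")

  # two roots
  writeLines(c("1 1 0 0 0 5 -1", "2 3 1 0 0 1 -1"), swc)
  expect_error(read_swc(swc), "exactly one root")

  # non-positive radius
  writeLines(c("1 1 0 0 0 5 -1", "2 3 1 0 0 0 1"), swc)
  expect_error(read_swc(swc), "radius")

  # unknown type code warns and falls back to basal dendrite
  writeLines(c("1 1 0 0 0 5 -1", "2 7 1 0 0 1 1"), swc)
  expect_warning(g2 <- read_swc(swc), "unknown")
  expect_equal(g2$vertices$region[2], "dendrite-basal")
})

test_that("SWC write/read round trip is the identity on a 50-vertex tree", {
  g <- random_tree(depth = 4, seed = 3)   # 1 soma + 31 dendritic vertices
  g <- resample_edges(g, 12)              # push past 50 vertices
  expect_gt(nrow(g$vertices), 50)
  swc <- tempfile(fileext = ".swc")
  write_swc(g, swc)
  g2 <- read_swc(swc)
  expect_equal(g2$vertices$x, g$vertices$x, tolerance = 1e-6)
  expect_equal(g2$vertices$y, g$vertices$y, tolerance = 1e-6)
  expect_equal(g2$vertices$z, g$vertices$z, tolerance = 1e-6)
  expect_equal(g2$vertices$radius, g$vertices$radius, tolerance = 1e-6)
  expect_equal(g2$vertices$parent, g$vertices$parent)
  expect_equal(g2$vertices$region, g$vertices$region)
})

test_that("multi-point somata collapse to one area-equivalent root", {
  swc <- tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 4 -1",
               "2 1 0 0 8 4 1",
               "3 1 0 0 -8 4 1",
               "4 3 10 0 0 1 1",
               "5 3 20 0 0 1 4"), swc)
  g <- read_swc(swc)
  expect_equal(sum(g$vertices$region == "soma"), 1L)
  expect_equal(g$root, 1L)
  # area equivalence: 2 segments of length 8, radius 4 -> 4 pi r^2 = 2*2pi*4*8
  expect_equal(g$vertices$radius[1], sqrt(2 * 2 * pi * 4 * 8 / (4 * pi)))
  # dendrite still attached below the collapsed root
  expect_equal(nrow(g$vertices), 3)
  expect_true(all(!is.na(g$vertices$parent[-1])))
})

test_that("path distance to soma follows the tree, not straight lines", {
  # root -> 0
  g <- make_ball_and_stick(n_seg = 10, L = 100, a = 1)
  expect_equal(path_distance_to_soma(g, g$root)$distance, 0)
  # straight chain of 10 x 10 um -> 100 um at the tip
  expect_equal(path_distance_to_soma(g, 11L)$distance, 100)
  # branched fixture vs independent parent-walk oracle
  g2 <- random_tree(depth = 5, seed = 11)
  ids <- c(2L, 7L, nrow(g2$vertices), sample.int(nrow(g2$vertices), 5))
  got <- path_distance_to_soma(g2, ids)$distance
  want <- vapply(ids, function(i) walk_distance(g2, i), numeric(1))
  expect_equal(got, want)
  # monotone non-decreasing from root towards every leaf
  d <- path_distance_to_soma(g2)$distance
  p <- g2$vertices$parent
  child <- which(!is.na(p))
  expect_true(all(d[child] >= d[p[child]]))
})

test_that("fixture generators honour their contracts", {
  g <- make_ball_and_stick(n_seg = 100, L = 1000, a = 1)
  expect_equal(nrow(g$vertices), 101)
  expect_equal(sum(!is.na(g$vertices$parent)), 100)

  bt <- make_binary_tree(depth = 4)
  expect_equal(sum(bt$vertices$region != "soma"), 31)  # 2^5 - 1 segments

  tc <- make_two_cell(gap = 2)
  expect_s3_class(tc, "network_geometry")
  # brute-force closest axon-dendrite vertex distance across the two cells
  ax <- tc$cells[[1]]$vertices
  ax <- ax[ax$region == "axon", ]
  de <- tc$cells[[2]]$vertices
  de <- de[de$region %in% c("dendrite-basal", "dendrite-apical"), ]
  dmin <- min(outer(seq_len(nrow(ax)), seq_len(nrow(de)), function(i, j) {
    sqrt((ax$x[i] - de$x[j])^2 + (ax$y[i] - de$y[j])^2 + (ax$z[i] - de$z[j])^2)
  }))
  expect_equal(dmin, 2, tolerance = 1e-12)

  expect_error(make_ball_and_stick(a = -1), "non-physical")
  expect_error(make_two_cell(gap = 0), "non-physical")
})

test_that("edge resampling preserves total cable length and topology", {
  g <- random_tree(depth = 4, seed = 5)
  g2 <- resample_edges(g, 3)
  expect_equal(sum(graph_edges(g2)$length), sum(graph_edges(g)$length),
               tolerance = 1e-9)
  expect_true(all(graph_edges(g2)$length <= 3 + 1e-9))
  # leaf count unchanged (no branch structure created or lost)
  leaves <- function(gr) sum(!gr$vertices$id %in% gr$vertices$parent)
  expect_equal(leaves(g2), leaves(g))
})

test_that("network exchange JSON round trips and is byte-deterministic", {
  net <- make_two_cell(gap = 2, n_seg = 5)
  syn <- distribute_primary(net$cells[[2]], 4, seed = 9, cell = 2L)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_network_json(net, f1, synapses = syn[, c("id", "kind", "cell",
                                                 "edge", "offset", "g_max")])
  write_network_json(net, f2, synapses = syn[, c("id", "kind", "cell",
                                                 "edge", "offset", "g_max")])
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_network_json(f1)
  expect_equal(length(back$network$cells), 2)
  expect_equal(back$network$cells[[1]]$vertices$x, net$cells[[1]]$vertices$x)
  expect_equal(back$network$cells[[2]]$cell_type, net$cells[[2]]$cell_type)
  expect_equal(nrow(back$synapses), 4)
})

test_that("neuron_graph validation rejects broken structures", {
  v <- tibble::tibble(id = 1:3, x = 0, y = 0, z = 0, radius = 1,
                      region = "soma", parent = c(NA, 1L, 2L))
  expect_s3_class(neuron_graph(v), "neuron_graph")
  v_cycle <- tibble::tibble(id = 1:3, x = 0, y = 0, z = 0, radius = 1,
                            region = "soma", parent = c(NA, 3L, 2L))
  expect_error(neuron_graph(v_cycle), "cycle")
  v_badr <- v; v_badr$radius[2] <- 0
  expect_error(neuron_graph(v_badr), "radii")
})
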