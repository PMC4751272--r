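test_that("edge sample space is length-weighted", {
  g <- neuron_graph(tibble::tibble(
    id = 1:3, x = c(0, 1, 4), y = 0, z = 0, radius = 1,
    region = c("soma", "dendrite-basal", "dendrite-basal"),
    parent = c(NA, 1L, 2L)))
  sp <- edge_sample_space(g)
  expect_equal(sp$p, c(0.25, 0.75))   # lengths 1 um and 3 um
  # single-edge degenerate space
  g1 <- make_ball_and_stick(n_seg = 1, L = 10, a = 1)
  expect_equal(edge_sample_space(g1)$p, 1)
  syn <- distribute_primary(g1, 25, seed = 1)
  expect_true(all(syn$edge == edge_sample_space(g1)$edge))
  # no eligible edges is an error
  expect_error(edge_sample_space(g, regions = "axon"), "empty")
})

test_that("placement frequencies match the length-weighted law (chi-square)", {
  g <- neuron_graph(tibble::tibble(
    id = 1:3, x = c(0, 1, 4), y = 0, z = 0, radius = 1,
    region = c("soma", "dendrite-basal", "dendrite-basal"),
    parent = c(NA, 1L, 2L)))
  syn <- distribute_primary(g, 1e5, seed = 42)
  obs <- table(factor(syn$edge, levels = edge_sample_space(g)$edge))
  p <- stats::chisq.test(obs, p = c(0.25, 0.75))$p.value
  expect_gt(p, 0.01)
  # offsets lie strictly inside (0, 1)
  expect_true(all(syn$offset > 0 & syn$offset < 1))
  # determinism per seed
  syn2 <- distribute_primary(g, 100, seed = 7)
  syn3 <- distribute_primary(g, 100, seed = 7)
  expect_identical(syn2$edge, syn3$edge)
  expect_identical(syn2$offset, syn3$offset)
})

test_that("uniform removal keeps counts, nesting and spatial law", {
  g <- make_binary_tree(depth = 5, seg_len = 10)
  syn <- distribute_primary(g, 1000, seed = 3)
  expect_identical(remove_uniform(syn, 0, seed = 1)$edge, syn$edge)
  expect_equal(nrow(remove_uniform(syn, 1, seed = 1)), 0)
  expect_equal(nrow(remove_uniform(syn, 0.977, seed = 1)), 23)
  # nested removals on a fixed seed: survivors at higher loss are a subset
  keep_key <- function(s) paste(s$edge, s$offset)
  k50 <- keep_key(remove_uniform(syn, 0.5, seed = 9))
  k80 <- keep_key(remove_uniform(syn, 0.8, seed = 9))
  expect_true(all(k80 %in% k50))
  # surviving synapses still follow the length-weighted distribution
  sp <- edge_sample_space(g)
  big <- distribute_primary(g, 2e4, seed = 5)
  surv <- remove_uniform(big, 0.6, seed = 5)
  obs <- table(factor(surv$edge, levels = sp$edge))
  expect_gt(stats::chisq.test(obs, p = sp$p)$p.value, 0.01)
})

test_that("activation patterns sample the normal law and honour sigma = 0", {
  g <- make_ball_and_stick(n_seg = 5, L = 50, a = 1)
  syn <- distribute_primary(g, 1e4, seed = 2)
  # fully synchronous: all parameters identical
  s0 <- sample_pattern(syn, activation_pattern(15, 0, 0.4, 0), seed = 1)
  expect_true(all(s0$t_onset == 15))
  expect_true(all(s0$tau == 0.4))
  # CLT bound: sample mean of 1e4 onsets within 3 sigma/sqrt(n) of 15
  s1 <- sample_pattern(syn, activation_pattern(15, 5, 0.4, 0), seed = 1)
  expect_lt(abs(mean(s1$t_onset) - 15), 3 * 5 / sqrt(1e4))
  # determinism
  s2 <- sample_pattern(syn, activation_pattern(15, 5, 2, 0.5), seed = 4)
  s3 <- sample_pattern(syn, activation_pattern(15, 5, 2, 0.5), seed = 4)
  expect_identical(s2$t_onset, s3$t_onset)
  expect_identical(s2$tau, s3$tau)
  # non-positive tau draws are rejected, redrawn and reported
  small <- distribute_primary(g, 500, seed = 2)
  expect_message(
    s4 <- sample_pattern(small, activation_pattern(0, 0, 0.3, 0.5), seed = 6),
    "resampled")
  expect_true(all(s4$tau > 0))
})

test_that("alpha conductance peaks at g_max one tau after onset", {
  expect_equal(alpha_conductance(5 + 0.4, 5, 0.4, 1.2), 1.2)
  # support bounds
  expect_equal(alpha_conductance(4.99, 5, 0.4, 1.2), 0)
  expect_equal(alpha_conductance(5 + 6 * 0.4 + 1e-9, 5, 0.4, 1.2), 0)
  # direct evaluation at t = onset + 2 tau: g = gmax * 2 e^-1
  expect_equal(alpha_conductance(2 * 0.4, 0, 0.4, 1.2), 1.2 * 2 * exp(-1))
  # non-negative everywhere and exact peak, across random parameters
  set.seed(8)
  for (k in 1:20) {
    tau <- runif(1, 0.1, 5); on <- runif(1, 0, 20); gm <- runif(1, 0.1, 3)
    tt <- seq(on - 2, on + 10 * tau, length.out = 400)
    gg <- alpha_conductance(tt, on, tau, gm)
    expect_true(all(gg >= 0))
    expect_equal(alpha_conductance(on + tau, on, tau, gm), gm)
    expect_true(all(gg <= gm + 1e-12))
  }
})

test_that("bi-exponential kinetics normalize to g_max at t_max", {
  k <- biexp_timing(0.2, 1.7)
  expect_equal(k$t_max, 0.2 * 1.7 / 1.5 * log(1.7 / 0.2))
  expect_equal(k$t_max, 0.4851, tolerance = 1e-4)
  expect_equal(biexp_conductance(k$t_max, 0.2, 1.7, 2.5), 2.5)
  expect_equal(biexp_conductance(0, 0.2, 1.7, 2.5), 0)
  expect_error(biexp_timing(0.5, 0.5), "tau2 > tau1")
  set.seed(9)
  for (i in 1:10) {
    t1 <- runif(1, 0.05, 1); t2 <- t1 + runif(1, 0.1, 3)
    tm <- biexp_timing(t1, t2)$t_max
    tt <- seq(0, 12 * t2, length.out = 500)
    gg <- biexp_conductance(tt, t1, t2, 1.7)
    expect_true(all(gg >= 0))
    expect_equal(max(gg) <= 1.7 + 1e-12, TRUE)
    expect_equal(biexp_conductance(tm, t1, t2, 1.7), 1.7)
  }
})

test_that("synaptic currents follow the outward-positive convention", {
  rec <- sample_pattern(
    distribute_primary(make_ball_and_stick(n_seg = 2, L = 20, a = 1), 1,
                       seed = 1, g_max = 1.2),
    activation_pattern(0, 0, 0.4, 0), seed = 1)
  # depolarizing at rest: negative (inward) current for E_rev = 0
  expect_lt(alpha_current(rec, -65, 0.4), 0)
  expect_equal(alpha_current(rec, 0, 0.4), 0)     # at reversal
  expect_gt(alpha_current(rec, 20, 0.4), 0)
})

test_that("threshold detection activates and re-activates synapses", {
  syn <- new_two_cell_synapse()
  # constant subthreshold trace: never activates
  s <- syn
  for (t in seq(0, 5, by = 0.1)) s <- update_activation(s, -65, t)
  expect_equal(length(s$activations[[1]]), 0)
  # one crossing -> exactly one event
  s <- syn
  vpre <- c(-65, -40, 5, 20, 5, -20)
  for (i in seq_along(vpre)) s <- update_activation(s, vpre[i], i * 0.1)
  expect_equal(length(s$activations[[1]]), 1)
  # two crossings separated by a subthreshold dip -> two events
  s <- syn
  vpre <- c(-65, 10, 10, -30, -30, 15, -65)
  for (i in seq_along(vpre)) s <- update_activation(s, vpre[i], i * 0.1)
  expect_equal(length(s$activations[[1]]), 2)
  ev <- activation_events(s)
  expect_equal(nrow(ev), 2)
})
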