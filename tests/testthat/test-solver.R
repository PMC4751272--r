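test_that("mesh geometry follows the finite-volume formulas", {
  # uniform cable: G = 2 pi / (r_c * 2 a^-2 * L) = pi a^2 / (r_c L)
  g <- make_ball_and_stick(n_seg = 2, L = 20, a = 1, soma_radius = 1)
  m <- build_mesh(g, r_c = 1.5)
  expect_equal(m$edges$G, rep(2 * pi / (1.5 * 2e12 * 1e-5), 2),
               tolerance = 1e-12)
  # mixed radii a1 = 1, a2 = 2, L = 10
  g2 <- neuron_graph(tibble::tibble(
    id = 1:2, x = c(0, 10), y = 0, z = 0, radius = c(1, 2),
    region = "soma", parent = c(NA, 1L)))
  m2 <- build_mesh(g2, r_c = 1.5)
  expect_equal(m2$edges$G, 2 * pi / (1.5 * 1.25e12 * 1e-5), tolerance = 1e-12)
  # interior vertex of a uniform chain: l_i sums two half-edges
  expect_equal(m$vertices$l_m[2], 10e-6)
  expect_equal(m$vertices$area[2], 2 * pi * 1e-6 * 10e-6)
  expect_equal(m$vertices$Cm[2], 1e-2 * 2 * pi * 1e-6 * 10e-6)
  # zero-length edge rejected
  g3 <- neuron_graph(tibble::tibble(
    id = 1:2, x = 0, y = 0, z = 0, radius = 1, region = "soma",
    parent = c(NA, 1L)))
  expect_error(build_mesh(g3), "zero-length")
})

test_that("Cuthill-McKee ordering yields one superdiagonal entry per row", {
  # path graph in natural order
  m <- build_mesh(make_ball_and_stick(n_seg = 30, L = 300, a = 1))
  expect_true(has_one_superdiagonal(m, m$order))
  expect_true(has_one_superdiagonal(m, cuthill_mckee_order(m)))
  # random binary tree around 200 vertices: verify row by row
  g <- resample_edges(random_tree(depth = 6, seed = 2), 8)
  mt <- build_mesh(g)
  expect_gt(mt$n, 200)
  ord <- cuthill_mckee_order(mt)
  pos <- integer(mt$n); pos[ord] <- seq_len(mt$n)
  for (i in seq_len(mt$n)) {
    nb <- c(mt$edges$j[mt$edges$i == i], mt$edges$i[mt$edges$j == i])
    expect_lte(sum(pos[nb] > pos[i]), 1)
  }
  # two disjoint cells: consecutive index blocks per component
  m2 <- build_mesh(make_two_cell(gap = 2, n_seg = 6))
  cells_in_order <- m2$vertices$cell[m2$order]
  expect_equal(length(rle(cells_in_order)$lengths), 2)
})

test_that("CFL estimate reacts to membrane conductance", {
  mech_off <- mechanisms(hh = FALSE, leak = FALSE)
  g <- make_ball_and_stick(n_seg = 10, L = 100, a = 1, soma_radius = 1)
  mesh <- build_mesh(g)
  st <- cable_state(mesh, mech_off)
  expect_equal(estimate_time_step(mesh, mech_off, st, dt_max = 0.5), 0.5)
  # passive patch: g_l = 1 S/m2, c_m = 1e-2 F/m2 -> bound safety * 1e-2 s
  mech_l <- mechanisms(membrane = membrane_spec(
    g_l = c(axon = 1, soma = 1, dendrite = 1), c_T = 1), hh = FALSE)
  st2 <- cable_state(mesh, mech_l)
  expect_equal(estimate_time_step(mesh, mech_l, st2, dt_max = 1, safety = 0.5),
               0.5 * 1e-2)
  # during an action potential the step shrinks relative to rest
  mech <- mechanisms()
  gax <- make_ball_and_stick(n_seg = 10, L = 100, a = 1, soma_radius = 8,
                             axon = list(n_seg = 10, L = 100, a = 0.5))
  mesh3 <- build_mesh(gax)
  st_rest <- cable_state(mesh3, mech)
  dt_rest <- estimate_time_step(mesh3, mech, st_rest, dt_max = 1)
  st_ap <- st_rest
  st_ap$V <- rep(0.0, mesh3$n)        # depolarized
  st_ap$m <- rep(0.9, mesh3$n); st_ap$h <- rep(0.5, mesh3$n)
  dt_ap <- estimate_time_step(mesh3, mech, st_ap, dt_max = 1)
  expect_lt(dt_ap, dt_rest)
})

test_that("constant state is steady without mechanisms; charge is conserved", {
  g <- random_tree(depth = 5, seed = 4)
  mesh <- build_mesh(g)
  mech_off <- mechanisms(hh = FALSE, leak = FALSE)
  st <- cable_state(mesh, mech_off, V0 = -0.05)
  out <- step(st, mesh, mech_off, dt = 1e-5)
  expect_equal(out$state$V, st$V, tolerance = 1e-14)
  # non-uniform start: total charge sum(C_i V_i) conserved to machine precision
  st2 <- st
  st2$V <- -0.065 + 0.02 * sin(seq_len(mesh$n))
  q0 <- sum(mesh$vertices$Cm * st2$V)
  for (k in 1:20) {
    r <- step(st2, mesh, mech_off, dt = 2e-5)
    st2 <- r$state
  }
  expect_equal(sum(mesh$vertices$Cm * st2$V), q0, tolerance = 1e-12)
})

test_that("single steps compose exactly into a simulation run", {
  g <- make_ball_and_stick(n_seg = 8, L = 80, a = 1, soma_radius = 6)
  mech <- mechanisms()
  mesh <- build_mesh(g)
  inj <- tibble::tibble(cell = 1L, vertex = 1L, amp = 0.1, t0 = 0, t1 = 10)
  sim <- simulate(simulation_config(g, mech, duration = 0.5, dt_max = 1e-5,
                                    safety = 1, record_dt = 0.5,
                                    injections = inj))
  st <- cable_state(mesh, mech)
  for (k in 1:50) st <- step(st, mesh, mech, dt = 1e-5, injections = inj)$state
  expect_equal(st$V, sim$state$V, tolerance = 1e-13)
  expect_equal(st$n, sim$state$n, tolerance = 1e-13)
})

test_that("tree LU solves the assembled system to near machine precision", {
  set.seed(10)
  g <- resample_edges(random_tree(depth = 5, seed = 2), 8)
  mesh <- build_mesh(g)
  v <- rnorm(mesh$n, -0.065, 0.01)
  imem <- rnorm(mesh$n, 0, 1e-12)
  sys <- assemble_system(mesh, v, imem, dt = 1e-5)
  expect_true(Matrix::isSymmetric(sys$A))
  x <- tree_solve_system(sys, mesh)
  res <- sqrt(sum((as.numeric(sys$A %*% x) - sys$b)^2)) / sqrt(sum(sys$b^2))
  expect_lt(res, 1e-10)
})

test_that("passive steady state converges to the analytic cable solution", {
  errs <- vapply(c(50, 100, 200), function(n) {
    g <- make_ball_and_stick(n_seg = n, L = 1000, a = 1, soma_radius = 1)
    ms <- membrane_spec(g_l = c(axon = 1, soma = 1, dendrite = 1), c_T = 1)
    mech <- mechanisms(membrane = ms, hh = FALSE,
                       E_l = c(axon = -0.065, soma = -0.065, dendrite = -0.065))
    inj <- tibble::tibble(cell = 1L, vertex = 1L, amp = 0.1, t0 = 0, t1 = 1e9)
    sim <- simulate(simulation_config(g, mech, duration = 150, dt_max = 5e-4,
                                      record_dt = 150, probes = "all",
                                      injections = inj))
    tr <- sim$traces[sim$traces$time == max(sim$traces$time), ]
    tr <- tr[order(tr$vertex), ]
    want <- passive_cable_analytic(seq(0, 1000, length.out = n + 1),
                                   1000, 1, 1, 1.5, 0.1e-9)
    max(abs(tr$V - want)) / max(abs(want + 65))
  }, numeric(1))
  expect_lt(errs[3], 0.01)          # 200 compartments within 1 %
  expect_true(all(diff(errs) < 0))  # error decreases under refinement
})

test_that("partitioned additive-correction solve matches the monolithic LU", {
  set.seed(11)
  g <- make_ball_and_stick(n_seg = 99, L = 990, a = 1, soma_radius = 5)
  mesh <- build_mesh(g)
  v <- rnorm(mesh$n, -0.065, 0.005)
  sys <- assemble_system(mesh, v, rnorm(mesh$n, 0, 1e-12), dt = 1e-6)
  mono <- tree_solve_system(sys, mesh)
  # no cell cut: exactly one iteration
  net <- make_two_cell(gap = 2)
  mesh2 <- build_mesh(net)
  sys2 <- assemble_system(mesh2, rnorm(mesh2$n, -0.065, 0.005),
                          rep(0, mesh2$n), dt = 1e-6)
  ps2 <- partitioned_solve(sys2, split(mesh2$vertices$index,
                                       mesh2$vertices$cell))
  expect_equal(ps2$iterations, 1L)
  expect_equal(ps2$solution, tree_solve_system(sys2, mesh2),
               tolerance = 1e-10)
  # cable cut into blocks: equal to the monolithic solve, few iterations
  for (blocks in list(list(1:50, 50:mesh$n),
                      list(1:30, 30:70, 70:mesh$n))) {
    ps <- partitioned_solve(sys, blocks)
    expect_lte(ps$iterations, 15)
    expect_lt(max(abs(ps$solution - mono)), 1e-9 * max(abs(mono)))
  }
  # degenerate tolerance returns the start iterate untouched
  x0 <- rep(1, mesh$n)
  ps0 <- partitioned_solve(sys, list(1:50, 50:mesh$n), x0 = x0,
                           reduction_factor = 1)
  expect_equal(ps0$iterations, 0L)
  expect_identical(ps0$solution, x0)
})

test_that("violating the CFL bound triggers detected divergence", {
  g <- make_ball_and_stick(n_seg = 20, L = 200, a = 1, soma_radius = 8)
  mech <- mechanisms()
  mesh <- build_mesh(g)
  st <- cable_state(mesh, mech)
  dt_ok <- estimate_time_step(mesh, mech, st, dt_max = 1)
  diverged <- FALSE
  for (k in 1:500) {
    out <- tryCatch(step(st, mesh, mech, dt = dt_ok * 50),
                    error = function(e) e)
    if (inherits(out, "error")) {
      diverged <- TRUE
      expect_match(conditionMessage(out), "CFL")
      break
    }
    st <- out$state
  }
  expect_true(diverged)
})

test_that("simulation records, rests stably, and transmits one step late", {
  # duration 0: initial state only
  g <- make_ball_and_stick(n_seg = 5, L = 50, a = 1)
  sim0 <- simulate(simulation_config(g, mechanisms(), duration = 0))
  expect_equal(nrow(sim0$traces), 1)
  expect_equal(sim0$traces$V, -65)

  # calibrated network fixture at rest stays at rest
  net <- make_two_cell(gap = 2, n_seg = 10)
  simr <- simulate(simulation_config(net, mechanisms(), duration = 5,
                                     dt_max = 2e-5, record_dt = 1))
  expect_lt(max(abs(simr$traces$V + 65)), 1e-6)

  # presynaptic spike triggers postsynaptic depolarization one step later
  syn <- create_interconnecting_synapses(net, dist_synapse = 3)[1, ]
  inj <- tibble::tibble(cell = 1L, vertex = 1L, amp = 1.5, t0 = 1, t1 = 3)
  sim <- simulate(simulation_config(net, mechanisms(), synapses = syn,
                                    duration = 10, dt_max = 1e-5,
                                    record_dt = 0.05,
                                    probes = tibble::tibble(cell = c(1L, 2L),
                                                            vertex = c(1L, 1L)),
                                    injections = inj))
  pre <- sim$traces[sim$traces$cell == 1, ]
  post <- sim$traces[sim$traces$cell == 2, ]
  expect_gte(length(detect_spikes(pre)), 1)
  expect_equal(nrow(sim$events), 1)
  expect_gt(max(post$V), -60)      # clear depolarization
  # nothing postsynaptic happens before the presynaptic threshold crossing
  expect_lt(max(abs(post$V[post$time <= sim$events$time] + 65)), 1e-6)
})
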