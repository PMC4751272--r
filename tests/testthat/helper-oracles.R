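# Shared oracles and fixture builders for the test suite.

# Independent path-distance oracle: walk parent pointers, summing segment
# lengths, one vertex at a time (no vectorized ordering tricks).
walk_distance <- function(graph, vertex) {
  v <- graph$vertices
  d <- 0
  i <- vertex
  while (!is.na(v$parent[i])) {
    p <- v$parent[i]
    d <- d + sqrt((v$x[i] - v$x[p])^2 + (v$y[i] - v$y[p])^2 +
                  (v$z[i] - v$z[p])^2)
    i <- p
  }
  d
}

# High-accuracy single-compartment Hodgkin-Huxley reference using deSolve,
# same equations, adaptive integrator with bounded step.
hh_reference <- function(spec, region, area, Cm, I_amp, t_on, t_off,
                         duration, out_dt = 2e-5) {
  El <- calibrate_leak_reversal(spec, region)
  rhs <- function(t, y, p) {
    r <- hh_rates((y[1] - spec$V_r) * 1e3)
    i_hh <- spec$c_T * (spec$g_K[[region]] * y[2]^4 * (y[1] - spec$E_K) +
                        spec$g_Na[[region]] * y[3]^3 * y[4] * (y[1] - spec$E_Na))
    i_l <- spec$c_T * spec$g_l[[region]] * (y[1] - El)
    I <- if (t >= t_on && t < t_off) I_amp else 0
    list(c((-(i_hh + i_l) * area + I) / Cm,
           spec$c_T * (r$alpha_n * (1 - y[2]) - r$beta_n * y[2]) * 1e3,
           spec$c_T * (r$alpha_m * (1 - y[3]) - r$beta_m * y[3]) * 1e3,
           spec$c_T * (r$alpha_h * (1 - y[4]) - r$beta_h * y[4]) * 1e3))
  }
  g0 <- hh_steady(0)
  out <- deSolve::ode(c(spec$V_r, g0$n, g0$m, g0$h),
                      seq(0, duration, by = out_dt), rhs, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-13,
                      hmax = 1e-5)
  tibble::tibble(time = out[, 1] * 1e3, V = out[, 2] * 1e3,
                 n = out[, 3], m = out[, 4], h = out[, 5])
}

# Analytic steady state of a sealed passive cable with a current I
# injected at x = 0 (voltage relative to the leak reversal):
# V(x) = I r_a lambda cosh((L - x)/lambda) / sinh(L/lambda).
passive_cable_analytic <- function(x_um, L_um, a_um, g_l, r_c, I_amp,
                                   E_rest_mV = -65) {
  a <- a_um * 1e-6; L <- L_um * 1e-6; x <- x_um * 1e-6
  lambda <- sqrt(a / (2 * g_l * r_c))
  r_a <- r_c / (pi * a^2)
  E_rest_mV + I_amp * r_a * lambda * cosh((L - x) / lambda) /
    sinh(L / lambda) * 1e3
}

# two-compartment isopotential soma used for single-compartment HH tests
tiny_soma <- function(radius = 5) {
  neuron_graph(tibble::tibble(id = 1:2, x = c(0, 1), y = 0, z = 0,
                              radius = radius, region = "soma",
                              parent = c(NA, 1L)))
}

# random subtree fixture: a binary tree with jittered segment lengths
random_tree <- function(depth = 6, seed = 1) {
  g <- make_binary_tree(depth = depth, seg_len = 15)
  withr::with_seed(seed, {
    v <- g$vertices
    v$x <- v$x + stats::rnorm(nrow(v), 0, 0.5)
    v$y <- v$y + stats::rnorm(nrow(v), 0, 0.5)
    v$x[1] <- 0; v$y[1] <- 0
  })
  neuron_graph(v, cell_type = g$cell_type)
}

# one bare interconnecting synapse record for activation-logic tests
new_two_cell_synapse <- function() {
  cablenet:::new_synapse_set(tibble::tibble(
    kind = "interconnecting", cell = 2L, edge = 1L, offset = 0.5,
    g_max = 1, tau1 = 0.2, tau2 = 1.7, e_rev = 0, v_th = -10,
    pre_cell = 1L, pre_vertex = 5L))
}
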