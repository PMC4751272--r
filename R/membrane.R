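# Hodgkin-Huxley channels, calibrated leak, VDCC and calcium pumps.
# Convention used throughout the package: membrane current densities are
# OUTWARD-positive at the mechanism level and subtracted once from the
# charge balance by the solver.  Voltages are SI volts at the interfaces;
# the classical HH rate functions work internally in mV above rest and
# 1/ms, as published.

#' Default membrane parameters
#'
#' Region-specific channel conductances and reversal potentials of the
#' network model, SI units.  Defaults are the large-scale network
#' parameter set (axon/soma/dendrite potassium, sodium and leak
#' conductances; Nernst potentials; resting potential; temperature factor).
#' The leak reversal `E_l` is not stored here: it is derived by
#' [calibrate_leak_reversal()] so that the total membrane current vanishes
#' at rest.
#'
#' @param g_K,g_Na,g_l Named numeric vectors (`axon`, `soma`, `dendrite`),
#'   S m^-2.
#' @param E_K,E_Na Nernst potentials, V.
#' @param V_r Resting potential, V.
#' @param c_T Temperature factor multiplying channel rates and current.
#' @return A list of class `membrane_spec`.
#' @export
membrane_spec <- function(g_K = c(axon = 400, soma = 200, dendrite = 30),
                          g_Na = c(axon = 30000, soma = 1500, dendrite = 40),
                          g_l = c(axon = 200, soma = 1, dendrite = 1),
                          E_K = -0.09, E_Na = 0.06, V_r = -0.065,
                          c_T = 3.21) {
  if (any(c(g_K, g_Na, g_l) < 0)) abort("conductances must be >= 0")
  structure(list(g_K = g_K, g_Na = g_Na, g_l = g_l,
                 E_K = E_K, E_Na = E_Na, V_r = V_r, c_T = c_T),
            class = "membrane_spec")
}

#' Classical Hodgkin-Huxley rate functions
#'
#' The original squid-axon rate constants, evaluated at `v = V - V_r`
#' millivolts above rest, in 1/ms.  Removable singularities (alpha_n at
#' v = 10 mV, alpha_m at v = 25 mV) are replaced by their analytic limits.
#'
#' @param v Membrane potential relative to rest, mV (vectorized).
#' @return Tibble with columns `alpha_n`, `beta_n`, `alpha_m`, `beta_m`,
#'   `alpha_h`, `beta_h` (1/ms).
#' @export
hh_rates <- function(v) {
  # x/(exp(x/10)-1) with the limit 10 at x = 0
  expm1_frac <- function(x) ifelse(abs(x) < 1e-7, 10 - x / 2, x / expm1(x / 10))
  tibble(
    alpha_n = 0.01 * expm1_frac(10 - v),
    beta_n  = 0.125 * exp(-v / 80),
    alpha_m = 0.1 * expm1_frac(25 - v),
    beta_m  = 4 * exp(-v / 18),
    alpha_h = 0.07 * exp(-v / 20),
    beta_h  = 1 / (exp((30 - v) / 10) + 1))
}

#' Steady-state HH gate values
#'
#' `g_inf = alpha/(alpha+beta)` per gate; at rest (`v = 0`) these are the
#' initialization values of every simulation.
#'
#' @inheritParams hh_rates
#' @return Tibble with columns `n`, `m`, `h`.
#' @export
hh_steady <- function(v = 0) {
  r <- hh_rates(v)
  tibble(n = r$alpha_n / (r$alpha_n + r$beta_n),
         m = r$alpha_m / (r$alpha_m + r$beta_m),
         h = r$alpha_h / (r$alpha_h + r$beta_h))
}

#' Explicit gate update
#'
#' Forward-Euler step `dg = c_T (alpha (1-g) - beta g) dt` for each gate,
#' evaluated at the previous step's potential and clamped to \[0, 1\].  This
#' is the explicit treatment of the nonlinear inner states: gates are
#' advanced before the linear solve, using only the previous solution.
#'
#' @param gates Tibble/list with numeric `n`, `m`, `h` (same length as
#'   `v_prev`).
#' @param v_prev Previous-step potential relative to rest, mV.
#' @param dt Time step, ms.
#' @param c_T Temperature factor.
#' @return Tibble with updated `n`, `m`, `h`.
#' @export
hh_gate_step <- function(gates, v_prev, dt, c_T = 3.21) {
  stopifnot(dt > 0)
  r <- hh_rates(v_prev)
  clamp01 <- function(x) pmin(1, pmax(0, x))
  tibble(
    n = clamp01(gates$n + c_T * (r$alpha_n * (1 - gates$n) - r$beta_n * gates$n) * dt),
    m = clamp01(gates$m + c_T * (r$alpha_m * (1 - gates$m) - r$beta_m * gates$m) * dt),
    h = clamp01(gates$h + c_T * (r$alpha_h * (1 - gates$h) - r$beta_h * gates$h) * dt))
}

#' Hodgkin-Huxley current density
#'
#' Outward-positive flux density
#' `i_hh = c_T (g_K n^4 (V - E_K) + g_Na m^3 h (V - E_Na))` with the
#' region-specific conductances of `spec`.
#'
#' @param gates Tibble/list with `n`, `m`, `h`.
#' @param V Membrane potential, V (vectorized).
#' @param spec A [membrane_spec()].
#' @param region `"axon"`, `"soma"` or `"dendrite"`.
#' @return Current density, A m^-2.
#' @export
hh_current_density <- function(gates, V, spec = membrane_spec(),
                               region = c("soma", "axon", "dendrite")) {
  region <- match.arg(region)
  spec$c_T * (spec$g_K[[region]] * gates$n^4 * (V - spec$E_K) +
              spec$g_Na[[region]] * gates$m^3 * gates$h * (V - spec$E_Na))
}

#' Calibrate the leak reversal potential
#'
#' Solves `i_hh(V_r) + c_T g_l (V_r - E_l) = 0` for `E_l` with the HH gates
#' at their resting steady state, so that the resting potential is an exact
#' equilibrium of the full membrane.  The temperature factor multiplies
#' both terms and cancels; the calibration is therefore computed with
#' `c_T = 1`.
#'
#' @param spec A [membrane_spec()].
#' @param region `"axon"`, `"soma"` or `"dendrite"`.
#' @return Leak reversal potential `E_l`, V.
#' @export
calibrate_leak_reversal <- function(spec = membrane_spec(),
                                    region = c("axon", "soma", "dendrite")) {
  region <- match.arg(region)
  g_l <- spec$g_l[[region]]
  if (g_l <= 0) abort("leak conductance must be positive for calibration")
  g0 <- hh_steady(0)
  spec1 <- spec
  spec1$c_T <- 1
  i_rest <- hh_current_density(g0, spec$V_r, spec1, region)
  spec$V_r + i_rest / g_l
}

#' Leak current density
#'
#' `i_l = c_T g_l (V - E_l)`, outward positive.
#'
#' @inheritParams hh_current_density
#' @param E_l Leak reversal, V; default calibrated via
#'   [calibrate_leak_reversal()].
#' @return Current density, A m^-2.
#' @export
leak_current_density <- function(V, spec = membrane_spec(),
                                 region = c("soma", "axon", "dendrite"),
                                 E_l = NULL) {
  region <- match.arg(region)
  if (is.null(E_l)) E_l <- calibrate_leak_reversal(spec, region)
  spec$c_T * spec$g_l[[region]] * (V - E_l)
}

# ---------------------------------------------------------------------------
# Calcium machinery: N-type VDCC (Borg-Graham formalism), NCX / PMCA pumps,
# calibrated calcium leak.  None of these parameters are printed in the
# source model description; defaults are literature-typical magnitudes and
# are configuration, not claims.

#' Calcium mechanism parameters
#'
#' @param ca_rest Resting cytosolic calcium, mM.
#' @param ca_ext Extracellular calcium, mM.
#' @param D_ca Axial diffusion coefficient, m^2 s^-1.
#' @param ampa_ca_fraction Fraction of AMPA synaptic current carried by
#'   calcium (reduced to 0.001 to lump fast buffering).
#' @param vdcc Borg-Graham N-type parameters: permeability `P` (m s^-1),
#'   activation gate (`z_m` effective gating charge, `V12_m` half-activation
#'   V, `tau_m` s, exponent `p_m`), inactivation gate (`z_h`, `V12_h`,
#'   `tau_h`).
#' @param ncx First-order (Michaelis) sodium-calcium exchanger: `f_max`
#'   (mol m^-2 s^-1), `K` (mM).
#' @param pmca Second-order Hill plasma-membrane calcium pump: `f_max`,
#'   `K`.
#' @param temperature Kelvin, enters the GHK flux.
#' @return List of class `calcium_spec`.
#' @export
calcium_spec <- function(ca_rest = 5e-5, ca_ext = 1.5,
                         D_ca = 2.2e-10, ampa_ca_fraction = 0.001,
                         vdcc = list(P = 1e-6, z_m = 3.4, V12_m = -0.021,
                                     tau_m = 1.5e-3, p_m = 2,
                                     z_h = -2, V12_h = -0.040, tau_h = 75e-3),
                         ncx = list(f_max = 2.5e-8, K = 1.8e-3),
                         pmca = list(f_max = 8.5e-9, K = 6e-5),
                         temperature = 310) {
  stopifnot(ca_rest > 0, ca_ext > 0)
  structure(list(ca_rest = ca_rest, ca_ext = ca_ext, D_ca = D_ca,
                 ampa_ca_fraction = ampa_ca_fraction, vdcc = vdcc,
                 ncx = ncx, pmca = pmca, temperature = temperature),
            class = "calcium_spec")
}

FARADAY <- 96485.33212
GAS_R <- 8.31446

#' VDCC gate steady state and time constants
#'
#' Borg-Graham formalism: the equilibrium of a two-state gate with
#' exponential voltage-dependent transition rates is the Boltzmann curve
#' `x_inf(V) = 1 / (1 + exp(-z (V - V12) F / (R T)))`; relaxation uses a
#' fixed time constant per gate.
#'
#' @param V Membrane potential, V (vectorized).
#' @param spec A [calcium_spec()].
#' @return Tibble with columns `m_inf`, `h_inf`.
#' @export
vdcc_steady <- function(V, spec = calcium_spec()) {
  k <- FARADAY / (GAS_R * spec$temperature)
  p <- spec$vdcc
  tibble(m_inf = 1 / (1 + exp(-p$z_m * (V - p$V12_m) * k)),
         h_inf = 1 / (1 + exp(-p$z_h * (V - p$V12_h) * k)))
}

#' VDCC calcium current density
#'
#' Goldman-Hodgkin-Katz flux through the open fraction `m^p h` of N-type
#' channels (outward positive, so physiological calcium entry is negative):
#' `i = P m^p h z^2 F^2 V/(RT) (ca_i - ca_o exp(-zFV/RT)) / (1 - exp(-zFV/RT))`.
#'
#' @param state Tibble/list with gate values `m`, `h` (same length as `V`).
#' @param V Membrane potential, V.
#' @param ca Cytosolic calcium, mM.
#' @param spec A [calcium_spec()].
#' @return Current density, A m^-2.
#' @export
vdcc_current_density <- function(state, V, ca, spec = calcium_spec()) {
  p <- spec$vdcc
  open <- state$m^(p$p_m) * state$h
  open * p$P * ghk_flux(V, ca, spec$ca_ext, spec$temperature)
}

# GHK current density per unit permeability for a divalent ion; mM equals
# mol m^-3, so concentrations enter 1:1.
ghk_flux <- function(V, ca_in, ca_out, temperature) {
  z <- 2
  u <- z * FARADAY * V / (GAS_R * temperature)
  e <- exp(-u)
  num <- ifelse(abs(u) < 1e-9, ca_in - ca_out,
                u * (ca_in - ca_out * e) / (1 - e))
  z * FARADAY * num
}

#' Calcium pump flux
#'
#' Outward (extruding) calcium flux of the two plasma-membrane pumps:
#' NCX is first-order Michaelis (`f_max c/(K + c)`), PMCA a second-order
#' Hill pump (`f_max c^2/(K^2 + c^2)`).
#'
#' @param kind `"NCX"` or `"PMCA"`.
#' @param ca Cytosolic calcium, mM (vectorized, >= 0).
#' @param spec A [calcium_spec()].
#' @return Flux, mol m^-2 s^-1 (outward positive).
#' @export
pump_flux <- function(kind = c("NCX", "PMCA"), ca, spec = calcium_spec()) {
  kind <- match.arg(kind)
  if (any(ca < 0)) abort("calcium concentration must be >= 0")
  if (kind == "NCX") {
    spec$ncx$f_max * ca / (spec$ncx$K + ca)
  } else {
    spec$pmca$f_max * ca^2 / (spec$pmca$K^2 + ca^2)
  }
}

#' Calibrate the calcium leak
#'
#' Constant inward leak flux balancing every calcium membrane mechanism at
#' the resting state (pumps at resting calcium plus the VDCC at resting
#' potential and equilibrium gating), so that the resting calcium
#' concentration is an exact fixed point of the simulation.
#'
#' @param spec A [calcium_spec()].
#' @param V_r Resting potential, V.
#' @return Leak flux, mol m^-2 s^-1 (the value to subtract from the outward
#'   balance).
#' @export
calibrate_calcium_leak <- function(spec = calcium_spec(), V_r = -0.065) {
  g <- vdcc_steady(V_r, spec)
  i_vdcc <- vdcc_current_density(list(m = g$m_inf, h = g$h_inf), V_r,
                                 spec$ca_rest, spec)
  flux_vdcc <- i_vdcc / (2 * FARADAY)   # A m^-2 -> mol m^-2 s^-1, z = 2
  pump_flux("NCX", spec$ca_rest, spec) +
    pump_flux("PMCA", spec$ca_rest, spec) + flux_vdcc
}
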