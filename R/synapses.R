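# Stochastic synapse placement, activation patterns, synapse loss and
# synaptic conductance kinetics.
#
# A synapse set is a tibble (class "synapse_set") with one row per synapse.
# User-facing kinetic units follow field convention: conductances in nS,
# times in ms, potentials in mV.  Columns:
#   id, kind ("primary"/"interconnecting"), cell, edge, offset;
#   primary:          g_max, t_onset, tau, e_rev
#   interconnecting:  g_max, tau1, tau2, e_rev, v_th, pre_cell, pre_vertex,
#                     active (currently above threshold), activations
#                     (list column of activation times, ms)

new_synapse_set <- function(df) {
  df <- tibble::as_tibble(df)
  defaults <- list(kind = NA_character_, cell = 1L, edge = NA_integer_,
                   offset = NA_real_, g_max = NA_real_, t_onset = NA_real_,
                   tau = NA_real_, tau1 = NA_real_, tau2 = NA_real_,
                   e_rev = 0, v_th = NA_real_, pre_cell = NA_integer_,
                   pre_vertex = NA_integer_)
  for (nm in names(defaults)) {
    if (!nm %in% names(df)) df[[nm]] <- rep(defaults[[nm]], nrow(df))
  }
  if (!"activations" %in% names(df)) {
    df$activations <- rep(list(numeric(0)), nrow(df))
  }
  if (!"active" %in% names(df)) df$active <- rep(FALSE, nrow(df))
  df$id <- seq_len(nrow(df))
  class(df) <- c("synapse_set", class(tibble::tibble()))
  df
}

#' Empty synapse set
#' @return A zero-row synapse set tibble.
#' @export
empty_synapse_set <- function() {
  new_synapse_set(tibble(kind = character(0)))
}

#' Length-weighted edge sample space
#'
#' The sample space for stochastic synapse placement: all edges of the
#' requested regions, each with placement probability proportional to its
#' Euclidean length, `p_j = ||e_j|| / sum_k ||e_k||`.
#'
#' @param graph A [neuron_graph()].
#' @param regions Regions whose edges are eligible; default basal and
#'   apical dendrites.  An edge's region is its child vertex's region.
#' @return Tibble with columns `edge`, `parent`, `child`, `length`
#'   (micrometres) and `p` (summing to 1).
#' @export
edge_sample_space <- function(graph,
                              regions = c("dendrite-basal", "dendrite-apical")) {
  e <- graph_edges(graph)
  e$region <- graph$vertices$region[e$child]
  e <- dplyr::filter(e, .data$region %in% regions)
  if (nrow(e) == 0) abort("empty edge sample space: no edges in requested regions")
  e$p <- e$length / sum(e$length)
  e[, c("edge", "parent", "child", "length", "p")]
}

#' Distribute primary synapses on a dendritic tree
#'
#' Draws `n_syn` edge indices from the length-weighted distribution of
#' [edge_sample_space()] and, for each, an offset from the continuous
#' uniform distribution on (0, 1) locating the synapse along its edge.
#' Kinetic parameters (`t_onset`, `tau`) are left unset until
#' [sample_pattern()] assigns an activation pattern.
#'
#' @param graph A [neuron_graph()].
#' @param n_syn Number of synapses.
#' @param regions Eligible regions (see [edge_sample_space()]).
#' @param seed Integer seed; placement is reproducible per seed.
#' @param g_max Maximal conductance attached to each synapse, nS.
#' @param cell Cell index recorded on the synapses (for network use).
#' @return A synapse set of `n_syn` primary synapses.
#' @export
distribute_primary <- function(graph, n_syn,
                               regions = c("dendrite-basal", "dendrite-apical"),
                               seed = 1L, g_max = 1.2, cell = 1L) {
  space <- edge_sample_space(graph, regions)
  withr_seed(seed, {
    edges <- sample(space$edge, n_syn, replace = TRUE, prob = space$p)
    offs <- runif(n_syn)
  })
  # guard the open interval: an offset of exactly 0 or 1 has probability 0
  # but would break the location contract
  offs[offs == 0 | offs == 1] <- 0.5
  new_synapse_set(tibble(kind = "primary", cell = cell, edge = edges,
                         offset = offs, g_max = g_max, e_rev = 0))
}

# run code with a local RNG seed without disturbing the caller's RNG
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(code))
}

#' Remove a uniform fraction of synapses
#'
#' Models synapse loss: retains `round((1 - loss_fraction) * n)` synapses
#' chosen by uniform sampling without replacement.  On a fixed seed the
#' removals are nested: a higher loss fraction removes a superset of the
#' synapses removed at any lower fraction, so loss curves within one sample
#' configuration are comparable.
#'
#' @param synapses A synapse set.
#' @param loss_fraction Fraction removed, in \[0, 1\].
#' @param seed Integer seed.
#' @return The surviving synapse set (ids re-numbered).
#' @export
remove_uniform <- function(synapses, loss_fraction, seed = 1L) {
  stopifnot(loss_fraction >= 0, loss_fraction <= 1)
  n <- nrow(synapses)
  keep_n <- round((1 - loss_fraction) * n)
  ord <- withr_seed(seed, sample.int(n))
  new_synapse_set(synapses[sort(ord[seq_len(keep_n)]), ])
}

#' Activation pattern of primary synapses
#'
#' Onset times and alpha-function time constants of a set of primary
#' synapses are drawn independently from normal distributions
#' `N(mu_onset, sigma_onset^2)` and `N(mu_tau, sigma_tau^2)`.  The degree
#' of input synchrony is controlled by `sigma_onset` (0 = fully
#' synchronous).
#'
#' @param mu_onset,sigma_onset Mean and SD of the onset time, ms.
#' @param mu_tau,sigma_tau Mean and SD of the rise/decay constant, ms.
#' @return List of class `activation_pattern`.
#' @export
activation_pattern <- function(mu_onset = 15, sigma_onset = 5,
                               mu_tau = 0.4, sigma_tau = 0) {
  stopifnot(sigma_onset >= 0, sigma_tau >= 0, mu_tau > 0)
  structure(list(mu_onset = mu_onset, sigma_onset = sigma_onset,
                 mu_tau = mu_tau, sigma_tau = sigma_tau),
            class = "activation_pattern")
}

#' Sample an activation pattern onto primary synapses
#'
#' Assigns each primary synapse `t_onset ~ N(mu_onset, sigma_onset^2)` and
#' `tau ~ N(mu_tau, sigma_tau^2)` independently.  A zero standard
#' deviation yields exactly the mean for every synapse.  Draws of
#' `tau <= 0` are rejected and redrawn (reported via a message).
#'
#' @param synapses A synapse set of primary synapses.
#' @param pattern An [activation_pattern()].
#' @param seed Integer seed.
#' @return The synapse set with `t_onset` and `tau` filled in.
#' @export
sample_pattern <- function(synapses, pattern, seed = 1L) {
  if (any(synapses$kind != "primary")) {
    abort("activation patterns apply to primary synapses only")
  }
  n <- nrow(synapses)
  withr_seed(seed, {
    onset <- if (pattern$sigma_onset == 0) rep(pattern$mu_onset, n) else
      rnorm(n, pattern$mu_onset, pattern$sigma_onset)
    tau <- if (pattern$sigma_tau == 0) rep(pattern$mu_tau, n) else
      rnorm(n, pattern$mu_tau, pattern$sigma_tau)
    rejected <- 0L
    while (any(tau <= 0)) {
      bad <- which(tau <= 0)
      rejected <- rejected + length(bad)
      tau[bad] <- rnorm(length(bad), pattern$mu_tau, pattern$sigma_tau)
    }
  })
  if (rejected > 0) {
    rlang::inform(sprintf("resampled %d non-positive tau draw(s)", rejected))
  }
  synapses$t_onset <- onset
  synapses$tau <- tau
  synapses
}

#' Alpha-function synaptic conductance
#'
#' `g(t) = g_max (t - t_onset)/tau exp(-(t - t_onset - tau)/tau)` on the
#' support `t_onset <= t <= t_onset + 6 tau` and 0 outside; the peak value
#' `g_max` is attained exactly at `t = t_onset + tau`.
#'
#' @param t Time, ms (vectorized).
#' @param t_onset Onset time, ms.
#' @param tau Rise/decay constant, ms (> 0).
#' @param g_max Maximal conductance, nS.
#' @return Conductance, nS.
#' @export
alpha_conductance <- function(t, t_onset, tau, g_max = 1) {
  stopifnot(all(tau > 0))
  s <- t - t_onset
  g <- g_max * (s / tau) * exp(-(s - tau) / tau)
  ifelse(s >= 0 & s <= 6 * tau, g, 0)
}

#' Primary (alpha) synaptic current
#'
#' Outward-positive current `I = g(t) (V - E_rev)`; with the default
#' glutamatergic reversal `E_rev = 0` mV this is negative (depolarizing)
#' at rest once the solver subtracts it from the membrane balance.
#'
#' @param rec One-or-more-row synapse set with sampled `t_onset`, `tau`.
#' @param V Postsynaptic membrane potential, mV.
#' @param t Time, ms.
#' @return Current, nA (`nS * mV * 1e-3`).
#' @export
alpha_current <- function(rec, V, t) {
  g <- alpha_conductance(t, rec$t_onset, rec$tau, rec$g_max)
  g * (V - rec$e_rev) * 1e-3
}

#' Bi-exponential timing constants
#'
#' Peak time `t_max = tau1 tau2/(tau2 - tau1) log(tau2/tau1)` and the
#' normalizer `n = (exp(-t_max/tau2) - exp(-t_max/tau1))^-1` making the
#' conductance exactly `g_max` at `t_max`.
#'
#' @param tau1,tau2 Rise and decay constants, ms, `tau2 > tau1 > 0`.
#' @return List with `t_max` (ms) and `n`.
#' @export
biexp_timing <- function(tau1, tau2) {
  if (any(tau1 <= 0) || any(tau2 <= tau1)) {
    abort("bi-exponential kinetics require tau2 > tau1 > 0")
  }
  t_max <- tau1 * tau2 / (tau2 - tau1) * log(tau2 / tau1)
  list(t_max = t_max, n = 1 / (exp(-t_max / tau2) - exp(-t_max / tau1)))
}

#' Bi-exponential synaptic conductance
#'
#' `g(t) = g_max n (exp(-t/tau2) - exp(-t/tau1))` for time `t >= 0` since
#' activation, 0 before.
#'
#' @param t_since Time since activation, ms (vectorized).
#' @inheritParams biexp_timing
#' @param g_max Maximal conductance, nS.
#' @return Conductance, nS.
#' @export
biexp_conductance <- function(t_since, tau1, tau2, g_max = 1) {
  k <- biexp_timing(tau1, tau2)
  ifelse(t_since >= 0,
         g_max * k$n * (exp(-t_since / tau2) - exp(-t_since / tau1)), 0)
}

#' Interconnecting (bi-exponential) synaptic current
#'
#' Outward-positive current of an activated interconnecting synapse,
#' summed over all of its recorded activation events.
#'
#' @param rec A one-row synapse set (interconnecting).
#' @param V Postsynaptic membrane potential, mV.
#' @param t_since Time since (single) activation, ms; if `NULL`, all events
#'   in `rec$activations[[1]]` relative to `t` are summed.
#' @param t Absolute time, ms (used with the event list).
#' @return Current, nA.
#' @export
biexp_current <- function(rec, V, t_since = NULL, t = NULL) {
  if (is.null(t_since)) {
    if (is.null(t)) abort("supply either t_since or t")
    t_since <- t - rec$activations[[1]]
    if (length(t_since) == 0) return(0)
    g <- sum(biexp_conductance(t_since, rec$tau1, rec$tau2, rec$g_max))
  } else {
    g <- biexp_conductance(t_since, rec$tau1, rec$tau2, rec$g_max)
  }
  g * (V - rec$e_rev) * 1e-3
}

#' Update interconnecting synapse activation state
#'
#' Threshold detection on the previous time step's presynaptic potential:
#' an upward crossing of `v_th` appends an activation event at time `t`;
#' the synapse can only re-activate after the presynaptic potential has
#' fallen below threshold again.
#'
#' @param synapses Synapse set (interconnecting rows are updated; others
#'   pass through).
#' @param V_pre Presynaptic membrane potential per synapse, mV (previous
#'   step's solution).
#' @param t Current time, ms.
#' @return The synapse set with updated `active` flags and `activations`.
#' @export
update_activation <- function(synapses, V_pre, t) {
  inter <- which(synapses$kind == "interconnecting")
  V_pre <- rep_len(V_pre, nrow(synapses))
  for (i in inter) {
    above <- V_pre[i] >= synapses$v_th[i]
    if (above && !synapses$active[i]) {
      synapses$activations[[i]] <- c(synapses$activations[[i]], t)
    }
    synapses$active[i] <- above
  }
  synapses
}

#' Export synapse activation events
#'
#' @param synapses A synapse set.
#' @param path Optional CSV path; when given the table is also written.
#' @return Tibble with columns `synapse`, `time` (ms), one row per
#'   activation event.
#' @export
activation_events <- function(synapses, path = NULL) {
  ev <- purrr::map2_dfr(synapses$id, synapses$activations, function(id, times) {
    if (length(times) == 0) return(tibble(synapse = integer(0), time = numeric(0)))
    tibble(synapse = id, time = times)
  })
  if (!is.null(path)) utils::write.csv(ev, path, row.names = FALSE)
  ev
}
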