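# Spike/calcium analysis and the two study protocols: synapse loss vs.
# input synchrony on a single cell, and connectivity-driven activity
# waves in a layered network.

#' Detect spikes in a membrane-potential trace
#'
#' Upward threshold crossings separated by at least a refractory period.
#'
#' @param trace Tibble with columns `time` (ms) and `V` (mV), or a
#'   numeric V vector with `time` supplied separately.
#' @param time Time base, ms (when `trace` is a bare vector).
#' @param threshold Crossing threshold, mV.
#' @param refractory Minimum inter-spike interval, ms.
#' @return Numeric vector of spike times (ms).
#' @export
detect_spikes <- function(trace, time = NULL, threshold = 0, refractory = 3) {
  if (is.data.frame(trace)) {
    time <- trace$time
    v <- trace$V
  } else v <- trace
  stopifnot(length(v) == length(time))
  if (length(v) < 2) return(numeric(0))
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  spikes <- numeric(0)
  for (i in up) {
    if (length(spikes) == 0 || time[i] - spikes[length(spikes)] >= refractory) {
      spikes <- c(spikes, time[i])
    }
  }
  spikes
}

#' Calcium trace metrics
#'
#' Quantifies the stepwise calcium increases accompanying action
#' potentials and the exponential relaxation to the resting level
#' afterwards: per-spike step sizes are measured as the concentration
#' rise from just before each spike to the maximum within a short window
#' after it; the decay time constant is fit by log-linear regression on
#' the post-activity tail (relative to the trace's initial equilibrium).
#'
#' @param trace Tibble with columns `time` (ms) and `ca` (mM).
#' @param spikes Spike times, ms (from [detect_spikes()] on the matching
#'   voltage trace).
#' @param window Post-spike window for the step maximum, ms.
#' @param tail_skip Delay after the last spike before the decay fit, ms.
#' @return List: `steps` tibble (`spike_time`, `step` mM), `decay_tau`
#'   (ms, `NA` with `decay_flag = TRUE` when the tail is too short).
#' @export
calcium_metrics <- function(trace, spikes, window = 6, tail_skip = 10) {
  time <- trace$time; ca <- trace$ca
  steps <- tibble(spike_time = numeric(0), step = numeric(0))
  for (ts in spikes) {
    before <- ca[which(time <= ts)]
    base <- if (length(before) > 0) before[length(before)] else ca[1]
    win <- ca[time >= ts & time <= ts + window]
    if (length(win) > 0) {
      steps <- dplyr::bind_rows(steps,
        tibble(spike_time = ts, step = max(win) - base))
    }
  }
  ca_eq <- ca[1]
  t_tail <- if (length(spikes) > 0) max(spikes) + tail_skip else Inf
  tail_idx <- which(time >= t_tail & ca > ca_eq * (1 + 1e-6))
  if (length(tail_idx) < 2) {
    return(list(steps = steps, decay_tau = NA_real_, decay_flag = TRUE))
  }
  fit <- lm(log(ca[tail_idx] - ca_eq) ~ time[tail_idx])
  list(steps = steps, decay_tau = -1 / coef(fit)[[2]], decay_flag = FALSE)
}

#' Detect step increases in a calcium trace
#'
#' A calcium step is a burst of rapid concentration rise (channel-driven
#' influx during an action potential) standing out against the slow
#' diffusive and pump-driven background.  The rise rate `d[Ca]/dt` is
#' thresholded at `frac` of its maximum (with an absolute floor
#' `min_rate` so a flat trace yields no steps); upward threshold
#' crossings separated by a refractory period mark the steps.
#' Independent of any voltage trace, so step counts can be compared with
#' spike counts.
#'
#' @param trace Tibble with `time` (ms) and `ca` (mM).
#' @param min_rate Absolute rate floor, mM/ms.
#' @param frac Relative threshold as a fraction of the peak rise rate.
#' @param refractory Minimum step separation, ms.
#' @return Tibble (`onset`, `rise`) per detected step; `rise` is the
#'   concentration increase up to the next step (or the trace maximum
#'   afterwards).
#' @export
detect_ca_steps <- function(trace, min_rate = 1e-6, frac = 0.3,
                            refractory = 2.5) {
  time <- trace$time; ca <- trace$ca
  if (length(time) < 3) return(tibble(onset = numeric(0), rise = numeric(0)))
  rate <- diff(ca) / pmax(diff(time), 1e-9)
  if (max(rate) < min_rate) return(tibble(onset = numeric(0), rise = numeric(0)))
  thr <- max(min_rate, frac * max(rate))
  onsets <- detect_spikes(rate, time = time[-1], threshold = thr,
                          refractory = refractory)
  if (length(onsets) == 0) return(tibble(onset = numeric(0), rise = numeric(0)))
  ends <- c(onsets[-1], max(time))
  rise <- vapply(seq_along(onsets), function(k) {
    i0 <- which(time >= onsets[k])[1]
    win <- ca[time >= onsets[k] & time <= ends[k]]
    max(win) - ca[max(i0 - 1L, 1L)]
  }, numeric(1))
  tibble(onset = onsets, rise = rise)
}

#' Synapse-loss study configuration
#'
#' The protocol: distribute `n_syn` excitatory synapses on the morphology
#' in `n_samples` random configurations, activate them with alpha-function
#' kinetics under three synchrony levels, successively remove uniform
#' portions of the synapses, and record spike counts and somatic calcium
#' per (sample, loss, synchrony).
#'
#' @param morphology A [neuron_graph()] or a path to an SWC file.  The
#'   default is a desk-scale soma + dendrite + axon cable fixture.
#' @param n_syn Number of synapses at zero loss.
#' @param n_samples Number of random synapse distributions.
#' @param loss_grid Loss fractions, each in \[0, 1\].
#' @param synchrony Tibble (`label`, `mu_onset`, `sigma_onset`), ms.  The
#'   defaults pair `mu_onset = 3 sigma_onset`: full synchrony (0, 0),
#'   moderate (15, 5) and high (30, 10) asynchrony.
#' @param g_max,tau Alpha-function parameters (fast AMPA), nS and ms.
#' @param calcium A [calcium_spec()] (or `NULL` to skip calcium).
#' @param duration_pad Extra simulated time beyond the last expected
#'   onset, ms.
#' @param dt_max,safety,record_dt Solver options (see
#'   [simulation_config()]).
#' @param seed Master seed; all sample/pattern/removal seeds derive from
#'   it.
#' @return List of class `loss_study_config`.
#' @export
loss_study_config <- function(
    morphology = make_ball_and_stick(n_seg = 40, L = 400, a = 1,
                                     soma_radius = 8,
                                     axon = list(n_seg = 20, L = 200, a = 0.5)),
    n_syn = 200, n_samples = 20,
    loss_grid = c(seq(0, 0.9, by = 0.1), 0.95, 0.977),
    synchrony = tibble(label = c("synchronous", "moderate", "high"),
                       mu_onset = c(0, 15, 30), sigma_onset = c(0, 5, 10)),
    g_max = 1.2, tau = 0.4, calcium = calcium_spec(),
    duration_pad = 25, dt_max = 2e-5, safety = 0.5, record_dt = 0.1,
    seed = 1L) {
  stopifnot(all(loss_grid >= 0 & loss_grid <= 1), n_samples >= 1)
  structure(list(morphology = morphology, n_syn = n_syn,
                 n_samples = n_samples, loss_grid = sort(loss_grid),
                 synchrony = synchrony, g_max = g_max, tau = tau,
                 calcium = calcium, duration_pad = duration_pad,
                 dt_max = dt_max, safety = safety, record_dt = record_dt,
                 seed = seed),
            class = "loss_study_config")
}

#' Full-scale synapse-loss protocol
#'
#' The original protocol at full scale: 1000 synapses, 100 sample
#' distributions, a loss grid bracketing the reported breakdown points.
#' Requires an externally obtained reconstructed morphology (an SWC file,
#' e.g. the layer 3 pyramidal reconstruction the single-cell study used);
#' none is bundled.
#'
#' @param swc_path Path to the reconstruction.
#' @param ... Overrides passed to [loss_study_config()].
#' @return A `loss_study_config`.
#' @export
full_loss_protocol <- function(swc_path, ...) {
  loss_study_config(
    morphology = swc_path, n_syn = 1000, n_samples = 100,
    loss_grid = c(seq(0, 0.9, by = 0.05), 0.95, 0.977), ...)
}

#' Run the synapse-loss study
#'
#' For every sample distribution, synchrony level and loss fraction:
#' sample placement and activation pattern, remove the loss fraction
#' (nested within a sample, so higher loss removes a superset), simulate,
#' and record spike counts at the soma and axon tip plus somatic calcium
#' metrics.  Fully seeded and reproducible.
#'
#' @param config A [loss_study_config()].
#' @param progress Print a line per sample.
#' @return Object of class `loss_study`: `results` (one row per sample x
#'   synchrony x loss), `summary` (mean/SD spike count and responding
#'   fraction), `breakdown` (largest loss with >= 90 % responding per
#'   synchrony level) and the config.
#' @export
run_loss_study <- function(config, progress = FALSE) {
  graph <- if (is.character(config$morphology)) {
    if (!file.exists(config$morphology)) {
      abort(paste0("morphology file not found: ", config$morphology,
                   " (reconstructions are not bundled; supply an SWC file)"))
    }
    read_swc(config$morphology)
  } else config$morphology

  mech <- mechanisms(calcium = config$calcium)
  mesh <- build_mesh(graph)
  soma_vid <- graph$root
  ax <- which(graph$vertices$region == "axon")
  axon_vid <- if (length(ax) > 0) {
    d <- path_distance_to_soma(graph, ax)
    ax[which.max(d$distance)]
  } else soma_vid
  probes <- tibble(cell = 1L, vertex = unique(c(soma_vid, axon_vid)))

  rows <- list()
  for (s in seq_len(config$n_samples)) {
    syn0 <- distribute_primary(graph, config$n_syn,
                               seed = config$seed + 1000L * s,
                               g_max = config$g_max)
    for (yi in seq_len(nrow(config$synchrony))) {
      lvl <- config$synchrony[yi, ]
      pattern <- activation_pattern(lvl$mu_onset, lvl$sigma_onset,
                                    config$tau, 0)
      syn <- sample_pattern(syn0, pattern, seed = config$seed + 1000L * s + yi)
      duration <- lvl$mu_onset + 4 * lvl$sigma_onset + config$duration_pad
      for (loss in config$loss_grid) {
        kept <- remove_uniform(syn, loss, seed = config$seed + 1000L * s)
        sim <- simulate(simulation_config(
          graph, mech, synapses = if (nrow(kept) > 0) kept else NULL,
          duration = duration, dt_max = config$dt_max,
          safety = config$safety, record_dt = config$record_dt,
          probes = probes), mesh = mesh)
        soma_tr <- sim$traces[sim$traces$vertex == soma_vid, ]
        axon_tr <- sim$traces[sim$traces$vertex == axon_vid, ]
        spk <- detect_spikes(soma_tr)
        spk_ax <- detect_spikes(axon_tr)
        ca_steps <- NA_integer_; peak_ca <- NA_real_; decay_tau <- NA_real_
        if (!is.null(config$calcium)) {
          peak_ca <- max(soma_tr$ca)
          ca_steps <- nrow(detect_ca_steps(soma_tr))
          cm <- calcium_metrics(soma_tr, spk)
          decay_tau <- cm$decay_tau
        }
        rows[[length(rows) + 1L]] <- tibble(
          sample = s, synchrony = lvl$label, loss = loss,
          n_syn = nrow(kept), spikes = length(spk),
          spikes_axon = length(spk_ax), peak_ca = peak_ca,
          ca_steps = ca_steps, decay_tau = decay_tau)
      }
    }
    if (progress) message(sprintf("sample %d/%d done", s, config$n_samples))
  }
  results <- dplyr::bind_rows(rows)
  structure(list(results = results,
                 summary = summarize_loss_study(results),
                 breakdown = breakdown_loss(results),
                 config = config),
            class = "loss_study")
}

#' Summaries of a loss study
#'
#' @param results The `results` tibble of a [run_loss_study()] object.
#' @return Per (synchrony, loss): mean and SD of the spike count and the
#'   fraction of samples with at least one spike.
#' @export
summarize_loss_study <- function(results) {
  dplyr::summarise(
    dplyr::group_by(results, .data$synchrony, .data$loss),
    mean_spikes = mean(.data$spikes), sd_spikes = stats::sd(.data$spikes),
    frac_responding = mean(.data$spikes >= 1), .groups = "drop")
}

#' Breakdown loss per synchrony level
#'
#' The largest loss fraction at which at least `min_frac` of the sample
#' distributions still elicit one or more action potentials ("complete
#' signal breakdown" is the first grid point below that share).
#'
#' @inheritParams summarize_loss_study
#' @param min_frac Responding-share threshold.
#' @return Tibble (`synchrony`, `breakdown_loss`); -Inf if no grid point
#'   qualifies.
#' @export
breakdown_loss <- function(results, min_frac = 0.9) {
  s <- summarize_loss_study(results)
  dplyr::summarise(
    dplyr::group_by(s, .data$synchrony),
    breakdown_loss = {
      ok <- .data$loss[.data$frac_responding >= min_frac]
      if (length(ok) == 0) -Inf else max(ok)
    }, .groups = "drop")
}

#' @export
print.loss_study <- function(x, ...) {
  cat(sprintf("<loss_study> %d samples x %d synchrony levels x %d loss levels\n",
              x$config$n_samples, nrow(x$config$synchrony),
              length(x$config$loss_grid)))
  print(x$breakdown)
  invisible(x)
}

#' Synapse-count scaling with the creation distance
#'
#' Counts the synapses the distance rule creates on a fixed network for a
#' sweep of `dist_synapse` values and fits the log-log slope.  For
#' section lengths well below the probed distances the count grows with
#' the volume of the eligible sphere, i.e. cubically.
#'
#' @param net A [network_geometry()].
#' @param dists Creation distances to probe, micrometres.
#' @param conn A [connectivity_matrix()].
#' @return List: `counts` tibble (`dist_synapse`, `count`), `slope` of
#'   `log(count) ~ log(dist)`.
#' @export
synapse_count_scaling <- function(net, dists = 1:5,
                                  conn = default_connectivity()) {
  syn <- create_interconnecting_synapses(net, max(dists), conn)
  counts <- tibble(dist_synapse = dists,
                   count = vapply(dists, function(d)
                     sum(syn$distance < d), numeric(1)))
  if (any(counts$count == 0)) {
    return(list(counts = counts, slope = NA_real_))
  }
  fit <- lm(log(count) ~ log(dist_synapse), data = counts)
  list(counts = counts, slope = coef(fit)[[2]])
}

#' Network study configuration
#'
#' @param netgen A [netgen_config()]; the default is a reduced column
#'   (the full 10,000-cell geometry is not a desk-scale object).
#' @param dist_sweep Synapse creation distances compared on the same
#'   geometry seed, micrometres.
#' @param pattern Thalamic activation pattern
#'   ([activation_pattern()]; onset (5, 2.5) ms, duration (2.5, 0.1) ms).
#' @param g_max Thalamic synapse conductance, nS.
#' @param duration Simulated time, ms.
#' @param active_threshold Soma counted active at or above this
#'   potential, mV.
#' @param active_window A synapse counts as active for this long after an
#'   activation event, ms.
#' @param dt_max,safety,record_dt Solver options.
#' @param seed Master seed.
#' @return List of class `network_study_config`.
#' @export
network_study_config <- function(
    netgen = netgen_config(
      layers = tibble::tribble(
        ~cell_type,       ~count, ~z_min, ~z_max,
        "L2/3-pyramidal", 8L,     190,    280,
        "L4-stellate",    8L,     120,    190,
        "L5A-pyramidal",  4L,     60,     120,
        "L5B-pyramidal",  4L,     0,      60),
      box_xy = c(80, 80), edge_length = 1, seed = 1L),
    dist_sweep = c(2, 4, 6),
    pattern = activation_pattern(5, 2.5, 2.5, 0.1),
    g_max = 1.2, duration = 20, active_threshold = -45,
    active_window = 5, dt_max = 2e-5, safety = 0.5, record_dt = 0.25,
    seed = 1L) {
  structure(list(netgen = netgen, dist_sweep = dist_sweep,
                 pattern = pattern, g_max = g_max, duration = duration,
                 active_threshold = active_threshold,
                 active_window = active_window, dt_max = dt_max,
                 safety = safety, record_dt = record_dt, seed = seed),
            class = "network_study_config")
}

#' Run the network connectivity study
#'
#' Generates one layered network geometry, then for every creation
#' distance in the sweep: creates the interconnecting synapses, places
#' the same thalamic input pattern, simulates, and reports per layer and
#' time the fraction of active somata (V at or above the activity
#' threshold) and per projection the number of active synapses over
#' time.
#'
#' @param config A [network_study_config()].
#' @param progress Print a line per sweep entry.
#' @return Object of class `network_study`: `activity` (dist_synapse,
#'   layer, time, frac_active), `projections` (dist_synapse, projection,
#'   time, active_synapses), `peaks` (peak fraction and time per layer
#'   and distance), `synapse_counts`, and the config.
#' @export
run_network_study <- function(config, progress = FALSE) {
  net <- generate_network(config$netgen)
  types <- vapply(net$cells, function(g) g$cell_type, character(1))
  thal0 <- place_thalamic_inputs(net, seed = config$seed,
                                 g_max = config$g_max)
  thal <- sample_pattern(thal0, config$pattern, seed = config$seed + 1L)

  act_rows <- list(); proj_rows <- list(); cnt_rows <- list()
  for (d in config$dist_sweep) {
    inter <- create_interconnecting_synapses(net, d)
    synapses <- new_synapse_set(dplyr::bind_rows(thal, inter))
    sim <- simulate(simulation_config(
      net, mechanisms(), synapses = synapses, duration = config$duration,
      dt_max = config$dt_max, safety = config$safety,
      record_dt = config$record_dt, probes = "soma"))
    tr <- sim$traces
    tr$layer <- types[tr$cell]
    act <- dplyr::summarise(
      dplyr::group_by(tr, .data$layer, .data$time),
      frac_active = mean(.data$V >= config$active_threshold),
      .groups = "drop")
    act$dist_synapse <- d
    act_rows[[length(act_rows) + 1L]] <- act

    # active interconnecting synapses per projection over time
    syn_out <- sim$synapses
    inter_rows <- which(syn_out$kind == "interconnecting")
    times <- sort(unique(tr$time))
    if (length(inter_rows) > 0) {
      ev <- activation_events(syn_out[inter_rows, ])
      if (nrow(ev) > 0) {
        lab <- paste0(types[syn_out$pre_cell[inter_rows]], " -> ",
                      types[syn_out$cell[inter_rows]])
        ev$projection <- lab[match(ev$synapse,
                                   syn_out$id[inter_rows])]
        pr <- purrr::map_dfr(times, function(tt) {
          on <- ev[ev$time <= tt & tt < ev$time + config$active_window, ]
          if (nrow(on) == 0) return(tibble(projection = character(0),
                                           time = numeric(0),
                                           active_synapses = integer(0)))
          cnt <- dplyr::count(on, .data$projection,
                              name = "active_synapses")
          cnt$time <- tt
          cnt
        })
        if (nrow(pr) > 0) {
          pr$dist_synapse <- d
          proj_rows[[length(proj_rows) + 1L]] <- pr
        }
      }
    }
    cnt_rows[[length(cnt_rows) + 1L]] <-
      tibble(dist_synapse = d, n_interconnecting = length(inter_rows))
    if (progress) message(sprintf("dist_synapse = %g um done", d))
  }
  activity <- dplyr::bind_rows(act_rows)
  peaks <- dplyr::summarise(
    dplyr::group_by(activity, .data$dist_synapse, .data$layer),
    peak_fraction = max(.data$frac_active),
    peak_time = .data$time[which.max(.data$frac_active)],
    onset_time = {
      on <- .data$time[.data$frac_active > 0]
      if (length(on) == 0) Inf else min(on)
    },
    .groups = "drop")
  structure(list(activity = activity,
                 projections = dplyr::bind_rows(proj_rows),
                 peaks = peaks,
                 synapse_counts = dplyr::bind_rows(cnt_rows),
                 config = config),
            class = "network_study")
}

#' @export
print.network_study <- function(x, ...) {
  cat("<network_study>\n")
  print(x$peaks)
  invisible(x)
}
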