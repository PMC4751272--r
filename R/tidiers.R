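# broom-style accessors for the result objects

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a simulation result
#'
#' @param x A `cable_result` from [simulate()].
#' @param ... Unused.
#' @return The probe trace tibble (`time` ms, `cell`, `vertex`, `V` mV,
#'   `ca` mM).
#' @export
tidy.cable_result <- function(x, ...) x$traces

#' @rdname tidy.cable_result
#' @export
glance.cable_result <- function(x, ...) {
  tibble(steps = x$steps, t_end = x$state$t * 1e3,
         dt_min = if (nrow(x$dt_history) > 0) min(x$dt_history$dt) else NA_real_,
         dt_max = if (nrow(x$dt_history) > 0) max(x$dt_history$dt) else NA_real_,
         n_probes = length(unique(paste(x$traces$cell, x$traces$vertex))),
         n_events = nrow(x$events))
}

#' Tidy a loss study
#'
#' @param x A `loss_study` from [run_loss_study()].
#' @param ... Unused.
#' @return The per-(sample, synchrony, loss) results tibble.
#' @export
tidy.loss_study <- function(x, ...) x$results

#' @rdname tidy.loss_study
#' @export
glance.loss_study <- function(x, ...) {
  b <- tidyr::pivot_wider(x$breakdown, names_from = "synchrony",
                          values_from = "breakdown_loss",
                          names_prefix = "breakdown_")
  dplyr::bind_cols(tibble(n_samples = x$config$n_samples,
                          n_syn = x$config$n_syn,
                          n_loss_levels = length(x$config$loss_grid)), b)
}

#' Tidy a network study
#'
#' @param x A `network_study` from [run_network_study()].
#' @param ... Unused.
#' @return The layer-activity tibble.
#' @export
tidy.network_study <- function(x, ...) x$activity

#' @rdname tidy.network_study
#' @export
glance.network_study <- function(x, ...) x$peaks
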