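# ggplot2 displays for the result objects

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point
#'   geom_errorbar facet_wrap labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot probe traces of a simulation
#'
#' @param object A `cable_result`.
#' @param what `"V"` (mV) or `"ca"` (mM).
#' @param ... Unused.
#' @return A ggplot: one panel per probe vertex.
#' @export
autoplot.cable_result <- function(object, what = c("V", "ca"), ...) {
  what <- match.arg(what)
  tr <- object$traces
  tr$probe <- paste0("cell ", tr$cell, " / vertex ", tr$vertex)
  ggplot(tr, aes(x = .data$time, y = .data[[what]])) +
    geom_line() +
    facet_wrap(~probe, scales = "free_y") +
    labs(x = "time [ms]",
         y = if (what == "V") "membrane potential [mV]" else "[Ca2+] [mM]") +
    theme_minimal()
}

#' Plot a loss study
#'
#' Mean spike count (with SD bars) or responding fraction against the
#' loss fraction, one curve per synchrony level.
#'
#' @param object A `loss_study`.
#' @param what `"spikes"` or `"responding"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.loss_study <- function(object, what = c("spikes", "responding"), ...) {
  what <- match.arg(what)
  s <- object$summary
  if (what == "spikes") {
    ggplot(s, aes(x = .data$loss, y = .data$mean_spikes,
                  colour = .data$synchrony)) +
      geom_line() + geom_point() +
      geom_errorbar(aes(ymin = .data$mean_spikes - .data$sd_spikes,
                        ymax = .data$mean_spikes + .data$sd_spikes),
                    width = 0.02) +
      labs(x = "synapse loss fraction", y = "evoked action potentials") +
      theme_minimal()
  } else {
    ggplot(s, aes(x = .data$loss, y = .data$frac_responding,
                  colour = .data$synchrony)) +
      geom_line() + geom_point() +
      labs(x = "synapse loss fraction",
           y = "fraction of samples with >= 1 spike") +
      theme_minimal()
  }
}

#' Plot a network study
#'
#' Fraction of active somata per layer over time, one panel per synapse
#' creation distance.
#'
#' @param object A `network_study`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.network_study <- function(object, ...) {
  ggplot(object$activity,
         aes(x = .data$time, y = .data$frac_active, colour = .data$layer)) +
    geom_line() +
    facet_wrap(~dist_synapse, labeller = ggplot2::label_both) +
    labs(x = "time [ms]", y = "fraction of active somata (V >= -45 mV)") +
    theme_minimal()
}
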