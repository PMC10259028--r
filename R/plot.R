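# ggplot2 views of trace tibbles.

utils::globalVariables(c("generation", "value", "component", "gene"))

#' Plot mean fitness components along a trace
#'
#' Line plot of mean total fitness and its components against generation,
#' one line per component — the per-branch counterpart of a mean-fitness
#' progression panel.
#'
#' @param trace A `grnevo_trace` tibble from [run_branch()] (also found in
#'   `grnevo_run$traces`).
#' @return A ggplot object.
#' @export
plot_fitness_trace <- function(trace) {
  comps <- c("mean_total", "mean_boundedness", "mean_participation",
             "mean_stability", "fraction_mature")
  long <- do.call(rbind, lapply(comps, function(cm) {
    data.frame(generation = trace$generation,
               component = sub("^(mean_|fraction_)", "", cm),
               value = trace[[cm]])
  }))
  ggplot2::ggplot(long, ggplot2::aes(generation, value,
                                     colour = component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "population mean",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-gene participation along a trace
#'
#' Shows, for each gene, the proportion of the population expressing it at
#' each traced generation. The seed gene sits at 1 throughout; genes
#' outside the working network drift toward 0.
#'
#' @param trace A `grnevo_trace` tibble.
#' @return A ggplot object.
#' @export
plot_participation <- function(trace) {
  cols <- grep("^p_gene", names(trace), value = TRUE)
  long <- do.call(rbind, lapply(cols, function(cm) {
    data.frame(generation = trace$generation,
               gene = sub("^p_", "", cm),
               value = trace[[cm]])
  }))
  ggplot2::ggplot(long, ggplot2::aes(generation, value, colour = gene)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "generation", y = "proportion of population",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.grnevo_trace <- function(object, ...) plot_fitness_trace(object)
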