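#' @importFrom ggplot2 ggplot aes geom_line geom_tile geom_point labs
#'   facet_wrap scale_fill_viridis_c autoplot theme_minimal geom_col
NULL

#' @export
ggplot2::autoplot

#' Plot compartment occupancy over time
#'
#' Cell numbers per compartment and phenotype versus time.
#'
#' @param object An `epidrift_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot epidrift_trajectory
#' @export
autoplot.epidrift_trajectory <- function(object, ...) {
  ggplot(object$counts,
         aes(x = .data$time, y = .data$n, colour = .data$phenotype)) +
    geom_line() +
    facet_wrap(~.data$environment) +
    labs(x = "time (steps)", y = "cells", colour = NULL) +
    theme_minimal()
}

#' Heatmap of per-gene regulatory states
#'
#' Mirrors the gene-state panels of the study: per compartment, genes
#' (sorted by average H3K4me3 modification in the proliferative
#' compartment) against time, coloured by the chosen quantity.
#'
#' @param traj An `epidrift_trajectory`.
#' @param quantity One of `"mean_expression"`, `"mean_h3k4me3"`,
#'   `"mean_methylation"` or the corresponding variances.
#' @return A ggplot.
#' @export
plot_gene_states <- function(traj, quantity = "mean_h3k4me3") {
  gs <- traj$gene_state
  stopifnot(quantity %in% setdiff(names(gs), c("time", "environment",
                                               "gene", "n_cells")))
  ord <- summarize_states(traj)
  ord <- ord[ord$environment == "omega", c("gene", "rank_h3k4me3_omega")]
  gs <- dplyr::left_join(gs, ord, by = "gene")
  ggplot(gs, aes(x = .data$time, y = .data$rank_h3k4me3_omega,
                 fill = .data[[quantity]])) +
    geom_tile() +
    facet_wrap(~.data$environment) +
    scale_fill_viridis_c() +
    labs(x = "time (steps)", y = "gene (ranked by H3K4me3 in omega)",
         fill = quantity) +
    theme_minimal()
}

#' Plot the clone census
#'
#' Stacked per-clone cell counts over time (clonal composition).
#'
#' @param traj An `epidrift_trajectory`.
#' @return A ggplot.
#' @export
plot_clones <- function(traj) {
  bc <- clone_census(traj)$by_clone
  ggplot(bc, aes(x = .data$time, y = .data$n,
                 fill = factor(.data$clone))) +
    geom_col(position = "stack", width = max(diff(unique(bc$time)))) +
    labs(x = "time (steps)", y = "cells", fill = "clone") +
    theme_minimal()
}

#' Plot a histone-chain stationary law
#'
#' @param n_h Nucleosome count.
#' @param w_bs Unmethylated CpG fraction.
#' @param p Parameters.
#' @return A ggplot of the stationary probabilities over `0:n_h`.
#' @export
plot_histone_stationary <- function(n_h, w_bs = 1, p = epidrift_params()) {
  sd <- histone_stationary_distribution(n_h, w_bs, p)
  df <- tibble(n_hm = 0:n_h, probability = sd$pi)
  ggplot(df, aes(x = .data$n_hm, y = .data$probability)) +
    geom_col() +
    labs(x = "modified nucleosomes",
         y = "stationary probability",
         title = sprintf("n_h = %d, w_bs = %.2f, %s", n_h, w_bs,
                         if (sd$bimodal) "bimodal" else "unimodal")) +
    theme_minimal()
}
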