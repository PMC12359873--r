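#' @importFrom ggplot2 ggplot aes geom_col geom_errorbar geom_line
#'   geom_point geom_vline labs theme_bw autoplot scale_y_continuous
NULL

#' @export
ggplot2::autoplot

#' Plot spike-in conversion / false-positive rates
#'
#' @param object `scm_spikein_report`.
#' @param ... Unused.
#' @return A ggplot: one bar per control class with its Wilson 95% CI.
#' @export
autoplot.scm_spikein_report <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$class, y = 100 * .data$rate)) +
    geom_col(fill = "grey35") +
    geom_errorbar(aes(ymin = 100 * .data$conf_low,
                      ymax = 100 * .data$conf_high), width = 0.2) +
    labs(x = NULL, y = "modified calls (%)",
         title = "Spike-in conversion and false-positive rates") +
    theme_bw()
}

#' Plot a CpG saturation curve
#'
#' @param curve Output of [saturation()].
#' @return A ggplot of covered CpGs against sampled read pairs.
#' @export
plot_saturation <- function(curve) {
  ggplot(curve, aes(x = .data$n_pairs, y = .data$cpgs_covered)) +
    geom_line() + geom_point() +
    labs(x = "read pairs sampled", y = "distinct CpG sites covered",
         title = "CpG coverage saturation") +
    theme_bw()
}

#' Plot a metagene profile
#'
#' @param profile Output of [metagene()].
#' @param flank,body_length Geometry used (for segment boundaries).
#' @return A ggplot of mean level across the scaled gene body, with TSS
#'   and TES boundaries marked.
#' @export
plot_metagene <- function(profile, flank = 5000L, body_length = 5000L) {
  ggplot(profile, aes(x = .data$rel_pos, y = .data$mean_level)) +
    geom_line() +
    geom_vline(xintercept = c(0, body_length), linetype = "dashed") +
    labs(x = "position (bp; body rescaled)", y = "mean modification level",
         title = "Metagene profile (TSS to TES)") +
    theme_bw()
}

#' Plot a clustering embedding
#'
#' @param object `scm_cluster`.
#' @param ... Unused.
#' @return A ggplot of the 2-D embedding coloured by cluster.
#' @export
autoplot.scm_cluster <- function(object, ...) {
  ggplot(tidy(object),
         aes(x = .data$dim1, y = .data$dim2,
             colour = factor(.data$cluster))) +
    geom_point(size = 2) +
    labs(x = "PC1", y = "PC2", colour = "cluster",
         title = "Cell clustering on gene-body levels") +
    theme_bw()
}

#' Plot a binned level track for one contig
#'
#' @param bins Output of [bin_levels()].
#' @param contig Contig to show.
#' @return A ggplot of level along the contig, one line per cell.
#' @export
plot_bin_track <- function(bins, contig) {
  df <- filter(bins, .data$contig == !!contig, !is.na(.data$level))
  ggplot(df, aes(x = .data$start0, y = .data$level, group = .data$cell)) +
    geom_line(alpha = 0.5) +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = sprintf("%s position (bp)", contig), y = "level") +
    theme_bw()
}
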