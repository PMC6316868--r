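#' Block-length histogram for a set of calls
#'
#' Mirrors the standard block-size histogram (1 bp bins, x-axis capped by
#' default so the bulk of the distribution is visible).
#'
#' @param object A `bblock_calls` object.
#' @param binwidth Bin width in bp.
#' @param xmax Upper x limit in bp (blocks beyond it are not drawn).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bblock_calls <- function(object, binwidth = 1, xmax = 5000, ...) {
  len <- tibble(length = object$blocks$end - object$blocks$start)
  ggplot2::ggplot(len, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "firebrick") +
    ggplot2::coord_cartesian(xlim = c(0, xmax)) +
    ggplot2::labs(
      x = "Block length (bp)", y = "Number of blocks",
      title = sprintf("B block lengths: %s", object$sample_id),
      subtitle = sprintf("%d blocks; %.2f%% of bases passing thresholds",
                         object$counters$n_blocks, object$counters$pct_passing)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-base coverage and SCR for a region
#'
#' Two aligned panels: scaled coverage of carrier and reference, and the
#' per-base SCR with the calling threshold drawn as a dashed line.
#'
#' @param scr An `scr_tbl` from [scr_table()].
#' @param chrom Chromosome name.
#' @param start,end Region bounds (0-based half-open).
#' @param scr_min Threshold line to draw.
#' @return A ggplot object.
#' @export
plot_scr_region <- function(scr, chrom, start, end, scr_min = 3) {
  sel <- scr$chrom == chrom & scr$pos >= start & scr$pos < end
  if (!any(sel)) abort("Region has no data in the SCR table.")
  d <- as_tibble(scr[sel, ])
  long <- tidyr::pivot_longer(
    select(d, "pos", "carrier_scaled", "reference_scaled", "scr"),
    cols = c("carrier_scaled", "reference_scaled", "scr"),
    names_to = "track", values_to = "value"
  )
  long$panel <- ifelse(long$track == "scr", "SCR", "Scaled coverage")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pos, y = .data$value,
                                     colour = .data$track)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::geom_hline(
      data = tibble(panel = "SCR", y = scr_min),
      ggplot2::aes(yintercept = .data$y), linetype = "dashed",
      inherit.aes = FALSE
    ) +
    ggplot2::labs(x = sprintf("%s position (bp)", chrom), y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}
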