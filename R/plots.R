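#' Phasing profile plot of a PHAS locus
#'
#' Read abundance by 5'-end phase coordinate across the locus, in-register
#' species highlighted — the standard way of eyeballing a phased locus.
#'
#' @param locus one row of a [scan_phas()] result.
#' @param hits,tags optional full hit/tag tables to show out-of-register
#'   signal as well; with the default NULL only the in-register species
#'   (the nested `phasirnas`) are drawn.
#' @return a ggplot object.
#' @export
plot_phasing <- function(locus, hits = NULL, tags = NULL) {
  ph <- locus$phasirnas[[1]]
  df <- tibble(position = ph$position, abundance = ph$abundance,
               register = "in-register")
  if (!is.null(hits) && !is.null(tags)) {
    h <- dplyr::left_join(hits, tags[c("tag_id", "total")], by = "tag_id")
    h <- h[h$chrom == locus$chrom & h$start >= locus$start &
             h$start < locus$end, ]
    x <- phase_coord(h$start, h$strand, h$length)
    out <- !(x %% locus$period == locus$register & h$length == locus$period)
    df <- dplyr::bind_rows(df, tibble(position = h$start[out],
                                      abundance = h$total[out],
                                      register = "out-of-register"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$abundance,
                                   colour = .data$register)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = sprintf("%s (period %d, score %.1f)", locus$locus_id,
                      locus$period, locus$phasing_score),
      x = sprintf("%s position", locus$chrom), y = "abundance") +
    ggplot2::theme_minimal()
}

#' Degradome target plot (t-plot)
#'
#' 5'-end read density along one transcript with the predicted cleavage
#' position marked.
#'
#' @param profile sparse profile from [map_degradome()].
#' @param transcript_id transcript to draw.
#' @param cleavage_pos optional 0-based predicted cleavage coordinate.
#' @return a ggplot object.
#' @export
plot_tplot <- function(profile, transcript_id, cleavage_pos = NULL) {
  p <- profile[profile$transcript_id == transcript_id, ]
  g <- ggplot2::ggplot(p, ggplot2::aes(x = .data$position, y = .data$reads)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, yend = 0)) +
    ggplot2::labs(title = transcript_id, x = "transcript position",
                  y = "degradome 5' ends") +
    ggplot2::theme_minimal()
  if (!is.null(cleavage_pos)) {
    g <- g + ggplot2::geom_vline(xintercept = cleavage_pos,
                                 linetype = "dashed", colour = "red")
  }
  g
}

#' Volcano plot of a differential-expression result
#'
#' @param object a `phasnet_de` from [differential()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.phasnet_de <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = -log10(.data$fdr),
                                   colour = .data$passes)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * attr(object, "fc_min"),
                        linetype = "dotted") +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "fdr_max")),
                        linetype = "dotted") +
    ggplot2::labs(x = "log2 fold change (reproductive / vegetative)",
                  y = "-log10 FDR", colour = "passes") +
    ggplot2::theme_minimal()
}

#' Fold-change landscape of an assembled network
#'
#' miRNA versus mRNA fold change of every triple, coloured by model label —
#' the scatter view of the two regulatory modes.
#'
#' @param object a `phasnet_network`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.phasnet_network <- function(object, ...) {
  df <- object$triples
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc_mirna,
                                   y = .data$log2fc_mrna,
                                   colour = .data$model)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "log2FC miRNA", y = "log2FC mRNA",
                  colour = "model") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
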