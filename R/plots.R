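# ggplot2 displays for the main result types.

#' Plot a gene neighbourhood
#'
#' Gene boxes along each scaffold, strand shown by fill; assembly-gap runs
#' drawn as grey bands.
#'
#' @param record An [assembly_record()].
#' @param highlight Optional gene id drawn with a distinct outline.
#' @return A ggplot object.
#' @export
plot_neighborhood <- function(record, highlight = NULL) {
  stopifnot(inherits(record, "assembly_record"))
  genes <- gene_spans(record$annotations)
  gaps <- NULL
  if (!is.null(record$scaffolds)) {
    gaps <- purrr::map_dfr(seq_len(nrow(record$scaffolds)), function(i) {
      g <- gap_runs(record$scaffolds$sequence[i])
      if (nrow(g) > 0) g$scaffold_id <- record$scaffolds$id[i]
      g
    })
  }
  p <- ggplot2::ggplot(genes)
  if (!is.null(gaps) && nrow(gaps) > 0) {
    p <- p + ggplot2::geom_rect(
      data = gaps, fill = "grey80",
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -0.45, ymax = 0.45))
  }
  p + ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = ifelse(.data$strand == "+", 0.05, -0.4),
                   ymax = ifelse(.data$strand == "+", 0.4, -0.05),
                   fill = .data$strand),
      colour = "grey20") +
    ggplot2::geom_text(
      ggplot2::aes(x = (.data$start + .data$end) / 2,
                   y = ifelse(.data$strand == "+", 0.55, -0.55),
                   label = .data$gene_id), size = 3) +
    ggplot2::facet_wrap(~scaffold_id, ncol = 1, scales = "free_x") +
    ggplot2::scale_y_continuous(limits = c(-0.8, 0.8), breaks = NULL) +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  title = record$genome_id) +
    ggplot2::theme_minimal()
}

#' @rdname autoplots
#' @param object A result object.
#' @param ... Unused.
#' @method autoplot coverage_profile
#' @export
autoplot.coverage_profile <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$codon, y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "darkgreen") +
    ggplot2::labs(x = "codon", y = "exact-match read depth") +
    ggplot2::theme_minimal()
  if (!is.null(object$domains)) {
    p <- p + ggplot2::geom_rect(
      data = object$domains, inherit.aes = FALSE, alpha = 0.15,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf,
                   ymax = Inf, fill = .data$domain)) +
      ggplot2::labs(fill = "domain")
  }
  p
}

#' Autoplot methods for missedgene result objects
#'
#' @name autoplots
#' @rdname autoplots
#' @method autoplot spliced_alignment
#' @export
autoplot.spliced_alignment <- function(object, ...) {
  ex <- tidy(object)
  if (nrow(ex) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "empty alignment") +
             ggplot2::theme_void())
  }
  ggplot2::ggplot(ex) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$gstart, xend = .data$gend, y = 0, yend = 0),
      linewidth = 6, colour = "steelblue") +
    ggplot2::geom_segment(
      data = ex[-nrow(ex), , drop = FALSE],
      ggplot2::aes(x = .data$gend,
                   xend = ex$gstart[-1], y = 0, yend = 0),
      linetype = "dotted", colour = "grey40") +
    ggplot2::geom_text(
      ggplot2::aes(x = (.data$gstart + .data$gend) / 2, y = 0.12,
                   label = .data$exon), size = 3) +
    ggplot2::scale_y_continuous(limits = c(-0.3, 0.3), breaks = NULL) +
    ggplot2::labs(x = "genomic position (bp)", y = NULL,
                  title = sprintf("%d exon(s), strand %s, score %.0f",
                                  nrow(ex), object$strand, object$score)) +
    ggplot2::theme_minimal()
}
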