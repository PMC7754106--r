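#' Locus-compare scatter plot
#'
#' Plots GWAS against eQTL `-log10(P)` for the shared variants of one gene
#' and dataset, highlighting the risk variant when present.
#'
#' @param pairs Paired table from [locuscompare_table()].
#' @param risk_variant Optional risk-variant id to highlight.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_locuscompare <- function(pairs, risk_variant = NULL, title = NULL) {
  pairs <- as_tibble(pairs) %>%
    mutate(is_risk = !is.null(risk_variant) &
             .data$variant_id %in% risk_variant)
  p <- ggplot2::ggplot(pairs, ggplot2::aes(x = .data$neglog10p_qtl,
                                           y = .data$neglog10p_gwas)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_risk), size = 1.6,
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey35",
                                            `TRUE` = "purple")) +
    ggplot2::labs(x = expression(-log[10] * "P (eQTL)"),
                  y = expression(-log[10] * "P (GWAS)"), title = title) +
    ggplot2::theme_minimal()
  if (any(pairs$is_risk)) {
    p <- p + ggplot2::geom_text(
      data = filter(pairs, .data$is_risk),
      ggplot2::aes(label = .data$variant_id),
      vjust = -1, size = 3, colour = "purple"
    )
  }
  p
}

#' Regional association plot with locus shading
#'
#' Manhattan-style `-log10(P)` by position, with partitioned locus regions
#' shaded and lead variants marked.
#'
#' @param sumstats Summary-statistics tibble.
#' @param loci A `locus_set` from [partition_loci()].
#' @param chrom Optional chromosome to restrict to.
#' @return A ggplot object.
#' @export
plot_loci <- function(sumstats, loci, chrom = NULL) {
  ss <- as_tibble(sumstats)
  lt <- as_tibble(loci)
  if (!is.null(chrom)) {
    ss <- filter(ss, .data$chrom == .env$chrom)
    lt <- filter(lt, .data$chrom == .env$chrom)
  }
  leads <- if (nrow(lt)) purrr::list_rbind(lt$leads) else ss[0, ]
  p <- ggplot2::ggplot(ss, ggplot2::aes(x = .data$pos,
                                        y = -log10(.data$p))) +
    ggplot2::geom_point(size = 0.8, colour = "grey40")
  if (nrow(lt) > 0) {
    p <- p + ggplot2::geom_rect(
      data = lt,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.15
    )
  }
  if (nrow(leads) > 0) {
    p <- p + ggplot2::geom_point(data = leads, colour = "purple", size = 2)
  }
  p +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = expression(-log[10] * "P")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.locus_set <- function(object, sumstats = NULL, ...) {
  if (is.null(sumstats)) {
    sumstats <- if (nrow(object)) {
      purrr::list_rbind(object$leads)
    } else {
      tibble(chrom = character(), pos = numeric(), p = numeric())
    }
  }
  plot_loci(sumstats, object, ...)
}

#' Evidence heatmap for a locus
#'
#' Tile plot of the evidence bits per gene (0, 1 or missing), genes ordered
#' by conclusion score.
#'
#' @param object An `evidence_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evidence_table <- function(object, ...) {
  long <- as_tibble(object) %>%
    arrange(.data$conclusion) %>%
    mutate(gene = factor(.data$gene, levels = .data$gene)) %>%
    tidyr::pivot_longer(all_of(evidence_columns()), names_to = "column",
                        values_to = "bit") %>%
    mutate(column = factor(.data$column, levels = evidence_columns()),
           bit = factor(.data$bit, levels = c(0, 1)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$column, y = .data$gene,
                                     fill = .data$bit)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(`0` = "grey85", `1` = "steelblue"),
                               na.value = "grey98", name = "bit") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
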