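#' Locus-compare table for one gene and eQTL dataset
#'
#' Inner-joins GWAS and eQTL associations on variant id within a locus
#' window and returns the paired `-log10(P)` values that a locus-compare
#' scatter plots. Duplicate eQTL rows for one variant (e.g. several isoforms
#' of an isoQTL dataset) collapse to the smallest eQTL P with a warning.
#'
#' @param gwas_region Summary-statistics tibble restricted to one locus
#'   window.
#' @param eqtl eQTL tibble (one gene, one dataset) with columns
#'   `variant_id`, `p`.
#'
#' @return Tibble with columns `variant_id`, `pos`, `neglog10p_gwas`,
#'   `neglog10p_qtl`, ordered by position.
#' @export
locuscompare_table <- function(gwas_region, eqtl) {
  eqtl <- as_tibble(eqtl)
  if (nrow(eqtl) > 0 && anyDuplicated(eqtl$variant_id)) {
    warn("duplicate eQTL rows per variant collapsed to the smallest P")
    eqtl <- eqtl %>%
      group_by(.data$variant_id) %>%
      summarise(p = min(.data$p), .groups = "drop")
  }
  as_tibble(gwas_region) %>%
    select("variant_id", "pos", p_gwas = "p") %>%
    inner_join(select(eqtl, "variant_id", p_qtl = "p"), by = "variant_id") %>%
    mutate(neglog10p_gwas = -log10(.data$p_gwas),
           neglog10p_qtl = -log10(.data$p_qtl)) %>%
    arrange(.data$pos) %>%
    select("variant_id", "pos", "neglog10p_gwas", "neglog10p_qtl")
}

#' Is a locus-compare plot eligible?
#'
#' A plot is kept only if its shared variants include the locus risk variant
#' itself or at least one good proxy (r2 > 0.7 by default, from
#' [find_proxies()]); otherwise the scatter says nothing about the risk
#' signal and the plot is omitted.
#'
#' @param pairs Paired table from [locuscompare_table()].
#' @param risk_variant Risk-variant id.
#' @param proxies Character vector of proxy ids (or a [find_proxies()]
#'   result).
#' @return Logical flag.
#' @export
plot_eligible <- function(pairs, risk_variant, proxies = character()) {
  if (is.data.frame(proxies)) proxies <- proxies$variant_id
  nrow(pairs) > 0 &&
    (risk_variant %in% pairs$variant_id || any(proxies %in% pairs$variant_id))
}

#' GWAS-eQTL Pearson correlation
#'
#' Pearson correlation between the GWAS and eQTL `-log10(P)` columns of a
#' locus-compare table. Returns `NA` when fewer than `min_variants` variants
#' are shared, or (with a warning) when either column has zero variance.
#'
#' @param pairs Paired table from [locuscompare_table()].
#' @param min_variants Minimum shared variants required. Default 10.
#' @return Correlation coefficient in `[-1, 1]`, or `NA`.
#' @export
gwas_qtl_correlation <- function(pairs, min_variants = 10) {
  if (nrow(pairs) < min_variants) return(NA_real_)
  if (var(pairs$neglog10p_gwas) == 0 || var(pairs$neglog10p_qtl) == 0) {
    warn("zero variance in -log10(P); correlation undefined")
    return(NA_real_)
  }
  cor(pairs$neglog10p_gwas, pairs$neglog10p_qtl, method = "pearson")
}

#' Colocalization summary for the genes of one locus
#'
#' Runs [locuscompare_table()], [plot_eligible()] and
#' [gwas_qtl_correlation()] for every gene-by-dataset combination present in
#' the eQTL input, against one locus window of GWAS results.
#'
#' @param gwas_region Summary statistics restricted to the locus window.
#' @param eqtl Long eQTL tibble with columns `gene`, `variant_id`, `p`,
#'   `dataset`.
#' @param risk_variant Risk-variant id of the locus.
#' @param proxies Proxy ids for the risk variant (r2 > 0.7).
#' @param t [thresholds()] (supplies `min_variants`).
#'
#' @return Tibble with one row per gene and dataset: `n_shared`, `eligible`,
#'   `pearson_r` (`NA` when insufficient data).
#' @export
coloc_results <- function(gwas_region, eqtl, risk_variant,
                          proxies = character(), t = thresholds()) {
  eqtl <- as_tibble(eqtl)
  if (nrow(eqtl) == 0) {
    return(tibble(gene = character(), dataset = character(),
                  n_shared = integer(), eligible = logical(),
                  pearson_r = numeric()))
  }
  eqtl %>%
    group_by(.data$gene, .data$dataset) %>%
    dplyr::group_modify(function(rows, key) {
      pairs <- suppressWarnings(locuscompare_table(gwas_region, rows))
      eligible <- plot_eligible(pairs, risk_variant, proxies)
      tibble(
        n_shared = nrow(pairs),
        eligible = eligible,
        # correlation only reported for plots that would actually be drawn
        pearson_r = if (eligible) {
          suppressWarnings(
            gwas_qtl_correlation(pairs, min_variants = t$min_variants))
        } else {
          NA_real_
        }
      )
    }) %>%
    ungroup() %>%
    arrange(.data$gene, .data$dataset)
}
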