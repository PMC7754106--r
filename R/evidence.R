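#' Expression evidence bits
#'
#' A gene counts as expressed in a context when its mean TPM strictly
#' exceeds the cutoff (default 5 TPM) in that context: bulk brain, bulk
#' substantia nigra (`nigra`) and substantia-nigra dopaminergic neurons
#' (`dan`). A context with no record for the gene yields `NA`; a gene with
#' no expression records at all is `NA` in all three columns.
#'
#' @param gene Gene symbol.
#' @param expr Expression tibble (`gene`, `context`, `mean_tpm`).
#' @param t [thresholds()].
#' @return One-row tibble with `brain_expr`, `nigra_expr`, `dan_expr`.
#' @export
#' @examples
#' expr <- tibble::tibble(gene = "G", context = c("brain", "nigra", "dan"),
#'                        mean_tpm = c(6, 2, 7))
#' expression_bits("G", expr)
expression_bits <- function(gene, expr, t = thresholds()) {
  rows <- filter(as_tibble(expr), .data$gene == .env$gene)
  one <- function(ctx) {
    v <- rows$mean_tpm[rows$context == ctx]
    if (length(v) == 0) NA_integer_ else as.integer(v[1] > t$tpm_cutoff)
  }
  tibble(brain_expr = one("brain"), nigra_expr = one("nigra"),
         dan_expr = one("dan"))
}

#' QTL evidence bits
#'
#' `qtl_brain` is set when any brain dataset (brain eQTL or brain isoQTL)
#' has an eligible locus-compare plot; `qtl_blood` when the blood eQTL
#' dataset does. `qtl_correl` is 1 when any eligible plot's GWAS-eQTL
#' Pearson correlation strictly exceeds `correl_cutoff` in magnitude, `NA`
#' when the gene has no eligible brain or blood plot at all, and 0
#' otherwise.
#'
#' @param coloc [coloc_results()] rows for one gene.
#' @param t [thresholds()].
#' @return One-row tibble with `qtl_brain`, `qtl_blood`, `qtl_correl`.
#' @export
qtl_bits <- function(coloc, t = thresholds()) {
  coloc <- as_tibble(coloc)
  eligible <- filter(coloc, .data$eligible)
  qtl_brain <- as.integer(any(eligible$dataset %in%
                                c("brain_eqtl", "brain_isoqtl")))
  qtl_blood <- as.integer(any(eligible$dataset == "blood_eqtl"))
  qtl_correl <- if (qtl_brain == 0 && qtl_blood == 0) {
    NA_integer_
  } else {
    r <- eligible$pearson_r
    as.integer(any(!is.na(r) & abs(r) > t$correl_cutoff))
  }
  tibble(qtl_brain = qtl_brain, qtl_blood = qtl_blood, qtl_correl = qtl_correl)
}

#' Literature evidence bit
#'
#' Set when the disease-plus-gene query returns at least `lit_min_hits`
#' results (default 5, inclusive).
#'
#' @param n_hits Non-negative hit count of the combined query.
#' @param t [thresholds()].
#' @return Integer 0/1.
#' @export
literature_bit <- function(n_hits, t = thresholds()) {
  if (any(is.na(n_hits)) || any(n_hits < 0)) {
    abort("literature hit counts must be non-negative",
          class = "lr_input_error")
  }
  as.integer(n_hits >= t$lit_min_hits)
}

#' Literature query strings
#'
#' The exact PubMed-style query strings whose hit counts feed
#' [literature_bit()]; emitted so a supplied count table can be reproduced
#' against the live database.
#'
#' @param gene Gene symbol.
#' @return Named list with `query_pd` and `query_gene`.
#' @export
#' @examples
#' build_queries("P2RY12")$query_pd
build_queries <- function(gene) {
  list(
    query_pd = paste0(gene, "[Title/Abstract] AND Parkinson's[Title/Abstract]"),
    query_gene = paste0(gene, "[Title/Abstract]")
  )
}

#' Constraint (variant-intolerance) evidence bit
#'
#' Set when the upper limit of the 90% confidence interval of the
#' observed/expected ratio is strictly below `oe_upper_max` (default 0.35)
#' for any variant class (synonymous, missense, loss-of-function). `NA`
#' when the gene has no constraint record.
#'
#' @param rec One-row constraint tibble for the gene, or `NULL`/empty when
#'   absent.
#' @param t [thresholds()].
#' @return Integer 0/1 or `NA`.
#' @export
constraint_bit <- function(rec, t = thresholds()) {
  if (is.null(rec) || nrow(as_tibble(rec)) == 0) return(NA_integer_)
  rec <- as_tibble(rec)
  uppers <- c(rec$oe_syn_upper[1], rec$oe_mis_upper[1], rec$oe_lof_upper[1])
  if (all(is.na(uppers))) return(NA_integer_)
  as.integer(min(uppers, na.rm = TRUE) < t$oe_upper_max)
}

#' Burden evidence bit
#'
#' Set when the gene's minimum burden P value beats the Bonferroni-corrected
#' level `alpha / n` for either source, where `n` is the number of genes
#' with data in that source's burden tests. `NA` when the gene has no
#' burden record (or no P value in either source).
#'
#' @param rec One-row burden tibble (`min_p_exome`, `min_p_imputed`) or
#'   `NULL` when absent.
#' @param n_exome_genes,n_imputed_genes Number of genes with data in the
#'   exome / imputed burden tests (the Bonferroni denominators).
#' @param t [thresholds()].
#' @return Integer 0/1 or `NA`.
#' @export
burden_bit <- function(rec, n_exome_genes, n_imputed_genes, t = thresholds()) {
  if (n_exome_genes < 1 || n_imputed_genes < 1) {
    abort("burden gene counts must be >= 1", class = "lr_config_error")
  }
  if (is.null(rec) || nrow(as_tibble(rec)) == 0) return(NA_integer_)
  rec <- as_tibble(rec)
  pe <- rec$min_p_exome[1]
  pi_ <- rec$min_p_imputed[1]
  if (is.na(pe) && is.na(pi_)) return(NA_integer_)
  hit <- (!is.na(pe) && pe < t$alpha / n_exome_genes) ||
    (!is.na(pi_) && pi_ < t$alpha / n_imputed_genes)
  as.integer(hit)
}

#' Gene-list flag bits
#'
#' Membership indicators (upper-cased exact symbol match) for the
#' meta-analysis-nominated gene list, the monogenic PD/parkinsonism gene
#' list and the Mendelian disease-gene list (HGMD disease-causing plus
#' OMIM).
#'
#' @param gene Gene symbol.
#' @param flags List from [read_flags()] (`nominated_meta5`, `pd_genes`,
#'   `disease_genes`).
#' @return One-row tibble with `nominated_meta5`, `pd_gene`, `disease_gene`.
#' @export
flag_bits <- function(gene, flags) {
  g <- toupper(gene)
  tibble(
    nominated_meta5 = as.integer(g %in% toupper(flags$nominated_meta5)),
    pd_gene = as.integer(g %in% toupper(flags$pd_genes)),
    disease_gene = as.integer(g %in% toupper(flags$disease_genes))
  )
}

#' Assemble the per-gene evidence table for one locus
#'
#' Composes all evidence bits for every gene in the locus window and fills
#' the weighted conclusion score. Genes are taken from the union of
#' `flank`-windows around the locus lead variants; eligibility of
#' locus-compare plots uses the locus leads as risk variants plus any
#' supplied (or panel-derived) proxies.
#'
#' @param locus One locus: a single row of a `locus_set` (or a list with
#'   `locus_id`, `chrom`, `start`, `end` and a `leads` tibble).
#' @param genes Gene annotation tibble ([read_genes()]).
#' @param sumstats Full summary-statistics tibble.
#' @param eqtl Long eQTL tibble (`gene`, `variant_id`, `p`, `dataset`).
#' @param expression Expression tibble ([read_expression()]).
#' @param literature Literature-count tibble ([read_literature()]); genes
#'   missing from it count as zero hits.
#' @param constraint Constraint tibble ([read_constraint()]).
#' @param burden Burden tibble ([read_burden()]).
#' @param flags Flag sets ([read_flags()]).
#' @param panel Optional [genotype_panel()]; when given, proxies of each
#'   lead at `r2 > 0.7` are found in it.
#' @param proxies Optional character vector of proxy ids (used as-is when
#'   `panel` is `NULL`).
#' @param t [thresholds()].
#' @param weights [weight_config()].
#' @param flank Gene-window half-width in bp. Default 1 Mb.
#' @param n_exome_genes,n_imputed_genes Bonferroni denominators for the
#'   burden bit; default to the number of genes with data in the supplied
#'   burden table.
#'
#' @return An `evidence_table` tibble: `locus_id`, `gene`, the twelve
#'   evidence bits and `conclusion`.
#' @export
assemble_evidence <- function(locus, genes, sumstats, eqtl, expression,
                              literature, constraint, burden, flags,
                              panel = NULL, proxies = NULL, t = thresholds(),
                              weights = weight_config(), flank = 1e6,
                              n_exome_genes = NULL, n_imputed_genes = NULL) {
  locus <- as_locus_row(locus)
  leads <- locus$leads
  genes <- as_tibble(genes)
  # duplicate annotation rows for one symbol inside the window are ambiguous
  # (distinct from the same gene being reached from several leads)
  in_window <- purrr::map_lgl(seq_len(nrow(genes)), function(i)
    any(genes$chrom[i] == leads$chrom &
          genes$start[i] <= leads$pos + flank &
          genes$end[i] >= leads$pos - flank))
  if (anyDuplicated(genes$symbol[in_window])) {
    abort("duplicated gene symbols within the locus", class = "lr_format_error")
  }
  locus_genes <- genes_in_window(leads, genes, flank = flank)

  burden <- as_tibble(burden)
  n_exome_genes <- n_exome_genes %||% max(1L, sum(!is.na(burden$min_p_exome)))
  n_imputed_genes <- n_imputed_genes %||% max(1L, sum(!is.na(burden$min_p_imputed)))

  gwas_region <- as_tibble(sumstats) %>%
    filter(.data$chrom == locus$chrom,
           .data$pos >= locus$start, .data$pos <= locus$end)
  if (!is.null(panel)) {
    proxies <- unique(unlist(purrr::map(leads$variant_id, function(id) {
      if (!id %in% panel$variants$variant_id) return(character())
      find_proxies(id, panel, r2_min = 0.7)$variant_id
    })))
  }
  proxies <- proxies %||% character()
  eqtl_locus <- as_tibble(eqtl) %>% filter(.data$gene %in% locus_genes$symbol)
  coloc <- coloc_results(gwas_region, eqtl_locus,
                         risk_variant = leads$variant_id,
                         proxies = proxies, t = t)

  rows <- purrr::map(locus_genes$symbol, function(g) {
    lit <- filter(as_tibble(literature), .data$gene == g)
    n_hits <- if (nrow(lit) > 0) lit$n_hits_pd[1] else 0L
    bind_cols(
      tibble(gene = g),
      expression_bits(g, expression, t),
      qtl_bits(filter(coloc, .data$gene == g), t),
      tibble(literature = literature_bit(n_hits, t)),
      tibble(variant_intolerant = constraint_bit(
        filter(as_tibble(constraint), .data$gene == g), t)),
      tibble(burden = burden_bit(filter(burden, .data$gene == g),
                                 n_exome_genes, n_imputed_genes, t)),
      flag_bits(g, flags)
    )
  }) %>% purrr::list_rbind()

  if (length(rows) == 0 || nrow(rows) == 0) {
    rows <- tibble(gene = character()) %>%
      bind_cols(as_tibble(sapply(evidence_columns(), function(x) integer(),
                                 simplify = FALSE)))
  }
  out <- rows %>%
    mutate(locus_id = locus$locus_id, .before = 1) %>%
    mutate(conclusion = conclusion_score(., weights))
  class(out) <- c("evidence_table", class(tibble()))
  attr(out, "weights") <- weights
  out
}

as_locus_row <- function(locus) {
  if (inherits(locus, "locus_set") || (is.data.frame(locus) && "leads" %in% names(locus))) {
    locus <- as_tibble(locus)
    if (nrow(locus) != 1) {
      abort("`locus` must be a single locus row", class = "lr_input_error")
    }
    list(locus_id = locus$locus_id[[1]], chrom = locus$chrom[[1]],
         start = locus$start[[1]], end = locus$end[[1]],
         leads = locus$leads[[1]])
  } else if (is.list(locus) && !is.null(locus$leads)) {
    locus
  } else {
    abort("`locus` must be a locus_set row or list with a `leads` tibble",
          class = "lr_input_error")
  }
}
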