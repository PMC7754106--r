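#' Simulation configuration
#'
#' Parameters of the seeded synthetic-data generator. Haplotypes follow a
#' block-copying model: within a block each variant copies a latent block
#' haplotype with probability `copy_prob` (else it draws an independent
#' allele at the same frequency), which plants haplotypic correlation of
#' about `copy_prob^2` between block-mates. GWAS summary statistics are
#' simulated directly on the z-score scale,
#' `z = sqrt(n_gwas) * r(variant, causal) * effect_beta + N(0, 1)`,
#' with two-sided normal P values; colocalized genes inherit the GWAS
#' z-profile plus independent noise, non-colocalized genes get their own
#' causal variant in a different haplotype block.
#'
#' @param seed Integer seed fixing all randomness end-to-end.
#' @param n_samples Diploid panel size. Default 400.
#' @param n_variants Variants per locus. Default 60.
#' @param n_loci Number of planted loci. Default 1.
#' @param block_size Variants per haplotype block. Default 10.
#' @param copy_prob Within-block copying probability. Default 0.95.
#' @param effect_beta Per-causal effect on the log-odds scale. Default 0.12.
#' @param n_gwas Effective GWAS sample size used for the z-score scale.
#'   Default 20000.
#' @param coloc_genes,non_coloc_genes Genes per locus sharing / not sharing
#'   the GWAS causal variant. Defaults 2 and 2.
#' @param eqtl_noise Standard deviation of the noise added to eQTL
#'   z-scores. Default 2.
#' @param locus_spacing Distance between locus centers (bp). Default 10 Mb.
#' @param locus_span Span covered by each locus's variants (bp). Default 1 Mb.
#'
#' @return A list of class `lr_sim_config`.
#' @export
sim_config <- function(seed = 1, n_samples = 400, n_variants = 60, n_loci = 1,
                       block_size = 10, copy_prob = 0.95, effect_beta = 0.12,
                       n_gwas = 20000, coloc_genes = 2, non_coloc_genes = 2,
                       eqtl_noise = 2, locus_spacing = 1e7, locus_span = 1e6) {
  cfg <- as.list(environment())
  counts <- c("n_samples", "n_variants", "n_loci", "block_size",
              "coloc_genes", "non_coloc_genes")
  if (any(vapply(cfg[counts], function(x) x < 1, logical(1)))) {
    abort("simulation counts must be >= 1", class = "lr_config_error")
  }
  if (cfg$n_samples < 2) {
    abort("`n_samples` must be >= 2", class = "lr_config_error")
  }
  if (cfg$copy_prob < 0 || cfg$copy_prob > 1) {
    abort("`copy_prob` must lie in [0, 1]", class = "lr_config_error")
  }
  structure(cfg, class = "lr_sim_config")
}

sim_variant_map <- function(cfg) {
  purrr::map(seq_len(cfg$n_loci), function(l) {
    center <- 5e6 + (l - 1) * cfg$locus_spacing
    pos <- round(seq(center - cfg$locus_span / 2, center + cfg$locus_span / 2,
                     length.out = cfg$n_variants))
    tibble(
      variant_id = paste0("rs", l, "_", seq_len(cfg$n_variants)),
      chrom = "1",
      pos = pos,
      locus = l,
      block = (seq_len(cfg$n_variants) - 1) %/% cfg$block_size + 1L
    )
  }) %>% purrr::list_rbind()
}

#' Simulate a diploid reference panel with planted block LD
#'
#' @param cfg A [sim_config()].
#' @return A [genotype_panel()]; the variant map (with block assignment and
#'   the planted causal ids) is attached as attribute `truth`.
#' @export
simulate_panel <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  vmap <- sim_variant_map(cfg)
  n_hap <- 2 * cfg$n_samples
  haps <- matrix(0L, nrow = n_hap, ncol = nrow(vmap))
  for (key in unique(paste(vmap$locus, vmap$block))) {
    idx <- which(paste(vmap$locus, vmap$block) == key)
    f <- runif(1, 0.2, 0.8)
    latent <- rbinom(n_hap, 1, f)
    for (j in idx) {
      copy <- rbinom(n_hap, 1, cfg$copy_prob)
      haps[, j] <- ifelse(copy == 1, latent, rbinom(n_hap, 1, f))
    }
  }
  dosages <- haps[seq(1, n_hap, by = 2), , drop = FALSE] +
    haps[seq(2, n_hap, by = 2), , drop = FALSE]
  storage.mode(dosages) <- "numeric"
  colnames(dosages) <- vmap$variant_id
  rownames(dosages) <- paste0("S", seq_len(cfg$n_samples))
  variants <- vmap %>%
    select("variant_id", "chrom", "pos") %>%
    mutate(ref = "A", alt = "G")
  panel <- genotype_panel(variants, dosages)
  causal <- vmap %>%
    group_by(.data$locus) %>%
    slice(ceiling(dplyr::n() / 2)) %>%
    ungroup() %>%
    pull("variant_id")
  attr(panel, "truth") <- list(variant_map = vmap, causal = causal)
  panel
}

sim_assoc_z <- function(panel, causal_id, effect, n_gwas) {
  g_causal <- panel$dosages[, causal_id]
  r <- suppressWarnings(apply(panel$dosages, 2, function(g) {
    if (var(g) == 0 || var(g_causal) == 0) 0 else cor(g, g_causal)
  }))
  sqrt(n_gwas) * r * effect + rnorm(ncol(panel$dosages))
}

#' Simulate GWAS summary statistics over a panel
#'
#' @param cfg A [sim_config()].
#' @param panel Panel from [simulate_panel()] (same config).
#' @return Summary-statistics tibble in the [read_sumstats()] layout.
#' @export
simulate_sumstats <- function(cfg = sim_config(), panel = simulate_panel(cfg)) {
  force(panel)  # the panel draws from its own seed; realize it before reseeding
  set.seed(cfg$seed + 1L)
  truth <- attr(panel, "truth")
  se <- 1 / sqrt(cfg$n_gwas)
  z <- unname(unlist(purrr::map(seq_along(truth$causal), function(l) {
    ids <- truth$variant_map$variant_id[truth$variant_map$locus == l]
    sub <- genotype_panel(
      filter(panel$variants, .data$variant_id %in% ids),
      panel$dosages[, ids, drop = FALSE]
    )
    sim_assoc_z(sub, truth$causal[l], cfg$effect_beta, cfg$n_gwas)
  })))
  panel$variants %>%
    select("variant_id", "chrom", "pos") %>%
    mutate(
      allele_effect = "G", allele_other = "A",
      beta = z * se, se = se,
      p = pmax(2 * pnorm(-abs(z)), 1e-300)
    )
}

#' Simulate eQTL association tables with known colocalization truth
#'
#' @param cfg A [sim_config()].
#' @param panel Panel from [simulate_panel()].
#' @param sumstats Summary statistics from [simulate_sumstats()].
#' @return Long eQTL tibble (`gene`, `variant_id`, `p`, `dataset`); the
#'   per-gene truth labels (`coloc` flag, causal id, locus) are attached as
#'   attribute `truth`.
#' @export
simulate_eqtl <- function(cfg = sim_config(), panel = simulate_panel(cfg),
                          sumstats = simulate_sumstats(cfg, panel)) {
  force(panel)
  force(sumstats)  # upstream stages reseed; realize them before reseeding
  set.seed(cfg$seed + 2L)
  truth <- attr(panel, "truth")
  vmap <- truth$variant_map
  genes <- list()
  tabs <- list()
  for (l in seq_len(cfg$n_loci)) {
    ids <- vmap$variant_id[vmap$locus == l]
    ss <- filter(sumstats, .data$variant_id %in% ids)
    z_gwas <- ss$beta / ss$se
    causal_block <- vmap$block[vmap$variant_id == truth$causal[l]]
    # independent causal for non-coloc genes: first variant of another block
    alt_pool <- vmap %>% filter(.data$locus == l, .data$block != causal_block)
    for (k in seq_len(cfg$coloc_genes + cfg$non_coloc_genes)) {
      is_coloc <- k <= cfg$coloc_genes
      gene <- paste0("L", l, if (is_coloc) "C" else "N",
                     if (is_coloc) k else k - cfg$coloc_genes)
      if (is_coloc) {
        base_z <- z_gwas
        causal_id <- truth$causal[l]
      } else {
        causal_id <- alt_pool$variant_id[
          1 + ((k - cfg$coloc_genes - 1) * cfg$block_size) %% nrow(alt_pool)]
        sub <- genotype_panel(
          filter(panel$variants, .data$variant_id %in% ids),
          panel$dosages[, ids, drop = FALSE]
        )
        base_z <- sim_assoc_z(sub, causal_id, cfg$effect_beta, cfg$n_gwas)
      }
      for (ds in c("brain_eqtl", "blood_eqtl", "brain_isoqtl")) {
        z <- base_z + cfg$eqtl_noise * rnorm(length(base_z))
        tabs[[length(tabs) + 1L]] <- tibble(
          gene = gene, variant_id = ss$variant_id,
          p = pmax(2 * pnorm(-abs(z)), 1e-300), dataset = ds
        )
      }
      genes[[length(genes) + 1L]] <- tibble(
        gene = gene, locus = l, coloc = is_coloc, causal_id = causal_id
      )
    }
  }
  out <- purrr::list_rbind(tabs)
  attr(out, "truth") <- purrr::list_rbind(genes)
  out
}

#' Write a complete synthetic input bundle
#'
#' Generates a panel, summary statistics, eQTL tables and companion
#' per-gene tables (expression, constraint, burden, flags, literature) with
#' known ground truth, and writes them in the formats the readers expect:
#' `sumstats.tsv`, `genes.bed`, `panel.vcf`, `eqtl_brain.tsv`,
#' `eqtl_blood.tsv`, `eqtl_isoqtl.tsv`, `expression.tsv`,
#' `constraint.tsv`, `burden.tsv`, `flags.yaml`, `literature.tsv` and
#' `truth.json`.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
simulate_bundle <- function(cfg = sim_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- simulate_panel(cfg)
  sumstats <- simulate_sumstats(cfg, panel)
  eqtl <- simulate_eqtl(cfg, panel, sumstats)
  truth_genes <- attr(eqtl, "truth")
  vmap <- attr(panel, "truth")$variant_map

  readr::write_tsv(
    sumstats %>%
      select(SNP = "variant_id", CHR = "chrom", BP = "pos",
             A1 = "allele_effect", A2 = "allele_other",
             BETA = "beta", SE = "se", P = "p"),
    file.path(dir, "sumstats.tsv"), progress = FALSE
  )

  set.seed(cfg$seed + 3L)
  # genes tiled near each locus center; BED is 0-based half-open
  gene_pos <- truth_genes %>%
    group_by(.data$locus) %>%
    mutate(.i = row_number()) %>%
    ungroup() %>%
    mutate(
      center = 5e6 + (.data$locus - 1) * cfg$locus_spacing,
      start1 = .data$center - 4e5 + (.data$.i - 1) * 2e5,
      end1 = .data$start1 + 5e4
    )
  writeLines(
    paste(paste0("chr", "1"), format(gene_pos$start1 - 1, scientific = FALSE,
                                     trim = TRUE),
          format(gene_pos$end1, scientific = FALSE, trim = TRUE),
          gene_pos$gene, sep = "\t"),
    file.path(dir, "genes.bed")
  )

  write_panel_vcf(panel, file.path(dir, "panel.vcf"))
  for (ds in c("brain_eqtl", "blood_eqtl", "brain_isoqtl")) {
    fn <- c(brain_eqtl = "eqtl_brain.tsv", blood_eqtl = "eqtl_blood.tsv",
            brain_isoqtl = "eqtl_isoqtl.tsv")[[ds]]
    readr::write_tsv(filter(eqtl, .data$dataset == ds), file.path(dir, fn),
                     progress = FALSE)
  }

  expression <- tidyr::expand_grid(
    gene = truth_genes$gene, context = c("brain", "nigra", "dan")
  ) %>%
    mutate(mean_tpm = round(runif(dplyr::n(), 0, 20), 2))
  readr::write_tsv(expression, file.path(dir, "expression.tsv"),
                   progress = FALSE)

  constraint <- tibble(
    gene = truth_genes$gene,
    syn_z = round(rnorm(nrow(truth_genes)), 2),
    mis_z = round(rnorm(nrow(truth_genes)), 2),
    pLI = round(runif(nrow(truth_genes)), 3),
    oe_syn = 1, oe_syn_upper = 1.2,
    oe_mis = round(runif(nrow(truth_genes), 0.3, 1), 2)
  ) %>%
    mutate(oe_mis_upper = .data$oe_mis + 0.2,
           oe_lof = round(runif(dplyr::n(), 0.05, 0.9), 2),
           oe_lof_upper = .data$oe_lof + 0.15)
  readr::write_tsv(constraint, file.path(dir, "constraint.tsv"),
                   progress = FALSE)

  burden <- tibble(
    gene = truth_genes$gene,
    min_p_exome = signif(runif(nrow(truth_genes), 1e-6, 1), 3),
    min_p_imputed = signif(runif(nrow(truth_genes), 1e-6, 1), 3)
  )
  readr::write_tsv(burden, file.path(dir, "burden.tsv"), progress = FALSE)

  yaml::write_yaml(
    list(nominated_meta5 = list(truth_genes$gene[1]),
         pd_genes = list(), disease_genes = list(truth_genes$gene[1])),
    file.path(dir, "flags.yaml")
  )

  literature <- tibble(
    gene = truth_genes$gene,
    n_hits_pd = rbinom(nrow(truth_genes), 20, 0.2),
    n_hits_gene = rbinom(nrow(truth_genes), 200, 0.3)
  )
  readr::write_tsv(literature, file.path(dir, "literature.tsv"),
                   progress = FALSE)

  jsonlite::write_json(
    list(config = unclass(cfg),
         causal = attr(panel, "truth")$causal,
         genes = truth_genes,
         blocks = vmap),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

# minimal single-chromosome VCF 4.2 writer for simulated panels
write_panel_vcf <- function(panel, path) {
  v <- panel$variants
  gt_code <- function(d) {
    ifelse(is.na(d), "./.", c("0/0", "0/1", "1/1")[d + 1])
  }
  gt <- apply(panel$dosages, 1, gt_code)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(v))
  body <- paste(
    v$chrom, format(v$pos, scientific = FALSE, trim = TRUE), v$variant_id,
    v$ref %||% "A", v$alt %||% "G", ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(panel$dosages)), collapse = "\t")
  )
  writeLines(c(header, body), path)
}
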