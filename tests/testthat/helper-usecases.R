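# Deterministic input bundles reconstructing the two published worked
# examples from the facts stated for them (expression above/below cutoff,
# locus-compare eligibility and correlation, flag-set membership, constraint
# and burden records). Everything is fixed numbers: no RNG.

usecase_gwas_profile <- function(risk_id, risk_neglog, chrom, center) {
  other <- c(8.2, 7.6, 6.9, 6.1, 5.4, 4.8, 4.1, 3.5, 2.9, 2.2, 1.8, 1.2,
             0.8, 0.4)
  ids <- c(risk_id, paste0(risk_id, "_n", seq_along(other)))
  neglog <- c(risk_neglog, other)
  tibble::tibble(
    variant_id = ids, chrom = chrom,
    pos = center + (seq_along(ids) - 1) * 2e4,
    allele_effect = "A", allele_other = "G",
    beta = -0.05, se = 0.01, p = 10^-neglog
  )
}

# eQTL profile tracking the GWAS signal closely enough that the Pearson
# correlation of the -log10 P columns clearly exceeds 0.3
usecase_eqtl_profile <- function(gwas, gene, dataset, scale = 0.8) {
  wobble <- rep(c(0.3, -0.2, 0.1, -0.3, 0.2), length.out = nrow(gwas))
  tibble::tibble(
    gene = gene, variant_id = gwas$variant_id,
    p = 10^-pmax(scale * -log10(gwas$p) + wobble, 0.01),
    dataset = dataset
  )
}

usecase_p2ry12 <- function() {
  gwas <- usecase_gwas_profile("rs11707416", -log10(1.13e-10), "3", 151e6)
  list(
    gene = "P2RY12",
    gwas = gwas,
    genes = tibble::tibble(symbol = "P2RY12", chrom = "3",
                           start = 151.05e6, end = 151.1e6, strand = "+"),
    # correlated, risk-variant-anchored plots in brain and blood
    eqtl = dplyr::bind_rows(
      usecase_eqtl_profile(gwas, "P2RY12", "brain_eqtl"),
      usecase_eqtl_profile(gwas, "P2RY12", "blood_eqtl", scale = 0.7)
    ),
    # expressed above 5 TPM in brain, nigra and dopaminergic neurons
    expression = tibble::tibble(
      gene = "P2RY12", context = c("brain", "nigra", "dan"),
      mean_tpm = c(12.0, 9.5, 21.0)
    ),
    # no reported PD literature for the gene
    literature = tibble::tibble(gene = "P2RY12", n_hits_pd = 0L,
                                n_hits_gene = 150L),
    # unconstrained gene: all CI upper bounds well above 0.35
    constraint = tibble::tibble(
      gene = "P2RY12", syn_z = 0.1, mis_z = 0.3, pLI = 0.01,
      oe_syn = 1.0, oe_syn_upper = 1.2, oe_mis = 0.9, oe_mis_upper = 1.1,
      oe_lof = 0.8, oe_lof_upper = 1.3
    ),
    # no burden data for the gene
    burden = empty_burden(),
    # Mendelian disease link (platelet-type bleeding disorder 8) only
    flags = list(nominated_meta5 = character(), pd_genes = character(),
                 disease_genes = "P2RY12")
  )
}

usecase_dyrk1a <- function() {
  gwas <- usecase_gwas_profile("rs2248244", -log10(2.74e-11), "21", 38e6)
  list(
    gene = "DYRK1A",
    gwas = gwas,
    genes = tibble::tibble(symbol = "DYRK1A", chrom = "21",
                           start = 38.1e6, end = 38.25e6, strand = "+"),
    # brain eQTL, blood eQTL and brain isoQTL all eligible and correlated
    eqtl = dplyr::bind_rows(
      usecase_eqtl_profile(gwas, "DYRK1A", "brain_eqtl"),
      usecase_eqtl_profile(gwas, "DYRK1A", "blood_eqtl", scale = 0.7),
      usecase_eqtl_profile(gwas, "DYRK1A", "brain_isoqtl", scale = 0.9)
    ),
    expression = tibble::tibble(
      gene = "DYRK1A", context = c("brain", "nigra", "dan"),
      mean_tpm = c(18.0, 14.0, 25.0)
    ),
    # well represented in the PD literature
    literature = tibble::tibble(gene = "DYRK1A", n_hits_pd = 40L,
                                n_hits_gene = 900L),
    # loss-of-function intolerant: pLI 1, low LoF CI upper bound
    constraint = tibble::tibble(
      gene = "DYRK1A", syn_z = 0.5, mis_z = 2.9, pLI = 1.0,
      oe_syn = 1.0, oe_syn_upper = 1.1, oe_mis = 0.6, oe_mis_upper = 0.7,
      oe_lof = 0.05, oe_lof_upper = 0.12
    ),
    # burden data present but not significant after Bonferroni correction
    burden = tibble::tibble(gene = "DYRK1A", min_p_exome = 0.02,
                            min_p_imputed = 0.4),
    # nominated in the risk GWAS and linked to MRD7; not a monogenic PD gene
    flags = list(nominated_meta5 = "DYRK1A", pd_genes = character(),
                 disease_genes = "DYRK1A")
  )
}

score_usecase <- function(uc) {
  loci <- locusrank::partition_loci(uc$gwas)
  stopifnot(nrow(loci) == 1)
  ev <- locusrank::assemble_evidence(
    loci[1, ], uc$genes, uc$gwas, uc$eqtl, uc$expression, uc$literature,
    uc$constraint, uc$burden, uc$flags,
    n_exome_genes = 1480, n_imputed_genes = 1026
  )
  ev[ev$gene == uc$gene, , drop = FALSE]
}
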