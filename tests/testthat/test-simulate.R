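test_that("simulation is deterministic per seed", {
  cfg <- sim_config(seed = 12, n_variants = 30, n_samples = 100)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$dosages, p2$dosages)
  s1 <- simulate_sumstats(cfg, p1)
  s2 <- simulate_sumstats(cfg, p2)
  expect_identical(s1, s2)
  e1 <- simulate_eqtl(cfg, p1, s1)
  e2 <- simulate_eqtl(cfg, p2, s2)
  expect_identical(as.data.frame(e1), as.data.frame(e2))

  p3 <- simulate_panel(sim_config(seed = 13, n_variants = 30, n_samples = 100))
  expect_false(identical(p1$dosages, p3$dosages))
})

test_that("copying probability 1 plants perfect within-block LD", {
  cfg <- sim_config(seed = 4, n_variants = 12, block_size = 6,
                    n_samples = 120, copy_prob = 1)
  panel <- simulate_panel(cfg)
  ids <- panel$variants$variant_id
  for (pair in list(c(1, 3), c(2, 6), c(7, 12))) {
    s <- ld_pair_report(ids[pair[1]], ids[pair[2]], panel)
    if (s$status != "ok") next
    # pairs in the same block are exact copies; across blocks unconstrained
    same_block <- (pair[1] - 1) %/% 6 == (pair[2] - 1) %/% 6
    if (same_block) expect_equal(s$r2, 1, tolerance = 1e-6)
  }
})

test_that("copying probability 0 gives near-independent variants", {
  cfg <- sim_config(seed = 6, n_variants = 25, block_size = 5,
                    n_samples = 300, copy_prob = 0)
  panel <- simulate_panel(cfg)
  ids <- panel$variants$variant_id
  set.seed(60)
  r2s <- replicate(50, {
    pick <- sample(ids, 2)
    s <- ld_pair_report(pick[1], pick[2], panel)
    if (s$status == "ok") s$r2 else NA_real_
  })
  expect_lt(mean(r2s, na.rm = TRUE), 0.1)
})

test_that("null effects produce no significant variants", {
  for (seed in 1:3) {
    cfg <- sim_config(seed = seed, effect_beta = 0, n_variants = 40,
                      n_samples = 150)
    panel <- simulate_panel(cfg)
    ss <- simulate_sumstats(cfg, panel)
    expect_equal(nrow(partition_loci(ss)), 0, info = paste("seed", seed))
  }
})

test_that("a strong causal yields one locus containing it; distant causals split", {
  cfg <- sim_config(seed = 3)
  panel <- simulate_panel(cfg)
  ss <- simulate_sumstats(cfg, panel)
  loci <- partition_loci(ss)
  expect_equal(nrow(loci), 1)
  causal <- attr(panel, "truth")$causal
  causal_pos <- panel$variants$pos[panel$variants$variant_id == causal]
  expect_true(loci$start <= causal_pos && causal_pos <= loci$end)

  # two causals 3 Mb apart: windows [c-1Mb, c+1Mb] leave a >100 kb gap
  cfg2 <- sim_config(seed = 3, n_loci = 2, locus_spacing = 3e6)
  panel2 <- simulate_panel(cfg2)
  ss2 <- simulate_sumstats(cfg2, panel2)
  expect_equal(nrow(partition_loci(ss2)), 2)
})

test_that("noise-free colocalized genes correlate perfectly with the GWAS", {
  cfg <- sim_config(seed = 8, eqtl_noise = 0, non_coloc_genes = 1)
  panel <- simulate_panel(cfg)
  ss <- simulate_sumstats(cfg, panel)
  eqtl <- simulate_eqtl(cfg, panel, ss)
  truth <- attr(eqtl, "truth")
  coloc_gene <- truth$gene[truth$coloc][1]
  pairs <- locuscompare_table(
    ss, dplyr::filter(eqtl, gene == coloc_gene, dataset == "brain_eqtl"))
  expect_equal(gwas_qtl_correlation(pairs), 1, tolerance = 1e-9)
})

test_that("the bundle writer round-trips through the package readers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 9, n_variants = 20, n_samples = 60)
  simulate_bundle(cfg, dir)
  expected <- c("sumstats.tsv", "genes.bed", "panel.vcf", "eqtl_brain.tsv",
                "eqtl_blood.tsv", "eqtl_isoqtl.tsv", "expression.tsv",
                "constraint.tsv", "burden.tsv", "flags.yaml",
                "literature.tsv", "truth.json")
  expect_true(all(file.exists(file.path(dir, expected))))

  ss <- suppressMessages(read_sumstats(file.path(dir, "sumstats.tsv")))
  direct <- simulate_sumstats(cfg, simulate_panel(cfg))
  expect_equal(ss$variant_id, direct$variant_id)
  expect_equal(ss$p, direct$p, tolerance = 1e-12)

  panel <- suppressMessages(read_panel(file.path(dir, "panel.vcf")))
  direct_panel <- simulate_panel(cfg)
  expect_equal(unname(panel$dosages), unname(direct_panel$dosages))

  genes <- read_genes(file.path(dir, "genes.bed"), format = "bed")
  expect_gt(nrow(genes), 0)
  eq <- read_eqtl(file.path(dir, "eqtl_brain.tsv"))
  expect_true(all(eq$dataset == "brain_eqtl"))
  expect_s3_class(read_constraint(file.path(dir, "constraint.tsv")), "tbl_df")
  expect_s3_class(read_burden(file.path(dir, "burden.tsv")), "tbl_df")
  expect_type(read_flags(file.path(dir, "flags.yaml")), "list")
})

test_that("plot builders return ggplot objects", {
  cfg <- sim_config(seed = 2, n_variants = 20, n_samples = 80)
  panel <- simulate_panel(cfg)
  ss <- simulate_sumstats(cfg, panel)
  loci <- partition_loci(ss)
  expect_s3_class(plot_loci(ss, loci), "ggplot")
  expect_s3_class(autoplot(loci, sumstats = ss), "ggplot")
  eqtl <- simulate_eqtl(cfg, panel, ss)
  g1 <- attr(eqtl, "truth")$gene[1]
  pairs <- locuscompare_table(
    ss, dplyr::filter(eqtl, gene == g1, dataset == "brain_eqtl"))
  expect_s3_class(plot_locuscompare(pairs, risk_variant = ss$variant_id[1]),
                  "ggplot")
})
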