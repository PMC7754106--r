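test_that("expression bits use a strict 5 TPM cutoff and NA for missing data", {
  expr <- tibble::tibble(
    gene = c("G1", "G1", "G1", "G2"),
    context = c("brain", "nigra", "dan", "brain"),
    mean_tpm = c(6, 2, 7, 5.0)
  )
  b1 <- expression_bits("G1", expr)
  expect_equal(as.integer(b1), c(1L, 0L, 1L))
  # exactly at the cutoff is not expressed
  expect_equal(expression_bits("G2", expr)$brain_expr, 0L)
  # context without a record is NA
  expect_true(is.na(expression_bits("G2", expr)$nigra_expr))
  # gene absent from the table entirely
  expect_true(all(is.na(unlist(expression_bits("G3", expr)))))
})

test_that("qtl bits distinguish eligibility, correlation, and absence", {
  coloc_row <- function(ds, eligible, r) {
    tibble::tibble(gene = "G", dataset = ds, n_shared = 20L,
                   eligible = eligible, pearson_r = r)
  }
  # eligible brain plot with |r| > 0.3
  b <- qtl_bits(coloc_row("brain_eqtl", TRUE, 0.35))
  expect_equal(as.integer(b), c(1L, 0L, 1L))
  # eligible blood only, weak correlation
  b <- qtl_bits(coloc_row("blood_eqtl", TRUE, 0.1))
  expect_equal(as.integer(b), c(0L, 1L, 0L))
  # negative correlations count by magnitude
  b <- qtl_bits(coloc_row("brain_isoqtl", TRUE, -0.9))
  expect_equal(as.integer(b), c(1L, 0L, 1L))
  # exactly at the cutoff does not pass (strict >)
  b <- qtl_bits(coloc_row("brain_eqtl", TRUE, 0.3))
  expect_equal(b$qtl_correl, 0L)
  # no eligible plots at all -> correl is NA, not 0
  b <- qtl_bits(coloc_row("brain_eqtl", FALSE, NA_real_))
  expect_equal(as.integer(b[, 1:2]), c(0L, 0L))
  expect_true(is.na(b$qtl_correl))
  # eligible plot but correlation unavailable -> 0 (plots exist)
  b <- qtl_bits(coloc_row("blood_eqtl", TRUE, NA_real_))
  expect_equal(b$qtl_correl, 0L)
})

test_that("literature bit is inclusive at 5 hits and queries are exact", {
  expect_equal(literature_bit(5), 1L)
  expect_equal(literature_bit(4), 0L)
  expect_error(literature_bit(-1), class = "lr_input_error")
  q <- build_queries("P2RY12")
  expect_identical(q$query_pd,
                   "P2RY12[Title/Abstract] AND Parkinson's[Title/Abstract]")
  expect_identical(q$query_gene, "P2RY12[Title/Abstract]")
})

test_that("constraint bit reads the 90% CI upper bound strictly", {
  rec <- tibble::tibble(gene = "G", syn_z = 1, mis_z = 1, pLI = 0.5,
                        oe_syn = 1, oe_syn_upper = 1.3,
                        oe_mis = 1, oe_mis_upper = 1.2,
                        oe_lof = 0.2, oe_lof_upper = 0.30)
  expect_equal(constraint_bit(rec), 1L)
  all35 <- dplyr::mutate(rec, oe_syn_upper = 0.35, oe_mis_upper = 0.35,
                         oe_lof_upper = 0.35)
  expect_equal(constraint_bit(all35), 0L)
  expect_true(is.na(constraint_bit(NULL)))
  expect_true(is.na(constraint_bit(rec[0, ])))
})

test_that("burden bit applies per-source Bonferroni correction", {
  rec <- tibble::tibble(gene = "G", min_p_exome = 1e-6,
                        min_p_imputed = NA_real_)
  expect_equal(burden_bit(rec, 1480, 1026), 1L)  # 1e-6 < 0.05/1480
  rec2 <- tibble::tibble(gene = "G", min_p_exome = 1e-4,
                         min_p_imputed = 1e-3)
  expect_equal(burden_bit(rec2, 1480, 1026), 0L)  # both above their levels
  expect_true(is.na(burden_bit(NULL, 1480, 1026)))
  # absent value in both sources behaves like an absent gene
  rec3 <- tibble::tibble(gene = "G", min_p_exome = NA_real_,
                         min_p_imputed = NA_real_)
  expect_true(is.na(burden_bit(rec3, 1480, 1026)))
  expect_error(burden_bit(rec, 0, 1026), class = "lr_config_error")
})

test_that("flag bits are case-insensitive membership indicators", {
  flags <- list(nominated_meta5 = "Dyrk1a", pd_genes = c("SNCA", "LRRK2"),
                disease_genes = c("DYRK1A", "P2RY12"))
  expect_equal(as.integer(flag_bits("dyrk1a", flags)), c(1L, 0L, 1L))
  expect_equal(as.integer(flag_bits("SNCA", flags)), c(0L, 1L, 0L))
  expect_equal(as.integer(flag_bits("NOPE", flags)), c(0L, 0L, 0L))
})

test_that("raising thresholds never turns a 0 into a 1", {
  expr <- tibble::tibble(gene = "G", context = "brain", mean_tpm = 7)
  for (cut in c(5, 6, 7, 8)) {
    bit <- expression_bits("G", expr, thresholds(tpm_cutoff = cut))$brain_expr
    if (cut >= 7) expect_equal(bit, 0L) else expect_equal(bit, 1L)
  }
  hits <- 6
  b5 <- literature_bit(hits, thresholds(lit_min_hits = 5))
  b7 <- literature_bit(hits, thresholds(lit_min_hits = 7))
  expect_lte(b7, b5)
})

test_that("assemble_evidence composes all bits for the locus genes", {
  ss <- dplyr::bind_rows(
    purrr::map(1:12, function(i)
      sumstats_row(paste0("rs", i), "1", 5e6 + i * 1e4,
                   if (i == 6) 1e-12 else 10^-runif(1, 0, 4)))
  )
  loci <- partition_loci(ss)
  genes <- tibble::tibble(symbol = c("HIT", "BARE"), chrom = "1",
                          start = c(5.0e6, 5.2e6), end = c(5.1e6, 5.3e6),
                          strand = "+")
  expr <- tibble::tibble(gene = "HIT", context = c("brain", "nigra", "dan"),
                         mean_tpm = c(10, 10, 10))
  eqtl <- tibble::tibble(gene = "HIT", variant_id = ss$variant_id,
                         p = ss$p, dataset = "brain_eqtl")
  lit <- tibble::tibble(gene = "HIT", n_hits_pd = 9L, n_hits_gene = 10L)
  constraint <- tibble::tibble(
    gene = "HIT", syn_z = 1, mis_z = 2, pLI = 1,
    oe_syn = 0.9, oe_syn_upper = 1.1, oe_mis = 0.5, oe_mis_upper = 0.7,
    oe_lof = 0.1, oe_lof_upper = 0.2)
  burden <- tibble::tibble(gene = "HIT", min_p_exome = 1e-9,
                           min_p_imputed = NA_real_)
  flags <- list(nominated_meta5 = "HIT", pd_genes = "HIT",
                disease_genes = "HIT")
  ev <- assemble_evidence(loci[1, ], genes, ss, eqtl, expr, lit, constraint,
                          burden, flags, n_exome_genes = 1480,
                          n_imputed_genes = 1026)
  hit <- dplyr::filter(ev, gene == "HIT")
  expect_equal(as.integer(hit[, evidence_columns()]),
               c(1L, 1L, 1L, 1L, 0L, 1L, 1L, 1L, 1L, 1L, 1L, 1L))
  expect_equal(hit$conclusion, 11)

  # gene with no data anywhere: expression/constraint/burden NA, qtl 0/0/NA
  bare <- dplyr::filter(ev, gene == "BARE")
  expect_true(all(is.na(bare[, c("brain_expr", "nigra_expr", "dan_expr",
                                 "qtl_correl", "variant_intolerant",
                                 "burden")])))
  expect_equal(as.integer(bare[, c("qtl_brain", "qtl_blood", "literature",
                                   "nominated_meta5", "pd_gene",
                                   "disease_gene")]),
               rep(0L, 6))
  expect_equal(bare$conclusion, 0)

  # empty gene table -> empty evidence table
  ev0 <- assemble_evidence(loci[1, ], genes[0, ], ss, eqtl, expr, lit,
                           constraint, burden, flags)
  expect_equal(nrow(ev0), 0)

  # duplicated symbols within the locus are refused
  expect_error(
    assemble_evidence(loci[1, ], dplyr::bind_rows(genes, genes[1, ]), ss,
                      eqtl, expr, lit, constraint, burden, flags),
    class = "lr_format_error")
})

test_that("NA appears only in the six columns that allow it", {
  ss <- sumstats_row("rs1", "1", 5e6, 1e-10)
  loci <- partition_loci(ss)
  genes <- tibble::tibble(symbol = "LONE", chrom = "1", start = 5.1e6,
                          end = 5.2e6, strand = "+")
  ev <- assemble_evidence(loci[1, ], genes, ss,
                          tibble::tibble(gene = character(),
                                         variant_id = character(),
                                         p = numeric(), dataset = character()),
                          tibble::tibble(gene = character(),
                                         context = character(),
                                         mean_tpm = numeric()),
                          tibble::tibble(gene = character(),
                                         n_hits_pd = integer(),
                                         n_hits_gene = integer()),
                          empty_constraint(), empty_burden(), no_flags())
  bits <- ev[, evidence_columns()]
  na_cols <- names(bits)[vapply(bits, anyNA, logical(1))]
  expect_true(all(na_cols %in% c("brain_expr", "nigra_expr", "dan_expr",
                                 "qtl_correl", "variant_intolerant",
                                 "burden")))
  vals <- unlist(bits)
  expect_true(all(is.na(vals) | vals %in% c(0L, 1L)))
})
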