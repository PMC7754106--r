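test_that("a single significant variant spans lead +/- window", {
  ss <- dplyr::bind_rows(
    sumstats_row("rs1", "1", 5e6, 1e-10),
    sumstats_row("rs2", "1", 5.2e6, 0.4)
  )
  loci <- partition_loci(ss)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$start, 4e6)
  expect_equal(loci$end, 6e6)
  expect_equal(loci$n_leads, 1L)
  expect_equal(loci$leads[[1]]$variant_id, "rs1")
})

test_that("no genome-wide-significant variant yields an empty locus set", {
  ss <- sumstats_row("rs1", "1", 5e6, 1e-7)
  loci <- partition_loci(ss)
  expect_s3_class(loci, "locus_set")
  expect_equal(nrow(loci), 0)
  expect_equal(nrow(partition_loci(ss[0, ])), 0)
})

test_that("regions merge at a 100 kb edge gap but not beyond", {
  # peaks 2.05 Mb apart: edges (p1 + 1 Mb) and (p2 - 1 Mb) are 50 kb apart
  ss <- dplyr::bind_rows(
    sumstats_row("rsA", "1", 5e6, 1e-12),
    sumstats_row("rsB", "1", 7.05e6, 1e-9)
  )
  merged <- partition_loci(ss)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$start, 4e6)
  expect_equal(merged$end, 8.05e6)
  expect_equal(merged$n_leads, 2L)
  expect_equal(merged$n_merged, 2L)
  # extraction order: smaller P first
  expect_equal(merged$leads[[1]]$variant_id, c("rsA", "rsB"))

  # peaks 2.2 Mb apart: edge gap 200 kb -> two loci
  ss2 <- dplyr::bind_rows(
    sumstats_row("rsA", "1", 5e6, 1e-12),
    sumstats_row("rsB", "1", 7.2e6, 1e-9)
  )
  split <- partition_loci(ss2)
  expect_equal(nrow(split), 2)
  expect_equal(split$start, c(4e6, 6.2e6))
  expect_equal(split$end, c(6e6, 8.2e6))
})

test_that("window is clipped at position 1 and config is validated", {
  ss <- sumstats_row("rs1", "1", 5e5, 1e-10)
  loci <- partition_loci(ss)
  expect_equal(loci$start, 1)
  expect_error(partition_config(window = -5), class = "lr_config_error")
  expect_error(partition_config(p_threshold = 2), class = "lr_config_error")
})

test_that("partitioning is invariant to input row order", {
  ss <- random_sumstats(42)
  loci_a <- partition_loci(ss)
  set.seed(1)
  loci_b <- partition_loci(ss[sample(nrow(ss)), ])
  expect_equal(tidy(loci_a), tidy(loci_b))
})

test_that("every significant variant lies in exactly one locus and loci are separated", {
  cfg <- partition_config()
  for (seed in 1:10) {
    ss <- random_sumstats(seed)
    loci <- partition_loci(ss, cfg)
    sig <- dplyr::filter(ss, p < cfg$p_threshold)
    for (i in seq_len(nrow(sig))) {
      hits <- sum(loci$chrom == sig$chrom[i] &
                    loci$start <= sig$pos[i] & loci$end >= sig$pos[i])
      expect_equal(hits, 1)
    }
    per_chr <- split(loci, loci$chrom)
    for (lc in per_chr) {
      if (nrow(lc) < 2) next
      lc <- lc[order(lc$start), ]
      gaps <- lc$start[-1] - lc$end[-nrow(lc)]
      expect_true(all(gaps > cfg$merge_gap))
    }
  }
})

test_that("partition matches the brute-force extraction oracle", {
  for (seed in 1:15) {
    ss <- random_sumstats(seed)
    loci <- tidy(partition_loci(ss))
    oracle <- partition_oracle(ss)
    expect_equal(nrow(loci), nrow(oracle), info = paste("seed", seed))
    if (nrow(loci) == 0) next
    loci <- loci[order(loci$chrom, loci$start), ]
    expect_equal(loci$start, oracle$start, info = paste("seed", seed))
    expect_equal(loci$end, oracle$end, info = paste("seed", seed))
    expect_equal(loci$n_leads, oracle$n_leads, info = paste("seed", seed))
    sorted_ids <- vapply(strsplit(loci$lead_rsids, ","), function(x)
      paste(sort(x), collapse = ","), character(1))
    expect_equal(sorted_ids, oracle$lead_ids, info = paste("seed", seed))
  }
})

test_that("genes_in_window applies the 1 bp overlap rule", {
  lead <- sumstats_row("rs1", "1", 5e6, 1e-10)
  genes <- tibble::tibble(
    symbol = c("IN_EDGE", "OUT", "SPAN"),
    chrom = "1",
    start = c(5e6 + 999000, 5e6 + 1.5e6, 3e6),
    end = c(5e6 + 1050000, 5e6 + 1.6e6, 7e6),
    strand = "+"
  )
  hit <- genes_in_window(lead, genes)
  expect_setequal(hit$symbol, c("IN_EDGE", "SPAN"))
  expect_equal(nrow(genes_in_window(lead, genes[0, ])), 0)
  expect_error(genes_in_window(lead, genes, flank = 0),
               class = "lr_config_error")
})

test_that("multi-lead loci take the union of gene windows, deduplicated", {
  leads <- dplyr::bind_rows(
    sumstats_row("rs1", "1", 5e6, 1e-12),
    sumstats_row("rs2", "1", 7.05e6, 1e-9)
  )
  genes <- tibble::tibble(
    symbol = c("NEAR1", "NEAR2", "BOTH"),
    chrom = "1",
    start = c(4.1e6, 8.0e6, 5.9e6),
    end = c(4.2e6, 8.04e6, 6.2e6),
    strand = "+"
  )
  hit <- genes_in_window(leads, genes)
  expect_setequal(hit$symbol, c("NEAR1", "NEAR2", "BOTH"))
  expect_equal(nrow(hit), 3)  # BOTH not duplicated
})

test_that("locus tables round-trip through TSV", {
  ss <- random_sumstats(7)
  loci <- partition_loci(ss)
  tf <- tempfile(fileext = ".tsv")
  write_loci(loci, tf)
  expect_equal(as.data.frame(read_loci(tf)), as.data.frame(tidy(loci)),
               ignore_attr = TRUE)
})

test_that("locus_set summaries expose counts", {
  ss <- dplyr::bind_rows(
    sumstats_row("rsA", "1", 5e6, 1e-12),
    sumstats_row("rsB", "2", 8e6, 1e-9)
  )
  g <- glance(partition_loci(ss))
  expect_equal(g$n_loci, 2L)
  expect_equal(g$n_leads, 2L)
  expect_equal(g$min_p, 1e-12)
})
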