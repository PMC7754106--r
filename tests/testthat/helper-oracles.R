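# Independent brute-force oracles and fixture builders shared across tests.
# These deliberately use plain loops and naive data structures so they share
# no code path with the package implementation they check.

# --- LD: direct haplotype counting (valid only without double heterozygotes)
counting_ld_oracle <- function(ga, gb) {
  keep <- !is.na(ga) & !is.na(gb)
  ga <- ga[keep]; gb <- gb[keep]
  stopifnot(!any(ga == 1 & gb == 1))
  counts <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
  for (i in seq_along(ga)) {
    a_alleles <- switch(as.character(ga[i]), "0" = c(0, 0), "1" = c(1, 0),
                        "2" = c(1, 1))
    b_alleles <- switch(as.character(gb[i]), "0" = c(0, 0), "1" = c(1, 0),
                        "2" = c(1, 1))
    # without a double het at most one locus is heterozygous, so assigning
    # the sorted alleles positionally is the unique phasing
    for (k in 1:2) {
      hap <- paste0(if (a_alleles[k] == 1) "A" else "a",
                    if (b_alleles[k] == 1) "B" else "b")
      key <- c(AB = "AB", Ab = "Ab", aB = "aB", ab = "ab")[[hap]]
      counts[key] <- counts[key] + 1
    }
  }
  f <- counts / sum(counts)
  p_a <- f[["AB"]] + f[["Ab"]]
  p_b <- f[["AB"]] + f[["aB"]]
  d <- f[["AB"]] - p_a * p_b
  d_max <- if (d >= 0) min(p_a * (1 - p_b), (1 - p_a) * p_b)
           else min(p_a * p_b, (1 - p_a) * (1 - p_b))
  list(
    f = f, p_a = p_a, p_b = p_b, d = d,
    d_prime = if (d_max == 0) 0 else abs(d) / d_max,
    r2 = d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
  )
}

# boundary fixtures engineered from rational haplotype counts (no double
# heterozygotes, so counting is exact): r2 = 4/5 and r2 = 7/10
ld_fixture_r2_0p8 <- function() {
  list(ga = c(rep(2, 4), 2, rep(0, 4)), gb = c(rep(2, 4), 1, rep(0, 4)))
}
ld_fixture_r2_0p7 <- function() {
  list(ga = c(rep(2, 8), 2, 2, rep(0, 7)), gb = c(rep(2, 8), 1, 0, rep(0, 7)))
}

make_panel <- function(dosages, chrom = "1", pos = NULL) {
  ids <- colnames(dosages)
  if (is.null(pos)) pos <- seq_len(ncol(dosages)) * 1000
  locusrank::genotype_panel(
    tibble::tibble(variant_id = ids, chrom = chrom, pos = pos,
                   ref = "A", alt = "G"),
    dosages
  )
}

# --- partition: naive simulation of the extraction loop plus an igraph
# connected-component merge of the lead windows
partition_oracle <- function(ss, p_threshold = 5e-8, window = 1e6,
                             merge_gap = 1e5) {
  out <- list()
  for (chr in unique(ss$chrom)) {
    rows <- ss[ss$chrom == chr, , drop = FALSE]
    rows <- rows[order(rows$pos), , drop = FALSE]
    pool <- rep(TRUE, nrow(rows))
    leads <- list()
    repeat {
      sig <- which(pool & rows$p < p_threshold)
      if (length(sig) == 0) break
      best <- sig[order(rows$p[sig], rows$pos[sig])][1]
      leads[[length(leads) + 1]] <- rows[best, , drop = FALSE]
      pool[pool & abs(rows$pos - rows$pos[best]) <= window] <- FALSE
    }
    if (length(leads) == 0) next
    starts <- vapply(leads, function(l) max(1, l$pos - window), numeric(1))
    ends <- vapply(leads, function(l) l$pos + window, numeric(1))
    n <- length(leads)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      gap <- max(starts[i], starts[j]) - min(ends[i], ends[j])
      adj[i, j] <- gap <= merge_gap
    }
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))$membership
    for (cc in unique(comp)) {
      idx <- which(comp == cc)
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = chr, start = min(starts[idx]), end = max(ends[idx]),
        n_leads = length(idx),
        lead_ids = paste(sort(vapply(idx, function(i) leads[[i]]$variant_id,
                                     character(1))), collapse = ","),
        min_p = min(vapply(idx, function(i) leads[[i]]$p, numeric(1)))
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_leads = integer(),
                          lead_ids = character(), min_p = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

random_sumstats <- function(seed, n_variants = 150) {
  set.seed(seed)
  n <- sample(20:n_variants, 1)
  chrom <- sample(c("1", "2"), n, replace = TRUE)
  pos <- round(runif(n, 1e5, 2e7))
  # mixture of null and strongly associated variants so locus geometry varies
  p <- ifelse(runif(n) < 0.15, 10^-runif(n, 8, 30), runif(n))
  tibble::tibble(
    variant_id = paste0("rs", seq_len(n)), chrom = chrom, pos = pos,
    allele_effect = "A", allele_other = "G",
    beta = rnorm(n, 0, 0.1), se = 0.01, p = p
  ) |> dplyr::distinct(chrom, pos, .keep_all = TRUE)
}

sumstats_row <- function(id, chrom, pos, p) {
  tibble::tibble(variant_id = id, chrom = chrom, pos = pos,
                 allele_effect = "A", allele_other = "G",
                 beta = 0.1, se = 0.01, p = p)
}

empty_constraint <- function() {
  tibble::tibble(gene = character(), syn_z = numeric(), mis_z = numeric(),
                 pLI = numeric(), oe_syn = numeric(), oe_syn_upper = numeric(),
                 oe_mis = numeric(), oe_mis_upper = numeric(),
                 oe_lof = numeric(), oe_lof_upper = numeric())
}

empty_burden <- function() {
  tibble::tibble(gene = character(), min_p_exome = numeric(),
                 min_p_imputed = numeric())
}

no_flags <- function() {
  list(nominated_meta5 = character(), pd_genes = character(),
       disease_genes = character())
}
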