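#' Partition GWAS summary statistics into risk loci
#'
#' Splits a summary-statistics table into risk regions by iterative lead
#' extraction, processed per chromosome: the remaining variant with the
#' smallest P value below `cfg$p_threshold` becomes a lead, it and every
#' variant within `cfg$window` bp of it are extracted, and the region
#' `[lead - window, lead + window]` (clipped at position 1) is recorded.
#' When no significant variant remains, regions whose edges are within
#' `cfg$merge_gap` bp of each other are merged transitively. Ties on P are
#' broken by chromosome then position, so the result does not depend on
#' input row order.
#'
#' @param sumstats Tibble of summary statistics from [read_sumstats()].
#' @param cfg A [partition_config()].
#'
#' @return A `locus_set` tibble with columns `locus_id`, `chrom`, `start`,
#'   `end`, `n_leads`, `min_p`, `n_merged` and a `leads` list-column holding
#'   the lead variants of each locus in extraction order. Loci are numbered
#'   by (chromosome, start).
#' @export
#' @examples
#' ss <- tibble::tibble(
#'   variant_id = c("rs1", "rs2"), chrom = "1", pos = c(5e6, 9e6),
#'   allele_effect = "A", allele_other = "G", beta = 0.1, se = 0.01,
#'   p = c(1e-10, 0.5)
#' )
#' partition_loci(ss)
partition_loci <- function(sumstats, cfg = partition_config()) {
  if (!inherits(cfg, "lr_partition_config")) cfg <- do.call(partition_config, cfg)
  sumstats <- as_tibble(sumstats)
  empty <- sumstats[0, , drop = FALSE]
  if (nrow(sumstats) == 0 || !any(sumstats$p < cfg$p_threshold)) {
    return(new_locus_set(tibble(
      locus_id = integer(), chrom = character(), start = numeric(),
      end = numeric(), n_leads = integer(), min_p = numeric(),
      n_merged = integer(), leads = list()
    ), cfg))
  }

  regions <- sumstats %>%
    dplyr::group_split(.data$chrom) %>%
    purrr::map(extract_chromosome_regions, cfg = cfg) %>%
    purrr::list_rbind()

  out <- regions %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::group_modify(~ merge_regions(.x, cfg$merge_gap)) %>%
    ungroup() %>%
    mutate(.chrom_rank = chrom_rank(.data$chrom)) %>%
    arrange(.data$.chrom_rank, .data$start) %>%
    mutate(locus_id = row_number()) %>%
    select("locus_id", "chrom", "start", "end", "n_leads", "min_p",
           "n_merged", "leads")
  new_locus_set(out, cfg)
}

# iterative lead extraction on one chromosome; returns pre-merge regions
extract_chromosome_regions <- function(ss, cfg) {
  ss <- arrange(ss, .data$p, .data$pos)
  remaining <- rep(TRUE, nrow(ss))
  out <- list()
  k <- 0L
  repeat {
    cand <- which(remaining & ss$p < cfg$p_threshold)
    if (length(cand) == 0) break
    lead_i <- cand[1]  # sorted by (p, pos): first hit is the tie-broken lead
    lead <- ss[lead_i, , drop = FALSE]
    hit <- remaining & abs(ss$pos - lead$pos) <= cfg$window
    remaining[hit] <- FALSE
    k <- k + 1L
    out[[k]] <- tibble(
      chrom = lead$chrom,
      start = max(1, lead$pos - cfg$window),
      end = lead$pos + cfg$window,
      min_p = lead$p,
      leads = list(mutate(lead, .extraction = k))
    )
  }
  purrr::list_rbind(out)
}

# transitive gap-merge of same-chromosome regions (scan over start-sorted
# intervals is the fixpoint of pairwise merging)
merge_regions <- function(regions, merge_gap) {
  regions <- arrange(regions, .data$start, .data$end)
  grp <- cumsum(c(1, (regions$start[-1] - cummax_shift(regions$end)) > merge_gap))
  regions %>%
    mutate(.grp = grp) %>%
    group_by(.data$.grp) %>%
    summarise(
      start = min(.data$start), end = max(.data$end),
      min_p = min(.data$min_p), n_merged = dplyr::n(),
      leads = list(
        purrr::list_rbind(.data$leads) %>%
          arrange(.data$.extraction) %>% select(-".extraction")
      ),
      .groups = "drop"
    ) %>%
    mutate(n_leads = vapply(.data$leads, nrow, integer(1))) %>%
    select(-".grp")
}

# running max of region ends, shifted by one (for gap computation)
cummax_shift <- function(x) {
  if (length(x) <= 1) return(numeric(0))
  cummax(x)[-length(x)]
}

chrom_rank <- function(chrom) {
  n <- suppressWarnings(as.numeric(chrom))
  n[chrom %in% c("X", "x")] <- 23
  n[chrom %in% c("Y", "y")] <- 24
  n[is.na(n)] <- 25
  n
}

new_locus_set <- function(x, cfg) {
  structure(x, class = c("locus_set", class(tibble())), partition_config = cfg)
}

#' Genes within the window around lead variants
#'
#' Returns genes whose interval overlaps `[pos - flank, pos + flank]` of any
#' supplied lead variant by at least one base pair; for a locus with several
#' leads the union over leads is returned, deduplicated by symbol.
#'
#' @param leads Tibble with columns `chrom` and `pos` (one row per lead), or
#'   a single row of a `leads` list-column.
#' @param genes Gene tibble from [read_genes()].
#' @param flank Window half-width in bp; default 1 Mb each side.
#'
#' @return Tibble of overlapping genes, ordered by (chrom, start, symbol).
#' @export
genes_in_window <- function(leads, genes, flank = 1e6) {
  if (!is.numeric(flank) || length(flank) != 1 || !is.finite(flank) || flank <= 0) {
    abort("`flank` must be a positive number of base pairs",
          class = "lr_config_error")
  }
  leads <- as_tibble(leads)
  genes <- as_tibble(genes)
  if (nrow(genes) == 0 || nrow(leads) == 0) return(genes[0, , drop = FALSE])
  hits <- purrr::map(seq_len(nrow(leads)), function(i) {
    filter(genes,
           .data$chrom == leads$chrom[i],
           .data$start <= leads$pos[i] + flank,
           .data$end >= leads$pos[i] - flank)
  })
  purrr::list_rbind(hits) %>%
    distinct(.data$symbol, .keep_all = TRUE) %>%
    arrange(chrom_rank(.data$chrom), .data$start, .data$symbol)
}

#' Write / read a locus table
#'
#' Flat TSV export of a `locus_set`: `locus_id`, `chrom`, `start`, `end`,
#' `n_leads`, `lead_rsids` (comma-joined, extraction order), `min_p`.
#'
#' @param loci A `locus_set` from [partition_loci()].
#' @param path Output path.
#' @return The flat tibble, invisibly (for `write_loci`); a tibble for
#'   `read_loci`.
#' @export
write_loci <- function(loci, path) {
  flat <- tidy_locus_table(loci)
  readr::write_tsv(flat, path, na = "NA", progress = FALSE)
  invisible(flat)
}

#' @rdname write_loci
#' @export
read_loci <- function(path) {
  readr::read_tsv(path, na = "NA", progress = FALSE,
                  col_types = readr::cols(
                    locus_id = "i", chrom = "c", start = "d", end = "d",
                    n_leads = "i", lead_rsids = "c", min_p = "d"
                  ))
}

tidy_locus_table <- function(loci) {
  loci <- as_tibble(loci)
  if (nrow(loci) == 0) {
    return(tibble(locus_id = integer(), chrom = character(), start = numeric(),
                  end = numeric(), n_leads = integer(), lead_rsids = character(),
                  min_p = numeric()))
  }
  loci %>%
    mutate(lead_rsids = purrr::map_chr(
      .data$leads, ~ paste(.x$variant_id, collapse = ","))) %>%
    select("locus_id", "chrom", "start", "end", "n_leads", "lead_rsids", "min_p")
}

#' @export
tidy.locus_set <- function(x, ...) tidy_locus_table(x)

#' @export
glance.locus_set <- function(x, ...) {
  tibble(
    n_loci = nrow(x),
    n_leads = if (nrow(x)) sum(x$n_leads) else 0L,
    n_merged = if (nrow(x)) sum(x$n_merged > 1) else 0L,
    min_p = if (nrow(x)) min(x$min_p) else NA_real_,
    span_bp = if (nrow(x)) sum(x$end - x$start + 1) else 0
  )
}

#' @export
print.locus_set <- function(x, ...) {
  cat("<locus_set> ", nrow(x), " locus/loci\n", sep = "")
  print(tidy_locus_table(x), ...)
  invisible(x)
}
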