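#' Read GWAS summary statistics
#'
#' Reads a tab-separated summary-statistics table into the canonical
#' per-variant layout used throughout the package. Coordinates are 1-based;
#' chromosome labels are normalized by stripping a leading `"chr"`; odds
#' ratios are log-transformed to the beta scale when the dialect declares an
#' `OR` column. Malformed rows (P outside (0, 1], non-positive SE, position
#' below 1) are dropped with a warning, as are all rows of any multi-allelic
#' site (more than two distinct alleles observed at one chrom:pos).
#'
#' @param path Path to a TSV file with a header row.
#' @param dialect Named character vector mapping canonical column names
#'   (`SNP`, `CHR`, `BP`, `A1`, `A2`, `BETA` or `OR`, `SE`, `P`) to the names
#'   used in the file. Canonical names present in the file need not be mapped.
#'
#' @return A tibble with columns `variant_id`, `chrom`, `pos`,
#'   `allele_effect`, `allele_other`, `beta`, `se`, `p`. The number of
#'   accepted records is reported via a message.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("SNP\tCHR\tBP\tA1\tA2\tBETA\tSE\tP",
#'              "rs1\t1\t100\tA\tG\t0.1\t0.02\t1e-9"), tf)
#' read_sumstats(tf)
read_sumstats <- function(path, dialect = character()) {
  if (!file.exists(path)) {
    abort(paste0("summary statistics file not found: ", path),
          class = "lr_io_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  resolve <- function(canon) {
    nm <- if (canon %in% names(dialect)) unname(dialect[[canon]]) else canon
    if (nm %in% names(raw)) nm else NA_character_
  }
  required <- c("SNP", "CHR", "BP", "A1", "A2", "SE", "P")
  cols <- vapply(required, resolve, character(1))
  if (anyNA(cols)) {
    abort(paste0("summary statistics missing required column(s): ",
                 paste(required[is.na(cols)], collapse = ", ")),
          class = "lr_format_error")
  }
  beta_col <- resolve("BETA")
  or_col <- resolve("OR")
  if (is.na(beta_col) && is.na(or_col)) {
    abort("summary statistics missing required column: BETA (or OR)",
          class = "lr_format_error")
  }
  eff <- if (!is.na(beta_col)) raw[[beta_col]] else raw[[or_col]]
  out <- tibble(
    variant_id = raw[[cols[["SNP"]]]],
    chrom = sub("^chr", "", raw[[cols[["CHR"]]]]),
    pos = suppressWarnings(as.numeric(raw[[cols[["BP"]]]])),
    allele_effect = toupper(raw[[cols[["A1"]]]]),
    allele_other = toupper(raw[[cols[["A2"]]]]),
    beta = suppressWarnings(as.numeric(eff)),
    se = suppressWarnings(as.numeric(raw[[cols[["SE"]]]])),
    p = suppressWarnings(as.numeric(raw[[cols[["P"]]]]))
  )
  if (is.na(beta_col)) out$beta <- log(out$beta)
  n_in <- nrow(out)

  ok <- !is.na(out$p) & out$p > 0 & out$p <= 1 &
    !is.na(out$se) & out$se > 0 &
    !is.na(out$pos) & out$pos >= 1 & !is.na(out$beta)
  if (any(!ok)) {
    warn(paste0(sum(!ok), " row(s) rejected: P outside (0,1], SE <= 0, ",
                "bad position or unparseable effect"))
    out <- out[ok, , drop = FALSE]
  }

  # multi-allelic: >2 distinct alleles observed across rows at one chrom:pos
  if (nrow(out) > 0) {
    multi <- out %>%
      tidyr::pivot_longer(c("allele_effect", "allele_other"),
                          values_to = "allele") %>%
      group_by(.data$chrom, .data$pos) %>%
      summarise(n_alleles = dplyr::n_distinct(.data$allele), .groups = "drop") %>%
      filter(.data$n_alleles > 2)
    if (nrow(multi) > 0) {
      n_before <- nrow(out)
      out <- anti_join(out, multi, by = c("chrom", "pos"))
      warn(paste0(n_before - nrow(out),
                  " row(s) dropped at multi-allelic site(s)"))
    }
  }

  dup <- duplicated(out[, c("variant_id", "chrom", "pos")])
  if (any(dup)) {
    warn(paste0(sum(dup), " duplicated record(s) dropped"))
    out <- out[!dup, , drop = FALSE]
  }
  inform(paste0("read_sumstats: ", nrow(out), " of ", n_in,
                " record(s) accepted"))
  out
}

#' Read gene annotation
#'
#' Imports gene intervals from BED (0-based half-open, converted to 1-based
#' inclusive at this boundary) or GFF3 (`gene` features only, already
#' 1-based). Zero-width intervals are dropped with a warning.
#'
#' @param path Path to the annotation file.
#' @param format `"bed"` or `"gff3"`.
#'
#' @return A tibble with columns `symbol`, `chrom`, `start`, `end`, `strand`.
#' @export
read_genes <- function(path, format = c("bed", "gff3")) {
  format <- tryCatch(match.arg(format), error = function(e)
    abort(paste0("unknown gene annotation format: ", format[1]),
          class = "lr_format_error"))
  if (!file.exists(path)) {
    abort(paste0("gene annotation file not found: ", path),
          class = "lr_io_error")
  }
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed")
  if (format == "gff3") {
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    meta <- S4Vectors::mcols(gr)
    symbol <- if ("Name" %in% names(meta)) as.character(meta$Name)
      else if ("gene_name" %in% names(meta)) as.character(meta$gene_name)
      else as.character(meta$ID)
  } else {
    symbol <- as.character(gr$name)
  }
  out <- tibble(
    symbol = symbol,
    chrom = sub("^chr", "", as.character(GenomicRanges::seqnames(gr))),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  ) %>%
    mutate(strand = if_else(.data$strand %in% c("+", "-"), .data$strand, "+"))
  zero <- out$end < out$start
  if (any(zero)) {
    warn(paste0(sum(zero), " zero-length interval(s) dropped"))
    out <- out[!zero, , drop = FALSE]
  }
  out
}

#' Construct a genotype panel
#'
#' Container for an unphased diploid reference panel: a variant table and a
#' samples-by-variants matrix of alternate-allele dosages in `{0, 1, 2, NA}`.
#'
#' @param variants Tibble with columns `variant_id`, `chrom`, `pos` (and
#'   optionally `ref`, `alt`).
#' @param dosages Numeric matrix, samples in rows, variants in columns;
#'   column names must equal `variants$variant_id`.
#'
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(variants, dosages) {
  variants <- as_tibble(variants)
  stopifnot(is.matrix(dosages))
  if (is.null(colnames(dosages))) colnames(dosages) <- variants$variant_id
  if (!identical(colnames(dosages), variants$variant_id)) {
    abort("dosage columns do not match variant table", class = "lr_format_error")
  }
  bad <- stats::na.omit(unique(as.vector(dosages)))
  if (length(setdiff(bad, c(0, 1, 2))) > 0) {
    abort("dosages must be 0, 1, 2 or NA", class = "lr_format_error")
  }
  if (anyDuplicated(variants$variant_id)) {
    abort("duplicated variant ids in panel", class = "lr_format_error")
  }
  structure(list(variants = variants, dosages = dosages),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", nrow(x$dosages), " samples x ",
      ncol(x$dosages), " variants\n", sep = "")
  invisible(x)
}

#' Read a diploid reference panel from VCF
#'
#' Parses GT fields into alternate-allele dosages. Non-biallelic sites are
#' skipped (count reported); missing genotypes become `NA`. Haploid GT calls
#' are an error because LD estimation assumes diploid samples.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @return A [genotype_panel()].
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("VCF not found: ", path), class = "lr_io_error")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) {   # single-variant VCFs drop to a named vector
    fixm <- matrix(fixm, nrow = 1, dimnames = list(NULL, names(fixm)))
  }
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  if (ncol(v@gt) < 2) {
    abort("VCF contains no samples", class = "lr_format_error")
  }
  biallelic <- !grepl(",", fix$ALT) & fix$ALT != "." & fix$REF != "."
  n_skipped <- sum(!biallelic)
  if (n_skipped > 0) {
    inform(paste0("read_panel: ", n_skipped, " non-biallelic site(s) skipped"))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) {
    gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  }
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]

  alleles <- gsub("\\|", "/", gt)
  haploid <- !is.na(alleles) & !grepl("/", alleles)
  if (any(haploid)) {
    bad_sample <- colnames(alleles)[which(haploid, arr.ind = TRUE)[1, 2]]
    abort(paste0("haploid genotype for sample ", bad_sample,
                 "; diploid GT required"), class = "lr_format_error")
  }
  dose_one <- function(g) {
    if (is.na(g) || g %in% c("./.", ".")) return(NA_real_)
    parts <- strsplit(g, "/", fixed = TRUE)[[1]]
    if (any(parts == ".")) return(NA_real_)
    sum(parts != "0")
  }
  dosages <- t(apply(alleles, 1, function(row) vapply(row, dose_one, numeric(1))))
  if (nrow(fix) == 1) dosages <- matrix(dosages, nrow = 1)
  dosages <- t(dosages)  # samples x variants

  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  variants <- tibble(
    variant_id = ids,
    chrom = sub("^chr", "", fix$CHROM),
    pos = as.numeric(fix$POS),
    ref = fix$REF,
    alt = fix$ALT
  )
  colnames(dosages) <- variants$variant_id
  rownames(dosages) <- colnames(gt)
  genotype_panel(variants, dosages)
}

evidence_output_columns <- function() {
  c("locus_id", "gene", evidence_columns(), "conclusion")
}

#' Write / read a per-locus evidence table
#'
#' Writes evidence rows in a deterministic column order. `NA` bits are
#' serialized as the literal string `NA` in TSV and as `null` in JSON, and
#' both formats round-trip losslessly through [read_evidence()].
#'
#' @param x Evidence tibble for a single locus (as produced by
#'   [assemble_evidence()] or [rank_genes()]).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `x`, invisibly.
#' @export
write_evidence <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  x <- as_tibble(x)
  if (nrow(x) > 0 && "locus_id" %in% names(x) &&
      length(unique(x$locus_id)) > 1) {
    abort("evidence rows must share one locus id", class = "lr_format_error")
  }
  cols <- intersect(c(evidence_output_columns(), "rank"), names(x))
  x <- x[, c(cols, setdiff(names(x), cols)), drop = FALSE]
  if (format == "tsv") {
    readr::write_tsv(x, path, na = "NA", progress = FALSE)
  } else {
    jsonlite::write_json(x, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(x)
}

#' @rdname write_evidence
#' @export
read_evidence <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- readr::read_tsv(path, na = "NA", progress = FALSE,
                           col_types = readr::cols())
  } else {
    out <- as_tibble(jsonlite::fromJSON(path))
  }
  bit_cols <- intersect(evidence_columns(), names(out))
  out %>% mutate(across(all_of(bit_cols), as.integer))
}

#' Read a long gene-by-context expression table
#'
#' @param path TSV with columns `gene`, `context`, `mean_tpm`.
#' @return Tibble of mean TPM per gene and context.
#' @export
read_expression <- function(path) {
  out <- read_simple_tsv(path, c("gene", "context", "mean_tpm"))
  out$mean_tpm <- as.numeric(out$mean_tpm)
  if (any(is.na(out$mean_tpm) | out$mean_tpm < 0)) {
    abort("mean_tpm must be numeric and >= 0", class = "lr_format_error")
  }
  if (anyDuplicated(out[, c("gene", "context")])) {
    abort("one expression record per (gene, context) required",
          class = "lr_format_error")
  }
  out
}

#' Read an eQTL association table
#'
#' @param path TSV with columns `gene`, `variant_id`, `p` (a `dataset` column
#'   is honoured if present).
#' @param dataset Dataset label: `"brain_eqtl"`, `"blood_eqtl"` or
#'   `"brain_isoqtl"`; used when the file has no `dataset` column.
#' @return Tibble of eQTL records.
#' @export
read_eqtl <- function(path, dataset = c("brain_eqtl", "blood_eqtl", "brain_isoqtl")) {
  out <- read_simple_tsv(path, c("gene", "variant_id", "p"), optional = "dataset")
  out$p <- as.numeric(out$p)
  if (any(is.na(out$p) | out$p <= 0 | out$p > 1)) {
    abort("eQTL P values must lie in (0, 1]", class = "lr_format_error")
  }
  if (!"dataset" %in% names(out)) out$dataset <- match.arg(dataset)
  known <- c("brain_eqtl", "blood_eqtl", "brain_isoqtl")
  if (length(setdiff(unique(out$dataset), known)) > 0) {
    abort(paste0("unknown eQTL dataset label(s): ",
                 paste(setdiff(unique(out$dataset), known), collapse = ", ")),
          class = "lr_format_error")
  }
  out
}

#' Read a gnomAD-style constraint table
#'
#' @param path TSV with columns `gene`, `syn_z`, `mis_z`, `pLI`, `oe_syn`,
#'   `oe_syn_upper`, `oe_mis`, `oe_mis_upper`, `oe_lof`, `oe_lof_upper`.
#' @return Tibble with one row per gene.
#' @export
read_constraint <- function(path) {
  cols <- c("gene", "syn_z", "mis_z", "pLI", "oe_syn", "oe_syn_upper",
            "oe_mis", "oe_mis_upper", "oe_lof", "oe_lof_upper")
  out <- read_simple_tsv(path, cols)
  out <- out %>% mutate(across(!all_of("gene"), as.numeric))
  if (any(!is.na(out$pLI) & (out$pLI < 0 | out$pLI > 1))) {
    abort("pLI must lie in [0, 1]", class = "lr_format_error")
  }
  for (cls in c("syn", "mis", "lof")) {
    oe <- out[[paste0("oe_", cls)]]
    up <- out[[paste0("oe_", cls, "_upper")]]
    if (any(!is.na(oe) & !is.na(up) & oe > up)) {
      abort(paste0("oe_", cls, " exceeds its 90% CI upper bound"),
            class = "lr_format_error")
    }
  }
  out
}

#' Read a burden-test minimum-P table
#'
#' @param path TSV with columns `gene`, `min_p_exome`, `min_p_imputed`
#'   (empty/NA cells mean no test for that source).
#' @return Tibble with one row per gene.
#' @export
read_burden <- function(path) {
  out <- read_simple_tsv(path, c("gene", "min_p_exome", "min_p_imputed"))
  out$min_p_exome <- as.numeric(out$min_p_exome)
  out$min_p_imputed <- as.numeric(out$min_p_imputed)
  for (col in c("min_p_exome", "min_p_imputed")) {
    v <- out[[col]]
    if (any(!is.na(v) & (v <= 0 | v > 1))) {
      abort(paste0(col, " values must lie in (0, 1]"), class = "lr_format_error")
    }
  }
  out
}

#' Read gene flag sets from YAML
#'
#' @param path YAML file with keys `nominated_meta5`, `pd_genes`,
#'   `disease_genes`, each a list of gene symbols.
#' @return A named list of three upper-cased character vectors.
#' @export
read_flags <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("flags file not found: ", path), class = "lr_io_error")
  }
  y <- yaml::read_yaml(path)
  out <- lapply(c(nominated_meta5 = "nominated_meta5", pd_genes = "pd_genes",
                  disease_genes = "disease_genes"), function(k) {
    v <- unlist(y[[k]]) %||% character()
    v <- toupper(as.character(v))
    if (any(!nzchar(v))) {
      abort(paste0("empty gene symbol in flag set ", k), class = "lr_format_error")
    }
    unique(v)
  })
  out
}

#' Read per-gene literature hit counts
#'
#' @param path TSV with columns `gene`, `n_hits_pd`, `n_hits_gene`.
#' @return Tibble of hit counts.
#' @export
read_literature <- function(path) {
  out <- read_simple_tsv(path, c("gene", "n_hits_pd", "n_hits_gene"))
  out$n_hits_pd <- as.integer(out$n_hits_pd)
  out$n_hits_gene <- as.integer(out$n_hits_gene)
  if (any(is.na(out$n_hits_pd) | out$n_hits_pd < 0)) {
    abort("literature hit counts must be non-negative integers",
          class = "lr_input_error")
  }
  out
}

#' Read GWAS-catalog associations
#'
#' @param path TSV with catalog-style columns `SNPS`, `MAPPED_TRAIT`,
#'   `PUBMEDID`.
#' @return Tibble with columns `variant_id`, `trait`, `study_ref`.
#' @export
read_catalog <- function(path) {
  out <- read_simple_tsv(path, c("SNPS", "MAPPED_TRAIT", "PUBMEDID"))
  out <- tibble(variant_id = out$SNPS, trait = out$MAPPED_TRAIT,
                study_ref = as.character(out$PUBMEDID))
  if (any(is.na(out$variant_id) | !nzchar(out$variant_id))) {
    abort("catalog variant ids must be non-empty", class = "lr_format_error")
  }
  out
}

#' Read a coding-variant annotation table
#'
#' CADD scores and allele frequencies are passthrough input columns computed
#' by external annotation pipelines.
#'
#' @param path TSV with columns `SNP`, `GENE`, `HGVS`, `CADD_PHRED`, `AF`.
#' @return Tibble with columns `variant_id`, `gene`, `hgvs`, `cadd`, `af`.
#' @export
read_coding_variants <- function(path) {
  out <- read_simple_tsv(path, c("SNP", "GENE", "HGVS", "CADD_PHRED", "AF"))
  out <- tibble(variant_id = out$SNP, gene = out$GENE, hgvs = out$HGVS,
                cadd = as.numeric(out$CADD_PHRED), af = as.numeric(out$AF))
  if (any(!is.na(out$af) & (out$af < 0 | out$af > 1))) {
    abort("allele frequencies must lie in [0, 1]", class = "lr_format_error")
  }
  out
}

read_simple_tsv <- function(path, required, optional = character()) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "lr_io_error")
  }
  out <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    abort(paste0(basename(path), " missing required column(s): ",
                 paste(missing, collapse = ", ")), class = "lr_format_error")
  }
  out[, c(required, intersect(optional, names(out))), drop = FALSE]
}
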