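#' Evidence column names
#'
#' The twelve binary (0/1/NA) evidence columns summed into the conclusion
#' score, in canonical output order.
#'
#' @return Character vector of column names.
#' @export
evidence_columns <- function() {
  c(
    "brain_expr", "nigra_expr", "dan_expr",
    "qtl_brain", "qtl_blood", "qtl_correl",
    "literature", "variant_intolerant", "burden",
    "nominated_meta5", "pd_gene", "disease_gene"
  )
}

# columns where a missing upstream record is reported as NA rather than 0
na_allowed_columns <- function() {
  c("brain_expr", "nigra_expr", "dan_expr", "qtl_correl",
    "variant_intolerant", "burden")
}

#' Evidence thresholds
#'
#' Cutoffs applied when data sources are mapped to evidence bits.
#'
#' @param tpm_cutoff Mean expression (TPM) a gene must strictly exceed to be
#'   called expressed in a context. Default 5.
#' @param correl_cutoff Magnitude of the GWAS-eQTL Pearson correlation a
#'   locus-compare plot must strictly exceed for the QTL-correl bit. Default 0.3.
#' @param lit_min_hits Minimum number of disease-plus-gene literature hits
#'   (inclusive) for the literature bit. Default 5.
#' @param oe_upper_max Bound the 90% CI upper limit of an observed/expected
#'   constraint ratio must fall strictly below for the variant-intolerant bit.
#'   Default 0.35.
#' @param alpha Significance level Bonferroni-divided by the number of genes
#'   with burden data. Default 0.05.
#' @param min_variants Minimum shared variants for a GWAS-eQTL correlation to
#'   be reported. Default 10; must be at least 3.
#'
#' @return A list of class `lr_thresholds`.
#' @export
#' @examples
#' thresholds(correl_cutoff = 0.5)
thresholds <- function(tpm_cutoff = 5, correl_cutoff = 0.3, lit_min_hits = 5,
                       oe_upper_max = 0.35, alpha = 0.05, min_variants = 10) {
  vals <- list(
    tpm_cutoff = tpm_cutoff, correl_cutoff = correl_cutoff,
    lit_min_hits = lit_min_hits, oe_upper_max = oe_upper_max,
    alpha = alpha, min_variants = min_variants
  )
  bad <- names(vals)[!vapply(vals, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("thresholds must be positive scalars; offending: ",
                 paste(bad, collapse = ", ")), class = "lr_config_error")
  }
  if (vals$correl_cutoff >= 1) {
    abort("`correl_cutoff` must be < 1", class = "lr_config_error")
  }
  if (vals$min_variants < 3) {
    abort("`min_variants` must be >= 3", class = "lr_config_error")
  }
  structure(vals, class = "lr_thresholds")
}

#' Locus partition configuration
#'
#' @param p_threshold Genome-wide significance threshold; variants with
#'   P strictly below it seed loci. Default 5e-8.
#' @param window Half-width (bp) of the extraction window around each lead
#'   variant. Default 1e6 (1 Mb each side).
#' @param merge_gap Maximum edge-to-edge gap (bp, inclusive) at which two
#'   regions are merged. Default 1e5 (100 kb).
#'
#' @return A list of class `lr_partition_config`.
#' @export
partition_config <- function(p_threshold = 5e-8, window = 1e6, merge_gap = 1e5) {
  vals <- list(p_threshold = p_threshold, window = window, merge_gap = merge_gap)
  bad <- names(vals)[!vapply(vals, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("partition_config values must be positive scalars; offending: ",
                 paste(bad, collapse = ", ")), class = "lr_config_error")
  }
  if (vals$p_threshold >= 1) {
    abort("`p_threshold` must be < 1", class = "lr_config_error")
  }
  structure(vals, class = "lr_partition_config")
}

#' Evidence column weights
#'
#' Integer weight (0-4) applied to each evidence column in the conclusion
#' score; 0 removes a column from the sum, 4 quadruples its points.
#'
#' @param ... Named integer overrides, e.g. `literature = 0`, or a single
#'   named list/vector. Unnamed columns keep the default weight of 1.
#'
#' @return Named integer vector over [evidence_columns()], class `lr_weights`.
#' @export
#' @examples
#' weight_config(qtl_correl = 4, literature = 0)
weight_config <- function(...) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) &&
      (is.list(dots[[1]]) || !is.null(names(dots[[1]])))) {
    dots <- as.list(dots[[1]])
  }
  w <- setNames(rep(1L, length(evidence_columns())), evidence_columns())
  if (length(dots) > 0) {
    unknown <- setdiff(names(dots), evidence_columns())
    if (length(unknown) > 0 || is.null(names(dots)) || any(names(dots) == "")) {
      abort(paste0("unknown evidence column(s) in weights: ",
                   paste(unknown, collapse = ", ")), class = "lr_config_error")
    }
    vals <- unlist(dots)
    if (!is.numeric(vals) || any(!is.finite(vals)) ||
        any(vals != as.integer(vals)) || any(vals < 0) || any(vals > 4)) {
      abort("weights must be integers in 0..4", class = "lr_config_error")
    }
    w[names(dots)] <- as.integer(vals)
  }
  structure(w, class = c("lr_weights", "integer"))
}

#' Read a weight configuration from YAML
#'
#' The file maps evidence column names to integer weights in 0-4; columns not
#' mentioned default to 1.
#'
#' @param path Path to a YAML file.
#' @return An `lr_weights` vector.
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("weights file not found: ", path), class = "lr_io_error")
  }
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  weight_config(y)
}

#' @export
print.lr_weights <- function(x, ...) {
  cat("<evidence weights>\n")
  print(setNames(as.integer(x), names(x)))
  invisible(x)
}
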