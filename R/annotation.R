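#' Annotate coding variants with LD to the risk variant
#'
#' Attaches `r2` and `d_prime` versus the locus risk variant to each coding
#' variant found in the panel; coding variants absent from the panel are
#' kept with missing LD fields and a warning. CADD scores and allele
#' frequencies are passthrough input columns.
#'
#' @param risk Risk-variant id (present in the panel).
#' @param coding Coding-variant tibble ([read_coding_variants()]).
#' @param panel A [genotype_panel()].
#' @return `coding` with `r2` and `d_prime` columns, sorted by descending
#'   `r2` (absent-LD rows last).
#' @export
annotate_coding <- function(risk, coding, panel) {
  panel_dosage(panel, risk)  # errors early if risk is absent
  coding <- as_tibble(coding)
  if (nrow(coding) == 0) {
    return(mutate(coding, r2 = numeric(), d_prime = numeric()))
  }
  ld <- purrr::map(coding$variant_id, function(id) {
    if (!id %in% panel$variants$variant_id) {
      return(tibble(r2 = NA_real_, d_prime = NA_real_))
    }
    s <- ld_pair_report(risk, id, panel)
    tibble(r2 = s$r2, d_prime = s$d_prime)
  }) %>% purrr::list_rbind()
  n_absent <- sum(is.na(ld$r2) & !coding$variant_id %in% panel$variants$variant_id)
  if (n_absent > 0) {
    warn(paste0(n_absent, " coding variant(s) absent from panel; ",
                "LD fields left missing"))
  }
  bind_cols(coding, ld) %>%
    arrange(is.na(.data$r2), desc(.data$r2), .data$variant_id)
}

#' Overlap with GWAS-catalog associations
#'
#' Reports catalog variants in strong LD with the risk variant
#' (`r2 > r2_min` and `|D'| > dprime_min`, both strict), i.e. other traits
#' whose published risk signals overlap this locus.
#'
#' @param risk Risk-variant id (present in the panel).
#' @param catalog Catalog tibble ([read_catalog()]).
#' @param panel A [genotype_panel()].
#' @param r2_min Strict r2 bound. Default 0.8.
#' @param dprime_min Strict D' bound. Default 0.9.
#' @return Tibble with one row per (variant, trait): `trait`, `variant_id`,
#'   `study_ref`, `r2`, `d_prime`.
#' @export
catalog_overlap <- function(risk, catalog, panel, r2_min = 0.8,
                            dprime_min = 0.9) {
  panel_dosage(panel, risk)
  catalog <- as_tibble(catalog) %>%
    filter(.data$variant_id %in% panel$variants$variant_id) %>%
    distinct(.data$variant_id, .data$trait, .keep_all = TRUE)
  if (nrow(catalog) == 0) {
    return(tibble(trait = character(), variant_id = character(),
                  study_ref = character(), r2 = numeric(),
                  d_prime = numeric()))
  }
  ld <- purrr::map(unique(catalog$variant_id), function(id) {
    s <- ld_pair_report(risk, id, panel)
    tibble(variant_id = id, r2 = s$r2, d_prime = s$d_prime,
           status = s$status)
  }) %>% purrr::list_rbind()
  catalog %>%
    inner_join(ld, by = "variant_id") %>%
    filter(.data$status == "ok", .data$r2 > r2_min,
           .data$d_prime > dprime_min) %>%
    arrange(desc(.data$r2), .data$variant_id, .data$trait) %>%
    select("trait", "variant_id", "study_ref", "r2", "d_prime")
}
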