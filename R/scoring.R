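#' Weighted conclusion score
#'
#' The conclusion score of a gene is the weighted sum of its evidence bits,
#' `sum_w[col] * bit[col]`, with `NA` bits contributing nothing. With the
#' default unit weights it is simply the number of evidence columns set to
#' 1; weights of 0-4 let a user silence or amplify individual columns.
#'
#' @param rows Tibble (or one row) containing the [evidence_columns()].
#' @param w [weight_config()] (or anything it accepts).
#' @return Numeric vector of scores, one per row, each in
#'   `[0, 4 * length(evidence_columns())]`.
#' @export
#' @examples
#' row <- tibble::tibble(brain_expr = 1, nigra_expr = 1, dan_expr = 1,
#'   qtl_brain = 1, qtl_blood = 1, qtl_correl = 1, literature = 0,
#'   variant_intolerant = NA, burden = NA, nominated_meta5 = 0,
#'   pd_gene = 0, disease_gene = 1)
#' conclusion_score(row)  # 7
conclusion_score <- function(rows, w = weight_config()) {
  if (!inherits(w, "lr_weights")) w <- weight_config(w)
  rows <- as_tibble(rows)
  missing_cols <- setdiff(evidence_columns(), names(rows))
  if (length(missing_cols) > 0) {
    abort(paste0("evidence column(s) missing: ",
                 paste(missing_cols, collapse = ", ")),
          class = "lr_input_error")
  }
  bits <- as.matrix(rows[, evidence_columns(), drop = FALSE])
  storage.mode(bits) <- "numeric"
  if (any(!is.na(bits) & !(bits %in% c(0, 1)))) {
    abort("evidence bits must be 0, 1 or NA", class = "lr_input_error")
  }
  bits[is.na(bits)] <- 0
  as.numeric(bits %*% as.numeric(w[evidence_columns()]))
}

#' Rank genes within a locus
#'
#' Recomputes conclusion scores under the supplied weights and orders genes
#' by descending score, breaking ties by gene symbol.
#'
#' @param rows Evidence tibble for one locus ([assemble_evidence()]).
#' @param w [weight_config()].
#' @return The tibble ordered by rank, with refreshed `conclusion` and a
#'   `rank` column (1 = top candidate).
#' @export
rank_genes <- function(rows, w = weight_config()) {
  if (!inherits(w, "lr_weights")) w <- weight_config(w)
  rows <- as_tibble(rows)
  out <- rows %>%
    mutate(conclusion = conclusion_score(rows, w)) %>%
    arrange(desc(.data$conclusion), .data$gene) %>%
    mutate(rank = row_number())
  class(out) <- c("evidence_table", class(tibble()))
  attr(out, "weights") <- w
  out
}

#' @export
glance.evidence_table <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    top_gene = if (nrow(x)) x$gene[which.max(x$conclusion)] else NA_character_,
    top_score = if (nrow(x)) max(x$conclusion) else NA_real_,
    n_na_bits = sum(is.na(as.matrix(
      as_tibble(x)[, intersect(evidence_columns(), names(x))])))
  )
}

#' @export
print.evidence_table <- function(x, ...) {
  cat("<evidence_table> ", nrow(x), " gene(s)\n", sep = "")
  NextMethod()
}
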