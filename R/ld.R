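#' Pairwise linkage disequilibrium by EM haplotype-frequency estimation
#'
#' Estimates the four two-locus haplotype frequencies from unphased diploid
#' dosage vectors by expectation-maximization, started at linkage
#' equilibrium, and derives the classical LD summaries: the covariance
#' `D = f(AB) - p_A p_B`, its normalization `D' = |D| / D_max` and the
#' squared correlation `r2 = D^2 / (p_A p_a p_B p_b)`. Only the
#' double-heterozygote genotype is phase-ambiguous; all other genotype
#' classes contribute haplotypes deterministically, so in their absence the
#' EM fixed point equals direct haplotype counting. Samples missing either
#' dosage are dropped pairwise.
#'
#' @param ga,gb Alternate-allele dosage vectors in `{0, 1, 2, NA}` of equal
#'   length.
#' @param tol Convergence tolerance on the haplotype-frequency update
#'   (max absolute change). Default 1e-8.
#' @param max_iter Maximum EM iterations. Default 1000.
#'
#' @return An object of class `ld_stats`: haplotype frequencies
#'   (`hap_freqs`, named `AB`, `Ab`, `aB`, `ab`), allele frequencies of the
#'   counted (alternate) allele (`p_a`, `p_b`), `d`, `d_prime`, `r2`, the
#'   per-iteration log-likelihood trace (`loglik`), `n`, `n_iter`,
#'   `converged`, and a `status` of `"ok"`, `"monomorphic"` (LD undefined)
#'   or `"insufficient_data"`.
#' @export
#' @examples
#' em_haplotypes(c(0, 1, 2, 1, 0), c(0, 1, 2, 1, 0))$r2
em_haplotypes <- function(ga, gb, tol = 1e-8, max_iter = 1000) {
  stopifnot(length(ga) == length(gb))
  keep <- !is.na(ga) & !is.na(gb)
  ga <- ga[keep]; gb <- gb[keep]
  n <- length(ga)
  if (n < 2) {
    return(new_ld_stats(status = "insufficient_data", n = n))
  }
  if (var(ga) == 0 || var(gb) == 0) {
    return(new_ld_stats(status = "monomorphic", n = n))
  }

  # deterministic haplotype contributions of the nine genotype classes;
  # only (1,1) is ambiguous between AB/ab and Ab/aB
  n_ab <- 2 * sum(ga == 0 & gb == 0) + sum(ga == 0 & gb == 1) +
    sum(ga == 1 & gb == 0)
  n_aB <- 2 * sum(ga == 0 & gb == 2) + sum(ga == 0 & gb == 1) +
    sum(ga == 1 & gb == 2)
  n_Ab <- 2 * sum(ga == 2 & gb == 0) + sum(ga == 1 & gb == 0) +
    sum(ga == 2 & gb == 1)
  n_AB <- 2 * sum(ga == 2 & gb == 2) + sum(ga == 2 & gb == 1) +
    sum(ga == 1 & gb == 2)
  n_dh <- sum(ga == 1 & gb == 1)

  p_a <- mean(ga) / 2
  p_b <- mean(gb) / 2
  f <- c(AB = p_a * p_b, Ab = p_a * (1 - p_b),
         aB = (1 - p_a) * p_b, ab = (1 - p_a) * (1 - p_b))

  loglik <- pair_loglik(ga, gb, f)
  n_iter <- 0L
  converged <- FALSE
  while (n_iter < max_iter) {
    n_iter <- n_iter + 1L
    cis <- f[["AB"]] * f[["ab"]]
    trans <- f[["Ab"]] * f[["aB"]]
    q <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    f_new <- c(
      AB = (n_AB + q * n_dh) / (2 * n),
      Ab = (n_Ab + (1 - q) * n_dh) / (2 * n),
      aB = (n_aB + (1 - q) * n_dh) / (2 * n),
      ab = (n_ab + q * n_dh) / (2 * n)
    )
    loglik <- c(loglik, pair_loglik(ga, gb, f_new))
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  p_a <- f[["AB"]] + f[["Ab"]]
  p_b <- f[["AB"]] + f[["aB"]]
  d <- f[["AB"]] - p_a * p_b
  d_max <- if (d >= 0) {
    min(p_a * (1 - p_b), (1 - p_a) * p_b)
  } else {
    min(p_a * p_b, (1 - p_a) * (1 - p_b))
  }
  denom <- max(p_a * (1 - p_a) * p_b * (1 - p_b), 1e-12)
  r2 <- min(d^2 / denom, 1)
  d_prime <- if (d_max < 1e-12) 0 else min(abs(d) / d_max, 1)

  new_ld_stats(
    status = "ok", n = n, p_a = p_a, p_b = p_b, hap_freqs = f,
    d = d, d_prime = d_prime, r2 = r2, loglik = loglik,
    n_iter = n_iter, converged = converged
  )
}

pair_loglik <- function(ga, gb, f) {
  # genotype-class probabilities under random union of haplotypes
  prob <- function(i, j) {
    switch(paste(i, j),
      "0 0" = f[["ab"]]^2,
      "0 1" = 2 * f[["ab"]] * f[["aB"]],
      "0 2" = f[["aB"]]^2,
      "1 0" = 2 * f[["ab"]] * f[["Ab"]],
      "1 1" = 2 * (f[["AB"]] * f[["ab"]] + f[["Ab"]] * f[["aB"]]),
      "1 2" = 2 * f[["aB"]] * f[["AB"]],
      "2 0" = f[["Ab"]]^2,
      "2 1" = 2 * f[["Ab"]] * f[["AB"]],
      "2 2" = f[["AB"]]^2
    )
  }
  ll <- 0
  for (i in 0:2) for (j in 0:2) {
    nij <- sum(ga == i & gb == j)
    if (nij > 0) ll <- ll + nij * log(max(prob(i, j), 1e-300))
  }
  ll
}

new_ld_stats <- function(status, n, p_a = NA_real_, p_b = NA_real_,
                         hap_freqs = setNames(rep(NA_real_, 4),
                                              c("AB", "Ab", "aB", "ab")),
                         d = NA_real_, d_prime = NA_real_, r2 = NA_real_,
                         loglik = numeric(), n_iter = 0L, converged = FALSE,
                         id_a = NA_character_, id_b = NA_character_) {
  structure(
    list(id_a = id_a, id_b = id_b, status = status, n = n, p_a = p_a,
         p_b = p_b, hap_freqs = hap_freqs, d = d, d_prime = d_prime,
         r2 = r2, loglik = loglik, n_iter = n_iter, converged = converged),
    class = "ld_stats"
  )
}

#' @export
print.ld_stats <- function(x, ...) {
  cat("<ld_stats> status=", x$status, " n=", x$n, sep = "")
  if (x$status == "ok") {
    cat(sprintf(" r2=%.4f D'=%.4f D=%.5f (EM: %d iter%s)",
                x$r2, x$d_prime, x$d, x$n_iter,
                if (x$converged) ", converged" else ""))
  }
  cat("\n")
  invisible(x)
}

#' @export
tidy.ld_stats <- function(x, ...) {
  tibble(
    id_a = x$id_a, id_b = x$id_b, n = x$n, p_a = x$p_a, p_b = x$p_b,
    d = x$d, d_prime = x$d_prime, r2 = x$r2, n_iter = x$n_iter,
    converged = x$converged, status = x$status
  )
}

#' @export
glance.ld_stats <- function(x, ...) {
  tibble(r2 = x$r2, d_prime = x$d_prime, n = x$n, status = x$status,
         loglik = if (length(x$loglik)) x$loglik[length(x$loglik)] else NA_real_)
}

panel_dosage <- function(panel, id) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!id %in% panel$variants$variant_id) {
    abort(paste0("variant not in panel: ", id), class = "lr_lookup_error")
  }
  panel$dosages[, id]
}

#' LD between two panel variants
#'
#' Symmetric convenience wrapper around [em_haplotypes()] for two variants
#' of a [genotype_panel()].
#'
#' @param a,b Variant ids present in the panel.
#' @param panel A [genotype_panel()].
#' @inheritParams em_haplotypes
#' @return An `ld_stats` object carrying the two ids.
#' @export
ld_pair_report <- function(a, b, panel, tol = 1e-8, max_iter = 1000) {
  out <- em_haplotypes(panel_dosage(panel, a), panel_dosage(panel, b),
                       tol = tol, max_iter = max_iter)
  out$id_a <- a
  out$id_b <- b
  out
}

#' Find proxy variants in high LD with a target
#'
#' Scans panel variants in a region around the target and returns those with
#' `r2` strictly greater than `r2_min`, the rule used to decide whether a
#' locus-compare plot without the risk variant itself is still anchored by a
#' good stand-in.
#'
#' @param target Variant id present in the panel.
#' @param panel A [genotype_panel()].
#' @param region Optional numeric `c(start, end)` in bp; default is
#'   `target position +/- flank` on the target's chromosome.
#' @param r2_min Strict lower bound on r2. Default 0.7.
#' @param flank Half-width of the default region. Default 1 Mb.
#'
#' @return Tibble of proxies (`variant_id`, `chrom`, `pos`, `n`, `p_a`,
#'   `p_b`, `d`, `d_prime`, `r2`), sorted by descending r2 then position;
#'   the target itself is excluded.
#' @export
find_proxies <- function(target, panel, region = NULL, r2_min = 0.7,
                         flank = 1e6) {
  tv <- filter(panel$variants, .data$variant_id == target)
  if (nrow(tv) == 0) {
    abort(paste0("variant not in panel: ", target), class = "lr_lookup_error")
  }
  if (is.null(region)) region <- c(tv$pos - flank, tv$pos + flank)
  cand <- panel$variants %>%
    filter(.data$chrom == tv$chrom,
           .data$pos >= region[1], .data$pos <= region[2],
           .data$variant_id != target)
  stats_tbl <- purrr::map(cand$variant_id, function(id) {
    s <- ld_pair_report(target, id, panel)
    tibble(variant_id = id, n = s$n, p_a = s$p_a, p_b = s$p_b, d = s$d,
           d_prime = s$d_prime, r2 = s$r2, status = s$status)
  }) %>% purrr::list_rbind()
  if (nrow(stats_tbl) == 0) {
    return(tibble(variant_id = character(), chrom = character(),
                  pos = numeric(), n = integer(), p_a = numeric(),
                  p_b = numeric(), d = numeric(), d_prime = numeric(),
                  r2 = numeric()))
  }
  stats_tbl %>%
    left_join(select(cand, "variant_id", "chrom", "pos"), by = "variant_id") %>%
    filter(.data$status == "ok", .data$r2 > r2_min) %>%
    arrange(desc(.data$r2), .data$pos) %>%
    select("variant_id", "chrom", "pos", "n", "p_a", "p_b", "d",
           "d_prime", "r2")
}
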