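#' Build a term contingency table from gene lists
#'
#' For each term, counts study hits (k), study size (n), population hits
#' (K) and population size (N) from a term-to-gene map.  Genes absent from
#' the population are ignored; the study list is intersected with the
#' population.
#'
#' @param study Character vector of study gene ids.
#' @param population Character vector of population (background) gene ids.
#' @param term_map Tibble with columns `term_id`, `gene_id` and optionally
#'   `term_name`.
#' @return Tibble: `term_id` (+ `term_name` if supplied), `study_hits`,
#'   `study_size`, `population_hits`, `population_size`.
#' @export
build_term_table <- function(study, population, term_map) {
  population <- unique(population)
  study <- intersect(unique(study), population)
  tm <- term_map |> filter(.data$gene_id %in% population)
  n <- length(study)
  N <- length(population)
  out <- tm |>
    group_by(term_id) |>
    summarise(
      study_hits = sum(unique(.data$gene_id) %in% study),
      population_hits = dplyr::n_distinct(.data$gene_id),
      .groups = "drop"
    ) |>
    mutate(study_size = n, population_size = N) |>
    select(term_id, study_hits, study_size, population_hits, population_size)
  if ("term_name" %in% names(term_map)) {
    out <- out |>
      left_join(distinct(term_map, term_id, .data$term_name), by = "term_id")
  }
  out
}

#' One-sided Fisher overrepresentation test with BH correction
#'
#' For each term, the enrichment p-value is the upper hypergeometric tail
#' P(X >= k) for X ~ Hypergeom(N, K, n); fold enrichment is (k/n)/(K/N).
#' Benjamini-Hochberg step-up adjustment is applied across all tested
#' terms, and terms with `fdr < alpha` are flagged significant.  Terms
#' with K = 0 and k = 0 are untestable and dropped rather than reported at
#' p = 1, so they do not inflate the number of tests.
#'
#' @param term_table Tibble from [build_term_table()] (columns
#'   `term_id`, `study_hits`, `study_size`, `population_hits`,
#'   `population_size`).
#' @param alpha Significance level on the adjusted p-value, default 0.05.
#' @return Tibble: `term_id`, `study_hits`, `study_size`,
#'   `population_hits`, `population_size`, `fold_enrichment`, `p_value`,
#'   `fdr`, `significant`, sorted by `fdr` then `p_value`.
#' @export
fisher_overrep <- function(term_table, alpha = 0.05) {
  tt <- as_tibble(term_table)
  k <- tt$study_hits
  n <- tt$study_size
  K <- tt$population_hits
  N <- tt$population_size
  if (any(k > n | n > N | k > K | K > N)) {
    abort("term table violates k <= n <= N and k <= K <= N")
  }
  if (any(K == 0 & k > 0)) {
    abort("inconsistent term table: study hits for a term absent from the population")
  }
  keep <- !(K == 0 & k == 0)
  tt <- tt[keep, , drop = FALSE]
  if (nrow(tt) == 0L) {
    return(tt |>
             mutate(fold_enrichment = numeric(0), p_value = numeric(0),
                    fdr = numeric(0), significant = logical(0)))
  }
  k <- tt$study_hits; n <- tt$study_size
  K <- tt$population_hits; N <- tt$population_size
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- (k / n) / (K / N)
  tt |>
    mutate(
      fold_enrichment = fold,
      p_value = p,
      fdr = bh_adjust(p),
      significant = fdr < alpha
    ) |>
    arrange(fdr, p_value, term_id)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment: with p-values sorted ascending, the i-th
#' adjusted value is `min_{j >= i} (p_j * m / j)` clipped at 1, returned in
#' the original order.
#'
#' @param pvalues Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}
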