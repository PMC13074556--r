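#' Filter BLAST hits by identity and alignment length
#'
#' Retains hits with `pident >= min_pident` and `aln_length >= min_length`
#' (inclusive thresholds), optionally restricted to a lineage set.  Row
#' order is preserved; raising either threshold never enlarges the result.
#'
#' @param hits Hit tibble (see [read_blast_hits()]).
#' @param min_pident Minimum percent identity, default 90.
#' @param min_length Minimum alignment length in bp, default 200.
#' @param restrict_to Optional character vector of donor lineages to keep;
#'   `NULL` keeps all.
#' @return The retained hits, in input order.
#' @export
filter_hits <- function(hits, min_pident = 90, min_length = 200,
                        restrict_to = NULL) {
  if (min_pident <= 0 || min_length <= 0) {
    abort("thresholds must be positive")
  }
  keep <- hits$pident >= min_pident & hits$aln_length >= min_length
  if (!is.null(restrict_to)) {
    keep <- keep & hits$donor_lineage %in% restrict_to
  }
  hits[keep, , drop = FALSE]
}

#' Merge same-lineage hits into contiguous blocks
#'
#' Per (contig, lineage), overlapping or abutting hit intervals — or those
#' separated by at most `max_gap` bp — are collapsed into blocks.  Each
#' block keeps the best identity and bit score among its member hits.
#' Coordinates are converted from BLAST 1-based inclusive to 0-based
#' half-open.
#'
#' @param hits Filtered hit tibble.
#' @param max_gap Maximum gap (bp) bridged when collapsing; 0 merges only
#'   true overlaps and abutments.
#' @return Tibble of blocks: `contig`, `start`, `end`, `lineage`,
#'   `best_pident`, `best_bitscore`, `n_hits`, sorted by contig, start,
#'   lineage.  Blocks of one lineage on one contig are pairwise disjoint.
#' @export
merge_lineage_blocks <- function(hits, max_gap = 0) {
  if (nrow(hits) == 0L) {
    return(empty_blocks())
  }
  hits |>
    mutate(.start = qstart - 1, .end = as.numeric(qend)) |>
    arrange(query_contig, donor_lineage, .start, .end) |>
    group_by(contig = query_contig, lineage = donor_lineage) |>
    mutate(.grp = cumsum(c(TRUE, .start[-1] > utils::head(cummax(.end), -1) + max_gap))) |>
    group_by(contig, lineage, .grp) |>
    summarise(
      start = min(.start),
      end = max(.end),
      best_pident = max(pident),
      best_bitscore = max(bitscore),
      n_hits = dplyr::n(),
      .groups = "drop"
    ) |>
    select(contig, start, end, lineage, best_pident, best_bitscore, n_hits) |>
    arrange(contig, start, end, lineage)
}
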