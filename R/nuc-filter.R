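#' Sequential ORF filtering cascade
#'
#' Applies the two decontamination stages that precede orthogroup analysis,
#' in order: (1) remove transposable-element ORFs (`te_flag` with
#' `te_evalue < te_evalue_max`, strict); (2) remove ORFs without a
#' Viridiplantae taxonomic assignment.  A per-stage ledger records
#' input/removed/retained counts; the ledger always conserves totals
#' (`n_in = n_removed + n_out` at each stage, stage 2 applied to stage-1
#' survivors).
#'
#' @param orfs Tibble with columns `orf_id`, `te_flag`, `te_evalue`,
#'   `is_viridiplantae` (others are carried through).
#' @param te_evalue_max Strict e-value cutoff for TE removal, default 0.05.
#' @return List with `retained` (tibble of surviving ORFs) and `ledger`
#'   (tibble: `stage`, `n_in`, `n_removed`, `n_out`).
#' @export
filter_cascade <- function(orfs, te_evalue_max = 0.05) {
  n0 <- nrow(orfs)
  rm1 <- orfs$te_flag & !is.na(orfs$te_evalue) & orfs$te_evalue < te_evalue_max
  if (n0 == 0L) rm1 <- logical(0)
  s1 <- orfs[!rm1, , drop = FALSE]
  rm2 <- !s1$is_viridiplantae
  retained <- s1[!rm2, , drop = FALSE]
  ledger <- tibble(
    stage = c("te_removal", "viridiplantae"),
    n_in = c(n0, nrow(s1)),
    n_removed = c(sum(rm1), sum(rm2)),
    n_out = c(nrow(s1), nrow(retained))
  )
  list(retained = retained, ledger = ledger)
}

#' Select candidate orthogroups for phylogenetic testing
#'
#' An orthogroup is a candidate when (i) at least one of its query-species
#' members has a best protein hit to a host-family taxon with
#' `evalue < evalue_max`, and (ii) it contains at least `min_taxa` distinct
#' taxa (topological informativeness).
#'
#' @param ogs Orthogroup membership tibble: `og_id`, `taxon`, `seq_id`.
#' @param besthits Best-hit tibble: `query_seq`, `subject_taxon`,
#'   `subject_family`, `evalue`; every `query_seq` must appear in `ogs`.
#' @param host_families Host family labels.
#' @param evalue_max Strict best-hit e-value cutoff, default 1e-5.
#' @param min_taxa Minimum distinct taxa per orthogroup, default 4.
#' @return Tibble with one row per orthogroup: `og_id`, `n_taxa`,
#'   `host_besthit`, `selected`, sorted by `og_id`.
#' @export
select_candidate_ogs <- function(ogs, besthits, host_families,
                                 evalue_max = 1e-5, min_taxa = 4) {
  unknown <- setdiff(unique(besthits$query_seq), ogs$seq_id)
  if (length(unknown)) {
    abort(sprintf("best hit for sequence %s absent from orthogroup membership",
                  unknown[1]))
  }
  if (nrow(ogs) == 0L) {
    return(tibble(og_id = character(), n_taxa = integer(),
                  host_besthit = logical(), selected = logical()))
  }
  qualifying <- besthits$query_seq[
    besthits$subject_family %in% host_families & besthits$evalue < evalue_max
  ]
  ogs |>
    group_by(og_id) |>
    summarise(
      n_taxa = n_distinct(taxon),
      host_besthit = any(seq_id %in% qualifying),
      .groups = "drop"
    ) |>
    mutate(selected = host_besthit & n_taxa >= min_taxa) |>
    arrange(og_id)
}
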