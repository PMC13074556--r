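#' End-to-end mitochondrial HGT scan
#'
#' Composes the mitochondrial pipeline: threshold filtering, same-lineage
#' block merging, best-evidence tiling, foreign-region calling, tree-
#' candidate flagging, coverage accounting and (optionally) cross-species
#' conservation screening.  All thresholds default to the detection
#' settings the pipeline was designed around (identity >= 90%, alignment
#' length >= 200 bp, regions > 500 bp, lineage coverage > 60%).
#'
#' @param hits Hit tibble (from [read_blast_hits()] or
#'   [simulate_mosaic()]).
#' @param contig_lengths Tibble `contig`, `length`.
#' @param host_lineages Donor (host) lineage labels.
#' @param native_lineages Native-order label(s), default `"Piperales"`.
#' @param coding Optional coding annotation tibble (`contig`, `start`,
#'   `end`).
#' @param sister_hits Optional conservation hit tibble with a `species`
#'   column (see [conservation_check()]).
#' @param min_pident,min_length Hit filters (inclusive).
#' @param max_gap Block-merge gap tolerance, bp.
#' @param min_region_len Strict region length cutoff, bp.
#' @param join_gap Gap bridged between same-donor runs when calling
#'   regions, bp.
#' @param coverage_threshold Strict per-lineage coverage fraction for tree
#'   candidacy.
#' @param conservation_min_pident,conservation_min_cov Conservation
#'   scoring thresholds.
#' @param incomplete_species Species whose assemblies are flagged
#'   incomplete for conservation scoring.
#' @param out_dir Optional output directory; when given, the tiling,
#'   regions, coverage, conservation table, run summary and a manifest are
#'   written as plain text (BED/TSV/JSON).  Reruns with identical inputs
#'   produce byte-identical files.
#' @return An object of class `mito_scan`: a list with `tiling`, `blocks`,
#'   `regions`, `coverage`, `conservation`, `summary` and `params`.
#' @export
run_mito <- function(hits, contig_lengths, host_lineages,
                     native_lineages = "Piperales",
                     coding = NULL, sister_hits = NULL,
                     min_pident = 90, min_length = 200, max_gap = 0,
                     min_region_len = 500, join_gap = 0,
                     coverage_threshold = 0.60,
                     conservation_min_pident = 90,
                     conservation_min_cov = 0.5,
                     incomplete_species = character(),
                     out_dir = NULL) {
  params <- list(
    host_lineages = host_lineages, native_lineages = native_lineages,
    min_pident = min_pident, min_length = min_length, max_gap = max_gap,
    min_region_len = min_region_len, join_gap = join_gap,
    coverage_threshold = coverage_threshold,
    conservation_min_pident = conservation_min_pident,
    conservation_min_cov = conservation_min_cov,
    incomplete_species = incomplete_species
  )
  fh <- filter_hits(hits, min_pident = min_pident, min_length = min_length)
  blocks <- merge_lineage_blocks(fh, max_gap = max_gap)
  tiling <- tile_genome(blocks, contig_lengths)
  regions <- call_foreign_regions(tiling, host_lineages,
                                  min_region_len = min_region_len,
                                  join_gap = join_gap)
  regions <- flag_tree_candidates(regions, blocks,
                                  coverage_threshold = coverage_threshold)
  coverage <- coverage_summary(tiling, contig_lengths, host_lineages,
                               native_lineages, coding = coding)
  conservation <- if (!is.null(sister_hits)) {
    conservation_check(regions, sister_hits,
                       min_pident = conservation_min_pident,
                       min_cov = conservation_min_cov,
                       incomplete_species = incomplete_species)
  } else {
    NULL
  }
  donor_bp <- regions |>
    group_by(donor_lineage) |>
    summarise(bp = sum(length), .groups = "drop")
  n_shared <- if (!is.null(conservation)) {
    conservation |>
      filter(status == "present") |>
      group_by(species) |>
      summarise(n_shared = n_distinct(region_id), .groups = "drop")
  } else {
    NULL
  }
  summary <- list(
    total_bp = sum(contig_lengths$length),
    n_contigs = nrow(contig_lengths),
    n_hits_in = nrow(hits),
    n_hits_retained = nrow(fh),
    n_foreign_regions = nrow(regions),
    foreign_bp = sum(regions$length),
    bp_per_donor = setNames(as.list(donor_bp$bp), donor_bp$donor_lineage),
    n_tree_candidates = sum(regions$needs_tree),
    n_shared = if (!is.null(n_shared)) {
      setNames(as.list(n_shared$n_shared), n_shared$species)
    } else {
      NULL
    }
  )
  res <- structure(
    list(tiling = tiling, blocks = blocks, regions = regions,
         coverage = coverage, conservation = conservation,
         summary = summary, params = params),
    class = "mito_scan"
  )
  if (!is.null(out_dir)) {
    write_mito_scan(res, out_dir)
  }
  res
}

write_mito_scan <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tiling_bed(res$tiling, file.path(out_dir, "tiling.bed"))
  write_regions_bed(res$regions, file.path(out_dir, "regions.bed"))
  readr::write_tsv(res$regions, file.path(out_dir, "regions.tsv"),
                   progress = FALSE)
  cov <- res$coverage
  readr::write_tsv(cov, file.path(out_dir, "coverage.tsv"), progress = FALSE)
  jsonlite::write_json(
    c(list(total_bp = attr(cov, "total_bp")),
      split(cov$bp, paste0(cov$category,
                           ifelse(is.na(cov$lineage), "", paste0(".", cov$lineage))))),
    file.path(out_dir, "coverage.json"), auto_unbox = TRUE, digits = NA
  )
  if (!is.null(res$conservation)) {
    readr::write_tsv(res$conservation, file.path(out_dir, "conservation.tsv"),
                     progress = FALSE)
  }
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_manifest(res$params, out_dir)
  invisible(out_dir)
}

write_manifest <- function(params, out_dir) {
  manifest <- list(
    config_hash = rlang::hash(params),
    package = "hgtmosaic",
    package_version = as.character(utils::packageVersion("hgtmosaic")),
    parameters = params
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' End-to-end nuclear HGT scan
#'
#' Composes the nuclear pipeline: the sequential ORF filtering cascade,
#' candidate-orthogroup selection, gene-tree classification of the
#' selected orthogroups, donor tallies and (optionally) term
#' overrepresentation on the HGT transcript set against all retained ORFs.
#'
#' @param orfs ORF annotation tibble (see [filter_cascade()]).
#' @param ogs Orthogroup membership tibble: `og_id`, `taxon`, `seq_id`.
#' @param besthits Best-hit tibble (see [select_candidate_ogs()]).
#' @param trees Tibble `og_id`, `newick`; only trees of selected
#'   orthogroups are classified.
#' @param lineage_map Taxon-to-lineage map (see [classify_tree()]); host
#'   families are taken from its `role == "host"` rows.
#' @param query_taxon Taxon label of the query species in `ogs`.
#' @param te_evalue_max,evalue_max,min_taxa,support_min Stage thresholds.
#' @param term_map Optional term-to-gene map for enrichment (`term_id`,
#'   `gene_id`).
#' @param alpha Significance level for enrichment.
#' @param out_dir Optional output directory (ledger, candidates, calls,
#'   donor summary, enrichment, manifest as TSV/JSON).
#' @return An object of class `nuc_scan`: a list with `ledger`,
#'   `retained`, `candidates`, `calls`, `donor_summary`, `enrichment` and
#'   `params`.
#' @export
run_nuclear <- function(orfs, ogs, besthits, trees, lineage_map,
                        query_taxon = "Prosopanche",
                        te_evalue_max = 0.05, evalue_max = 1e-5,
                        min_taxa = 4, support_min = 95,
                        term_map = NULL, alpha = 0.05, out_dir = NULL) {
  params <- list(
    query_taxon = query_taxon, te_evalue_max = te_evalue_max,
    evalue_max = evalue_max, min_taxa = min_taxa, support_min = support_min,
    alpha = alpha
  )
  casc <- filter_cascade(orfs, te_evalue_max = te_evalue_max)
  retained_ids <- casc$retained$orf_id
  ogs2 <- ogs |> filter(taxon != query_taxon | seq_id %in% retained_ids)
  bh2 <- besthits |> filter(query_seq %in% retained_ids)
  host_families <- unique(lineage_map$family[lineage_map$role == "host"])
  candidates <- select_candidate_ogs(ogs2, bh2, host_families,
                                     evalue_max = evalue_max,
                                     min_taxa = min_taxa)
  sel <- candidates$og_id[candidates$selected]
  calls <- classify_trees(trees |> filter(og_id %in% sel), lineage_map,
                          support_min = support_min)
  donor_summary <- summarize_donors(calls)
  enrichment <- NULL
  if (!is.null(term_map)) {
    study <- unique(unlist(calls$query_seqs[calls$verdict == "hgt"]))
    study <- intersect(study, retained_ids)
    if (length(study) > 0L) {
      tt <- build_term_table(study, retained_ids, term_map)
      enrichment <- fisher_overrep(tt, alpha = alpha)
    } else {
      enrichment <- fisher_overrep(
        build_term_table(character(0), retained_ids, term_map)[0, ],
        alpha = alpha
      )
    }
  }
  res <- structure(
    list(ledger = casc$ledger, retained = casc$retained,
         candidates = candidates, calls = calls,
         donor_summary = donor_summary, enrichment = enrichment,
         params = params),
    class = "nuc_scan"
  )
  if (!is.null(out_dir)) {
    write_nuc_scan(res, out_dir)
  }
  res
}

write_nuc_scan <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(res$ledger, file.path(out_dir, "ledger.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$candidates, file.path(out_dir, "candidates.tsv"),
                   progress = FALSE)
  calls_flat <- res$calls |>
    mutate(query_seqs = map_chr(query_seqs, paste, collapse = ","))
  readr::write_tsv(calls_flat, file.path(out_dir, "calls.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$donor_summary, file.path(out_dir, "donor_summary.tsv"),
                   progress = FALSE)
  if (!is.null(res$enrichment)) {
    readr::write_tsv(res$enrichment, file.path(out_dir, "enrichment.tsv"),
                     progress = FALSE)
  }
  write_manifest(res$params, out_dir)
  invisible(out_dir)
}

#' @export
print.mito_scan <- function(x, ...) {
  cat("<mito_scan>\n")
  cat(sprintf("  assembly: %d contigs, %s bp\n", x$summary$n_contigs,
              format(x$summary$total_bp, big.mark = ",")))
  cat(sprintf("  hits: %d in, %d passed thresholds\n",
              x$summary$n_hits_in, x$summary$n_hits_retained))
  cat(sprintf("  foreign regions (> %d bp): %d, %s bp total\n",
              x$params$min_region_len, x$summary$n_foreign_regions,
              format(x$summary$foreign_bp, big.mark = ",")))
  for (d in names(x$summary$bp_per_donor)) {
    cat(sprintf("    %s: %s bp\n", d,
                format(x$summary$bp_per_donor[[d]], big.mark = ",")))
  }
  cat(sprintf("  tree candidates: %d\n", x$summary$n_tree_candidates))
  invisible(x)
}

#' @export
print.nuc_scan <- function(x, ...) {
  cat("<nuc_scan>\n")
  print(as.data.frame(x$ledger), row.names = FALSE)
  cat(sprintf("  candidate orthogroups: %d\n", sum(x$candidates$selected)))
  cat(sprintf("  HGT calls: %d orthogroups\n", sum(x$calls$verdict == "hgt")))
  if (nrow(x$donor_summary)) {
    print(as.data.frame(x$donor_summary), row.names = FALSE)
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy mito_scan
#' @export
tidy.mito_scan <- function(x, ...) {
  x$regions
}

#' @method glance mito_scan
#' @export
glance.mito_scan <- function(x, ...) {
  tibble(
    total_bp = x$summary$total_bp,
    n_contigs = x$summary$n_contigs,
    n_foreign_regions = x$summary$n_foreign_regions,
    foreign_bp = x$summary$foreign_bp,
    n_donors = length(x$summary$bp_per_donor),
    n_tree_candidates = x$summary$n_tree_candidates
  )
}

#' @method tidy nuc_scan
#' @export
tidy.nuc_scan <- function(x, ...) {
  x$calls
}

#' @method glance nuc_scan
#' @export
glance.nuc_scan <- function(x, ...) {
  tibble(
    n_orfs_in = x$ledger$n_in[1],
    n_orfs_retained = x$ledger$n_out[nrow(x$ledger)],
    n_candidate_ogs = sum(x$candidates$selected),
    n_hgt_ogs = sum(x$calls$verdict == "hgt"),
    n_hgt_transcripts = sum(lengths(x$calls$query_seqs[x$calls$verdict == "hgt"])),
    n_donors = nrow(x$donor_summary)
  )
}
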