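#' Call foreign regions from a tiling
#'
#' Foreign regions are maximal runs of tiling segments assigned to one host
#' lineage; runs separated by at most `join_gap` bp are bridged.  Only
#' lineages in `host_lineages` yield regions (the native order never does),
#' and a region must be strictly longer than `min_region_len` bp
#' ("exceeding" the cutoff).
#'
#' @param tiling Segment tibble from [tile_genome()] (or [tile_contig()]).
#' @param host_lineages Character vector of donor (host) lineage labels.
#' @param min_region_len Strict minimum region length in bp, default 500.
#' @param join_gap Maximum gap (bp) bridged between same-donor runs,
#'   default 0.
#' @return Region tibble: `contig`, `start`, `end`, `donor_lineage`,
#'   `length`, `needs_tree` (initialised `NA`, see
#'   [flag_tree_candidates()]), sorted by contig then start.
#' @export
call_foreign_regions <- function(tiling, host_lineages, min_region_len = 500,
                                 join_gap = 0) {
  seg <- tiling |>
    filter(!is.na(lineage), lineage %in% host_lineages)
  if (nrow(seg) == 0L) {
    return(empty_regions())
  }
  seg |>
    group_by(contig, donor_lineage = lineage) |>
    group_modify(function(d, key) merge_iv(d$start, d$end, max_gap = join_gap)) |>
    ungroup() |>
    mutate(length = end - start, needs_tree = NA) |>
    filter(length > min_region_len) |>
    select(contig, start, end, donor_lineage, length, needs_tree) |>
    arrange(contig, start)
}

#' Flag regions needing phylogenetic confirmation
#'
#' A region is flagged for tree reconstruction when hits from at least two
#' distinct lineages each cover more than `coverage_threshold` of its span,
#' where coverage is measured on the merged same-lineage blocks (evaluated
#' independently per lineage).
#'
#' @param regions Region tibble from [call_foreign_regions()].
#' @param blocks Block tibble from [merge_lineage_blocks()] for the same
#'   contig set.
#' @param coverage_threshold Strict coverage fraction each lineage must
#'   exceed, default 0.60.
#' @return `regions` with `needs_tree` set, plus `n_lineages_covering`.
#' @export
flag_tree_candidates <- function(regions, blocks, coverage_threshold = 0.60) {
  if (nrow(regions) == 0L) {
    regions$needs_tree <- logical(0)
    regions$n_lineages_covering <- integer(0)
    return(regions)
  }
  n_cov <- vapply(seq_len(nrow(regions)), function(i) {
    b <- blocks[blocks$contig == regions$contig[i], , drop = FALSE]
    if (nrow(b) == 0L) return(0L)
    span <- regions$end[i] - regions$start[i]
    frac <- vapply(split(b, b$lineage), function(bl) {
      covered_bp(regions$start[i], regions$end[i], bl$start, bl$end) / span
    }, numeric(1))
    sum(frac > coverage_threshold)
  }, integer(1))
  regions |>
    mutate(n_lineages_covering = n_cov, needs_tree = n_cov >= 2L)
}

#' Score conservation of foreign regions in sister species
#'
#' Screens each called region against per-species hit tables obtained by
#' querying the region sequences against a sister species' contigs.  A
#' region is `present` in a species when hits at or above `min_pident`
#' cover at least `min_cov` of its span, `absent` otherwise, and `no_data`
#' when the species' assembly is flagged incomplete and no hits exist —
#' absence in a fragmentary draft is not evidence of a lineage-specific
#' gain.
#'
#' @param regions Region tibble; a `region_id` column is derived as
#'   `contig:start-end` and must match `sister_hits$query_contig`.
#' @param sister_hits Hit tibble with an additional `species` column; query
#'   coordinates are relative to the region sequence (1-based inclusive).
#' @param min_pident Minimum percent identity counted toward coverage.
#' @param min_cov Coverage fraction at which a region is scored present.
#' @param species Full species set to report; defaults to the species seen
#'   in `sister_hits`.
#' @param incomplete_species Species whose assemblies are flagged
#'   incomplete.
#' @return Long tibble: `region_id`, `contig`, `start`, `end`,
#'   `donor_lineage`, `species`, `coverage`, `status`.
#' @export
conservation_check <- function(regions, sister_hits, min_pident = 90,
                               min_cov = 0.5, species = NULL,
                               incomplete_species = character()) {
  species <- species %||% sort(unique(sister_hits$species))
  if (nrow(regions) == 0L || length(species) == 0L) {
    return(tibble(
      region_id = character(), contig = character(), start = numeric(),
      end = numeric(), donor_lineage = character(), species = character(),
      coverage = numeric(), status = character()
    ))
  }
  regions <- regions |>
    mutate(
      region_id = sprintf("%s:%d-%d", contig, as.integer(start), as.integer(end)),
      length = end - start
    )
  good <- sister_hits[sister_hits$pident >= min_pident, , drop = FALSE]
  grid <- tidyr::expand_grid(region_id = regions$region_id, species = species)
  grid <- grid |>
    left_join(regions |> select(region_id, contig, start, end, donor_lineage, length),
              by = "region_id")
  cov <- vapply(seq_len(nrow(grid)), function(i) {
    h <- good[good$species == grid$species[i] &
                good$query_contig == grid$region_id[i], , drop = FALSE]
    if (nrow(h) == 0L) return(0)
    covered_bp(0, grid$length[i], h$qstart - 1, h$qend) / grid$length[i]
  }, numeric(1))
  any_hit <- vapply(seq_len(nrow(grid)), function(i) {
    any(sister_hits$species == grid$species[i] &
          sister_hits$query_contig == grid$region_id[i])
  }, logical(1))
  grid |>
    mutate(
      coverage = cov,
      status = dplyr::case_when(
        coverage >= min_cov ~ "present",
        !any_hit & species %in% incomplete_species ~ "no_data",
        TRUE ~ "absent"
      )
    ) |>
    select(region_id, contig, start, end, donor_lineage, species, coverage, status) |>
    arrange(region_id, species)
}
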