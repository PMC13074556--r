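#' Tile one contig: assign every position to its strongest lineage
#'
#' Builds the non-overlapping tiling at the heart of donor assignment: each
#' position covered by at least one block goes to exactly one lineage — the
#' covering block with the highest best identity, ties broken by higher bit
#' score, then longer block, then lexicographic lineage label (a final
#' deterministic tie-break).  Uncovered positions are emitted as `no_hit`
#' segments, so segments partition `[0, contig_length)` exactly.
#'
#' @param blocks Block tibble from [merge_lineage_blocks()], all on one
#'   contig.
#' @param contig_length Contig length in bp; must be >= the largest block
#'   end.
#' @return Tibble of segments: `contig` (if present in `blocks`), `start`,
#'   `end`, `category` (`assigned`/`no_hit`), `lineage`, `pident`; sorted,
#'   non-overlapping, covering the contig.  Adjacent same-lineage segments
#'   are fused.
#' @export
tile_contig <- function(blocks, contig_length) {
  contig <- if (nrow(blocks) > 0 && "contig" %in% names(blocks)) {
    u <- unique(blocks$contig)
    if (length(u) > 1L) abort("tile_contig expects blocks from a single contig")
    u
  } else {
    NA_character_
  }
  if (nrow(blocks) > 0 && any(blocks$end > contig_length)) {
    abort("block end exceeds contig length")
  }
  if (nrow(blocks) > 0 && any(blocks$start < 0)) {
    abort("block start below 0")
  }
  if (nrow(blocks) == 0L) {
    return(tibble(
      contig = contig, start = 0, end = as.numeric(contig_length),
      category = "no_hit", lineage = NA_character_, pident = NA_real_
    ))
  }
  bp <- sort(unique(c(0, blocks$start, blocks$end, contig_length)))
  n_iv <- length(bp) - 1L
  blen <- blocks$end - blocks$start
  seg_lineage <- character(n_iv)
  seg_pident <- rep(NA_real_, n_iv)
  for (i in seq_len(n_iv)) {
    cov <- which(blocks$start <= bp[i] & blocks$end >= bp[i + 1L])
    if (length(cov) == 0L) {
      seg_lineage[i] <- NA_character_
    } else {
      j <- cov[order(-blocks$best_pident[cov], -blocks$best_bitscore[cov],
                     -blen[cov], blocks$lineage[cov])][1L]
      seg_lineage[i] <- blocks$lineage[j]
      seg_pident[i] <- blocks$best_pident[j]
    }
  }
  segs <- tibble(
    contig = contig, start = bp[-length(bp)], end = bp[-1L],
    category = ifelse(is.na(seg_lineage), "no_hit", "assigned"),
    lineage = seg_lineage, pident = seg_pident
  )
  # fuse adjacent segments with identical lineage assignment
  key <- paste(segs$category, segs$lineage)
  run <- cumsum(c(TRUE, key[-1L] != key[-length(key)]))
  segs |>
    mutate(.grp = run) |>
    group_by(.grp) |>
    summarise(
      contig = contig[1L], start = min(start), end = max(end),
      category = category[1L], lineage = lineage[1L],
      pident = if (all(is.na(pident))) NA_real_ else max(pident, na.rm = TRUE),
      .groups = "drop"
    ) |>
    select(contig, start, end, category, lineage, pident) |>
    arrange(start)
}

#' Tile every contig of an assembly
#'
#' Applies [tile_contig()] to each contig listed in `contig_lengths`,
#' including contigs without any block (tiled entirely as `no_hit`).
#'
#' @param blocks Block tibble from [merge_lineage_blocks()].
#' @param contig_lengths Tibble with columns `contig`, `length`.
#' @return Segment tibble over all contigs, sorted by contig then start.
#' @export
tile_genome <- function(blocks, contig_lengths) {
  unknown <- setdiff(unique(blocks$contig), contig_lengths$contig)
  if (length(unknown)) {
    abort(sprintf("blocks on unknown contig %s", unknown[1]))
  }
  purrr::map_dfr(seq_len(nrow(contig_lengths)), function(i) {
    ctg <- contig_lengths$contig[i]
    b <- blocks[blocks$contig == ctg, , drop = FALSE]
    if (nrow(b) == 0L) {
      b <- empty_blocks()
      b <- b[0, ]
    }
    out <- tile_contig(b, contig_lengths$length[i])
    out$contig <- ctg
    out
  }) |>
    arrange(contig, start)
}
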