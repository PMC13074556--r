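#' Account assembly coverage by genomic origin
#'
#' Partitions every position of the assembly into mutually exclusive
#' categories with precedence coding > host lineage > native order > other
#' angiosperm > no hit, and reports bp totals.  Category totals always sum
#' to the total assembly length.
#'
#' @param tiling Segment tibble from [tile_genome()] covering every contig.
#' @param contig_lengths Tibble with columns `contig`, `length`.
#' @param host_lineages Donor (host) lineage labels.
#' @param native_lineages Label(s) of the vertically inherited order.
#' @param coding Optional coding-region annotation tibble (`contig`,
#'   `start`, `end`, 0-based half-open); positions inside coding intervals
#'   are counted as `coding` regardless of hit assignment.
#' @param donor_breakdown When `TRUE` (default) host bp are reported per
#'   donor lineage; otherwise as a single `host_orders` row.
#' @return Tibble with columns `category`, `lineage` (`NA` outside host
#'   rows), `bp`; the attribute `total_bp` holds the assembly length.
#' @export
coverage_summary <- function(tiling, contig_lengths, host_lineages,
                             native_lineages, coding = NULL,
                             donor_breakdown = TRUE) {
  total_bp <- sum(contig_lengths$length)
  coding <- coding %||% tibble(contig = character(), start = numeric(), end = numeric())
  unknown <- setdiff(unique(coding$contig), contig_lengths$contig)
  if (length(unknown)) {
    abort(sprintf("coding annotation on unknown contig %s", unknown[1]))
  }
  lens <- setNames(contig_lengths$length, contig_lengths$contig)
  if (nrow(coding) > 0 &&
      any(coding$start < 0 | coding$end > lens[coding$contig])) {
    abort("coding annotation outside contig bounds")
  }
  # merged coding intervals per contig
  coding_m <- if (nrow(coding) > 0) {
    coding |>
      group_by(contig) |>
      group_modify(function(d, key) merge_iv(d$start, d$end)) |>
      ungroup()
  } else {
    tibble(contig = character(), start = numeric(), end = numeric())
  }
  coding_bp <- sum(coding_m$end - coding_m$start)

  seg_cat <- dplyr::case_when(
    is.na(tiling$lineage) ~ "no_hit",
    tiling$lineage %in% host_lineages ~ "host_orders",
    tiling$lineage %in% native_lineages ~ "native_order",
    TRUE ~ "other_angiosperms"
  )
  seg_cod <- vapply(seq_len(nrow(tiling)), function(i) {
    cm <- coding_m[coding_m$contig == tiling$contig[i], , drop = FALSE]
    if (nrow(cm) == 0L) return(0)
    sum(pmax(0, pmin(tiling$end[i], cm$end) - pmax(tiling$start[i], cm$start)))
  }, numeric(1))
  net <- (tiling$end - tiling$start) - seg_cod

  df <- tibble(
    category = seg_cat,
    lineage = ifelse(seg_cat == "host_orders", tiling$lineage, NA_character_),
    bp = net
  )
  if (!donor_breakdown) df$lineage <- NA_character_
  out <- df |>
    group_by(category, lineage) |>
    summarise(bp = sum(bp), .groups = "drop")
  out <- bind_rows(
    tibble(category = "coding", lineage = NA_character_, bp = coding_bp),
    out
  ) |>
    filter(bp > 0 | category == "no_hit") |>
    arrange(factor(category, levels = c("coding", "host_orders", "native_order",
                                        "other_angiosperms", "no_hit")),
            lineage)
  attr(out, "total_bp") <- total_bp
  out
}
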