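#' Read a BLAST tabular (outfmt 6) hit file
#'
#' Parses the standard 12-column BLAST tabular format.  An optional 13th
#' column carries the donor lineage (the database each hit came from); when
#' absent, every row is tagged with `lineage`.  Query coordinates are
#' normalised so that `qstart <= qend` (minus-strand hits are flipped; the
#' alignment span is preserved).
#'
#' @param path Path to a tab-separated hit file with at least 12 columns and
#'   no header, in the order qseqid, sseqid, pident, length, mismatch,
#'   gapopen, qstart, qend, sstart, send, evalue, bitscore.
#' @param lineage Donor lineage label applied to rows lacking a 13th column.
#' @return A tibble of hits with one row per alignment, columns
#'   `query_contig`, `subject_id`, `pident`, `aln_length`, `mismatches`,
#'   `gapopen`, `qstart`, `qend`, `sstart`, `send`, `evalue`, `bitscore`,
#'   `donor_lineage`.  Empty files yield a zero-row tibble.
#' @export
read_blast_hits <- function(path, lineage = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_hits())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    abort(sprintf(
      "malformed hit row at line %d: expected >= 12 tab-separated columns, found %d",
      which(nf < 12L)[1L], nf[which(nf < 12L)[1L]]
    ))
  }
  num_idx <- c(3:8, 11:12)
  parse_num <- function(j) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", j)))
    bad <- which(is.na(v))
    if (length(bad)) {
      abort(sprintf("malformed hit row at line %d: column %d is not numeric", bad[1L], j))
    }
    v
  }
  nums <- lapply(num_idx, parse_num)
  names(nums) <- c("pident", "aln_length", "mismatches", "gapopen",
                   "qstart", "qend", "evalue", "bitscore")
  lin <- if (any(nf >= 13L)) {
    vapply(fields, function(f) if (length(f) >= 13L) f[[13L]] else NA_character_, "")
  } else {
    NULL
  }
  if (is.null(lin) && is.null(lineage)) {
    abort("hits lack a 13th lineage column; supply `lineage`")
  }
  hits <- tibble(
    query_contig = vapply(fields, `[[`, "", 1L),
    subject_id = vapply(fields, `[[`, "", 2L),
    pident = nums$pident,
    aln_length = nums$aln_length,
    mismatches = nums$mismatches,
    gapopen = nums$gapopen,
    qstart = pmin(nums$qstart, nums$qend),
    qend = pmax(nums$qstart, nums$qend),
    sstart = as.numeric(vapply(fields, `[[`, "", 9L)),
    send = as.numeric(vapply(fields, `[[`, "", 10L)),
    evalue = nums$evalue,
    bitscore = nums$bitscore,
    donor_lineage = if (is.null(lin)) lineage else dplyr::coalesce(lin, lineage %||% NA_character_)
  )
  hits
}

#' Write hits as BLAST outfmt-6 TSV with a donor-lineage column
#'
#' @param hits Hit tibble as produced by [read_blast_hits()] or
#'   [simulate_mosaic()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_blast_hits <- function(hits, path) {
  out <- hits[, c(
    "query_contig", "subject_id", "pident", "aln_length", "mismatches",
    "gapopen", "qstart", "qend", "sstart", "send", "evalue", "bitscore",
    "donor_lineage"
  )]
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read / write two-column contig length tables
#'
#' @param path TSV with columns contig, length (no header).
#' @return Tibble with columns `contig`, `length`.
#' @export
read_contig_lengths <- function(path) {
  readr::read_tsv(path, col_names = c("contig", "length"),
                  col_types = "cd", progress = FALSE)
}

#' @rdname read_contig_lengths
#' @param contig_lengths Tibble with columns `contig`, `length`.
#' @export
write_contig_lengths <- function(contig_lengths, path) {
  readr::write_tsv(contig_lengths[, c("contig", "length")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write planted-tract truth records as BED6
#'
#' name = donor lineage, score = identity x 10, strand = ".".
#'
#' @param truth Truth tibble from [simulate_mosaic()].
#' @param path Output BED file.
#' @export
write_truth_bed <- function(truth, path) {
  out <- tibble(
    chrom = truth$contig,
    start = as.integer(truth$start),
    end = as.integer(truth$end),
    name = truth$donor_lineage,
    score = as.integer(round(truth$identity * 10)),
    strand = "."
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write a tiling as BED6
#'
#' name = assigned lineage (or `no_hit`), score = percent identity x 10.
#'
#' @param tiling Tiling tibble from [tile_genome()].
#' @param path Output BED file.
#' @export
write_tiling_bed <- function(tiling, path) {
  out <- tibble(
    chrom = tiling$contig,
    start = as.integer(tiling$start),
    end = as.integer(tiling$end),
    name = ifelse(is.na(tiling$lineage), "no_hit", tiling$lineage),
    score = as.integer(round(dplyr::coalesce(tiling$pident, 0) * 10)),
    strand = "."
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write called foreign regions as BED6
#'
#' @param regions Region tibble from [call_foreign_regions()].
#' @param path Output BED file.
#' @export
write_regions_bed <- function(regions, path) {
  out <- tibble(
    chrom = regions$contig,
    start = as.integer(regions$start),
    end = as.integer(regions$end),
    name = regions$donor_lineage,
    score = 0L,
    strand = "."
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a taxon-to-lineage map
#'
#' @param path TSV with header columns taxon, family, order, role; role is
#'   one of query, host, native, outgroup, other.
#' @return Tibble with those columns.
#' @export
read_lineage_map <- function(path) {
  lm <- readr::read_tsv(path, col_types = "cccc", progress = FALSE)
  need <- c("taxon", "family", "order", "role")
  if (!all(need %in% names(lm))) {
    abort("lineage map must have columns taxon, family, order, role")
  }
  lm[, need]
}

#' Read coding-region annotations from BED or GFF3
#'
#' BED coordinates are taken as 0-based half-open; GFF3 as 1-based inclusive
#' and converted.
#'
#' @param path Annotation file ending in .bed, .gff or .gff3.
#' @return Tibble with columns `contig`, `start`, `end` (0-based half-open).
#' @export
read_coding <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    b <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
    tibble(
      contig = b[[1]],
      start = as.numeric(b[[2]]),
      end = as.numeric(b[[3]])
    )
  } else if (ext %in% c("gff", "gff3")) {
    g <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
    if (ncol(g) < 5L) abort("GFF must have >= 5 columns")
    tibble(
      contig = g[[1]],
      start = as.numeric(g[[4]]) - 1,
      end = as.numeric(g[[5]])
    )
  } else {
    abort("unrecognised annotation format; expected .bed, .gff or .gff3")
  }
}
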