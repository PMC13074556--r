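# Interval helpers. All internal coordinates are 0-based half-open; BLAST
# input is converted from 1-based inclusive on read.

# Collapse intervals whose gap is <= max_gap into their union.
merge_iv <- function(start, end, max_gap = 0) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) {
    return(tibble(start = numeric(), end = numeric()))
  }
  o <- order(start, end)
  s <- as.numeric(start[o])
  e <- as.numeric(end[o])
  ecm <- cummax(e)
  new_run <- c(TRUE, s[-1L] > ecm[-length(ecm)] + max_gap)
  grp <- cumsum(new_run)
  tibble(
    start = as.numeric(tapply(s, grp, min)),
    end = as.numeric(tapply(e, grp, max))
  )
}

# Total bp of [s, e) covered by the union of (starts, ends).
covered_bp <- function(s, e, starts, ends) {
  if (length(starts) == 0L) {
    return(0)
  }
  m <- merge_iv(starts, ends)
  sum(pmax(0, pmin(e, m$end) - pmax(s, m$start)))
}

# Uniform integer draw on [lo, hi] from the current RNG stream.
rint <- function(lo, hi) {
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

empty_hits <- function() {
  tibble(
    query_contig = character(), subject_id = character(),
    pident = numeric(), aln_length = numeric(), mismatches = numeric(),
    gapopen = numeric(), qstart = numeric(), qend = numeric(),
    sstart = numeric(), send = numeric(), evalue = numeric(),
    bitscore = numeric(), donor_lineage = character()
  )
}

empty_blocks <- function() {
  tibble(
    contig = character(), start = numeric(), end = numeric(),
    lineage = character(), best_pident = numeric(),
    best_bitscore = numeric(), n_hits = integer()
  )
}

empty_regions <- function() {
  tibble(
    contig = character(), start = numeric(), end = numeric(),
    donor_lineage = character(), length = numeric(), needs_tree = logical()
  )
}
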