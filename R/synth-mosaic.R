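#' Default planted foreign tracts
#'
#' A set of foreign tracts emulating the mosaic structure of a holoparasite
#' mitochondrial assembly: a few dozen kilobase-scale tracts from several
#' host orders, at identities well above the 90% detection floor.
#'
#' @param n Number of tracts.
#' @param donors Donor lineage labels, recycled across tracts.
#' @param length_range Tract length range in bp.
#' @param identities Percent identities, recycled across tracts.
#' @return Tibble with columns `donor_lineage`, `length`, `identity`,
#'   `dropout_prob`.
#' @export
default_planted_tracts <- function(n = 25L,
                                   donors = c("Solanales", "Malvales", "Fabales"),
                                   length_range = c(1000L, 3000L),
                                   identities = c(92, 94, 95, 97, 99)) {
  tibble(
    donor_lineage = rep_len(donors, n),
    length = as.integer(round(seq(length_range[1], length_range[2], length.out = n))),
    identity = rep_len(identities, n),
    dropout_prob = 0
  )
}

#' Configuration for the mosaic-contig simulator
#'
#' Collects and validates every knob of [simulate_mosaic()].  A fixed seed
#' makes the generator byte-identical across runs.  Hit tables are emulated
#' statistically (no sequences are evolved): the detection pipeline consumes
#' hit tables, and direct emission gives exact truth control.
#'
#' @param seed Integer seed driving every random choice.
#' @param n_contigs Number of contigs in the synthetic assembly.
#' @param contig_length_range Integer pair, contig lengths in bp.
#' @param planted_tracts Tibble with columns `donor_lineage`, `length`
#'   (bp), `identity` (percent), `dropout_prob`; optional `contig` and
#'   `start` columns force explicit placement.
#' @param hit_jitter Maximum inward boundary offset per hit, bp.  The union
#'   of a tract's hits always covers at least `length - 2 * hit_jitter` bp.
#' @param decoy_rate Expected decoy hits per kb of contig.
#' @param decoy_identity_range Percent-identity range for low-identity
#'   decoys; must lie below the 90% detection floor.
#' @param fragmentation Maximum number of hits a tract is split into.
#' @param native_lineage Label of the vertically inherited order (decoys may
#'   also be drawn from it).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 7L,
                       n_contigs = 30L,
                       contig_length_range = c(5000L, 20000L),
                       planted_tracts = default_planted_tracts(),
                       hit_jitter = 25L,
                       decoy_rate = 0.5,
                       decoy_identity_range = c(70, 88),
                       fragmentation = 3L,
                       native_lineage = "Piperales") {
  seed <- as.integer(seed)
  if (is.na(seed)) abort("seed must be an integer")
  if (n_contigs < 1L) abort("n_contigs must be >= 1")
  if (length(contig_length_range) != 2L || contig_length_range[1] > contig_length_range[2] ||
      contig_length_range[1] <= 0) {
    abort("contig_length_range must be an ascending positive pair")
  }
  tr <- as_tibble(planted_tracts)
  need <- c("donor_lineage", "length", "identity", "dropout_prob")
  if (nrow(tr) > 0 && !all(need %in% names(tr))) {
    abort("planted_tracts needs columns donor_lineage, length, identity, dropout_prob")
  }
  if (nrow(tr) > 0) {
    if (any(tr$length <= 0)) abort("planted tract lengths must be > 0")
    if (any(tr$identity <= 0 | tr$identity > 100)) abort("tract identity must lie in (0, 100]")
    if (any(tr$dropout_prob < 0 | tr$dropout_prob > 1)) abort("dropout_prob must lie in [0, 1]")
  }
  if (hit_jitter < 0) abort("hit_jitter must be >= 0")
  if (decoy_rate < 0) abort("decoy_rate must be >= 0")
  if (length(decoy_identity_range) != 2L || decoy_identity_range[1] > decoy_identity_range[2]) {
    abort("decoy_identity_range must be an ascending pair")
  }
  if (decoy_identity_range[2] >= 90) {
    abort("decoy_identity_range must stay below the 90% detection floor")
  }
  if (fragmentation < 1L) abort("fragmentation must be >= 1")
  structure(
    list(
      seed = seed, n_contigs = as.integer(n_contigs),
      contig_length_range = as.integer(contig_length_range),
      planted_tracts = tr, hit_jitter = as.integer(hit_jitter),
      decoy_rate = decoy_rate, decoy_identity_range = decoy_identity_range,
      fragmentation = as.integer(fragmentation),
      native_lineage = native_lineage
    ),
    class = "sim_config"
  )
}

#' Simulate a mosaic assembly: hit table, truth records, contig lengths
#'
#' Plants non-overlapping foreign tracts on synthetic contigs and emits the
#' BLAST-style hit table such an assembly would produce: each non-dropped
#' tract is covered by 1..`fragmentation` overlapping hits at exactly its
#' configured identity, with inward boundary jitter of at most `hit_jitter`
#' bp, plus decoy hits that each violate at least one detection threshold
#' (identity < 90 or alignment length < 200).  The random stream is
#' partitioned per contig, so adding contigs never perturbs hits on earlier
#' ones.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `mosaic_sim` with elements `hits` (tibble, one
#'   row per alignment, see [read_blast_hits()] for columns plus a logical
#'   `decoy` column), `truth` (tibble `contig`, `start`, `end`,
#'   `donor_lineage`, `identity`, `dropped`, sorted by contig then start;
#'   coordinates 0-based half-open), `contig_lengths`, and the `config`.
#' @export
simulate_mosaic <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_contigs
  contigs <- sprintf("contig_%03d", seq_len(n))
  lens <- vapply(seq_len(n), function(i) {
    rint(config$contig_length_range[1], config$contig_length_range[2])
  }, integer(1))
  contig_lengths <- tibble(contig = contigs, length = as.numeric(lens))

  placed <- place_tracts(config$planted_tracts, contig_lengths)

  per_contig <- vector("list", n)
  dropped <- rep(FALSE, nrow(placed))
  for (i in seq_len(n)) {
    set.seed((config$seed * 1009L + i) %% 2147483647L)
    idx <- which(placed$contig == contigs[i])
    res <- sim_contig_hits(placed[idx, , drop = FALSE], contigs[i], lens[i], config)
    per_contig[[i]] <- res$hits
    dropped[idx] <- res$dropped
  }
  hits <- bind_rows(empty_hits() |> mutate(decoy = logical(0)), per_contig) |>
    arrange(query_contig, qstart, qend, donor_lineage)

  truth <- placed |>
    mutate(dropped = dropped) |>
    select(contig, start, end, donor_lineage, identity, dropped) |>
    arrange(contig, start)

  structure(
    list(hits = hits, truth = truth, contig_lengths = contig_lengths,
         config = config),
    class = "mosaic_sim"
  )
}

# Assign tracts to contigs without overlap.  Explicit contig/start columns
# are honoured and validated; otherwise tracts are placed largest-first in
# random free gaps, keeping a 150 bp margin between tracts so neighbouring
# tracts never fuse into one called region.
place_tracts <- function(tracts, contig_lengths) {
  empty <- tibble(
    tract_id = integer(), contig = character(), start = numeric(),
    end = numeric(), donor_lineage = character(), identity = numeric(),
    dropout_prob = numeric()
  )
  if (nrow(tracts) == 0L) {
    return(empty)
  }
  tracts <- tracts |> mutate(tract_id = dplyr::row_number())
  explicit <- all(c("contig", "start") %in% names(tracts))
  if (explicit) {
    out <- tracts |>
      mutate(start = as.numeric(start), end = start + length) |>
      select(tract_id, contig, start, end, donor_lineage, identity, dropout_prob)
    lens <- setNames(contig_lengths$length, contig_lengths$contig)
    unknown <- setdiff(out$contig, names(lens))
    if (length(unknown)) abort(sprintf("tract placed on unknown contig %s", unknown[1]))
    too_big <- out$end > lens[out$contig] | out$start < 0
    if (any(too_big)) {
      abort(sprintf("tract %d does not fit on contig %s",
                    out$tract_id[too_big][1], out$contig[too_big][1]))
    }
    by_contig <- split(out, out$contig)
    for (bc in by_contig) {
      bc <- bc[order(bc$start), ]
      if (nrow(bc) > 1 && any(bc$start[-1] < bc$end[-nrow(bc)])) {
        abort(sprintf("overlapping planted tracts on contig %s", bc$contig[1]))
      }
    }
    return(out)
  }
  # free-gap bookkeeping per contig
  free <- lapply(seq_len(nrow(contig_lengths)), function(i) {
    tibble(start = 0, end = contig_lengths$length[i])
  })
  names(free) <- contig_lengths$contig
  ord <- order(-tracts$length, tracts$tract_id)
  out <- vector("list", nrow(tracts))
  margin <- 150
  for (j in ord) {
    L <- tracts$length[j]
    fits <- vapply(free, function(g) any(g$end - g$start >= L), logical(1))
    if (!any(fits)) {
      abort(sprintf("tract %d (%d bp) does not fit on any contig", j, L))
    }
    ctg <- sample(names(free)[fits], 1L)
    g <- free[[ctg]]
    cand <- which(g$end - g$start >= L)
    gi <- cand[sample.int(length(cand), 1L)]
    s <- rint(as.integer(g$start[gi]), as.integer(g$end[gi] - L))
    e <- s + L
    # split the gap, keeping a margin around the placed tract
    left <- tibble(start = g$start[gi], end = max(g$start[gi], s - margin))
    right <- tibble(start = min(g$end[gi], e + margin), end = g$end[gi])
    keep <- bind_rows(left, right) |> filter(end - start > 0)
    free[[ctg]] <- bind_rows(g[-gi, , drop = FALSE], keep)
    out[[j]] <- tibble(
      tract_id = tracts$tract_id[j], contig = ctg, start = as.numeric(s),
      end = as.numeric(e), donor_lineage = tracts$donor_lineage[j],
      identity = tracts$identity[j], dropout_prob = tracts$dropout_prob[j]
    )
  }
  bind_rows(empty, out) |> arrange(tract_id)
}

# Hits for one contig: fragments per planted tract plus decoys, all drawn
# from the contig's private RNG stream.
sim_contig_hits <- function(tracts, contig, contig_len, config) {
  rows <- list()
  dropped <- rep(FALSE, nrow(tracts))
  if (nrow(tracts) > 0) {
    for (j in seq_len(nrow(tracts))) {
      dropped[j] <- runif(1) < tracts$dropout_prob[j]
      if (dropped[j]) next
      rows[[length(rows) + 1L]] <- tract_hits(
        s = tracts$start[j], e = tracts$end[j],
        identity = tracts$identity[j], donor = tracts$donor_lineage[j],
        contig = contig, config = config
      )
    }
  }
  n_dec <- rpois(1, config$decoy_rate * contig_len / 1000)
  if (n_dec > 0) {
    rows[[length(rows) + 1L]] <- decoy_hits(n_dec, contig, contig_len, config)
  }
  hits <- if (length(rows)) {
    bind_rows(rows)
  } else {
    empty_hits() |> mutate(decoy = logical(0))
  }
  list(hits = hits, dropped = dropped)
}

tract_hits <- function(s, e, identity, donor, contig, config) {
  L <- e - s
  k <- sample.int(config$fragmentation, 1L)
  # outer boundaries jittered inward only, so hit union >= L - 2 * jitter
  a0 <- s + if (config$hit_jitter > 0) rint(0L, config$hit_jitter) else 0L
  b0 <- e - if (config$hit_jitter > 0) rint(0L, config$hit_jitter) else 0L
  if (k > 1L) {
    cuts <- s + round(seq_len(k - 1L) * L / k)
    ov <- vapply(seq_len(k - 1L), function(i) rint(5L, 15L), integer(1))
    starts <- c(a0, cuts - ov)
    ends <- c(cuts + ov, b0)
  } else {
    starts <- a0
    ends <- b0
  }
  starts <- pmax(starts, s)
  ends <- pmin(ends, e)
  alen <- ends - starts
  keep <- alen > 0
  starts <- starts[keep]; ends <- ends[keep]; alen <- alen[keep]
  subj <- sprintf("%s_mt_%02d", tolower(donor), rint(1L, 50L))
  tibble(
    query_contig = contig,
    subject_id = subj,
    pident = identity,
    aln_length = as.numeric(alen),
    mismatches = round(alen * (100 - identity) / 100),
    gapopen = 0,
    qstart = as.numeric(starts + 1L),
    qend = as.numeric(ends),
    sstart = 1,
    send = as.numeric(alen),
    evalue = 0,
    bitscore = round(1.9 * alen, 1),
    donor_lineage = donor,
    decoy = FALSE
  )
}

decoy_hits <- function(n_dec, contig, contig_len, config) {
  lineages <- unique(c(config$planted_tracts$donor_lineage, config$native_lineage))
  out <- vector("list", n_dec)
  for (d in seq_len(n_dec)) {
    low_identity <- runif(1) < 0.5
    if (low_identity) {
      alen <- rint(200L, 800L)
      pid <- round(runif(1, config$decoy_identity_range[1],
                         config$decoy_identity_range[2]), 2)
    } else {
      alen <- rint(50L, 199L)
      pid <- round(runif(1, 80, 99), 2)
    }
    alen <- min(alen, contig_len - 1L)
    qs <- rint(0L, as.integer(contig_len - alen))
    lin <- sample(lineages, 1L)
    out[[d]] <- tibble(
      query_contig = contig,
      subject_id = sprintf("%s_mt_%02d", tolower(lin), rint(1L, 50L)),
      pident = pid,
      aln_length = as.numeric(alen),
      mismatches = round(alen * (100 - pid) / 100),
      gapopen = rint(0L, 3L),
      qstart = as.numeric(qs + 1L),
      qend = as.numeric(qs + alen),
      sstart = 1,
      send = as.numeric(alen),
      evalue = signif(10^runif(1, -8, -2), 3),
      bitscore = round(1.2 * alen, 1),
      donor_lineage = lin,
      decoy = TRUE
    )
  }
  bind_rows(out)
}

#' @export
print.mosaic_sim <- function(x, ...) {
  cat("<mosaic_sim>\n")
  cat(sprintf("  contigs: %d (total %s bp)\n",
              nrow(x$contig_lengths), format(sum(x$contig_lengths$length), big.mark = ",")))
  cat(sprintf("  planted tracts: %d (%d dropped)\n",
              nrow(x$truth), sum(x$truth$dropped)))
  cat(sprintf("  hits: %d (%d decoys)\n", nrow(x$hits), sum(x$hits$decoy)))
  invisible(x)
}
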