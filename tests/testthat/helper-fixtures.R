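# Shared fixture builders and independent oracles.

# Quick hit constructor with sensible defaults.
make_hits <- function(contig = "c1", qstart, qend, lineage = "Solanales",
                      pident = 95, bitscore = NULL, aln_length = NULL) {
  n <- max(length(qstart), length(qend), length(lineage), length(pident))
  qstart <- rep_len(qstart, n)
  qend <- rep_len(qend, n)
  lineage <- rep_len(lineage, n)
  pident <- rep_len(pident, n)
  alen <- aln_length %||% (qend - qstart + 1)
  tibble::tibble(
    query_contig = rep_len(contig, n),
    subject_id = sprintf("sub_%d", seq_len(n)),
    pident = pident,
    aln_length = rep_len(alen, n),
    mismatches = 0, gapopen = 0,
    qstart = as.numeric(qstart), qend = as.numeric(qend),
    sstart = 1, send = rep_len(alen, n),
    evalue = 0,
    bitscore = rep_len(bitscore %||% (2 * alen), n),
    donor_lineage = lineage
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Random valid block set on one contig: per-lineage intervals are merged
# with IRanges (independent of the package's own interval code), so the
# block disjointness invariant holds.  Scores are drawn from coarse grids
# so ties exercise the secondary tie-breakers.
random_blocks <- function(seed, contig_len = NULL, max_blocks = 50,
                          lineages = c("Solanales", "Malvales", "Fabales",
                                       "Piperales", "Rosales")) {
  set.seed(seed)
  contig_len <- contig_len %||% sample(2000:20000, 1)
  n_raw <- sample(1:max_blocks, 1)
  start <- sample(0:(contig_len - 100), n_raw, replace = TRUE)
  end <- pmin(start + sample(50:3000, n_raw, replace = TRUE), contig_len)
  lin <- sample(lineages, n_raw, replace = TRUE)
  pieces <- lapply(unique(lin), function(l) {
    ir <- IRanges::reduce(IRanges::IRanges(start = start[lin == l] + 1,
                                           end = end[lin == l]))
    tibble::tibble(contig = "c1",
                   start = as.numeric(IRanges::start(ir) - 1),
                   end = as.numeric(IRanges::end(ir)),
                   lineage = l)
  })
  blocks <- dplyr::bind_rows(pieces)
  blocks$best_pident <- sample(seq(90, 99, by = 0.5), nrow(blocks), replace = TRUE)
  blocks$best_bitscore <- sample(seq(100, 1000, by = 50), nrow(blocks), replace = TRUE)
  blocks$n_hits <- 1L
  list(blocks = blocks[order(blocks$start, blocks$end, blocks$lineage), ],
       contig_len = contig_len)
}

# Per-position winning lineage under the stated priority order
# (pident, bitscore, block length, lexicographic label): iterate blocks
# from worst to best so the best overwrites.
oracle_tile_positions <- function(blocks, contig_len) {
  lineage_at <- rep(NA_character_, contig_len)
  if (nrow(blocks) == 0) {
    return(lineage_at)
  }
  blen <- blocks$end - blocks$start
  ord <- order(-blocks$best_pident, -blocks$best_bitscore, -blen, blocks$lineage)
  for (i in rev(ord)) {
    lineage_at[(blocks$start[i] + 1):blocks$end[i]] <- blocks$lineage[i]
  }
  lineage_at
}

# Expand a tiling to a per-position lineage vector.
tiling_positions <- function(tiling, contig_len) {
  stopifnot(sum(tiling$end - tiling$start) == contig_len)
  rep(tiling$lineage, times = tiling$end - tiling$start)
}

# Explicit hypergeometric upper-tail sum P(X >= k).
hyper_tail <- function(k, n, K, N) {
  i <- k:min(K, n)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Brute-force BH step-up: q_i = min_{j >= i} p_(j) * m / j, original order.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# All-pairs identity graph -> connected components (independent clustering
# oracle for isoform collapse).
oracle_clusters <- function(seqs, threshold) {
  n <- nrow(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) {
        adj[i, j] <- adj[j, i] <-
          global_identity(seqs$sequence[i], seqs$sequence[j]) >= threshold
      }
    }
  }
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {
      cur <- cur + 1L
      queue <- s
      while (length(queue)) {
        v <- queue[1]
        queue <- queue[-1]
        if (comp[v] == 0L) {
          comp[v] <- cur
          queue <- c(queue, which(adj[v, ] & comp == 0L))
        }
      }
    }
  }
  comp
}

# Random DNA string / point-mutated variant.
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

mutate_dna <- function(seq, rate) {
  x <- strsplit(seq, "")[[1]]
  hit <- runif(length(x)) < rate
  x[hit] <- vapply(x[hit], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  paste(x, collapse = "")
}

# Rotate every internal node of a newick tree (children swapped), keeping
# node labels attached.
rotate_all_nodes <- function(newick) {
  phy <- ape::read.tree(text = newick)
  ntip <- length(phy$tip.label)
  for (nd in (ntip + 1):(ntip + phy$Nnode)) {
    phy <- ape::rotate(phy, nd)
  }
  ape::write.tree(phy)
}

default_hosts <- c("Solanales", "Malvales", "Fabales")

empty_blocks_tbl <- function() {
  tibble::tibble(
    contig = character(), start = numeric(), end = numeric(),
    lineage = character(), best_pident = numeric(),
    best_bitscore = numeric(), n_hits = integer()
  )
}
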