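test_that("hit filtering is inclusive at both thresholds and preserves order", {
  hits <- make_hits(qstart = c(1, 1, 1, 1), qend = c(200, 5000, 199, 300),
                    pident = c(90, 89.9, 95, 92))
  out <- filter_hits(hits)
  # pident 90 / length 200 retained; 89.9 dropped despite 5 kb; 199 bp dropped
  expect_equal(out$subject_id, c("sub_1", "sub_4"))
  expect_error(filter_hits(hits, min_pident = 0), "positive")
})

test_that("filtering is monotone in both thresholds and matches the row predicate", {
  set.seed(99)
  hits <- make_hits(qstart = sample(1:5000, 100, TRUE),
                    qend = sample(1:5000, 100, TRUE),
                    pident = runif(100, 80, 100))
  hits <- dplyr::mutate(hits, qs = pmin(qstart, qend), qe = pmax(qstart, qend),
                        qstart = qs, qend = qe,
                        aln_length = qend - qstart + 1)
  for (mp in c(85, 90, 95)) {
    for (ml in c(100, 200, 1000)) {
      got <- nrow(filter_hits(hits, mp, ml))
      want <- sum(hits$pident >= mp & hits$aln_length >= ml)
      expect_equal(got, want)
    }
  }
  base <- nrow(filter_hits(hits, 90, 200))
  expect_lte(nrow(filter_hits(hits, 92, 200)), base)
  expect_lte(nrow(filter_hits(hits, 90, 400)), base)
})

test_that("same-lineage overlapping hits merge; other lineages never do", {
  h <- make_hits(qstart = c(11, 51), qend = c(100, 150))
  b <- merge_lineage_blocks(h)
  expect_equal(nrow(b), 1)
  expect_equal(c(b$start, b$end), c(10, 150))

  h2 <- make_hits(qstart = c(11, 11), qend = c(100, 100),
                  lineage = c("Solanales", "Malvales"))
  b2 <- merge_lineage_blocks(h2)
  expect_equal(nrow(b2), 2)
  expect_setequal(b2$lineage, c("Solanales", "Malvales"))
})

test_that("block statistics are maxima over members; covered bp matches a per-position oracle", {
  set.seed(5)
  for (rep in 1:5) {
    L <- 4000
    n <- 50
    qs <- sample(1:(L - 60), n, TRUE)
    qe <- qs + sample(30:800, n, TRUE)
    qe <- pmin(qe, L)
    h <- make_hits(qstart = qs, qend = qe,
                   lineage = sample(c("Solanales", "Fabales"), n, TRUE),
                   pident = round(runif(n, 90, 100), 1),
                   bitscore = sample(100:900, n, TRUE))
    b <- merge_lineage_blocks(h)
    # per (lineage) covered positions equal the boolean-array union
    for (l in unique(h$donor_lineage)) {
      pos <- rep(FALSE, L)
      hi <- h[h$donor_lineage == l, ]
      for (i in seq_len(nrow(hi))) pos[hi$qstart[i]:hi$qend[i]] <- TRUE
      expect_equal(sum(b$end[b$lineage == l] - b$start[b$lineage == l]), sum(pos))
    }
    # best scores are member maxima
    for (i in seq_len(nrow(b))) {
      memb <- h$donor_lineage == b$lineage[i] &
        h$qstart - 1 >= b$start[i] & h$qend <= b$end[i]
      expect_equal(b$best_pident[i], max(h$pident[memb]))
      expect_equal(b$best_bitscore[i], max(h$bitscore[memb]))
      expect_equal(b$n_hits[i], sum(memb))
    }
  }
})

test_that("gap tolerance bridges blocks separated by at most max_gap", {
  h <- make_hits(qstart = c(1, 151), qend = c(100, 250))
  expect_equal(nrow(merge_lineage_blocks(h, max_gap = 0)), 2)
  expect_equal(nrow(merge_lineage_blocks(h, max_gap = 49)), 2)
  expect_equal(nrow(merge_lineage_blocks(h, max_gap = 50)), 1)
})

test_that("single-block tiling assigns the block and the rest no_hit", {
  b <- tibble::tibble(contig = "c1", start = 0, end = 1000, lineage = "Solanales",
                      best_pident = 95, best_bitscore = 500, n_hits = 1L)
  t <- tile_contig(b, 5000)
  expect_equal(nrow(t), 2)
  expect_equal(t$lineage, c("Solanales", NA))
  expect_equal(t$start, c(0, 1000))
  expect_equal(t$end, c(1000, 5000))
  expect_error(tile_contig(b, 800), "exceeds")
})

test_that("higher identity wins overlaps, with the handover at the overlap boundary", {
  b <- tibble::tibble(
    contig = "c1", start = c(0, 200), end = c(300, 600),
    lineage = c("A", "B"), best_pident = c(95, 92),
    best_bitscore = c(500, 500), n_hits = 1L
  )
  t <- tile_contig(b, 600)
  ta <- t[!is.na(t$lineage) & t$lineage == "A", ]
  tb <- t[!is.na(t$lineage) & t$lineage == "B", ]
  expect_equal(c(ta$start, ta$end), c(0, 300))
  expect_equal(c(tb$start, tb$end), c(300, 600))
})

test_that("tiling equals the per-position argmax oracle on random instances", {
  for (seed in 1:25) {
    rb <- random_blocks(seed)
    t <- tile_contig(rb$blocks, rb$contig_len)
    # structural invariants: sorted, non-overlapping, partition the contig
    expect_true(all(t$start < t$end))
    expect_true(all(diff(t$start) > 0))
    expect_equal(t$start[-1], t$end[-nrow(t)])
    expect_equal(t$start[1], 0)
    expect_equal(t$end[nrow(t)], rb$contig_len)
    expect_identical(tiling_positions(t, rb$contig_len),
                     oracle_tile_positions(rb$blocks, rb$contig_len))
  }
})

test_that("tie-breaking cascades through bitscore, length, then label", {
  base <- tibble::tibble(
    contig = "c1", start = c(0, 0), end = c(100, 200),
    lineage = c("B", "A"), best_pident = c(95, 95),
    best_bitscore = c(600, 500), n_hits = 1L
  )
  t <- tile_contig(base, 200)  # bitscore decides first 100 bp
  expect_equal(t$lineage[1], "B")
  base$best_bitscore <- c(500, 500)
  t <- tile_contig(base, 200)  # longer block decides
  expect_equal(t$lineage[1], "A")
  base$end <- c(100, 100)
  t <- tile_contig(base, 200)  # lexicographic label decides
  expect_equal(t$lineage[1], "A")
})
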