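hosts <- c("Solanales", "Malvales", "Fabales")

test_that("all-native tilings yield no foreign regions", {
  b <- tibble::tibble(contig = "c1", start = 0, end = 3000,
                      lineage = "Piperales", best_pident = 95,
                      best_bitscore = 500, n_hits = 1L)
  t <- tile_contig(b, 5000)
  expect_equal(nrow(call_foreign_regions(t, hosts)), 0)
})

test_that("the region length cutoff is strict: 500 bp excluded, 501 bp included", {
  for (len in c(500, 501)) {
    b <- tibble::tibble(contig = "c1", start = 100, end = 100 + len,
                        lineage = "Solanales", best_pident = 95,
                        best_bitscore = 500, n_hits = 1L)
    t <- tile_contig(b, 2000)
    r <- call_foreign_regions(t, hosts)
    expect_equal(nrow(r), as.integer(len > 500))
  }
})

test_that("join_gap bridges interrupted same-donor runs", {
  b <- tibble::tibble(
    contig = "c1", start = c(0, 700), end = c(600, 1300),
    lineage = "Solanales", best_pident = 95, best_bitscore = 500, n_hits = 1L
  )
  t <- tile_contig(b, 2000)
  expect_equal(nrow(call_foreign_regions(t, hosts, join_gap = 0)), 2)
  joined <- call_foreign_regions(t, hosts, join_gap = 100)
  expect_equal(nrow(joined), 1)
  expect_equal(c(joined$start, joined$end), c(0, 1300))
})

test_that("region calling is invariant to hit order", {
  sim <- simulate_mosaic(sim_config(seed = 21))
  go <- function(h) {
    blocks <- merge_lineage_blocks(filter_hits(h))
    call_foreign_regions(tile_genome(blocks, sim$contig_lengths), hosts)
  }
  r1 <- go(sim$hits)
  set.seed(1)
  r2 <- go(sim$hits[sample(nrow(sim$hits)), ])
  expect_identical(r1, r2)
})

test_that("tree candidacy needs two lineages each above the coverage threshold", {
  reg <- tibble::tibble(contig = "c1", start = 0, end = 1000,
                        donor_lineage = "Solanales", length = 1000,
                        needs_tree = NA)
  one <- tibble::tibble(contig = "c1", start = 0, end = 1000,
                        lineage = "Solanales", best_pident = 95,
                        best_bitscore = 500, n_hits = 1L)
  expect_false(flag_tree_candidates(reg, one)$needs_tree)
  # second lineage at 0.61 coverage -> flagged; at 0.59 -> not
  for (cov in c(0.61, 0.59)) {
    two <- dplyr::bind_rows(one, tibble::tibble(
      contig = "c1", start = 0, end = 1000 * cov, lineage = "Malvales",
      best_pident = 92, best_bitscore = 400, n_hits = 1L
    ))
    expect_equal(flag_tree_candidates(reg, two)$needs_tree, cov > 0.6)
  }
})

test_that("candidate flags equal a per-position coverage-fraction oracle", {
  set.seed(17)
  for (rep in 1:10) {
    rb <- random_blocks(rep + 300, contig_len = 8000)
    t <- tile_contig(rb$blocks, rb$contig_len)
    regs <- call_foreign_regions(t, hosts)
    flagged <- flag_tree_candidates(regs, rb$blocks)
    if (nrow(regs) == 0) next
    for (i in seq_len(nrow(flagged))) {
      span <- flagged$start[i]:(flagged$end[i] - 1)
      n_cov <- 0
      for (l in unique(rb$blocks$lineage)) {
        pos <- rep(FALSE, rb$contig_len)
        bl <- rb$blocks[rb$blocks$lineage == l, ]
        for (j in seq_len(nrow(bl))) pos[(bl$start[j] + 1):bl$end[j]] <- TRUE
        if (mean(pos[span + 1]) > 0.6) n_cov <- n_cov + 1
      }
      expect_equal(flagged$needs_tree[i], n_cov >= 2)
    }
  }
})

test_that("conservation status follows the coverage cutoff, with no_data for flagged drafts", {
  reg <- tibble::tibble(contig = "c1", start = 0, end = 1000,
                        donor_lineage = "Solanales", length = 1000,
                        needs_tree = FALSE)
  rid <- "c1:0-1000"
  mk <- function(cov, species = "P_pang") tibble::tibble(
    species = species, query_contig = rid, pident = 95,
    qstart = 1, qend = cov * 1000
  )
  for (cov in c(0.4, 0.5, 0.6)) {
    out <- conservation_check(reg, mk(cov))
    expect_equal(out$status, if (cov >= 0.5) "present" else "absent")
    expect_equal(out$coverage, cov)
  }
  # hits below the identity floor never count
  low <- mk(0.9)
  low$pident <- 85
  expect_equal(conservation_check(reg, low)$status, "absent")
  # empty table: absent, or no_data when the assembly is flagged incomplete
  empty <- mk(1)[0, ]
  expect_equal(nrow(conservation_check(reg, empty)), 0)
  out <- conservation_check(reg, empty, species = "P_bona",
                            incomplete_species = "P_bona")
  expect_equal(out$status, "no_data")
  out2 <- conservation_check(reg, empty, species = "P_bona")
  expect_equal(out2$status, "absent")
})
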