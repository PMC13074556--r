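hosts <- c("Solanales", "Malvales", "Fabales")

test_that("a trackless simulation reports zero foreign regions", {
  sim <- simulate_mosaic(sim_config(planted_tracts = default_planted_tracts(0)))
  res <- run_mito(sim$hits, sim$contig_lengths, hosts)
  expect_equal(res$summary$n_foreign_regions, 0)
  expect_equal(res$summary$foreign_bp, 0)
})

test_that("run summaries match truth-derived counts on a planted simulation", {
  sim <- simulate_mosaic(sim_config(seed = 7))
  res <- run_mito(sim$hits, sim$contig_lengths, hosts)
  expect_equal(res$summary$n_foreign_regions, nrow(sim$truth))
  # per-donor bp within jitter of the planted totals
  truth_bp <- tapply(sim$truth$end - sim$truth$start, sim$truth$donor_lineage, sum)
  jit <- 2 * sim$config$hit_jitter
  for (d in names(truth_bp)) {
    n_d <- sum(sim$truth$donor_lineage == d)
    expect_lte(abs(res$summary$bp_per_donor[[d]] - truth_bp[[d]]), n_d * jit)
  }
  ev <- evaluate_recovery(res$regions, sim$truth, boundary_tol = jit)
  expect_true(all(ev$recovered))
})

test_that("reruns with the same inputs write byte-identical artifacts", {
  sim <- simulate_mosaic(sim_config(seed = 7))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_mito(sim$hits, sim$contig_lengths, hosts, out_dir = d1)
  run_mito(sim$hits, sim$contig_lengths, hosts, out_dir = d2)
  files <- list.files(d1)
  expect_true(length(files) >= 5)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("an all-vertical tree set yields zero HGT calls and a graceful empty enrichment", {
  tt <- simulate_transcript_tables(200, seed = 5)
  lm <- tree_lineage_map()
  cand <- select_candidate_ogs(tt$ogs, tt$besthits,
                               unique(lm$family[lm$role == "host"]))
  sel <- cand$og_id[cand$selected]
  ts <- simulate_tree_set(n_per_kind = length(sel), kinds = "vertical",
                          seed_start = 900)
  trees <- tibble::tibble(og_id = sel,
                          newick = ts$trees$newick[seq_along(sel)])
  res <- run_nuclear(tt$orfs, tt$ogs, tt$besthits, trees, ts$lineage_map,
                     term_map = tibble::tibble(term_id = "T1",
                                               gene_id = tt$orfs$orf_id[1:20]))
  expect_equal(sum(res$calls$verdict == "hgt"), 0)
  expect_equal(nrow(res$donor_summary), 0)
  expect_equal(nrow(res$enrichment), 0)
})

test_that("nuclear runs tally donors to truth and conserve ORF counts", {
  tt <- simulate_transcript_tables(400, seed = 9)
  lm <- tree_lineage_map()
  # candidate set as the pipeline sees it: after the ORF cascade
  keep <- filter_cascade(tt$orfs)$retained$orf_id
  cand <- select_candidate_ogs(
    dplyr::filter(tt$ogs, taxon != "Prosopanche" | seq_id %in% keep),
    dplyr::filter(tt$besthits, query_seq %in% keep),
    unique(lm$family[lm$role == "host"])
  )
  sel <- cand$og_id[cand$selected]
  ts <- simulate_tree_set(n_per_kind = ceiling(length(sel) / 4),
                          seed_start = 950)
  trees <- dplyr::bind_cols(
    tibble::tibble(og_id = sel),
    ts$trees[seq_along(sel), c("newick", "expected_verdict", "donor_family")]
  )
  res <- run_nuclear(tt$orfs, tt$ogs, tt$besthits,
                     trees[, c("og_id", "newick")], ts$lineage_map)
  # ledger conserves totals
  expect_equal(res$ledger$n_in[1], sum(res$ledger$n_removed) +
                 res$ledger$n_out[nrow(res$ledger)])
  # donor summary equals the truth tally of expected-hgt trees
  truth_tally <- table(trees$donor_family[trees$expected_verdict == "hgt"])
  for (d in names(truth_tally)) {
    expect_equal(res$donor_summary$n_ogs[res$donor_summary$donor_family == d],
                 unname(as.integer(truth_tally[d])))
  }
  expect_equal(sum(res$calls$verdict == "hgt"), sum(truth_tally))
})

test_that("tidy and glance expose regions, calls and one-row overviews", {
  sim <- simulate_mosaic(sim_config(seed = 7))
  res <- run_mito(sim$hits, sim$contig_lengths, hosts)
  expect_identical(tidy(res), res$regions)
  g <- glance(res)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_foreign_regions, nrow(res$regions))
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
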