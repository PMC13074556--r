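spec_map <- tibble::tibble(
  taxon = c("Query", "HostA", "HostB", "Native1", "Native2", "Out1"),
  family = c("Hydnoraceae", "Fabaceae", "Fabaceae", "Hydnoraceae",
             "Hydnoraceae", "Amborellaceae"),
  order = c("Piperales", "Fabales", "Fabales", "Piperales", "Piperales",
            "Amborellales"),
  role = c("query", "host", "host", "native", "native", "outgroup")
)

test_that("a well-supported query sister to the host clade is an HGT call", {
  call <- classify_tree(
    "((Query,(HostA,HostB)99)96,((Native1,Native2)90,Out1));", spec_map
  )
  expect_equal(call$verdict, "hgt")
  expect_equal(call$donor_family, "Fabaceae")
  expect_equal(call$topology_class, "sister")
  expect_equal(call$key_node_support, 96L)
})

test_that("the same topology with key support at or below the threshold is ambiguous", {
  for (s in c(80, 95)) {
    call <- classify_tree(
      sprintf("((Query,(HostA,HostB)99)%d,((Native1,Native2)90,Out1));", s),
      spec_map
    )
    expect_equal(call$verdict, "ambiguous")
    expect_equal(call$key_node_support, s)
  }
  # strictly above the threshold passes
  call <- classify_tree(
    "((Query,(HostA,HostB)99)96,((Native1,Native2)90,Out1));", spec_map,
    support_min = 95
  )
  expect_equal(call$verdict, "hgt")
})

test_that("a query inside the native clade is vertical; inside the host clade is nested HGT", {
  vert <- classify_tree("((Native1,(Query,Native2)99)98,Out1);", spec_map)
  expect_equal(vert$verdict, "vertical")

  nest <- classify_tree(
    "((HostA,(Query,HostB)97)96,((Native1,Native2)90,Out1));", spec_map
  )
  expect_equal(nest$verdict, "hgt")
  expect_equal(nest$topology_class, "nested")
  expect_equal(nest$key_node_support, 97L)
})

test_that("mixed minimal clades and missing outgroups are refused as ambiguous", {
  mixed <- classify_tree(
    "((Query,(HostA,Native1)97)96,((HostB,Native2)90,Out1));", spec_map
  )
  expect_equal(mixed$verdict, "ambiguous")
  expect_equal(mixed$reason, "mixed_clade")

  no_out <- classify_tree(
    "((Query,(HostA,HostB)99)96,(Native1,Native2)90);",
    dplyr::filter(spec_map, taxon != "Out1")
  )
  expect_equal(no_out$verdict, "ambiguous")
  expect_equal(no_out$reason, "no_outgroup")

  expect_error(
    classify_tree("((HostA,(HostB,Native1)99)96,(Native2,Out1));", spec_map),
    "query"
  )
})

test_that("classification is invariant under internal-node rotation", {
  ts <- simulate_tree_set(n_per_kind = 5, seed_start = 500)
  for (i in seq_len(nrow(ts$trees))) {
    a <- classify_tree(ts$trees$newick[i], ts$lineage_map)
    b <- classify_tree(rotate_all_nodes(ts$trees$newick[i]), ts$lineage_map)
    expect_equal(a$verdict, b$verdict)
    expect_equal(a$donor_family, b$donor_family)
    expect_equal(a$key_node_support, b$key_node_support)
  }
})

test_that("no host-family leaves in the tree means no HGT call, ever", {
  nohost_map <- dplyr::filter(spec_map, role != "host")
  trees <- c(
    "((Query,(Native1,Native2)99)98,Out1);",
    "((Native1,(Query,Native2)99)98,Out1);"
  )
  for (nw in trees) {
    expect_false(classify_tree(nw, nohost_map)$verdict == "hgt")
  }
})

test_that("scenario sets are classified to match their truth labels", {
  ts <- simulate_tree_set(n_per_kind = 15, seed_start = 700)
  calls <- classify_trees(ts$trees[, c("og_id", "newick")], ts$lineage_map)
  expect_equal(calls$verdict, ts$trees$expected_verdict)
  hgt <- ts$trees$expected_verdict == "hgt"
  expect_equal(calls$donor_family[hgt], ts$trees$donor_family[hgt])
  expect_equal(calls$topology_class[hgt], ts$trees$expected_topology[hgt])
})

test_that("donor tallies partition HGT calls and their transcripts", {
  expect_equal(nrow(summarize_donors(
    classify_trees(tibble::tibble(og_id = character(), newick = character()),
                   spec_map)
  )), 0)
  calls <- tibble::tibble(
    og_id = sprintf("OG%d", 1:10),
    verdict = c(rep("hgt", 10)),
    donor_family = c(rep("Fabaceae", 5), rep("Solanaceae", 3), rep("Malvaceae", 2)),
    topology_class = "sister", key_node_support = 99L, n_query = 1L,
    query_seqs = as.list(sprintf("t%d", 1:10)), reason = NA_character_
  )
  out <- summarize_donors(calls)
  expect_equal(out$n_ogs, c(5L, 3L, 2L))
  expect_equal(out$prop_ogs, c(0.5, 0.3, 0.2))
  expect_equal(sum(out$prop_transcripts), 1)
  # grouping oracle on a random call set
  set.seed(44)
  calls$donor_family <- sample(c("A", "B", "C"), 10, TRUE)
  out2 <- summarize_donors(calls)
  oracle <- table(calls$donor_family)
  for (d in names(oracle)) {
    expect_equal(out2$n_ogs[out2$donor_family == d], unname(as.integer(oracle[d])))
  }
})
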