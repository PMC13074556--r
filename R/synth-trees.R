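# Gene-tree scenario simulator.  Trees are emitted as newick text with
# integer bootstrap-style labels on internal nodes; branch lengths are
# arbitrary positive values (only topology and support matter to the
# classifier).

family_order <- function(family) {
  known <- c(
    Fabaceae = "Fabales", Solanaceae = "Solanales", Malvaceae = "Malvales",
    Euphorbiaceae = "Malpighiales", Amaranthaceae = "Caryophyllales",
    Hydnoraceae = "Piperales", Amborellaceae = "Amborellales"
  )
  ifelse(family %in% names(known), known[family], paste0(family, "_order"))
}

#' Lineage map for simulated gene trees
#'
#' Builds the taxon -> (family, order, role) table covering every leaf that
#' [simulate_gene_tree()] can emit for the given donor families and clade
#' sizes.  One map serves a whole simulated tree set.
#'
#' @param donor_families Host (donor) family labels.
#' @param n_host_taxa,n_native_taxa,n_outgroup_taxa Maximum clade sizes used.
#' @return Tibble with columns `taxon`, `family`, `order`, `role`.
#' @export
tree_lineage_map <- function(donor_families = c("Fabaceae", "Solanaceae", "Malvaceae"),
                             n_host_taxa = 3L, n_native_taxa = 3L,
                             n_outgroup_taxa = 2L) {
  hosts <- purrr::map_dfr(donor_families, function(f) {
    tibble(
      taxon = sprintf("%s_h%d", f, seq_len(n_host_taxa)),
      family = f, order = unname(family_order(f)), role = "host"
    )
  })
  natives <- tibble(
    taxon = sprintf("Piperales_n%d", seq_len(n_native_taxa)),
    family = "Hydnoraceae", order = "Piperales", role = "native"
  )
  outs <- tibble(
    taxon = sprintf("Outgroup_o%d", seq_len(n_outgroup_taxa)),
    family = "Amborellaceae", order = "Amborellales", role = "outgroup"
  )
  query <- tibble(
    taxon = "Prosopanche_q1", family = "Hydnoraceae", order = "Piperales",
    role = "query"
  )
  bind_rows(query, hosts, natives, outs)
}

bl <- function() sprintf("%.3f", runif(1, 0.02, 0.3))

leaf <- function(name) paste0(name, ":", bl())

join2 <- function(a, b, support) {
  paste0("(", a, ",", b, ")", support, ":", bl())
}

# Random binary topology over pre-rendered parts; internal supports drawn
# from 96..100.
nwk_build <- function(parts) {
  while (length(parts) > 1L) {
    i <- sample.int(length(parts), 2L)
    joined <- join2(parts[i[1]], parts[i[2]], rint(96L, 100L))
    parts <- c(parts[-i], joined)
  }
  parts
}

#' Simulate one labelled gene tree
#'
#' Emits a rooted newick tree with integer support labels under one of five
#' scenarios: `vertical` (the query attaches inside the native clade),
#' `hgt_nested` (query buried inside the host-family clade), `hgt_sister`
#' (query sister to the whole host-family clade), `low_support` (an HGT
#' topology whose key node carries `support_at_key_node`), and
#' `mixed_clade` (the query's minimal clade mixes host and native leaves).
#' The key node is the smallest clade containing the query and a non-query
#' leaf — the node whose support gates an HGT call.
#'
#' @param kind Scenario name.
#' @param seed Integer seed.
#' @param donor_family Host family acting as donor in HGT scenarios.
#' @param n_host_taxa,n_native_taxa,n_outgroup_taxa Clade sizes; HGT
#'   scenarios need `n_host_taxa >= 1` (`hgt_nested` needs >= 2) and every
#'   scenario needs `n_outgroup_taxa >= 1`.
#' @param support_at_key_node Integer 0-100, applied to the key node in the
#'   `low_support` scenario.
#' @return List with `newick` (character), `lineage_map` (tibble), and
#'   `truth` (one-row tibble: `kind`, `truth_label`, `donor_family`,
#'   `expected_verdict`, `expected_topology`, `key_node_support`).
#' @export
simulate_gene_tree <- function(kind = c("vertical", "hgt_nested", "hgt_sister",
                                        "low_support", "mixed_clade"),
                               seed = 0L,
                               donor_family = "Fabaceae",
                               n_host_taxa = 3L,
                               n_native_taxa = 3L,
                               n_outgroup_taxa = 1L,
                               support_at_key_node = 80L) {
  kind <- match.arg(kind)
  if (n_outgroup_taxa < 1L) abort("scenarios require n_outgroup_taxa >= 1")
  if (kind %in% c("hgt_nested", "hgt_sister", "low_support", "mixed_clade") &&
      n_host_taxa < 1L) {
    abort("HGT scenarios require n_host_taxa >= 1")
  }
  if (kind == "hgt_nested" && n_host_taxa < 2L) {
    abort("hgt_nested requires n_host_taxa >= 2")
  }
  if (n_native_taxa < 1L) abort("scenarios require n_native_taxa >= 1")
  if (support_at_key_node < 0 || support_at_key_node > 100) {
    abort("support_at_key_node must lie in 0..100")
  }
  set.seed(as.integer(seed) %% 2147483647L)

  hosts <- sprintf("%s_h%d", donor_family, seq_len(n_host_taxa))
  natives <- sprintf("Piperales_n%d", seq_len(n_native_taxa))
  outs <- sprintf("Outgroup_o%d", seq_len(n_outgroup_taxa))
  q <- "Prosopanche_q1"

  host_leaves <- vapply(sample(hosts), leaf, "")
  native_leaves <- vapply(sample(natives), leaf, "")
  out_part <- nwk_build(vapply(outs, leaf, ""))

  key_support <- if (kind == "low_support") as.integer(support_at_key_node) else rint(96L, 100L)

  inner <- switch(
    kind,
    vertical = {
      qnat <- nwk_build(c(leaf(q), native_leaves))
      join2(qnat, nwk_build(host_leaves), rint(96L, 100L))
    },
    hgt_sister = ,
    low_support = {
      key <- join2(leaf(q), nwk_build(host_leaves), key_support)
      join2(key, nwk_build(native_leaves), rint(96L, 100L))
    },
    hgt_nested = {
      key <- join2(leaf(q), host_leaves[1], key_support)
      hostclade <- nwk_build(c(key, host_leaves[-1]))
      join2(hostclade, nwk_build(native_leaves), rint(96L, 100L))
    },
    mixed_clade = {
      mixpair <- join2(host_leaves[1], native_leaves[1], rint(96L, 100L))
      key <- join2(leaf(q), mixpair, key_support)
      parts <- c(key)
      if (length(native_leaves) > 1L) parts <- c(parts, nwk_build(native_leaves[-1]))
      if (length(host_leaves) > 1L) parts <- c(parts, nwk_build(host_leaves[-1]))
      nwk_build(parts)
    }
  )
  newick <- paste0("(", inner, ",", out_part, ");")

  truth <- tibble(
    kind = kind,
    truth_label = if (kind %in% c("hgt_nested", "hgt_sister", "low_support")) {
      sprintf("HGT(%s)", donor_family)
    } else {
      "vertical"
    },
    donor_family = if (kind %in% c("hgt_nested", "hgt_sister", "low_support")) donor_family else NA_character_,
    expected_verdict = switch(kind,
      vertical = "vertical", hgt_nested = "hgt", hgt_sister = "hgt",
      low_support = "ambiguous", mixed_clade = "ambiguous"
    ),
    expected_topology = switch(kind,
      hgt_nested = "nested", hgt_sister = "sister", low_support = "sister",
      "none"
    ),
    key_node_support = key_support
  )

  list(
    newick = newick,
    lineage_map = tree_lineage_map(donor_family, n_host_taxa, n_native_taxa,
                                   n_outgroup_taxa),
    truth = truth
  )
}

#' Simulate a labelled set of gene trees
#'
#' Generates `n_per_kind` trees per scenario with consecutive seeds starting
#' at `seed_start`, cycling donor families across trees.  All trees share a
#' single lineage map.
#'
#' @inheritParams simulate_gene_tree
#' @param n_per_kind Trees per scenario.
#' @param kinds Scenario names to include.
#' @param seed_start First seed; tree i uses `seed_start + i - 1`.
#' @param donor_families Donor families cycled across trees.
#' @return List with `trees` (tibble: `og_id`, `kind`, `seed`, `newick`,
#'   plus the truth columns of [simulate_gene_tree()]) and `lineage_map`.
#' @export
simulate_tree_set <- function(n_per_kind = 50L,
                              kinds = c("vertical", "hgt_nested", "hgt_sister",
                                        "low_support"),
                              seed_start = 0L,
                              donor_families = c("Fabaceae", "Solanaceae", "Malvaceae"),
                              n_host_taxa = 3L,
                              n_native_taxa = 3L,
                              n_outgroup_taxa = 1L,
                              support_at_key_node = 80L) {
  grid <- tidyr::expand_grid(kind = kinds, rep = seq_len(n_per_kind))
  grid$seed <- seed_start + seq_len(nrow(grid)) - 1L
  grid$donor_family <- rep_len(donor_families, nrow(grid))
  trees <- purrr::pmap(grid, function(kind, rep, seed, donor_family) {
    sim <- simulate_gene_tree(
      kind = kind, seed = seed, donor_family = donor_family,
      n_host_taxa = n_host_taxa, n_native_taxa = n_native_taxa,
      n_outgroup_taxa = n_outgroup_taxa,
      support_at_key_node = support_at_key_node
    )
    bind_cols(tibble(seed = seed, newick = sim$newick), sim$truth)
  })
  trees <- bind_rows(trees) |>
    mutate(og_id = sprintf("OG%04d", dplyr::row_number()), .before = 1)
  list(
    trees = trees,
    lineage_map = tree_lineage_map(donor_families, n_host_taxa, n_native_taxa,
                                   max(n_outgroup_taxa, 2L))
  )
}
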