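#' Classify a gene tree for horizontal transfer
#'
#' Applies the topology-and-support rule for a nuclear HGT call: after
#' rooting on the designated outgroup, each query leaf's minimal clade (the
#' smallest clade containing the query and at least one non-query leaf) is
#' inspected.  If its non-query leaves all belong to a single host family
#' and the clade's node support strictly exceeds `support_min`, the leaf is
#' an HGT call from that family — annotated `sister` when the clade
#' contains every leaf of the family in the tree, `nested` when the query
#' sits inside the family clade.  Non-query leaves all of the native order
#' give `vertical`; mixed composition or insufficient support gives
#' `ambiguous`.  Trees without an outgroup leaf cannot be rooted and are
#' reported `ambiguous` with a reason.  An orthogroup's verdict is `hgt`
#' when at least one query leaf passes.
#'
#' @param newick Newick text (or a `phylo` object) with integer support
#'   labels on internal nodes.
#' @param lineage_map Tibble `taxon`, `family`, `order`, `role` with roles
#'   `query`, `host`, `native`, `outgroup`, `other`.
#' @param support_min Strict support threshold for an HGT call, default 95
#'   (ultrafast bootstrap scale).
#' @param query_prefix Optional label prefix that also marks query leaves.
#' @param og_id Orthogroup identifier carried into the result.
#' @return One-row tibble: `og_id`, `verdict` (`hgt`/`vertical`/
#'   `ambiguous`), `donor_family`, `topology_class` (`nested`/`sister`/
#'   `none`), `key_node_support`, `n_query`, `query_seqs` (list column of
#'   the query leaves supporting the verdict), `reason`.
#' @export
classify_tree <- function(newick, lineage_map, support_min = 95,
                          query_prefix = NULL, og_id = NA_character_) {
  phy <- if (inherits(newick, "phylo")) newick else ape::read.tree(text = newick)
  if (is.null(phy)) abort("could not parse newick text")
  tips <- phy$tip.label
  if (length(tips) < 4L) abort("tree must have at least 4 leaves")
  role <- lineage_map$role[match(tips, lineage_map$taxon)]
  is_query <- (!is.na(role) & role == "query")
  if (!is.null(query_prefix)) {
    is_query <- is_query | startsWith(tips, query_prefix)
  }
  if (!any(is_query)) abort("no query leaf found in tree")
  host_fams <- unique(lineage_map$family[lineage_map$role == "host"])

  result <- function(verdict, donor = NA_character_, topo = "none",
                     support = NA_integer_, qseqs = tips[is_query],
                     reason = NA_character_) {
    tibble(
      og_id = og_id, verdict = verdict, donor_family = donor,
      topology_class = topo, key_node_support = support,
      n_query = sum(is_query), query_seqs = list(qseqs), reason = reason
    )
  }

  og_tips <- tips[!is.na(role) & role == "outgroup"]
  if (length(og_tips) == 0L) {
    return(result("ambiguous", reason = "no_outgroup"))
  }
  # Re-rooting an already outgroup-rooted tree can detach support labels
  # from their clades; only re-root when the outgroup is not yet a child
  # of the root.
  rphy <- if (outgroup_at_root(phy, og_tips)) {
    phy
  } else {
    tryCatch(
      ape::root(phy, outgroup = og_tips, resolve.root = TRUE, edgelabel = TRUE),
      error = function(e) NULL
    )
  }
  if (is.null(rphy)) {
    return(result("ambiguous", reason = "outgroup_not_monophyletic"))
  }

  rtips <- rphy$tip.label
  rrole <- lineage_map$role[match(rtips, lineage_map$taxon)]
  rfam <- lineage_map$family[match(rtips, lineage_map$taxon)]
  r_query <- (!is.na(rrole) & rrole == "query")
  if (!is.null(query_prefix)) {
    r_query <- r_query | startsWith(rtips, query_prefix)
  }
  ntip <- length(rtips)

  classify_leaf <- function(qi) {
    anc <- phangorn::Ancestors(rphy, qi, type = "all")
    clade <- NA_integer_
    others <- integer(0)
    for (node in anc) {
      dtips <- phangorn::Descendants(rphy, node, type = "tips")[[1]]
      others <- setdiff(dtips, which(r_query))
      if (length(others)) {
        clade <- node
        break
      }
    }
    if (is.na(clade)) {
      return(list(verdict = "ambiguous", donor = NA_character_, topo = "none",
                  support = NA_integer_, reason = "no_informative_clade"))
    }
    lab <- rphy$node.label[clade - ntip]
    supp <- suppressWarnings(as.integer(lab))
    ofam <- rfam[others]
    orole <- rrole[others]
    if (!anyNA(ofam) && length(unique(ofam)) == 1L && unique(ofam) %in% host_fams) {
      fam <- unique(ofam)
      if (!is.na(supp) && supp > support_min) {
        all_f <- which(rfam == fam & !r_query)
        topo <- if (setequal(others, all_f)) "sister" else "nested"
        list(verdict = "hgt", donor = fam, topo = topo, support = supp,
             reason = NA_character_)
      } else {
        list(verdict = "ambiguous", donor = fam, topo = "none", support = supp,
             reason = "low_support")
      }
    } else if (!anyNA(orole) && all(orole == "native")) {
      list(verdict = "vertical", donor = NA_character_, topo = "none",
           support = supp, reason = NA_character_)
    } else {
      list(verdict = "ambiguous", donor = NA_character_, topo = "none",
           support = supp, reason = "mixed_clade")
    }
  }

  leaf_calls <- purrr::map(which(r_query), classify_leaf)
  verdicts <- map_chr(leaf_calls, "verdict")
  qnames <- rtips[which(r_query)]
  if (any(verdicts == "hgt")) {
    hi <- which(verdicts == "hgt")
    supp <- vapply(leaf_calls[hi], function(x) as.integer(x$support), integer(1))
    best <- hi[which.max(supp)]
    result("hgt", donor = leaf_calls[[best]]$donor,
           topo = leaf_calls[[best]]$topo,
           support = leaf_calls[[best]]$support,
           qseqs = qnames[hi])
  } else if (any(verdicts == "vertical")) {
    vi <- which(verdicts == "vertical")
    supp <- suppressWarnings(as.integer(leaf_calls[[vi[1]]]$support))
    result("vertical", support = supp, qseqs = qnames[vi])
  } else {
    result("ambiguous",
           support = suppressWarnings(as.integer(leaf_calls[[1]]$support)),
           reason = leaf_calls[[1]]$reason)
  }
}

# TRUE when the outgroup tip set is exactly the tip set of one child of
# the (resolved) root.
outgroup_at_root <- function(phy, og_tips) {
  if (!ape::is.rooted(phy)) {
    return(FALSE)
  }
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  kids <- phy$edge[phy$edge[, 1] == root, 2]
  for (k in kids) {
    kt <- if (k <= ntip) k else phangorn::Descendants(phy, k, type = "tips")[[1]]
    if (setequal(phy$tip.label[kt], og_tips)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Classify a set of gene trees
#'
#' @param trees Tibble with columns `og_id` and `newick`.
#' @inheritParams classify_tree
#' @return Tibble of calls, one row per tree (see [classify_tree()]).
#' @export
classify_trees <- function(trees, lineage_map, support_min = 95,
                           query_prefix = NULL) {
  if (nrow(trees) == 0L) {
    return(classify_tree(
      "((a:1,b:1)99:1,(c:1,d:1)99:1);",
      tibble(taxon = c("a", "b", "c", "d"), family = "f", order = "o",
             role = c("query", "native", "native", "outgroup"))
    )[0, ])
  }
  purrr::map_dfr(seq_len(nrow(trees)), function(i) {
    classify_tree(trees$newick[i], lineage_map, support_min = support_min,
                  query_prefix = query_prefix, og_id = trees$og_id[i])
  })
}

#' Tally HGT calls by donor family
#'
#' Partitions the `hgt` calls by donor family, counting orthogroups and
#' individual query transcripts; proportions sum to 1 over donors.  Calls
#' are de-duplicated by `og_id` before tallying.
#'
#' @param calls Call tibble from [classify_trees()].
#' @return Tibble: `donor_family`, `n_ogs`, `n_transcripts`, `prop_ogs`,
#'   `prop_transcripts`, sorted by descending `n_ogs`.
#' @export
summarize_donors <- function(calls) {
  hgt <- calls |>
    distinct(og_id, .keep_all = TRUE) |>
    filter(verdict == "hgt")
  if (nrow(hgt) == 0L) {
    return(tibble(donor_family = character(), n_ogs = integer(),
                  n_transcripts = integer(), prop_ogs = numeric(),
                  prop_transcripts = numeric()))
  }
  hgt |>
    group_by(donor_family) |>
    summarise(
      n_ogs = n_distinct(og_id),
      n_transcripts = sum(lengths(query_seqs)),
      .groups = "drop"
    ) |>
    mutate(
      prop_ogs = n_ogs / sum(n_ogs),
      prop_transcripts = n_transcripts / sum(n_transcripts)
    ) |>
    arrange(desc(n_ogs), donor_family)
}
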