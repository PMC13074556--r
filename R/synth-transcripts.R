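#' Simulate transcript annotation tables for the filtering cascade
#'
#' Emits the per-ORF annotation tables the nuclear HGT cascade consumes —
#' transposable-element flags, taxonomic assignments, best-hit records and
#' orthogroup membership — together with truth flags that make the expected
#' count after every filter exactly computable by set arithmetic.
#'
#' TE and non-plant status are drawn independently; flagged TEs receive an
#' e-value drawn below the 0.05 removal threshold so the truth flag and the
#' filter predicate coincide.
#'
#' @param n_orfs Number of open reading frames.
#' @param te_frac Probability an ORF is flagged as a transposable element.
#' @param nonplant_frac Probability an ORF lacks a Viridiplantae assignment.
#' @param host_besthit_frac Probability an ORF's best protein hit is to a
#'   host-family taxon.
#' @param seed Integer seed.
#' @param host_families Host family labels used for best hits.
#' @param query_taxon Taxon label of the query species in the orthogroup
#'   table.
#' @param n_ogs Number of orthogroups; defaults to about one per five ORFs.
#' @return List of tibbles: `orfs` (orf_id, length, te_flag, te_evalue,
#'   tax_assignment, is_viridiplantae), `besthits` (query_seq,
#'   subject_taxon, subject_family, evalue), `ogs` (og_id, taxon, seq_id),
#'   and `truth` (orf_id, is_te, is_plant, host_besthit).
#' @export
simulate_transcript_tables <- function(n_orfs,
                                       te_frac = 0.08,
                                       nonplant_frac = 0.12,
                                       host_besthit_frac = 0.3,
                                       seed = 3L,
                                       host_families = c("Fabaceae", "Solanaceae", "Malvaceae"),
                                       query_taxon = "Prosopanche",
                                       n_ogs = NULL) {
  fracs <- c(te_frac, nonplant_frac, host_besthit_frac)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1]")
  if (n_orfs < 0) abort("n_orfs must be >= 0")
  if (n_orfs == 0L) {
    return(list(
      orfs = tibble(orf_id = character(), length = numeric(),
                    te_flag = logical(), te_evalue = numeric(),
                    tax_assignment = character(), is_viridiplantae = logical()),
      besthits = tibble(query_seq = character(), subject_taxon = character(),
                        subject_family = character(), evalue = numeric()),
      ogs = tibble(og_id = character(), taxon = character(), seq_id = character()),
      truth = tibble(orf_id = character(), is_te = logical(),
                     is_plant = logical(), host_besthit = logical())
    ))
  }
  set.seed(as.integer(seed))
  n_ogs <- n_ogs %||% max(1L, n_orfs %/% 5L)
  orf_id <- sprintf("ORF_%05d", seq_len(n_orfs))

  is_te <- runif(n_orfs) < te_frac
  te_evalue <- ifelse(is_te, signif(runif(n_orfs, 1e-6, 0.049), 3), NA_real_)
  is_plant <- runif(n_orfs) >= nonplant_frac
  tax <- ifelse(is_plant, "Viridiplantae",
                sample(c("Fungi", "Metazoa", "Bacteria"), n_orfs, replace = TRUE))

  orfs <- tibble(
    orf_id = orf_id,
    length = as.numeric(sample(300:3000, n_orfs, replace = TRUE)),
    te_flag = is_te,
    te_evalue = te_evalue,
    tax_assignment = tax,
    is_viridiplantae = is_plant
  )

  host_best <- runif(n_orfs) < host_besthit_frac
  fam <- ifelse(host_best,
                sample(host_families, n_orfs, replace = TRUE),
                sample(c("Piperaceae", "Poaceae", "Rosaceae"), n_orfs, replace = TRUE))
  besthits <- tibble(
    query_seq = orf_id,
    subject_taxon = paste0(fam, "_sp", sample(1:9, n_orfs, replace = TRUE)),
    subject_family = fam,
    evalue = 10^runif(n_orfs, -40, -6)
  )

  og_of <- sprintf("OG%05d", sample.int(n_ogs, n_orfs, replace = TRUE))
  ogs_query <- tibble(og_id = og_of, taxon = query_taxon, seq_id = orf_id)
  ref_taxa <- sprintf("RefSpecies_%02d", 1:20)
  ogs_other <- purrr::map_dfr(sort(unique(og_of)), function(og) {
    n_extra <- rint(0L, 8L)
    if (n_extra == 0L) {
      return(tibble(og_id = character(), taxon = character(), seq_id = character()))
    }
    taxa <- sample(ref_taxa, n_extra)
    tibble(og_id = og, taxon = taxa,
           seq_id = paste0(taxa, "_", og, "_g1"))
  })
  ogs <- bind_rows(ogs_query, ogs_other) |> arrange(og_id, taxon, seq_id)

  list(
    orfs = orfs,
    besthits = besthits,
    ogs = ogs,
    truth = tibble(orf_id = orf_id, is_te = is_te, is_plant = is_plant,
                   host_besthit = host_best)
  )
}
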