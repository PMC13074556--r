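---
title: "Detecting horizontal gene transfer footprints with hgtmosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting horizontal gene transfer footprints with hgtmosaic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgtmosaic)
```

## The problem

Parasitic plants exchange macromolecules with their hosts through the
haustorium, and over evolutionary time this contact leaves foreign DNA in
the parasite's mitochondrial and nuclear genomes. Detecting those
footprints is a two-sided inference problem. On the mitochondrial side,
intergenic regions of a draft assembly must be attributed to a donor
lineage from similarity searches against per-lineage databases — but hits
from different lineages overlap, and a principled, reproducible rule is
needed to decide which lineage "owns" each position. On the nuclear side,
a transcriptome contains tens of thousands of ORFs of which only a handful
are horizontally acquired; the signal must survive decontamination,
orthogroup-level screening, and finally a phylogenetic test on gene-tree
topology and support.

`hgtmosaic` implements the decision logic between the standard tools: it
consumes BLAST tabular output, orthogroup membership and best-hit tables,
and newick gene trees with support values, and produces donor-resolved
calls. Sequence search, alignment, and tree inference themselves are
delegated to the usual external tools.

## The mitochondrial model: blocks, tiling, regions

All internal coordinates are 0-based half-open; BLAST's 1-based inclusive
query coordinates are converted on read, and BED output is 0-based
half-open again. This makes interval arithmetic (unions, gaps,
intersections) exact and free of off-by-one ambiguity.

The pipeline has four stages:

1. **Filtering** (`filter_hits()`). Hits are retained at percent identity
   ≥ 90 and alignment length ≥ 200 bp. Both thresholds are inclusive:
   where the source conventions could be read either as ≥ or >, the
   methods-style reading (≥) wins, and both knobs are configurable. The
   filter is monotone — raising either threshold can only shrink the
   retained set — which the test suite checks as a property.

2. **Block merging** (`merge_lineage_blocks()`). Per contig and per donor
   lineage, overlapping or abutting hit intervals are collapsed into
   blocks; each block carries the best identity and bit score among its
   member hits. The gap tolerance `max_gap` defaults to 0 (merge only true
   overlaps and abutments): "contiguous" is taken literally, and a caller
   who wants to bridge small unaligned gaps can say so explicitly.

3. **Tiling** (`tile_contig()`). Where blocks from different lineages
   overlap, each position is assigned to the block with the highest
   identity; ties fall through to higher bit score, then longer block,
   then lexicographic lineage label. The label comparison is not
   biologically meaningful — it exists purely to make the tiling a total,
   deterministic function of its input, so that two runs (or two machines)
   can never disagree. The tiling partitions `[0, contig_length)` exactly:
   unassigned positions are explicit `no_hit` segments, and the segment
   lengths always sum to the contig length.

4. **Region calling** (`call_foreign_regions()`). Maximal same-donor runs
   become foreign regions when they are *strictly* longer than 500 bp
   ("exceeding" is read literally as >). Only host lineages yield regions;
   the native order never does, by construction. Regions where at least
   two lineages each cover more than 60% of the span (measured on the
   merged blocks, evaluated independently per lineage) are flagged
   `needs_tree`: for these, similarity alone cannot settle the donor and a
   phylogenetic tree is warranted. Tree inference itself is out of scope,
   but the resulting trees can be fed to `classify_tree()`.

Coverage accounting (`coverage_summary()`) assigns every position one
category with precedence coding > host order > native order > other
angiosperms > no hit. Precedence (rather than a union) is a design choice:
it makes the categories mutually exclusive, so the donut-style totals are
additive and always sum to the assembly length — an invariant the tests
enforce on every run.

Conservation screening (`conservation_check()`) asks whether each called
region is present in a sister species' assembly: present when hits at ≥ 90%
identity cover ≥ 0.5 of the region. The 0.5 coverage point is the
package's own default — there is no community-standard criterion for
"present in a fragmentary draft" — and the `incomplete_species` flag lets
absence in a known-incomplete assembly be reported as `no_data` rather
than `absent`, since missing contigs are not evidence of a missing region.

## The nuclear model: cascade, candidates, tree test

`filter_cascade()` applies two stages in order: transposable-element
removal (flagged ORFs with e-value strictly below 0.05) and then taxonomy
(ORFs without a Viridiplantae assignment are discarded). The ledger
records input/removed/retained counts per stage and conserves totals
exactly; this is the pipeline's audit trail.

`select_candidate_ogs()` keeps orthogroups where at least one query-species
member has its best protein hit against a host-family taxon at e-value
strictly below 1e-5, and where at least four distinct taxa are present —
fewer taxa cannot produce an informative rooted topology.

`collapse_isoforms()` removes assembly redundancy by greedy, length-first
clustering at 0.95 global identity, with the founder (longest member) as
representative. Identity is computed from a global pairwise alignment
(matches over alignment columns); fast word-filter heuristics of dedicated
clustering tools are deliberately not replicated, since input sets at this
stage are small. Near the threshold the greedy order can differ from an
all-pairs clustering; the tests therefore validate on sets built with a
clear margin (within-cluster identity well above, between-cluster well
below the cutoff).

`classify_tree()` is the HGT decision rule. Trees are rooted on the
designated outgroup leaves (outgroup rooting is the defensible default
when the inference tool emits unrooted trees; a tree already rooted on its
outgroup is left untouched, because re-rooting can detach support labels
from their clades). For each query leaf the classifier walks to the
smallest clade containing the query and at least one non-query leaf:

* non-query leaves all in one host family, support strictly > 95 → **hgt**,
  with the family as donor;
* non-query leaves all of the native order → **vertical**;
* mixed composition, or support ≤ 95, or no outgroup present →
  **ambiguous** (with a machine-readable reason).

"Sister" versus "nested" placement is annotated — sister when the clade
contains every leaf of the donor family in the tree, nested when the query
sits inside the family clade — but both satisfy the same call criterion,
so the subtype never changes the verdict. The "basal node of the clade"
whose support gates the call is taken to be the minimal clade's own node;
this is a definitional choice (the alternative — the node joining the
query to the family's full clade — coincides with it in the sister case).
With several query leaves in one tree, each is classified independently
and the orthogroup is `hgt` if any leaf passes, which supports counting
both orthogroups and individual transcripts per donor
(`summarize_donors()`).

## Enrichment

`fisher_overrep()` computes the one-sided enrichment p-value as the upper
hypergeometric tail P(X ≥ k) — the directional test appropriate for
overrepresentation — with Benjamini–Hochberg step-up adjustment across
terms and significance at FDR < 0.05. Terms with zero population hits are
untestable and are dropped rather than reported at p = 1, so they do not
inflate the number of tests. The implementation rests on R's
hypergeometric tail and `p.adjust`; the test suite pins both to explicit
closed-form oracles (the binomial-coefficient tail sum at 1e-10, and the
brute-force min-over-suffix step-up formula).

## What the synthetic generators emulate — and what they do not

The generators exist so that every stage can be validated against known
truth, at desk scale, with no external downloads.

`simulate_mosaic()` emulates the *hit structure* of a mosaic assembly, not
its sequences: tracts are planted with exact coordinates, each non-dropped
tract emits 1–3 overlapping hits at exactly its configured identity with
inward boundary jitter of at most `hit_jitter` bp (so the hit union covers
at least `length − 2·jitter`), and decoys are constructed to violate at
least one detection threshold. The default configuration — 30 contigs of
5–20 kb, 25 tracts of 1–3 kb from three host orders at identities 92–99%,
jitter 25 bp, 0.5 decoys/kb below 90% identity — is the package's standing
validation condition, chosen once to resemble a draft holoparasite
mitochondrial assembly. The random stream is partitioned per contig, so
enlarging the assembly never perturbs hits on existing contigs (tract
*placement* uses the master stream and does depend on the contig count).

What it does not emulate: sequence-level evolution, indels, repeat
structure, chimeric assembly artefacts, or alignment-score noise. Passing
the recovery test therefore shows that the interval logic — filtering,
merging, conflict resolution, tiling, calling — is correct under realistic
hit geometry; it does not certify performance on real alignments, where
identity estimates wobble and hit boundaries depend on the aligner.

`simulate_gene_tree()` builds newick trees by construction for five
scenarios (vertical, nested HGT, sister HGT, low-support HGT topology,
mixed clade), with randomised clade topologies and branch lengths, an
exact support value on the key node, and a truth label carrying both the
generative scenario and the *correct call* (for the low-support and mixed
scenarios the correct call is `ambiguous`). Branch lengths are arbitrary
because the classifier reads only topology and support.

`simulate_transcript_tables()` draws TE and non-plant status independently
per ORF, with flagged TEs given e-values below the removal cutoff, so the
expected count after each filter is a pure set-arithmetic function of the
emitted truth flags.

## Numerical and degenerate-input choices

* Empty inputs flow through: empty hit files, zero-tract configurations,
  zero-ORF tables and empty tree sets all yield typed empty results, and
  an empty enrichment study set is handled gracefully.
* `tile_contig()` refuses blocks beyond the contig end; explicit tract
  placements are validated against contig bounds and mutual overlap.
* Hits with reversed query coordinates (minus strand) are flipped on read;
  subject strand is otherwise ignored, since donor assignment uses query
  position only.
* All boundary comparisons are exact at their stated strictness: identity
  and length filters inclusive, region length and node support strict,
  TE and best-hit e-values strict.
* Output files are written with fixed formatting and no timestamps, so a
  rerun with the same inputs is byte-identical; each run directory carries
  a manifest with a hash of its parameters.

## Validation problem sizes

The acceptance checks run at deliberately modest sizes so the whole suite
completes in well under a minute per check on a single core: 100 random
tiling instances (contigs ≤ 20 kb, ≤ 50 blocks) against a per-position
argmax oracle; the 25-tract mosaic at seed 7 for end-to-end recovery; 200
scenario trees (50 per scenario) for the classifier; 1000 truth-flagged
ORFs for the cascade; 50 random contingency tables and 20 random p-vectors
for the statistics. These sizes are the package's own validation design,
and all are re-derived from scratch by `scripts/acceptance.R`.

## Known limitations

* Donor resolution is bounded by the database design: the tiling assigns
  the best *available* lineage, and a donor absent from every database can
  only surface as `no_hit` or be mis-attributed to its closest sampled
  relative. The `needs_tree` flag exists precisely to route such ambiguous
  regions to phylogenetics.
* The greedy isoform clustering is order-dependent within the identity
  threshold's margin, like the tool it mirrors.
* The classifier treats support labels as integers on the ultrafast
  bootstrap scale; trees with fractional or missing supports at the key
  node yield `ambiguous`, not an error.
* Conservation screening depends on sister-assembly completeness; the
  `no_data` category mitigates but cannot remove that bias.

```{r example}
sim <- simulate_mosaic(sim_config(seed = 7))
scan <- run_mito(sim$hits, sim$contig_lengths,
                 host_lineages = c("Solanales", "Malvales", "Fabales"))
glance(scan)
evaluate_recovery(scan$regions, sim$truth, boundary_tol = 50) |>
  dplyr::summarise(recovered = sum(recovered), n = dplyr::n())
```
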