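#' Collapse isoforms by greedy identity clustering
#'
#' Greedy length-first clustering in the style of CD-HIT: sequences are
#' sorted by length (descending); each joins the first existing cluster
#' whose representative it matches at or above `identity_threshold` global
#' identity, else it founds a new cluster.  The representative of a cluster
#' is its founder, i.e. its longest member.  Identity is computed from a
#' global (Needleman-Wunsch) pairwise alignment as matches over alignment
#' length; word-filter heuristics are not replicated.
#'
#' @param seqs Tibble with columns `id` and `sequence` (DNA, A/C/G/T).
#' @param identity_threshold Global identity at or above which a sequence
#'   joins a cluster, default 0.95.
#' @return Tibble: `id`, `length`, `cluster` (integer), `rep_id`,
#'   `representative` (logical), in input order.
#' @export
collapse_isoforms <- function(seqs, identity_threshold = 0.95) {
  if (nrow(seqs) == 0L) {
    abort("collapse_isoforms requires at least one sequence")
  }
  if (any(!nzchar(seqs$sequence))) abort("sequences must be non-empty")
  n <- nrow(seqs)
  len <- nchar(seqs$sequence)
  ord <- order(-len, seqs$id)
  cluster <- integer(n)
  reps <- integer(0)
  for (i in ord) {
    assigned <- FALSE
    for (r in reps) {
      if (global_identity(seqs$sequence[i], seqs$sequence[r]) >= identity_threshold) {
        cluster[i] <- cluster[r]
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      cluster[i] <- length(reps) + 1L
      reps <- c(reps, i)
    }
  }
  tibble(
    id = seqs$id,
    length = len,
    cluster = cluster,
    rep_id = seqs$id[reps][cluster],
    representative = seq_len(n) %in% reps
  )
}

#' Global pairwise identity between two DNA sequences
#'
#' Matches over global alignment length (Needleman-Wunsch, match +1,
#' mismatch -1, gap opening 4, gap extension 1), returned as a fraction.
#'
#' @param a,b DNA sequence strings.
#' @return Identity in `[0, 1]`.
#' @export
global_identity <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 4, gapExtension = 1
  )
  as.numeric(Biostrings::pid(aln, type = "PID1")) / 100
}
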