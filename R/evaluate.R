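#' Score called regions against planted truth
#'
#' Matches each non-dropped truth tract to called regions on the same
#' contig with the same donor lineage, by interval intersection.  A tract
#' is recovered when a same-donor region overlaps it and both boundary
#' offsets are within `boundary_tol` bp.
#'
#' @param regions Region tibble from [call_foreign_regions()].
#' @param truth Truth tibble from [simulate_mosaic()] (a `dropped` column,
#'   if present, excludes dropped tracts).
#' @param boundary_tol Maximum allowed |start| and |end| offset in bp.
#' @return `truth` with added columns `recovered`, `boundary_error`
#'   (max of the two offsets for the best-overlapping same-donor region;
#'   `NA` when none overlaps) and `reciprocal_overlap` (intersection over
#'   the longer of tract and region; 0 when none overlaps).
#' @export
evaluate_recovery <- function(regions, truth, boundary_tol = 50) {
  tr <- as_tibble(truth)
  if ("dropped" %in% names(tr)) {
    tr <- tr |> filter(!dropped)
  }
  if (nrow(tr) == 0L) {
    return(tr |> mutate(recovered = logical(0), boundary_error = numeric(0),
                        reciprocal_overlap = numeric(0)))
  }
  score <- purrr::map_dfr(seq_len(nrow(tr)), function(i) {
    cand <- regions[regions$contig == tr$contig[i] &
                      regions$donor_lineage == tr$donor_lineage[i], , drop = FALSE]
    if (nrow(cand) > 0) {
      inter <- pmax(0, pmin(tr$end[i], cand$end) - pmax(tr$start[i], cand$start))
      cand <- cand[inter > 0, , drop = FALSE]
      inter <- inter[inter > 0]
    }
    if (nrow(cand) == 0L) {
      return(tibble(recovered = FALSE, boundary_error = NA_real_,
                    reciprocal_overlap = 0))
    }
    j <- which.max(inter)
    be <- max(abs(cand$start[j] - tr$start[i]), abs(cand$end[j] - tr$end[i]))
    ro <- inter[j] / max(tr$end[i] - tr$start[i], cand$end[j] - cand$start[j])
    tibble(recovered = be <= boundary_tol, boundary_error = be,
           reciprocal_overlap = ro)
  })
  bind_cols(tr, score)
}
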