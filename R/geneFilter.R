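#' Gene-content filtering of detection records
#'
#' Applies the two gene-content cutoffs that gate predicted viral contigs
#' after detection: a minimum number of viral genes (default 1) and a
#' maximum host-to-viral gene ratio (default 1, inclusive). Kept records
#' satisfy `viral_genes >= minViralGenes` AND
#' `host_genes / viral_genes <= maxHostViralRatio`. These cutoffs are
#' deliberately separated from detection so they can be re-applied without
#' re-running the detectors.
#'
#' When `minViralGenes == 0`, records with zero viral genes make the ratio
#' undefined; the convention is to keep such a record iff it also has zero
#' host genes (a contig with host genes and no viral genes is always host
#' material).
#'
#' @param records detection-record data.frame with `viral_genes` and
#'   `host_genes` populated.
#' @param minViralGenes minimum viral gene count (inclusive).
#' @param maxHostViralRatio maximum host/viral gene ratio (inclusive).
#' @return list with `kept` (records passing) and `dropped` (records
#'   failing, with a `reason` column naming the first failed rule:
#'   `"min_viral_genes"` or `"host_viral_ratio"`).
#' @examples
#' r <- makeDetectionRecords(c("a", "b"), viral_genes = c(2L, 1L),
#'                           host_genes = c(1L, 2L))
#' applyGeneFilters(r)$dropped$reason
#' @export
applyGeneFilters <- function(records, minViralGenes = 1L,
                             maxHostViralRatio = 1) {
  .checkCols(records, c("viral_genes", "host_genes"), "records")
  if (minViralGenes < 0 || maxHostViralRatio < 0)
    .configError("gene-filter cutoffs must be non-negative")
  vg <- records$viral_genes
  hg <- records$host_genes
  if (anyNA(vg) || anyNA(hg))
    .schemaError("viral_genes/host_genes missing; cannot apply gene filters")
  passMin <- vg >= minViralGenes
  ## ratio rule; vg == 0 is only reachable when minViralGenes == 0, where
  ## the documented convention applies
  passRatio <- ifelse(vg > 0, hg / vg <= maxHostViralRatio, hg == 0)
  keep <- passMin & passRatio
  reason <- ifelse(!passMin, "min_viral_genes",
                   ifelse(!passRatio, "host_viral_ratio", NA_character_))
  dropped <- records[!keep, , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- reason[!keep]
  else dropped$reason <- character(0)
  rownames(dropped) <- NULL
  kept <- records[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, dropped = dropped)
}
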