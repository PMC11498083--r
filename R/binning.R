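#' Filter viral genome bins by protein redundancy
#'
#' Redundant (duplicated) proteins within a bin signal contamination by
#' unrelated sequence. The `conservative` mode keeps only bins with fewer
#' than two redundant proteins; the `relaxed` mode rejects only bins with
#' more than five, keeping the ambiguous 2-5 band that may still be clean.
#' Giant viruses (NCLDV) can legitimately carry ~10 redundant proteins in
#' an uncontaminated bin, so individual bins can be exempted via
#' `overrideBins` rather than by loosening the mode globally.
#'
#' @param bins data.frame with at least `bin_id` and `protein_redundancy`.
#' @param mode `"conservative"` or `"relaxed"`.
#' @param overrideBins character vector of bin IDs kept regardless of
#'   redundancy (per-bin NCLDV exemption).
#' @return list with `kept` and `rejected` data.frames; rejected rows
#'   carry a `reason` column.
#' @examples
#' b <- data.frame(bin_id = c("b1", "b2"), protein_redundancy = c(1L, 4L))
#' filterBins(b, "conservative")$rejected$bin_id
#' @export
filterBins <- function(bins, mode = c("conservative", "relaxed"),
                       overrideBins = character(0)) {
  mode <- tryCatch(match.arg(mode),
                   error = function(e) .configError("unknown bin-filter mode"))
  .checkCols(bins, c("bin_id", "protein_redundancy"), "bins")
  red <- bins$protein_redundancy
  if (anyNA(red))
    .schemaError("protein_redundancy missing; cannot filter bins")
  keep <- if (mode == "conservative") red < 2L else red <= 5L
  keep <- keep | bins$bin_id %in% overrideBins
  kept <- bins[keep, , drop = FALSE]
  rejected <- bins[!keep, , drop = FALSE]
  if (nrow(rejected))
    rejected$reason <- sprintf("protein_redundancy %d exceeds %s limit",
                               rejected$protein_redundancy, mode)
  else rejected$reason <- character(0)
  rownames(kept) <- rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}

#' Concatenate a multi-scaffold bin with 10-N linkers
#'
#' Quality estimators expect a single sequence per genome, so the member
#' scaffolds of a bin are joined, in membership order, with a linker of 10
#' N bases between consecutive members. The result length is the sum of
#' member lengths plus 10·(k−1).
#'
#' @param members a [Biostrings::DNAStringSet] of the bin's member
#'   sequences, in membership-table order; at least 2 members.
#' @param binId name for the concatenated sequence.
#' @return a length-1 [Biostrings::DNAStringSet] named `binId`.
#' @examples
#' m <- Biostrings::DNAStringSet(c(s1 = "ACGT", s2 = "GGCC"))
#' Biostrings::width(concatenateBin(m, "bin1"))  # 4 + 4 + 10
#' @export
concatenateBin <- function(members, binId = "bin") {
  if (length(members) < 2L)
    .schemaError("bin %s has %d member(s); concatenation needs >= 2",
                 binId, length(members))
  linker <- strrep("N", 10L)
  joined <- paste(as.character(members), collapse = linker)
  out <- Biostrings::DNAStringSet(joined)
  names(out) <- binId
  out
}

#' Combine kept vBins with unbinned vOTUs into one abundance matrix
#'
#' Final abundance tables carry one row per kept bin plus one row per
#' vOTU representative that is not a member of any kept bin, over the same
#' samples. A bin row's depth and covered fraction are the length-weighted
#' means over its members present in the vOTU matrix; its read count is
#' the member sum. A representative claimed by two kept bins is an error.
#'
#' @param keptBins data.frame with `bin_id` and a `members` list-column
#'   (or comma-separated `members` string) of member representative IDs.
#' @param votuMatrix a [VOTUCoverage] over representatives.
#' @return a [VOTUCoverage] whose rows are kept bins then unbinned
#'   representatives.
#' @export
combineVbinsUnbinned <- function(keptBins, votuMatrix) {
  stopifnot(is(votuMatrix, "VOTUCoverage"))
  if (nrow(keptBins) == 0L) return(votuMatrix)
  .checkCols(keptBins, c("bin_id", "members"), "bins")
  .assertNoDuplicates(keptBins$bin_id, "bin_id")
  memberList <- if (is.list(keptBins$members)) keptBins$members
    else strsplit(keptBins$members, ",", fixed = TRUE)
  memberList <- lapply(memberList, trimws)
  all_members <- unlist(memberList, use.names = FALSE)
  dup <- unique(all_members[duplicated(all_members)])
  if (length(dup))
    .schemaError("representative(s) claimed by two kept bins: %s",
                 paste(dup, collapse = ", "))
  reps <- rownames(votuMatrix)
  depth <- SummarizedExperiment::assay(votuMatrix, "depth")
  cf <- SummarizedExperiment::assay(votuMatrix, "coveredFraction")
  rc <- SummarizedExperiment::assay(votuMatrix, "readCount")
  rd <- SummarizedExperiment::rowData(votuMatrix)
  lens <- if ("length" %in% names(rd)) as.numeric(rd$length)
    else rep(1, length(reps))  # unweighted fallback when lengths are absent
  names(lens) <- reps

  binRow <- function(members, what) {
    known <- intersect(members, reps)
    if (!length(known))
      .schemaError("bin %s has no member present in the vOTU matrix", what)
    w <- lens[known] / sum(lens[known])
    list(depth = colSums(depth[known, , drop = FALSE] * w),
         cf = colSums(cf[known, , drop = FALSE] * w),
         rc = colSums(rc[known, , drop = FALSE]))
  }
  rows <- Map(binRow, memberList, keptBins$bin_id)
  bd <- do.call(rbind, lapply(rows, `[[`, "depth"))
  bcf <- do.call(rbind, lapply(rows, `[[`, "cf"))
  brc <- do.call(rbind, lapply(rows, `[[`, "rc"))
  rownames(bd) <- rownames(bcf) <- rownames(brc) <- keptBins$bin_id
  ## a bin member with zero coverage contributes weight but no depth; keep
  ## the depth==0 => cf==0 invariant by zeroing cf where depth vanished
  bcf[bd == 0] <- 0

  unbinned <- setdiff(reps, all_members)
  annCols <- c("bin_id", "row_type", "n_members", "length")
  binAnn <- S4Vectors::DataFrame(
    bin_id = keptBins$bin_id, row_type = "vBin",
    n_members = lengths(memberList),
    length = vapply(memberList, function(m)
      sum(lens[intersect(m, reps)]) + 10 * (length(m) - 1L), numeric(1)),
    row.names = keptBins$bin_id)
  unbAnn <- S4Vectors::DataFrame(
    bin_id = NA_character_, row_type = "unbinned_vOTU",
    n_members = 1L, length = lens[unbinned], row.names = unbinned)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(
      depth = rbind(bd, depth[unbinned, , drop = FALSE]),
      coveredFraction = rbind(bcf, cf[unbinned, , drop = FALSE]),
      readCount = rbind(brc, rc[unbinned, , drop = FALSE])),
    rowData = rbind(binAnn, unbAnn),
    colData = SummarizedExperiment::colData(votuMatrix))
  methods::new("VOTUCoverage", se)
}
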