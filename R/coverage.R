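#' Coverage statistics for one contig from read placements
#'
#' A placement is the aligned span of one read on the contig (1-based
#' inclusive); this abstraction stands in for sorted alignment files. The
#' covered fraction is the union of spans divided by the contig length
#' (horizontal coverage); mean depth is total aligned bases divided by
#' contig length; the read count is the number of placements.
#'
#' @param placements data.frame with columns `start`, `end` for a single
#'   contig (zero rows allowed).
#' @param contigLength contig length in bp.
#' @param contigId,sampleId identifiers stamped on the output row.
#' @return one-row data.frame with `contig_id`, `sample_id`, `mean_depth`,
#'   `covered_fraction`, `read_count`.
#' @examples
#' coveredStats(data.frame(start = c(1, 41), end = c(50, 80)), 100)
#' @export
coveredStats <- function(placements, contigLength, contigId = "contig",
                         sampleId = "sample") {
  if (nrow(placements)) {
    .checkCols(placements, c("start", "end"), "placements")
    if (any(placements$start < 1L | placements$start > placements$end |
            placements$end > contigLength))
      .schemaError("placement span outside [1, %d] on %s",
                   contigLength, contigId)
  }
  covered <- .unionWidth(placements$start, placements$end)
  total <- if (nrow(placements))
    sum(as.numeric(placements$end - placements$start + 1L)) else 0
  data.frame(contig_id = contigId, sample_id = sampleId,
             mean_depth = total / contigLength,
             covered_fraction = covered / contigLength,
             read_count = nrow(placements),
             stringsAsFactors = FALSE)
}

#' Per-sample coverage table from placements on many contigs
#'
#' Applies [coveredStats()] per contig; contigs with no placements get an
#' explicit all-zero row, so the output always has one row per declared
#' contig.
#'
#' @param placements data.frame with `contig_id`, `start`, `end`.
#' @param lengths named vector of contig lengths.
#' @param sampleId sample ID stamped on every row.
#' @return data.frame of coverage rows, one per contig in `lengths` order.
#' @export
coverageFromPlacements <- function(placements, lengths, sampleId = "sample") {
  if (nrow(placements)) {
    .checkCols(placements, c("contig_id", "start", "end"), "placements")
    unknown <- setdiff(unique(placements$contig_id), names(lengths))
    if (length(unknown))
      .schemaError("placements on undeclared contig(s): %s",
                   paste(unknown, collapse = ", "))
  }
  rows <- lapply(names(lengths), function(id) {
    p <- placements[placements$contig_id == id, , drop = FALSE]
    coveredStats(p, lengths[[id]], contigId = id, sampleId = sampleId)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the vOTU-by-sample coverage matrix
#'
#' Completes the observed per-sample coverage rows into a full
#' representatives-by-samples matrix (missing cells are 0), joins the
#' detection annotations as row metadata, and returns a [VOTUCoverage].
#' Coverage rows on contigs that are not known representatives are skipped
#' with a warning; duplicate (contig, sample) observations are an error.
#'
#' @param coverageRows data.frame of coverage rows
#'   (layout of [readCoverageTable()]), possibly concatenated over samples.
#' @param annotations data.frame keyed by `contig_id` — one row per
#'   representative — carried into `rowData`.
#' @param samples optional character vector fixing the full sample set
#'   (columns); defaults to the samples observed in `coverageRows`.
#' @return a [VOTUCoverage].
#' @export
buildCoverageMatrix <- function(coverageRows, annotations, samples = NULL) {
  .checkCols(coverageRows,
             c("contig_id", "sample_id", "mean_depth", "covered_fraction",
               "read_count"), "coverage rows")
  .checkCols(annotations, "contig_id", "annotations")
  .assertNoDuplicates(annotations$contig_id, "annotation contig_id")
  reps <- annotations$contig_id
  unknown <- !(coverageRows$contig_id %in% reps)
  if (any(unknown)) {
    .warnf("skipping %d coverage row(s) on unknown contig(s): %s",
           sum(unknown),
           paste(unique(coverageRows$contig_id[unknown]), collapse = ", "))
    coverageRows <- coverageRows[!unknown, , drop = FALSE]
  }
  if (is.null(samples))
    samples <- sort(unique(coverageRows$sample_id))
  if (length(samples) == 0L)
    .configError("no samples to build a matrix over")
  cellKey <- paste(coverageRows$contig_id, coverageRows$sample_id, sep = "\r")
  dup <- unique(cellKey[duplicated(cellKey)])
  if (length(dup))
    .schemaError("duplicate (contig, sample) coverage row(s): %s",
                 paste(gsub("\r", " / ", dup), collapse = ", "))
  blank <- matrix(0, nrow = length(reps), ncol = length(samples),
                  dimnames = list(reps, samples))
  depth <- cf <- rc <- blank
  if (nrow(coverageRows)) {
    i <- cbind(match(coverageRows$contig_id, reps),
               match(coverageRows$sample_id, samples))
    depth[i] <- coverageRows$mean_depth
    cf[i] <- coverageRows$covered_fraction
    rc[i] <- coverageRows$read_count
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(depth = depth, coveredFraction = cf, readCount = rc),
    rowData = S4Vectors::DataFrame(annotations, row.names = reps),
    colData = S4Vectors::DataFrame(sample_id = samples, row.names = samples))
  methods::new("VOTUCoverage", se)
}

#' Horizontal-coverage filtering of an abundance matrix
#'
#' For each threshold t, abundance (depth) and read-count cells whose
#' horizontal coverage falls below t are zeroed — the standard viromics
#' guard against spurious detections from reads piling up on a small part
#' of a genome — and rows left with no nonzero abundance are dropped.
#' The input matrix is untouched; the default thresholds are
#' 0.1, 0.5 and 0.9.
#'
#' @param mat a [VOTUCoverage].
#' @param thresholds numeric vector of covered-fraction thresholds in
#'   \[0,1\].
#' @param dropEmptyRows drop rows that become all-zero (default `TRUE`).
#' @return named list of [VOTUCoverage], one per threshold (names are the
#'   threshold values).
#' @export
applyHorizontalCoverage <- function(mat, thresholds = c(0.1, 0.5, 0.9),
                                    dropEmptyRows = TRUE) {
  stopifnot(is(mat, "VOTUCoverage"))
  if (any(thresholds < 0 | thresholds > 1))
    .configError("covered-fraction thresholds must lie in [0,1]")
  out <- lapply(thresholds, function(t) {
    depth <- SummarizedExperiment::assay(mat, "depth")
    rc <- SummarizedExperiment::assay(mat, "readCount")
    cf <- SummarizedExperiment::assay(mat, "coveredFraction")
    low <- cf < t
    depth[low] <- 0
    rc[low] <- 0
    m <- mat
    SummarizedExperiment::assay(m, "depth") <- depth
    SummarizedExperiment::assay(m, "readCount") <- rc
    if (dropEmptyRows) m <- m[rowSums(depth) > 0, , drop = FALSE]
    m
  })
  names(out) <- as.character(thresholds)
  out
}

#' Sequence-quality filter for the final abundance tables
#'
#' The `conservative` mode keeps a sequence iff it is longer than 5 kb, or
#' longer than 1 kb and of Complete, High-quality or Medium-quality tier
#' (both length comparisons strict). The `relaxed` mode instead re-applies
#' the default gene-content filters (minimum 1 viral gene, host/viral
#' ratio at most 1).
#'
#' @param records detection-record data.frame with `length` and `quality`
#'   populated (and gene counts for `relaxed`).
#' @param mode `"conservative"` or `"relaxed"`.
#' @return the filtered records.
#' @export
applySequenceFilter <- function(records, mode = c("conservative", "relaxed")) {
  mode <- tryCatch(match.arg(mode),
                   error = function(e) .configError("unknown mode"))
  if (mode == "relaxed") return(applyGeneFilters(records)$kept)
  .checkCols(records, c("length", "quality"), "records")
  if (anyNA(records$length))
    .schemaError("length missing; cannot apply sequence filter")
  good <- c("Complete", "High-quality", "Medium-quality")
  keep <- records$length > 5000L |
    (records$length > 1000L & records$quality %in% good)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flatten a coverage matrix to its TSV layout
#'
#' Annotation columns first, then one mean-depth column per sample and one
#' `<sample>_covered_fraction` column per sample, written via
#' [writeViralTable()].
#'
#' @param mat a [VOTUCoverage].
#' @param path output TSV path; `NULL` returns the data.frame without
#'   writing.
#' @return the flattened data.frame, invisibly when written.
#' @export
writeCoverageMatrix <- function(mat, path = NULL) {
  stopifnot(is(mat, "VOTUCoverage"))
  ann <- as.data.frame(SummarizedExperiment::rowData(mat))
  depth <- SummarizedExperiment::assay(mat, "depth")
  cf <- SummarizedExperiment::assay(mat, "coveredFraction")
  colnames(cf) <- paste0(colnames(cf), "_covered_fraction")
  flat <- cbind(ann, as.data.frame(depth), as.data.frame(cf))
  rownames(flat) <- NULL
  if (is.null(path)) return(flat)
  writeViralTable(flat, path)
  invisible(flat)
}
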