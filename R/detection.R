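## Columns every DetectionRecord data.frame carries.
.DETECTION_COLS <- c("contig_id", "sample_id", "is_provirus",
                     "parent_contig_id", "region_start", "region_end",
                     "length", "virus_score", "n_hallmarks", "n_genes",
                     "viral_genes", "host_genes", "quality", "completeness",
                     "taxonomy", "genome_type", "host_domain", "round")

#' Construct detection records
#'
#' Builds the canonical detection-record table (one row per predicted viral
#' or proviral sequence, detector scores and quality metrics joined) from
#' named vectors, filling unspecified fields with defaults. Used both by
#' [asDetectionRecords()] and by the fixture generators.
#'
#' @param contig_id character vector (required).
#' @param ... any other detection columns, recycled to length.
#' @return data.frame of detection records.
#' @export
makeDetectionRecords <- function(contig_id, ...) {
  n <- length(contig_id)
  defaults <- list(
    sample_id = "S1", is_provirus = FALSE,
    parent_contig_id = NA_character_,
    region_start = NA_integer_, region_end = NA_integer_,
    length = NA_integer_, virus_score = NA_real_,
    n_hallmarks = NA_integer_, n_genes = NA_integer_,
    viral_genes = NA_integer_, host_genes = NA_integer_,
    quality = "Not-determined", completeness = NA_real_,
    taxonomy = "", genome_type = "unknown", host_domain = "unknown",
    round = 1L)
  supplied <- list(...)
  unknown <- setdiff(names(supplied), names(defaults))
  if (length(unknown))
    .configError("unknown detection column(s): %s",
                 paste(unknown, collapse = ", "))
  fields <- modifyList(defaults, supplied)
  out <- data.frame(contig_id = as.character(contig_id),
                    stringsAsFactors = FALSE)
  for (nm in names(defaults)) out[[nm]] <- rep_len(fields[[nm]], n)
  validateDetectionRecords(out)
}

#' Validate a detection-record table
#'
#' Enforces the structural invariants: provirus rows carry a parent and a
#' region whose span equals the recorded length; round-2 rows are
#' proviruses; quality tiers are canonical.
#'
#' @param records detection-record data.frame.
#' @return `records`, invisibly amended (column order normalized).
#' @export
validateDetectionRecords <- function(records) {
  .checkCols(records, .DETECTION_COLS, "detection records")
  .assertNoDuplicates(records$contig_id, "detection contig_id")
  prov <- records$is_provirus
  bad <- prov & (is.na(records$parent_contig_id) |
                 is.na(records$region_start) | is.na(records$region_end))
  if (any(bad))
    .schemaError("provirus record without parent/region: %s",
                 paste(records$contig_id[bad], collapse = ", "))
  span <- records$region_end - records$region_start + 1L
  bad <- prov & !is.na(records$length) & span != records$length
  if (any(bad, na.rm = TRUE))
    .schemaError("provirus length != region span: %s",
                 paste(records$contig_id[which(bad)], collapse = ", "))
  if (any(records$round == 2L & !prov))
    .schemaError("round-2 record that is not a provirus")
  if (!all(records$quality %in% .QUALITY_TIERS))
    .schemaError("non-canonical quality tier(s): %s",
                 paste(setdiff(unique(records$quality), .QUALITY_TIERS),
                       collapse = ", "))
  invisible(records[, c(.DETECTION_COLS,
                        setdiff(names(records), .DETECTION_COLS))])
}

#' Convert a joined detection table to detection records
#'
#' Takes the output of [readDetectionTables()], stamps the sample ID and
#' detection round, derives provirus status (provirus topology or CheckV
#' provirus flag), and infers genome type and host domain from the taxonomy
#' lineage.
#'
#' @param joined data.frame from [readDetectionTables()].
#' @param sampleId sample the table belongs to.
#' @param round detection round, 1 (assembly) or 2 (trimmed proviruses).
#' @param genomeTypeMap mapping from [loadGenomeTypeMap()]; `NULL` loads
#'   the bundled default.
#' @return detection-record data.frame.
#' @export
asDetectionRecords <- function(joined, sampleId, round = 1L,
                               genomeTypeMap = NULL) {
  if (is.null(genomeTypeMap)) genomeTypeMap <- loadGenomeTypeMap()
  is_prov <- joined$topology == "provirus" | isTRUE(joined$provirus_flag) |
    joined$provirus_flag
  rs <- ifelse(!is.na(joined$provirus_start), joined$provirus_start,
               joined$region_start)
  re <- ifelse(!is.na(joined$provirus_end), joined$provirus_end,
               joined$region_end)
  ## "<parent>|provirus_<start>_<end>" IDs identify the parent directly
  parent <- ifelse(is_prov, sub("\\|provirus_.*$", "", joined$contig_id),
                   NA_character_)
  gt <- inferGenomeType(joined$taxonomy, genomeTypeMap)
  len <- ifelse(is_prov & !is.na(rs), re - rs + 1L, joined$length)
  makeDetectionRecords(
    contig_id = joined$contig_id,
    sample_id = sampleId,
    is_provirus = is_prov,
    parent_contig_id = parent,
    region_start = as.integer(rs), region_end = as.integer(re),
    length = as.integer(len),
    virus_score = joined$virus_score,
    n_hallmarks = joined$n_hallmarks,
    n_genes = joined$n_genes,
    viral_genes = joined$viral_genes,
    host_genes = joined$host_genes,
    quality = joined$quality,
    completeness = joined$completeness,
    taxonomy = joined$taxonomy,
    genome_type = gt$genome_type,
    host_domain = gt$host_domain,
    round = as.integer(round))
}

#' Detection filter presets
#'
#' The two post-classification presets applied to detector output:
#' `conservative` requires virus score >= 0.8, length >= 2500 bp and >= 1
#' virus hallmark gene; `relaxed` lowers these to score >= 0.7 and >= 0
#' hallmarks (same length floor).
#'
#' @param name `"conservative"` or `"relaxed"`.
#' @return list with `name`, `min_score`, `min_length`, `min_hallmarks`.
#' @examples
#' filterPreset("conservative")
#' @export
filterPreset <- function(name = c("conservative", "relaxed")) {
  name <- match.arg(name)
  switch(name,
    conservative = list(name = "conservative", min_score = 0.8,
                        min_length = 2500L, min_hallmarks = 1L),
    relaxed = list(name = "relaxed", min_score = 0.7,
                   min_length = 2500L, min_hallmarks = 0L))
}

#' Test detection records against a preset
#'
#' A record passes iff `virus_score >= min_score` AND
#' `length >= min_length` AND `n_hallmarks >= min_hallmarks` (all
#' inclusive). For proviruses the length tested is the trimmed-region
#' length, which is what the `length` column holds for round-2 records.
#' A missing score, length or hallmark count is a hard error — records
#' never pass silently.
#'
#' @param records detection-record data.frame.
#' @param preset a preset from [filterPreset()] (or its name).
#' @return logical vector, one element per record.
#' @export
passesPreset <- function(records, preset = filterPreset("conservative")) {
  if (is.character(preset)) preset <- filterPreset(preset)
  need <- c("virus_score", "length", "n_hallmarks")
  .checkCols(records, need, "detection records")
  if (anyNA(records$virus_score) || anyNA(records$length) ||
      anyNA(records$n_hallmarks))
    .schemaError("missing virus_score/length/n_hallmarks; cannot apply preset")
  records$virus_score >= preset$min_score &
    records$length >= preset$min_length &
    records$n_hallmarks >= preset$min_hallmarks
}

#' Prefix contig headers with the sample name
#'
#' Appends the sample name as a `<sample>__` prefix on each contig ID so
#' that identical assembly headers across samples cannot collide
#' downstream. Idempotent: IDs already carrying the prefix are left alone.
#'
#' @param contigs a named [Biostrings::DNAStringSet], or a character vector
#'   of IDs.
#' @param sampleId sample name; must be non-empty and free of whitespace
#'   and of the `"__"` separator.
#' @param enabled when `FALSE`, identity (the flag default upstream is on).
#' @return same type as `contigs`, IDs prefixed.
#' @export
prefixHeaders <- function(contigs, sampleId, enabled = TRUE) {
  if (!nzchar(sampleId) || grepl("\\s", sampleId) ||
      grepl(.PREFIX_SEP, sampleId, fixed = TRUE))
    .configError("invalid sample name for header prefixing: '%s'", sampleId)
  if (!enabled) return(contigs)
  ids <- if (is.character(contigs)) contigs else names(contigs)
  pre <- paste0(sampleId, .PREFIX_SEP)
  todo <- !startsWith(ids, pre)
  ids[todo] <- paste0(pre, ids[todo])
  .assertNoDuplicates(ids, "contig ID after prefixing")
  if (is.character(contigs)) return(ids)
  names(contigs) <- ids
  contigs
}

#' Drop contigs below a minimum size
#'
#' @param contigs a named [Biostrings::DNAStringSet].
#' @param minLen minimum length in bp (inclusive; `length >= minLen`
#'   is kept). 0 keeps everything.
#' @return the filtered `DNAStringSet`, input order preserved.
#' @export
filterMinSeqSize <- function(contigs, minLen = 0L) {
  if (minLen < 0) .configError("minLen must be >= 0")
  contigs[Biostrings::width(contigs) >= minLen]
}

#' Load the taxonomy-to-genome-type mapping
#'
#' The bundled mapping lists taxon names with their predicted genome type
#' (dsDNA/ssDNA/RNA) and host domain (prokaryotic/eukaryotic); e.g. the
#' *Caudoviricetes* class maps to dsDNA / prokaryotic. Users may supply
#' their own file with the same three tab-separated columns
#' (`taxon`, `genome_type`, `host_domain`).
#'
#' @param path optional path to an override mapping; `NULL` uses the
#'   bundled default.
#' @return data.frame with columns `taxon`, `genome_type`, `host_domain`.
#' @export
loadGenomeTypeMap <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "genome_type_map.tsv",
                        package = "viromics", mustWork = TRUE)
  if (!file.exists(path)) .configError("mapping file not found: %s", path)
  m <- tryCatch(read.delim(path, stringsAsFactors = FALSE),
                error = function(e)
                  .configError("malformed mapping file %s: %s", path,
                               conditionMessage(e)))
  req <- c("taxon", "genome_type", "host_domain")
  if (!all(req %in% names(m)))
    .configError("mapping file must have columns: %s",
                 paste(req, collapse = ", "))
  if (!all(m$genome_type %in% .GENOME_TYPES) ||
      !all(m$host_domain %in% .HOST_DOMAINS))
    .configError("mapping file contains unknown genome_type/host_domain")
  m
}

#' Infer genome type and host domain from a taxonomy lineage
#'
#' Scans the semicolon-delimited lineage from its most specific (rightmost)
#' rank leftwards and returns the mapping of the first rank found in the
#' taxon table; lineages with no mapped rank give
#' `(unknown, unknown)`.
#'
#' @param taxonomy character vector of lineage strings
#'   (e.g. `"Viruses;Duplodnaviria;...;Caudoviricetes"`).
#' @param mapping data.frame from [loadGenomeTypeMap()].
#' @return data.frame with columns `genome_type` and `host_domain`,
#'   one row per lineage.
#' @export
inferGenomeType <- function(taxonomy, mapping = loadGenomeTypeMap()) {
  lookupType <- setNames(mapping$genome_type, mapping$taxon)
  lookupHost <- setNames(mapping$host_domain, mapping$taxon)
  one <- function(lin) {
    if (is.na(lin) || !nzchar(lin)) return(c("unknown", "unknown"))
    ranks <- rev(trimws(strsplit(lin, ";", fixed = TRUE)[[1L]]))
    for (r in ranks) {
      if (nzchar(r) && r %in% names(lookupType))
        return(c(lookupType[[r]], lookupHost[[r]]))
    }
    c("unknown", "unknown")
  }
  res <- t(vapply(as.character(taxonomy), one, character(2), USE.NAMES = FALSE))
  data.frame(genome_type = res[, 1L], host_domain = res[, 2L],
             stringsAsFactors = FALSE)
}

#' Reconcile two detection rounds over trimmed proviruses
#'
#' When the quality-estimation step trims a host region off a predicted
#' provirus, the trimmed sequence is re-scored in a second detection round
#' so that all metrics reflect only the viral region. This function
#' substitutes the round-2 (trimmed) records for their round-1 parents: a
#' parent with k >= 1 trimmed children is dropped and contributes exactly
#' its k children; round-1 records without children pass through
#' unmodified. Child IDs follow `"<parent>|provirus_<start>_<end>"`.
#'
#' @param round1 detection records from the first round.
#' @param round2 detection records from the re-scored trimmed proviruses
#'   (may be empty or `NULL`); every row must name a `parent_contig_id`
#'   present in `round1`.
#' @return detection-record data.frame.
#' @export
reconcileProvirusRounds <- function(round1, round2 = NULL) {
  round1 <- validateDetectionRecords(round1)
  if (is.null(round2) || nrow(round2) == 0L) return(round1)
  round2 <- validateDetectionRecords(round2)
  if (any(round2$round != 2L))
    .schemaError("round-2 table contains rows not marked round == 2")
  orphan <- setdiff(round2$parent_contig_id, round1$contig_id)
  if (length(orphan))
    .schemaError("round-2 record(s) with no round-1 parent: %s",
                 paste(orphan, collapse = ", "))
  ## canonical child IDs
  want <- paste0(round2$parent_contig_id, "|provirus_",
                 round2$region_start, "_", round2$region_end)
  round2$contig_id <- want
  ## overlapping trimmed regions from one parent: keep both, warn
  for (p in unique(round2$parent_contig_id)) {
    kids <- round2[round2$parent_contig_id == p, , drop = FALSE]
    if (nrow(kids) > 1L) {
      ir <- IRanges::IRanges(kids$region_start, kids$region_end)
      if (any(IRanges::countOverlaps(ir) > 1L))
        .warnf("overlapping trimmed regions on parent %s; keeping both", p)
    }
  }
  keep <- !(round1$contig_id %in% round2$parent_contig_id)
  out <- rbind(round1[keep, , drop = FALSE], round2)
  rownames(out) <- NULL
  validateDetectionRecords(out)
}

#' Merge viral and proviral records with their sequences
#'
#' Produces the per-sample unfiltered table and FASTA: the table and the
#' sequence set have identical ID sets, sorted by sample then contig ID.
#' Provirus sequences are extracted from their parent contig at the
#' recorded 1-based inclusive region.
#'
#' @param records detection-record data.frame.
#' @param contigs named [Biostrings::DNAStringSet] containing every
#'   non-provirus record's sequence and every provirus record's parent.
#' @return list with elements `table` (sorted records) and `sequences`
#'   (a `DNAStringSet` in the same order).
#' @export
mergeVirusProvirus <- function(records, contigs) {
  records <- validateDetectionRecords(records)
  ord <- order(records$sample_id, records$contig_id)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  getSeq <- function(i) {
    r <- records[i, ]
    if (r$is_provirus) {
      if (!r$parent_contig_id %in% names(contigs))
        .schemaError("provirus %s: parent %s has no sequence",
                     r$contig_id, r$parent_contig_id)
      parent <- contigs[[r$parent_contig_id]]
      if (r$region_end > length(parent))
        .schemaError("provirus %s: region end %d exceeds parent length %d",
                     r$contig_id, r$region_end, length(parent))
      Biostrings::subseq(parent, r$region_start, r$region_end)
    } else {
      if (!r$contig_id %in% names(contigs))
        .schemaError("record %s has no sequence", r$contig_id)
      contigs[[r$contig_id]]
    }
  }
  seqList <- lapply(seq_len(nrow(records)), getSeq)
  seqs <- Biostrings::DNAStringSet(seqList)
  names(seqs) <- records$contig_id
  stopifnot(identical(names(seqs), records$contig_id))
  list(table = records, sequences = seqs)
}
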