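## Typed conditions so callers (and tests) can distinguish failure classes.
.typedStop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "viromics_error")))
}
.schemaError <- function(fmt, ...) .typedStop("viromics_schema_error", fmt, ...)
.parseError  <- function(fmt, ...) .typedStop("viromics_parse_error", fmt, ...)
.configError <- function(fmt, ...) .typedStop("viromics_config_error", fmt, ...)
.ioError     <- function(fmt, ...) .typedStop("viromics_io_error", fmt, ...)

## Column-name dialects. Each canonical column lists the accepted aliases;
## the first alias found in the file wins. geNomad's virus_summary.tsv and
## CheckV's quality_summary.tsv headers are accepted alongside generic names.
.GENOMAD_ALIASES <- list(
  contig_id      = c("contig_id", "seq_name"),
  length         = c("length", "seq_length"),
  topology       = c("topology"),
  provirus_start = c("provirus_start", "coord_start"),
  provirus_end   = c("provirus_end", "coord_end"),
  coordinates    = c("coordinates"),
  n_genes        = c("n_genes", "genes"),
  virus_score    = c("virus_score", "score"),
  n_hallmarks    = c("n_hallmarks", "hallmarks"),
  taxonomy       = c("taxonomy", "lineage"))

.CHECKV_ALIASES <- list(
  contig_id     = c("contig_id", "seq_name"),
  contig_length = c("contig_length", "length"),
  gene_count    = c("gene_count", "genes"),
  viral_genes   = c("viral_genes"),
  host_genes    = c("host_genes"),
  quality       = c("quality", "checkv_quality"),
  completeness  = c("completeness"),
  provirus_flag = c("provirus_flag", "provirus"),
  region_start  = c("region_start", "trim_start"),
  region_end    = c("region_end", "trim_end"))

.COVERAGE_ALIASES <- list(
  contig_id        = c("contig_id", "Contig", "genome"),
  sample_id        = c("sample_id", "sample"),
  mean_depth       = c("mean_depth", "Mean", "mean", "depth"),
  covered_fraction = c("covered_fraction", "Covered_Fraction",
                       "Covered Fraction", "covered.fraction"),
  read_count       = c("read_count", "Read_Count", "Read Count", "reads"))

.BLAST6_COLS <- c("query_id", "target_id", "pident", "aln_len", "mismatches",
                  "gap_opens", "q_start", "q_end", "t_start", "t_end",
                  "evalue", "bitscore")

## Rename columns of `df` to canonical names using an alias list; `required`
## canonical names must resolve or a schema error is raised.
.applyAliases <- function(df, aliases, required, what) {
  out <- df
  found <- character(0)
  for (canon in names(aliases)) {
    hit <- intersect(aliases[[canon]], names(df))
    if (length(hit)) {
      names(out)[names(out) == hit[1L]] <- canon
      found <- c(found, canon)
    }
  }
  missing <- setdiff(required, found)
  if (length(missing))
    .schemaError("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", "))
  out
}

#' Read a viral contig FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that enforces the
#' conventions the downstream stages rely on: the header token before the
#' first whitespace is the contig ID, IDs must be unique, and empty
#' sequences are an error.
#'
#' @param path path to a (possibly gzipped) FASTA file.
#' @return a [Biostrings::DNAStringSet] named by contig ID, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fna")
#' writeLines(c(">c1 a description", "ACGT", ">c2", "GGGGCC"), fa)
#' readViralFasta(fa)
#' @export
readViralFasta <- function(path) {
  if (!file.exists(path)) .ioError("FASTA file not found: %s", path)
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e)
                     .parseError("not a valid FASTA file (%s): %s",
                                 path, conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    .schemaError("duplicate contig ID(s) in %s: %s", path,
                 paste(dup, collapse = ", "))
  if (any(Biostrings::width(seqs) == 0L))
    .schemaError("empty sequence(s) in %s: %s", path,
                 paste(ids[Biostrings::width(seqs) == 0L], collapse = ", "))
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs a named [Biostrings::DNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeViralFasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, filepath = path, width = 80L)
  invisible(path)
}

#' Read a geNomad-style virus summary table
#'
#' Accepts both the native geNomad header dialect (`seq_name`,
#' `virus_score`, `n_hallmarks`, `coordinates` as `"start-end"`) and
#' generic names (`contig_id`, `score`, `hallmarks`, explicit
#' `provirus_start`/`provirus_end`). Scores are validated to \[0,1\] and
#' provirus coordinates must be present exactly for provirus topology rows.
#'
#' @param path TSV path.
#' @return data.frame with canonical columns `contig_id`, `length`,
#'   `topology`, `provirus_start`, `provirus_end`, `n_genes`,
#'   `virus_score`, `n_hallmarks`, `taxonomy`.
#' @export
readGenomadTable <- function(path) {
  if (!file.exists(path)) .ioError("table not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = c("NA", ""))
  df <- .applyAliases(df, .GENOMAD_ALIASES,
                      required = c("contig_id", "length", "topology",
                                   "n_genes", "virus_score", "n_hallmarks"),
                      what = basename(path))
  if (!"taxonomy" %in% names(df)) df$taxonomy <- ""
  df$taxonomy[is.na(df$taxonomy)] <- ""
  ## geNomad packs provirus coordinates into a single "start-end" column
  if ("coordinates" %in% names(df) && !"provirus_start" %in% names(df)) {
    parts <- strsplit(ifelse(is.na(df$coordinates), "", df$coordinates), "-")
    df$provirus_start <- as.integer(vapply(parts, function(p)
      if (length(p) == 2L) p[1L] else NA_character_, character(1)))
    df$provirus_end <- as.integer(vapply(parts, function(p)
      if (length(p) == 2L) p[2L] else NA_character_, character(1)))
  }
  if (!"provirus_start" %in% names(df)) df$provirus_start <- NA_integer_
  if (!"provirus_end" %in% names(df)) df$provirus_end <- NA_integer_
  df$provirus_start <- as.integer(df$provirus_start)
  df$provirus_end <- as.integer(df$provirus_end)
  df$length <- as.integer(df$length)
  df$n_genes <- as.integer(df$n_genes)
  df$n_hallmarks <- as.integer(df$n_hallmarks)
  df$virus_score <- as.numeric(df$virus_score)

  .assertNoDuplicates(df$contig_id, "contig_id in genomad table")
  if (any(is.na(df$virus_score) | df$virus_score < 0 | df$virus_score > 1))
    .schemaError("virus_score outside [0,1] (or missing) in %s", basename(path))
  bad <- !is.na(df$n_genes) & df$n_hallmarks > df$n_genes
  if (any(bad))
    .schemaError("n_hallmarks > n_genes for: %s",
                 paste(df$contig_id[bad], collapse = ", "))
  is_prov <- df$topology == "provirus"
  has_coord <- !is.na(df$provirus_start) & !is.na(df$provirus_end)
  if (any(is_prov & !has_coord))
    .schemaError("provirus row without coordinates: %s",
                 paste(df$contig_id[is_prov & !has_coord], collapse = ", "))
  if (any(!is_prov & has_coord))
    .schemaError("coordinates on non-provirus row: %s",
                 paste(df$contig_id[!is_prov & has_coord], collapse = ", "))
  if (any(has_coord & (df$provirus_start < 1L |
                       df$provirus_start >= df$provirus_end)))
    .schemaError("invalid provirus coordinates (need 1 <= start < end)")
  df[setdiff(names(df), "coordinates")]
}

#' Read a CheckV-style quality summary table
#'
#' Accepts the native CheckV header dialect (`checkv_quality`, `provirus`
#' as Yes/No) and generic names. Quality tiers are case-normalized via
#' [normalizeQualityTier()]; `viral_genes + host_genes <= gene_count` is
#' enforced.
#'
#' @param path TSV path.
#' @return data.frame with canonical columns `contig_id`, `contig_length`,
#'   `gene_count`, `viral_genes`, `host_genes`, `quality`, `completeness`,
#'   `provirus_flag`, `region_start`, `region_end`.
#' @export
readCheckvTable <- function(path) {
  if (!file.exists(path)) .ioError("table not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = c("NA", ""))
  df <- .applyAliases(df, .CHECKV_ALIASES,
                      required = c("contig_id", "contig_length", "gene_count",
                                   "viral_genes", "host_genes", "quality"),
                      what = basename(path))
  if (!"completeness" %in% names(df)) df$completeness <- NA_real_
  if (!"provirus_flag" %in% names(df)) df$provirus_flag <- FALSE
  if (!"region_start" %in% names(df)) df$region_start <- NA_integer_
  if (!"region_end" %in% names(df)) df$region_end <- NA_integer_
  if (is.character(df$provirus_flag))
    df$provirus_flag <- tolower(df$provirus_flag) %in% c("yes", "true", "1")
  df$contig_length <- as.integer(df$contig_length)
  df$gene_count <- as.integer(df$gene_count)
  df$viral_genes <- as.integer(df$viral_genes)
  df$host_genes <- as.integer(df$host_genes)
  df$completeness <- as.numeric(df$completeness)
  df$region_start <- as.integer(df$region_start)
  df$region_end <- as.integer(df$region_end)
  df$quality <- normalizeQualityTier(df$quality)

  .assertNoDuplicates(df$contig_id, "contig_id in checkv table")
  bad <- df$viral_genes + df$host_genes > df$gene_count
  if (any(bad, na.rm = TRUE))
    .schemaError("viral_genes + host_genes > gene_count for: %s",
                 paste(df$contig_id[which(bad)], collapse = ", "))
  if (any(!is.na(df$completeness) &
          (df$completeness < 0 | df$completeness > 100)))
    .schemaError("completeness outside [0,100] in %s", basename(path))
  has_region <- !is.na(df$region_start)
  if (any(has_region & !df$provirus_flag))
    .schemaError("trimmed region on a non-provirus row: %s",
                 paste(df$contig_id[has_region & !df$provirus_flag],
                       collapse = ", "))
  df[unique(c(names(.CHECKV_ALIASES), setdiff(names(df),
                                              names(.CHECKV_ALIASES))))]
}

#' Read and join detection tables
#'
#' Inner join of a geNomad-style summary and a CheckV-style quality summary
#' on `contig_id`. Rows present in only one table are reported as a warning
#' and excluded; an empty join is an error. This is the raw material for
#' [asDetectionRecords()].
#'
#' @param genomadPath,checkvPath TSV paths.
#' @return data.frame with the canonical columns of both tables
#'   (`length` from geNomad; CheckV's `contig_length` retained for
#'   cross-checks).
#' @export
readDetectionTables <- function(genomadPath, checkvPath) {
  g <- readGenomadTable(genomadPath)
  cv <- readCheckvTable(checkvPath)
  only_g <- setdiff(g$contig_id, cv$contig_id)
  only_c <- setdiff(cv$contig_id, g$contig_id)
  if (length(only_g) || length(only_c))
    .warnf("detection join dropped %d genomad-only and %d checkv-only row(s)",
           length(only_g), length(only_c))
  out <- merge(g, cv, by = "contig_id", sort = FALSE)
  if (nrow(out) == 0L)
    .schemaError("detection join produced 0 rows (no shared contig_id)")
  out[match(intersect(g$contig_id, out$contig_id), out$contig_id), ,
      drop = FALSE]
}

#' Read BLAST tabular (outfmt 6) alignments
#'
#' Standard 12-column headerless tabular output. Start > end on the target
#' is permitted (reverse strand) and normalized downstream.
#'
#' @param path BLAST tabular file.
#' @return data.frame with columns `query_id`, `target_id`, `pident`,
#'   `aln_len`, `mismatches`, `gap_opens`, `q_start`, `q_end`, `t_start`,
#'   `t_end`, `evalue`, `bitscore`.
#' @export
readBlastTable <- function(path) {
  if (!file.exists(path)) .ioError("alignment file not found: %s", path)
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0)
    return(stats::setNames(
      data.frame(matrix(nrow = 0, ncol = 12)), .BLAST6_COLS))
  df <- tryCatch(
    read.delim(path, header = FALSE, stringsAsFactors = FALSE),
    error = function(e) .parseError("cannot parse %s: %s", path,
                                    conditionMessage(e)))
  if (ncol(df) != 12L)
    .schemaError("expected 12 tab-separated columns (outfmt 6), got %d in %s",
                 ncol(df), basename(path))
  names(df) <- .BLAST6_COLS
  df$pident <- as.numeric(df$pident)
  if (any(is.na(df$pident) | df$pident < 0 | df$pident > 100))
    .schemaError("pident outside [0,100] in %s", basename(path))
  for (col in c("aln_len", "q_start", "q_end", "t_start", "t_end"))
    df[[col]] <- as.integer(df[[col]])
  if (any(df$aln_len <= 0L))
    .schemaError("non-positive alignment length in %s", basename(path))
  df
}

#' Write alignments in BLAST tabular (outfmt 6) layout
#'
#' @param alignments data.frame as returned by [readBlastTable()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBlastTable <- function(alignments, path) {
  .checkCols(alignments, .BLAST6_COLS, "alignments")
  write.table(alignments[, .BLAST6_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-sample coverage table
#'
#' Accepts either this package's canonical layout or a CoverM-style
#' per-sample table (`Contig`, `Mean`, `Covered Fraction`, `Read Count`);
#' in the latter case the sample ID is supplied by the caller.
#'
#' @param path TSV path.
#' @param sampleId sample ID to stamp when the file has no `sample_id`
#'   column.
#' @return data.frame with columns `contig_id`, `sample_id`, `mean_depth`,
#'   `covered_fraction`, `read_count`.
#' @export
readCoverageTable <- function(path, sampleId = NULL) {
  if (!file.exists(path)) .ioError("coverage table not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = c("NA", ""))
  df <- .applyAliases(df, .COVERAGE_ALIASES,
                      required = c("contig_id", "mean_depth",
                                   "covered_fraction", "read_count"),
                      what = basename(path))
  if (!"sample_id" %in% names(df)) {
    if (is.null(sampleId))
      .schemaError("%s has no sample_id column and no sampleId was supplied",
                   basename(path))
    df$sample_id <- sampleId
  }
  df$mean_depth <- as.numeric(df$mean_depth)
  df$covered_fraction <- as.numeric(df$covered_fraction)
  df$read_count <- as.integer(df$read_count)
  if (any(df$covered_fraction < 0 | df$covered_fraction > 1, na.rm = TRUE))
    .schemaError("covered_fraction outside [0,1] in %s", basename(path))
  if (any(df$mean_depth < 0, na.rm = TRUE))
    .schemaError("negative mean_depth in %s", basename(path))
  df[, c("contig_id", "sample_id", "mean_depth", "covered_fraction",
         "read_count")]
}

#' Write a table in the pipeline's TSV convention
#'
#' Tab-separated, header row, UTF-8, `"\n"` line endings, missing values as
#' `"NA"`, no quoting. All stage outputs go through this writer so that
#' `read* %then% writeViralTable` round-trips on typed fields.
#'
#' @param rows data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeViralTable <- function(rows, path) {
  ok <- tryCatch({
    con <- file(path, open = "wb")
    on.exit(close(con))
    write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE, na = "NA", eol = "\n",
                fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) .ioError("cannot write %s: %s", path,
                                  conditionMessage(e)))
  invisible(path)
}
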