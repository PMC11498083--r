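#' @importFrom methods new validObject is setClass setGeneric setMethod show
#' @importFrom stats setNames runif
#' @importFrom utils read.delim write.table modifyList
NULL

## Canonical CheckV quality tiers, in decreasing confidence order.
.QUALITY_TIERS <- c("Complete", "High-quality", "Medium-quality",
                    "Low-quality", "Not-determined")

.GENOME_TYPES <- c("dsDNA", "ssDNA", "RNA", "unknown")
.HOST_DOMAINS <- c("prokaryotic", "eukaryotic", "unknown")

## Separator used when sample names are prefixed onto contig headers.
.PREFIX_SEP <- "__"

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
## state afterwards so generators are pure functions of (parameters, seed).
.withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    .stopf("seed must be a single non-missing number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

.checkCols <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    .stopf("%s: missing required column(s): %s", what,
           paste(missing, collapse = ", "))
  invisible(df)
}

#' Normalize a CheckV quality string to its canonical tier
#'
#' Case-insensitive matching against the five canonical tiers
#' (`Complete`, `High-quality`, `Medium-quality`, `Low-quality`,
#' `Not-determined`); spaces and underscores are treated as hyphens.
#' Unrecognized strings map to `Not-determined` with a warning, so a typo in
#' an upstream table can never silently create a sixth tier.
#'
#' @param x character vector of quality strings.
#' @return character vector of canonical tier strings.
#' @examples
#' normalizeQualityTier(c("high-quality", "COMPLETE", "Low quality"))
#' @export
normalizeQualityTier <- function(x) {
  x <- as.character(x)
  key <- tolower(gsub("[ _]", "-", trimws(x)))
  canon <- setNames(.QUALITY_TIERS, tolower(.QUALITY_TIERS))
  out <- canon[key]
  out[is.na(x) | key == "" | key == "na"] <- "Not-determined"
  bad <- which(is.na(out))
  if (length(bad)) {
    .warnf("unknown quality tier(s) mapped to Not-determined: %s",
           paste(unique(x[bad]), collapse = ", "))
    out[bad] <- "Not-determined"
  }
  unname(out)
}

## Union length of 1-based inclusive intervals.
.unionWidth <- function(start, end) {
  if (!length(start)) return(0L)
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(start = start, end = end))))
}

.assertNoDuplicates <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    .stopf("duplicate %s: %s", what, paste(dup, collapse = ", "))
  invisible(ids)
}
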