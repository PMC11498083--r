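#' VOTUClusterSet: species-level vOTU clusters
#'
#' Container for the result of greedy ANI/AF clustering. Each cluster is a
#' representative (its longest member; ties broken by lexicographically
#' smallest ID) together with the members assigned to it. The clusters
#' partition the input ID set. `memberStats` records, for every
#' non-representative member, the global ANI and aligned fraction (AF)
#' against its representative.
#'
#' @slot clusters named list; names are representative IDs, elements are
#'   character vectors of member IDs (representative included, first).
#' @slot memberStats data.frame with columns `member_id`,
#'   `representative_id`, `ani`, `af` (one row per non-representative
#'   member).
#' @slot lengths named integer vector of sequence lengths (bp) covering all
#'   member IDs.
#'
#' @seealso [greedyCluster()], [representatives()], [clusterMembers()]
#' @export
setClass("VOTUClusterSet",
  representation(clusters = "list", memberStats = "data.frame",
                 lengths = "integer"))

setValidity("VOTUClusterSet", function(object) {
  cl <- object@clusters
  if (length(cl) == 0L) return(TRUE)
  if (is.null(names(cl)) || any(!nzchar(names(cl))))
    return("clusters must be named by representative ID")
  members <- unlist(cl, use.names = FALSE)
  if (anyDuplicated(members))
    return("clusters do not partition the ID set (duplicated member)")
  for (rep_id in names(cl)) {
    mem <- cl[[rep_id]]
    if (!rep_id %in% mem)
      return(sprintf("representative %s not among its members", rep_id))
    len <- object@lengths[mem]
    if (anyNA(len))
      return("member without a recorded length")
    ## representative must be the longest member; ties -> smallest ID
    best <- mem[order(-len, mem)][1L]
    if (best != rep_id)
      return(sprintf("representative %s is not the longest member", rep_id))
  }
  TRUE
})

#' @describeIn VOTUClusterSet compact display
#' @param object a `VOTUClusterSet`
#' @export
setMethod("show", "VOTUClusterSet", function(object) {
  n <- length(object@clusters)
  sizes <- lengths(object@clusters)
  cat("VOTUClusterSet with", n, "clusters over",
      sum(sizes), "sequences\n")
  if (n) {
    cat("  singletons:", sum(sizes == 1L),
        "| largest cluster:", max(sizes), "members\n")
    preview <- utils::head(names(object@clusters), 3L)
    cat("  representatives:", paste(preview, collapse = ", "),
        if (n > 3L) "..." else "", "\n")
  }
  invisible(NULL)
})

#' @export
setGeneric("representatives", function(x, ...) standardGeneric("representatives"))

#' @describeIn VOTUClusterSet representative IDs, one per cluster
#' @param x a `VOTUClusterSet`
#' @param ... unused
#' @export
setMethod("representatives", "VOTUClusterSet", function(x, ...) names(x@clusters))

#' @export
setGeneric("clusterMembers", function(x, ...) standardGeneric("clusterMembers"))

#' @describeIn VOTUClusterSet named list of member IDs per cluster
#' @export
setMethod("clusterMembers", "VOTUClusterSet", function(x, ...) x@clusters)

#' @export
setGeneric("memberStats", function(x, ...) standardGeneric("memberStats"))

#' @describeIn VOTUClusterSet per-member ANI/AF versus the representative
#' @export
setMethod("memberStats", "VOTUClusterSet", function(x, ...) x@memberStats)

#' @describeIn VOTUClusterSet number of clusters
#' @export
setMethod("length", "VOTUClusterSet", function(x) length(x@clusters))

#' Cluster membership as a data.frame
#'
#' One row per sequence, with its representative; the serialized form of a
#' [VOTUClusterSet] used in the cluster-membership TSV.
#'
#' @param x a `VOTUClusterSet`
#' @return data.frame with columns `representative_id`, `member_id`.
#' @export
clusterTable <- function(x) {
  stopifnot(is(x, "VOTUClusterSet"))
  cl <- x@clusters
  data.frame(
    representative_id = rep(names(cl), lengths(cl)),
    member_id = unlist(cl, use.names = FALSE),
    stringsAsFactors = FALSE)
}

#' VOTUCoverage: vOTU-by-sample abundance matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' coverage matrix built over vOTU representatives (or vBins) and samples.
#' Assays: `depth` (mean read depth), `coveredFraction` (horizontal
#' coverage in \[0,1\]), `readCount`. Row metadata carries the detection
#' annotations (scores, quality tiers, taxonomy, ...). The invariant
#' `depth == 0` wherever `coveredFraction == 0` is enforced.
#'
#' @seealso [buildCoverageMatrix()], [applyHorizontalCoverage()]
#' @export
setClass("VOTUCoverage", contains = "SummarizedExperiment")

setValidity("VOTUCoverage", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  need <- c("depth", "coveredFraction", "readCount")
  if (!all(need %in% an))
    return(sprintf("assays must include %s", paste(need, collapse = ", ")))
  d <- SummarizedExperiment::assay(object, "depth")
  cf <- SummarizedExperiment::assay(object, "coveredFraction")
  if (any(cf < 0 | cf > 1, na.rm = TRUE))
    return("coveredFraction outside [0,1]")
  if (any(d[cf == 0] != 0, na.rm = TRUE))
    return("nonzero depth where coveredFraction is 0")
  if (anyDuplicated(rownames(object)))
    return("duplicated row keys")
  TRUE
})

#' @export
setGeneric("abundance", function(x, ...) standardGeneric("abundance"))

#' @describeIn VOTUCoverage the mean-depth assay matrix
#' @param x a `VOTUCoverage`
#' @param ... unused
#' @export
setMethod("abundance", "VOTUCoverage", function(x, ...)
  SummarizedExperiment::assay(x, "depth"))

#' @export
setGeneric("coveredFraction", function(x, ...) standardGeneric("coveredFraction"))

#' @describeIn VOTUCoverage the horizontal-coverage assay matrix
#' @export
setMethod("coveredFraction", "VOTUCoverage", function(x, ...)
  SummarizedExperiment::assay(x, "coveredFraction"))

#' @export
setGeneric("readCounts", function(x, ...) standardGeneric("readCounts"))

#' @describeIn VOTUCoverage the read-count assay matrix
#' @export
setMethod("readCounts", "VOTUCoverage", function(x, ...)
  SummarizedExperiment::assay(x, "readCount"))

#' @describeIn VOTUCoverage compact display
#' @param object a `VOTUCoverage`
#' @export
setMethod("show", "VOTUCoverage", function(object) {
  cat("VOTUCoverage:", nrow(object), "vOTUs x", ncol(object), "samples\n")
  d <- SummarizedExperiment::assay(object, "depth")
  cat("  nonzero cells:", sum(d > 0), "/", length(d), "\n")
  callNextMethod()
})
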