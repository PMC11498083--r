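#' Merge local alignments into per-pair global ANI and aligned fractions
#'
#' Collapses BLAST-style local alignments (HSPs) between sequence pairs
#' into one global statistic per pair: the ANI is the alignment-length-
#' weighted mean of percent identities across all aligned regions, and the
#' query/target aligned fractions are computed on the union of the aligned
#' intervals so overlapping HSPs are not double-counted. Self-hits are
#' discarded. When an aligner reports both orientations of a pair, the
#' orientation with the greater total aligned length is kept (ties: the
#' one whose query ID sorts first).
#'
#' @param alignments data.frame in the layout of [readBlastTable()]
#'   (coordinates 1-based inclusive; target start > end means reverse
#'   strand and is normalized here).
#' @param lengths named vector of sequence lengths (bp) covering every ID
#'   in `alignments`.
#' @return data.frame with one row per pair: `query_id`, `target_id`,
#'   `n_alns`, `ani` (in \[0,100\]), `qcov`, `tcov` (in \[0,1\]).
#' @examples
#' aln <- data.frame(query_id = "a", target_id = "b", pident = 95,
#'                   aln_len = 1000L, mismatches = 50L, gap_opens = 0L,
#'                   q_start = 1L, q_end = 1000L, t_start = 1L,
#'                   t_end = 1000L, evalue = 0, bitscore = 1800)
#' computePairwiseANI(aln, c(a = 1000L, b = 1000L))
#' @export
computePairwiseANI <- function(alignments, lengths) {
  .checkCols(alignments,
             c("query_id", "target_id", "pident", "aln_len",
               "q_start", "q_end", "t_start", "t_end"),
             "alignments")
  if (is.null(names(lengths)) || anyNA(names(lengths)))
    .configError("lengths must be a named vector")
  if (nrow(alignments) == 0L)
    return(data.frame(query_id = character(0), target_id = character(0),
                      n_alns = integer(0), ani = numeric(0),
                      qcov = numeric(0), tcov = numeric(0)))
  unknown <- setdiff(unique(c(alignments$query_id, alignments$target_id)),
                     names(lengths))
  if (length(unknown))
    .schemaError("alignment ID(s) without a declared length: %s",
                 paste(unknown, collapse = ", "))
  a <- alignments
  ## normalize coordinates (reverse-strand hits have start > end)
  qs <- pmin(a$q_start, a$q_end); qe <- pmax(a$q_start, a$q_end)
  ts <- pmin(a$t_start, a$t_end); te <- pmax(a$t_start, a$t_end)
  qlen <- as.numeric(lengths[a$query_id])
  tlen <- as.numeric(lengths[a$target_id])
  if (any(qe > qlen) || any(te > tlen))
    .schemaError("alignment coordinate exceeds declared sequence length")
  keep <- a$query_id != a$target_id
  if (!any(keep))
    return(data.frame(query_id = character(0), target_id = character(0),
                      n_alns = integer(0), ani = numeric(0),
                      qcov = numeric(0), tcov = numeric(0)))
  a <- a[keep, , drop = FALSE]
  qs <- qs[keep]; qe <- qe[keep]; ts <- ts[keep]; te <- te[keep]

  key <- paste(a$query_id, a$target_id, sep = "\r")
  idx <- split(seq_len(nrow(a)), key)
  rows <- lapply(idx, function(i) {
    q <- a$query_id[i[1L]]; t <- a$target_id[i[1L]]
    tot <- sum(as.numeric(a$aln_len[i]))
    data.frame(
      query_id = q, target_id = t,
      n_alns = length(i),
      ani = sum(a$pident[i] * as.numeric(a$aln_len[i])) / tot,
      qcov = .unionWidth(qs[i], qe[i]) / as.numeric(lengths[[q]]),
      tcov = .unionWidth(ts[i], te[i]) / as.numeric(lengths[[t]]),
      total_aln_len = tot,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ## one row per unordered pair: keep the orientation with more aligned bases
  ukey <- ifelse(out$query_id < out$target_id,
                 paste(out$query_id, out$target_id, sep = "\r"),
                 paste(out$target_id, out$query_id, sep = "\r"))
  pick <- unlist(lapply(split(seq_len(nrow(out)), ukey), function(i) {
    if (length(i) == 1L) return(i)
    i[order(-out$total_aln_len[i], out$query_id[i])][1L]
  }), use.names = FALSE)
  out <- out[sort(pick), c("query_id", "target_id", "n_alns", "ani",
                           "qcov", "tcov"), drop = FALSE]
  rownames(out) <- NULL
  out
}

## AF of a pair = merged coverage of the shorter sequence; on a length tie,
## the larger of the two coverages.
.pairAF <- function(qcov, tcov, qlen, tlen) {
  ifelse(qlen < tlen, qcov, ifelse(tlen < qlen, tcov, pmax(qcov, tcov)))
}

#' Greedy centroid clustering into species-level vOTUs
#'
#' Sorts sequences by length descending (ties: ID ascending) and scans:
#' each still-unassigned sequence becomes a representative, and every
#' later unassigned sequence whose pair with that representative reaches
#' both thresholds joins it. A sequence joins the first qualifying
#' representative; sequences qualifying for none become singletons. The
#' alignment fraction (AF) of a pair is the merged coverage of the shorter
#' sequence. Default thresholds: ANI >= 95, AF >= 0.85 (both inclusive).
#'
#' @param pairs data.frame from [computePairwiseANI()].
#' @param lengths named vector of lengths covering every sequence to
#'   cluster (singletons without alignments included).
#' @param minAni minimum ANI, in \[0,100\].
#' @param minAf minimum aligned fraction, in \[0,1\].
#' @return a [VOTUClusterSet].
#' @export
greedyCluster <- function(pairs, lengths, minAni = 95, minAf = 0.85) {
  if (minAni < 0 || minAni > 100)
    .configError("minAni must be in [0,100]")
  if (minAf < 0 || minAf > 1)
    .configError("minAf must be in [0,1]")
  if (is.null(names(lengths)) || anyDuplicated(names(lengths)))
    .configError("lengths must be uniquely named")
  ids <- names(lengths)
  ord <- ids[order(-as.numeric(lengths), ids)]

  ## symmetric edge table keyed by the sorted ID pair
  edges <- new.env(parent = emptyenv(), size = max(16L, nrow(pairs) * 2L))
  if (nrow(pairs)) {
    af <- .pairAF(pairs$qcov, pairs$tcov,
                  as.numeric(lengths[pairs$query_id]),
                  as.numeric(lengths[pairs$target_id]))
    for (i in seq_len(nrow(pairs))) {
      q <- pairs$query_id[i]; t <- pairs$target_id[i]
      k <- if (q < t) paste(q, t, sep = "\r") else paste(t, q, sep = "\r")
      assign(k, c(pairs$ani[i], af[i]), envir = edges)
    }
  }
  lookup <- function(a, b) {
    k <- if (a < b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
    if (exists(k, envir = edges, inherits = FALSE))
      get(k, envir = edges) else NULL
  }

  assigned <- setNames(rep(FALSE, length(ord)), ord)
  clusters <- list()
  stats <- list()
  for (i in seq_along(ord)) {
    rep_id <- ord[i]
    if (assigned[[rep_id]]) next
    assigned[[rep_id]] <- TRUE
    members <- rep_id
    if (i < length(ord)) {
      for (cand in ord[(i + 1L):length(ord)]) {
        if (assigned[[cand]]) next
        e <- lookup(rep_id, cand)
        if (!is.null(e) && e[1L] >= minAni && e[2L] >= minAf) {
          assigned[[cand]] <- TRUE
          members <- c(members, cand)
          stats[[length(stats) + 1L]] <- data.frame(
            member_id = cand, representative_id = rep_id,
            ani = e[1L], af = e[2L], stringsAsFactors = FALSE)
        }
      }
    }
    clusters[[rep_id]] <- members
  }
  memberStats <- if (length(stats)) do.call(rbind, stats)
    else data.frame(member_id = character(0),
                    representative_id = character(0),
                    ani = numeric(0), af = numeric(0))
  new("VOTUClusterSet", clusters = clusters, memberStats = memberStats,
      lengths = setNames(as.integer(lengths), names(lengths)))
}

#' Extract the representative sequences of a cluster set
#'
#' One record per cluster, named by the representative ID, in cluster
#' order. The result is invariant under shuffling of the clustering input
#' because the greedy scan order is fully determined by (length, ID).
#'
#' @param clusters a [VOTUClusterSet].
#' @param contigs named [Biostrings::DNAStringSet] holding at least every
#'   representative's sequence.
#' @return a [Biostrings::DNAStringSet] of representatives.
#' @export
selectRepresentativeFasta <- function(clusters, contigs) {
  reps <- representatives(clusters)
  missing <- setdiff(reps, names(contigs))
  if (length(missing))
    .schemaError("representative(s) without a sequence: %s",
                 paste(missing, collapse = ", "))
  contigs[reps]
}
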