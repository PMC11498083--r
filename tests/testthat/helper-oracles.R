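## Independent reference implementations used to check the package's
## algorithms. These deliberately use different machinery (position-wise
## logical vectors, literal definition scans) from the implementation.

## Exact-arithmetic per-pair ANI/coverage oracle. Percent identities are
## carried as integer thousandths so the weighted mean is a ratio of
## integer sums; coverage is counted on per-position logical vectors.
oracle_pairwise_ani <- function(alignments, lengths) {
  a <- alignments[alignments$query_id != alignments$target_id, , drop = FALSE]
  if (!nrow(a)) return(NULL)
  key <- paste(a$query_id, a$target_id, sep = "|")
  out <- list()
  for (k in unique(key)) {
    i <- which(key == k)
    q <- a$query_id[i[1]]; t <- a$target_id[i[1]]
    pident_m <- round(a$pident[i] * 1000)        # integer thousandths
    wsum <- sum(pident_m * as.numeric(a$aln_len[i]))
    lsum <- sum(as.numeric(a$aln_len[i]))
    qmask <- logical(lengths[[q]]); tmask <- logical(lengths[[t]])
    for (j in i) {
      qs <- min(a$q_start[j], a$q_end[j]); qe <- max(a$q_start[j], a$q_end[j])
      ts <- min(a$t_start[j], a$t_end[j]); te <- max(a$t_start[j], a$t_end[j])
      qmask[qs:qe] <- TRUE
      tmask[ts:te] <- TRUE
    }
    out[[k]] <- data.frame(
      query_id = q, target_id = t, n_alns = length(i),
      ani = (wsum / lsum) / 1000,
      qcov = sum(qmask) / lengths[[q]],
      tcov = sum(tmask) / lengths[[t]],
      total_aln_len = lsum, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  ## collapse to unordered pairs: larger total aligned length wins,
  ## ties broken by query ID
  ukey <- ifelse(res$query_id < res$target_id,
                 paste(res$query_id, res$target_id, sep = "|"),
                 paste(res$target_id, res$query_id, sep = "|"))
  keep <- unlist(lapply(split(seq_len(nrow(res)), ukey), function(i) {
    i[order(-res$total_aln_len[i], res$query_id[i])][1]
  }))
  res <- res[sort(keep), c("query_id", "target_id", "n_alns", "ani",
                           "qcov", "tcov")]
  rownames(res) <- NULL
  res
}

## Literal sorted-scan greedy clustering, straight from the definition.
oracle_greedy <- function(pairs, lengths, minAni = 95, minAf = 0.85) {
  ids <- names(lengths)[order(-as.numeric(lengths), names(lengths))]
  n <- length(ids)
  ani <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  af <- ani
  if (!is.null(pairs) && nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      q <- pairs$query_id[i]; t <- pairs$target_id[i]
      ql <- lengths[[q]]; tl <- lengths[[t]]
      a <- if (ql < tl) pairs$qcov[i]
           else if (tl < ql) pairs$tcov[i]
           else max(pairs$qcov[i], pairs$tcov[i])
      ani[q, t] <- ani[t, q] <- pairs$ani[i]
      af[q, t] <- af[t, q] <- a
    }
  }
  assigned <- setNames(rep(FALSE, n), ids)
  clusters <- list()
  for (r in ids) {
    if (assigned[[r]]) next
    assigned[[r]] <- TRUE
    mem <- r
    later <- ids[seq_along(ids) > match(r, ids)]
    for (m in later) {
      if (assigned[[m]]) next
      if (!is.na(ani[r, m]) && ani[r, m] >= minAni && af[r, m] >= minAf) {
        assigned[[m]] <- TRUE
        mem <- c(mem, m)
      }
    }
    clusters[[r]] <- mem
  }
  clusters
}

## Position-wise coverage counting oracle.
oracle_covered <- function(placements, len) {
  depth <- integer(len)
  for (i in seq_len(nrow(placements))) {
    span <- placements$start[i]:placements$end[i]
    depth[span] <- depth[span] + 1L
  }
  list(covered_fraction = sum(depth > 0) / len,
       mean_depth = sum(depth) / len,
       read_count = nrow(placements))
}

## Random alignment-table generator for fuzzing (coordinates always within
## the declared lengths; self-hits and duplicate orientations allowed).
random_alignment_table <- function(nSeq, nAln, seed,
                                   lenRange = c(500L, 3000L),
                                   tieLengths = FALSE) {
  set.seed(seed)
  ids <- sprintf("s%03d", seq_len(nSeq))
  lens <- if (tieLengths) setNames(rep(1500L, nSeq), ids)
    else setNames(sample(lenRange[1]:lenRange[2], nSeq, replace = TRUE), ids)
  rows <- lapply(seq_len(nAln), function(i) {
    q <- sample(ids, 1); t <- sample(ids, 1)
    ql <- lens[[q]]; tl <- lens[[t]]
    qs <- sample.int(ql, 1); qe <- sample(qs:ql, 1)
    ts <- sample.int(tl, 1); te <- sample(ts:tl, 1)
    rev <- runif(1) < 0.3   # reverse-strand target convention
    data.frame(query_id = q, target_id = t,
               pident = round(runif(1, 70, 100), 3),
               aln_len = max(qe - qs + 1L, te - ts + 1L),
               mismatches = 0L, gap_opens = 0L,
               q_start = qs, q_end = qe,
               t_start = if (rev) te else ts,
               t_end = if (rev) ts else te,
               evalue = 0, bitscore = 100, stringsAsFactors = FALSE)
  })
  list(alignments = do.call(rbind, rows), lengths = lens)
}

## Random PairwiseANI-style tables for clustering fuzzing.
random_pair_table <- function(nSeq, seed, tieLengths = FALSE) {
  set.seed(seed)
  ids <- sprintf("q%02d", seq_len(nSeq))
  lens <- if (tieLengths) setNames(rep(2000L, nSeq), ids)
    else setNames(sample(1000:5000, nSeq, replace = TRUE), ids)
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < 0.6
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs))
    return(list(pairs = data.frame(query_id = character(0),
                                   target_id = character(0),
                                   n_alns = integer(0), ani = numeric(0),
                                   qcov = numeric(0), tcov = numeric(0)),
                lengths = lens))
  list(pairs = data.frame(
         query_id = pairs[, 1], target_id = pairs[, 2],
         n_alns = 1L,
         ani = round(runif(nrow(pairs), 85, 100), 2),
         qcov = round(runif(nrow(pairs), 0.5, 1), 3),
         tcov = round(runif(nrow(pairs), 0.5, 1), 3),
         stringsAsFactors = FALSE),
       lengths = lens)
}

## Cluster set -> membership vector keyed by member ID (for ARI).
partition_of <- function(clusterset) {
  tab <- clusterTable(clusterset)
  setNames(tab$representative_id, tab$member_id)
}

run_cli <- function(...) runSubcommand(c(...))

## Fingerprint of every data file (tables + FASTA) under a workdir;
## summary reports carry timestamps and are excluded by design.
workdir_digest <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE,
                           pattern = "\\.(tsv|fna)$"))
  vapply(files, function(f) paste(tools::md5sum(f)), character(1))
}
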