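## Hamming distance between two equal-length DNA strings (byte compare).
.hamming <- function(a, b) sum(charToRaw(a) != charToRaw(b))

.randomDNA <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Mutate a sequence to an exact divergence
#'
#' Substitutes exactly `round(divergence * length)` positions to a
#' different base (substitution-only, no indels), at positions chosen by
#' the seeded generator. Length is preserved and the realized Hamming
#' distance is exactly the forced count, which keeps percent identity in
#' closed form for the clustering fixtures.
#'
#' @param seq a single DNA string (character or
#'   [Biostrings::DNAString]).
#' @param divergence fraction of positions to substitute, in \[0,1\].
#' @param seed RNG seed.
#' @return character string of the same length.
#' @examples
#' mutateSequence(strrep("ACGT", 250), 0.03, seed = 1)
#' @export
mutateSequence <- function(seq, divergence, seed) {
  seq <- as.character(seq)
  if (divergence < 0 || divergence > 1)
    .configError("divergence must lie in [0,1]")
  n <- nchar(seq)
  k <- round(divergence * n)
  if (k == 0L) return(seq)
  .withSeed(seed, {
    pos <- sample.int(n, k)
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    bases <- c("A", "C", "G", "T")
    for (p in pos) {
      alt <- setdiff(bases, chars[p])
      chars[p] <- alt[sample.int(length(alt), 1L)]
    }
    paste(chars, collapse = "")
  })
}

#' Generate a planted-cluster viral community
#'
#' Emits a sequence set with known species-level cluster structure, the
#' truth table, and a synthetic all-vs-all alignment table in BLAST
#' tabular layout, derived from the sequences themselves rather than from
#' an aligner. Each cluster has an ancestor (kept as its longest member)
#' and members that are truncated mutants of it at divergence at most
#' `dWithin`, so the identity of every member against its cluster
#' representative is at least `100 * (1 - dWithin)`. Ancestors are
#' independent random sequences; their mutual divergence is checked
#' against `dBetween` and no between-cluster alignments are emitted
#' (at 25% between-cluster divergence a local aligner would report none).
#' Within-cluster alignments span the full shorter sequence with
#' `pident = 100 * (1 - observed divergence)`.
#'
#' @param nClusters number of planted clusters.
#' @param membersPerCluster members per cluster (ancestor included).
#' @param lenRange integer range the ancestor lengths are drawn from.
#' @param dWithin maximum member-to-ancestor divergence.
#' @param dBetween minimum ancestor-to-ancestor divergence; must exceed
#'   `dWithin`.
#' @param seed RNG seed.
#' @return list with `sequences` (a named [Biostrings::DNAStringSet]),
#'   `truth` (data.frame `contig_id`, `cluster`, `is_ancestor`), and
#'   `alignments` (BLAST-tabular data.frame).
#' @export
generateCommunity <- function(nClusters = 20L, membersPerCluster = 5L,
                              lenRange = c(5000L, 15000L), dWithin = 0.03,
                              dBetween = 0.25, seed = 7L) {
  if (dWithin >= dBetween)
    .configError("dWithin must be smaller than dBetween")
  if (nClusters < 1L || membersPerCluster < 1L)
    .configError("nClusters and membersPerCluster must be positive")
  .withSeed(seed, {
    seqs <- character(0)
    truth <- list()
    alns <- list()
    for (c_i in seq_len(nClusters)) {
      L <- sample(seq(lenRange[1L], lenRange[2L]), 1L)
      ancestor <- .randomDNA(L)
      ids <- sprintf("cl%02d_m%02d", c_i, seq_len(membersPerCluster))
      members <- character(membersPerCluster)
      members[1L] <- ancestor
      for (j in seq_len(membersPerCluster)[-1L]) {
        d <- runif(1L, 0, dWithin)
        ## truncation keeps the ancestor the unique longest member;
        ## truncate-then-mutate makes the member-vs-ancestor identity
        ## exactly 100 * (1 - round(d * keepLen) / keepLen)
        keepLen <- L - 10L * (j - 1L)
        members[j] <- mutateSequence(substr(ancestor, 1L, keepLen), d,
                                     seed = sample.int(1e6, 1L))
      }
      names(members) <- ids
      seqs <- c(seqs, members)
      truth[[c_i]] <- data.frame(contig_id = ids, cluster = c_i,
                                 is_ancestor = seq_along(ids) == 1L,
                                 stringsAsFactors = FALSE)
      ## full-length (over the shorter) within-cluster alignments
      for (a in seq_len(membersPerCluster - 1L)) {
        for (b in seq((a + 1L), membersPerCluster)) {
          span <- min(nchar(members[a]), nchar(members[b]))
          mism <- .hamming(substr(members[a], 1L, span),
                           substr(members[b], 1L, span))
          alns[[length(alns) + 1L]] <- data.frame(
            query_id = ids[a], target_id = ids[b],
            pident = 100 * (1 - mism / span), aln_len = span,
            mismatches = mism, gap_opens = 0L,
            q_start = 1L, q_end = span, t_start = 1L, t_end = span,
            evalue = 0, bitscore = 2 * span, stringsAsFactors = FALSE)
        }
      }
    }
    truth <- do.call(rbind, truth)
    ## ancestors must really be mutually diverged
    anc <- truth$contig_id[truth$is_ancestor]
    for (i in seq_along(anc)[-1L]) {
      for (j in seq_len(i - 1L)) {
        span <- min(nchar(seqs[[anc[i]]]), nchar(seqs[[anc[j]]]))
        d <- .hamming(substr(seqs[[anc[i]]], 1L, span),
                      substr(seqs[[anc[j]]], 1L, span)) / span
        if (d < dBetween)
          .configError("ancestors %s and %s diverged only %.3f < dBetween",
                       anc[i], anc[j], d)
      }
    }
    alignments <- if (length(alns)) do.call(rbind, alns)
      else stats::setNames(data.frame(matrix(nrow = 0, ncol = 12)),
                           .BLAST6_COLS)
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- names(seqs)
    list(sequences = out, truth = truth, alignments = alignments)
  })
}

#' Generate a detection fixture with planted preset outcomes
#'
#' Constructs detector-summary and quality-summary rows so that exactly
#' `nPassConservative` records pass the conservative preset and exactly
#' `nPassConservative + nPassRelaxedOnly` pass the relaxed one:
#' conservative passers draw score from \[0.8, 1\] with >= 1 hallmark;
#' relaxed-only passers draw score from \[0.7, 0.8) with 0 hallmarks;
#' failures fall below the score floor and/or the 2500 bp length floor.
#' Gene counts are planted so every preset passer also passes the default
#' gene filters.
#'
#' @param nPassConservative,nPassRelaxedOnly,nFail planted counts.
#' @param seed RNG seed.
#' @param sampleId sample stamped on the records.
#' @return list with `genomad` and `checkv` data.frames (the two table
#'   dialects) and `records` (the joined detection records).
#' @export
generateDetectionFixture <- function(nPassConservative, nPassRelaxedOnly,
                                     nFail, seed, sampleId = "S1") {
  if (min(nPassConservative, nPassRelaxedOnly, nFail) < 0)
    .configError("planted counts must be >= 0")
  .withSeed(seed, {
    n <- nPassConservative + nPassRelaxedOnly + nFail
    grp <- rep(c("cons", "rel", "fail"),
               c(nPassConservative, nPassRelaxedOnly, nFail))
    score <- numeric(n); len <- integer(n); hall <- integer(n)
    for (i in seq_len(n)) {
      if (grp[i] == "cons") {
        score[i] <- runif(1L, 0.8, 1.0)
        len[i] <- sample(2500:60000, 1L)
        hall[i] <- sample(1:5, 1L)
      } else if (grp[i] == "rel") {
        score[i] <- runif(1L, 0.7, 0.7999)
        len[i] <- sample(2500:60000, 1L)
        hall[i] <- 0L
      } else {
        mode <- sample(1:3, 1L)
        score[i] <- if (mode == 2L) runif(1L, 0.7, 1.0) else runif(1L, 0, 0.6999)
        len[i] <- if (mode == 1L) sample(2500:60000, 1L)
          else sample(300:2499, 1L)
        hall[i] <- sample(0:3, 1L)
      }
    }
    viral <- ifelse(grp == "fail", sample(0:3, n, replace = TRUE),
                    sample(1:6, n, replace = TRUE))
    host <- ifelse(grp == "fail", sample(0:5, n, replace = TRUE),
                   vapply(viral, function(v) sample(0:v, 1L), integer(1)))
    ngenes <- pmax(viral + host, hall) + sample(0:4, n, replace = TRUE)
    quality <- sample(.QUALITY_TIERS, n, replace = TRUE,
                      prob = c(0.02, 0.03, 0.1, 0.55, 0.3))
    ids <- sprintf("%s%sctg%04d", sampleId, .PREFIX_SEP, seq_len(n))
    taxonomy <- sample(
      c("Viruses;Duplodnaviria;Heunggongvirae;Uroviricota;Caudoviricetes",
        "Viruses;Monodnaviria;Sangervirae;Phixviricota;Malgrandaviricetes;Petitvirales;Microviridae",
        ""), n, replace = TRUE, prob = c(0.8, 0.1, 0.1))
    genomad <- data.frame(
      seq_name = ids, length = len, topology = "linear",
      coordinates = NA_character_, n_genes = ngenes, virus_score = score,
      n_hallmarks = hall, taxonomy = taxonomy, stringsAsFactors = FALSE)
    checkv <- data.frame(
      contig_id = ids, contig_length = len, gene_count = ngenes,
      viral_genes = viral, host_genes = host, checkv_quality = quality,
      completeness = round(runif(n, 5, 100), 2), provirus = "No",
      stringsAsFactors = FALSE)
    records <- makeDetectionRecords(
      contig_id = ids, sample_id = sampleId, length = len,
      virus_score = score, n_hallmarks = hall, n_genes = ngenes,
      viral_genes = viral, host_genes = host, quality = quality,
      taxonomy = taxonomy)
    list(genomad = genomad, checkv = checkv, records = records)
  })
}

#' Generate a gene-filter fixture with planted outcomes
#'
#' Plants records so that under the default gene filters exactly `nKeep`
#' pass, `nDropViral` fail the minimum-viral-genes rule, and `nDropRatio`
#' fail the host/viral ratio rule.
#'
#' @param nKeep,nDropViral,nDropRatio planted counts.
#' @param seed RNG seed.
#' @return detection-record data.frame.
#' @export
generateGeneFilterFixture <- function(nKeep, nDropViral, nDropRatio, seed) {
  .withSeed(seed, {
    n <- nKeep + nDropViral + nDropRatio
    grp <- rep(c("keep", "viral", "ratio"), c(nKeep, nDropViral, nDropRatio))
    viral <- integer(n); host <- integer(n)
    for (i in seq_len(n)) {
      if (grp[i] == "keep") {
        viral[i] <- sample(1:6, 1L); host[i] <- sample(0:viral[i], 1L)
      } else if (grp[i] == "viral") {
        viral[i] <- 0L; host[i] <- sample(0:5, 1L)
      } else {
        viral[i] <- sample(1:4, 1L)
        host[i] <- viral[i] + sample(1:5, 1L)
      }
    }
    makeDetectionRecords(
      contig_id = sprintf("gf_ctg%04d", seq_len(n)),
      length = sample(2500:60000, n, replace = TRUE),
      virus_score = runif(n, 0.8, 1), n_hallmarks = 1L,
      n_genes = viral + host, viral_genes = viral, host_genes = host)
  })
}

#' Generate a sequence-quality fixture with planted outcomes
#'
#' Plants records against the conservative sequence filter (longer than
#' 5 kb, or longer than 1 kb and Complete/High/Medium quality): `nKeepLong`
#' pass via the 5 kb branch, `nKeepQuality` via the quality branch, and
#' `nDrop` fail both.
#'
#' @param nKeepLong,nKeepQuality,nDrop planted counts.
#' @param seed RNG seed.
#' @return detection-record data.frame.
#' @export
generateQualityFixture <- function(nKeepLong, nKeepQuality, nDrop, seed) {
  .withSeed(seed, {
    n <- nKeepLong + nKeepQuality + nDrop
    grp <- rep(c("long", "qual", "drop"), c(nKeepLong, nKeepQuality, nDrop))
    good <- c("Complete", "High-quality", "Medium-quality")
    bad <- c("Low-quality", "Not-determined")
    len <- integer(n); quality <- character(n)
    for (i in seq_len(n)) {
      if (grp[i] == "long") {
        len[i] <- sample(5001:60000, 1L)
        quality[i] <- sample(bad, 1L)   # must pass via length alone
      } else if (grp[i] == "qual") {
        len[i] <- sample(1001:5000, 1L)
        quality[i] <- sample(good, 1L)
      } else if (runif(1L) < 0.5) {
        len[i] <- sample(1001:5000, 1L); quality[i] <- sample(bad, 1L)
      } else {
        len[i] <- sample(200:1000, 1L); quality[i] <- sample(good, 1L)
      }
    }
    makeDetectionRecords(
      contig_id = sprintf("qf_ctg%04d", seq_len(n)),
      length = len, quality = quality, virus_score = runif(n, 0.8, 1),
      n_hallmarks = 1L, n_genes = 4L, viral_genes = 2L, host_genes = 1L)
  })
}

#' Generate read placements hitting target covered fractions
#'
#' Lays non-overlapping spans of `readLen` bases down from position 1
#' until `round(target * length)` bases are covered (the last span is
#' shortened), so the realized covered fraction equals the target exactly
#' whenever `target * length` rounds to an integer, and is within 1/length
#' otherwise.
#'
#' @param lengths named vector of contig lengths.
#' @param targetCf covered-fraction target(s) in \[0,1\]; a scalar or a
#'   vector parallel to `lengths`.
#' @param seed RNG seed (reserved; the tiling itself is deterministic).
#' @param readLen span length in bp.
#' @return data.frame with `contig_id`, `start`, `end`.
#' @export
generatePlacements <- function(lengths, targetCf, seed = 1L, readLen = 100L) {
  if (any(targetCf < 0 | targetCf > 1))
    .configError("targetCf must lie in [0,1]")
  targetCf <- rep_len(targetCf, length(lengths))
  out <- list()
  for (i in seq_along(lengths)) {
    id <- names(lengths)[i]
    covered <- round(targetCf[i] * lengths[[i]])
    if (covered == 0) next
    starts <- seq(1L, covered, by = readLen)
    ends <- pmin(starts + readLen - 1L, covered)
    out[[id]] <- data.frame(contig_id = id, start = starts, end = ends,
                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
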