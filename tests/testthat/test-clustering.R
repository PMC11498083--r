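test_that("ANI merging matches its closed-form examples", {
  ## single full-length identical alignment
  one <- data.frame(query_id = "a", target_id = "b", pident = 100,
                    aln_len = 1000L, mismatches = 0L, gap_opens = 0L,
                    q_start = 1L, q_end = 1000L, t_start = 1L,
                    t_end = 1000L, evalue = 0, bitscore = 1)
  p <- computePairwiseANI(one, c(a = 1000L, b = 1000L))
  expect_equal(p$ani, 100)
  expect_equal(p$qcov, 1)
  expect_equal(p$tcov, 1)

  ## two disjoint HSPs -> length-weighted mean
  two <- rbind(one, one)
  two$pident <- c(90, 100)
  two$aln_len <- 500L
  two$q_start <- c(1L, 501L); two$q_end <- c(500L, 1000L)
  two$t_start <- c(1L, 501L); two$t_end <- c(500L, 1000L)
  p <- computePairwiseANI(two, c(a = 1000L, b = 1000L))
  expect_equal(p$ani, 95)
  expect_equal(p$qcov, 1)

  ## overlapping HSPs: coverage unions, identity weighting does not
  ov <- two
  ov$q_start <- c(1L, 401L); ov$q_end <- c(600L, 1000L)
  ov$aln_len <- 600L
  p <- computePairwiseANI(ov, c(a = 1000L, b = 1000L))
  expect_equal(p$qcov, 1)      # union 1..1000, not 1.2
  expect_equal(p$ani, 95)      # equal weights -> plain mean
})

test_that("ANI merging handles self-hits, strand, and unknown IDs", {
  tab <- random_alignment_table(6, 30, seed = 11)
  selfhit <- tab$alignments[1, ]
  selfhit$target_id <- selfhit$query_id
  p <- computePairwiseANI(rbind(tab$alignments, selfhit), tab$lengths)
  expect_false(any(p$query_id == p$target_id))

  rev <- tab$alignments[1, ]
  tmp <- rev$t_start; rev$t_start <- rev$t_end; rev$t_end <- tmp
  expect_silent(computePairwiseANI(rev, tab$lengths))

  bad <- tab$alignments[1, ]
  bad$query_id <- "ghost"
  expect_error(computePairwiseANI(bad, tab$lengths),
               class = "viromics_schema_error")
  bad <- tab$alignments[1, ]
  bad$q_end <- tab$lengths[[bad$query_id]] + 10L
  expect_error(computePairwiseANI(bad, tab$lengths),
               class = "viromics_schema_error")
})

test_that("ANI merging agrees with the exact-arithmetic oracle on random tables", {
  for (s in 1:25) {
    tab <- random_alignment_table(sample(3:12, 1), sample(10:60, 1),
                                  seed = 1000 + s)
    got <- computePairwiseANI(tab$alignments, tab$lengths)
    want <- oracle_pairwise_ani(tab$alignments, tab$lengths)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
      next
    }
    got <- got[order(got$query_id, got$target_id), ]
    want <- want[order(want$query_id, want$target_id), ]
    expect_identical(got$query_id, want$query_id)
    expect_lt(max(abs(got$ani - want$ani)), 1e-9)
    expect_lt(max(abs(got$qcov - want$qcov)), 1e-9)
    expect_lt(max(abs(got$tcov - want$tcov)), 1e-9)
  }
})

test_that("greedy clustering applies thresholds against representatives only", {
  lens <- c(A = 10000L, B = 8000L, C = 8000L)
  pairs <- data.frame(
    query_id = c("A", "A"), target_id = c("B", "C"), n_alns = 1L,
    ani = c(96, 90), qcov = c(0.9, 0.9), tcov = c(0.90, 0.90))
  cl <- greedyCluster(pairs, lens)
  expect_identical(clusterMembers(cl), list(A = c("A", "B"), C = "C"))

  ## chain A-B, B-C qualifying, A-C absent: C never joins via B
  chain <- data.frame(
    query_id = c("A", "B"), target_id = c("B", "C"), n_alns = 1L,
    ani = c(97, 97), qcov = c(0.95, 0.95), tcov = c(0.95, 0.95))
  lens2 <- c(A = 9000L, B = 8000L, C = 7000L)
  cl <- greedyCluster(chain, lens2)
  expect_identical(clusterMembers(cl), list(A = c("A", "B"), C = "C"))

  ## no alignments: all singletons
  cl <- greedyCluster(pairs[0, ], lens)
  expect_identical(length(cl), 3L)
  expect_true(all(lengths(clusterMembers(cl)) == 1L))

  expect_error(greedyCluster(pairs, lens, minAni = 101),
               class = "viromics_config_error")
  expect_error(greedyCluster(pairs, lens, minAf = -0.1),
               class = "viromics_config_error")
})

test_that("AF is evaluated on the shorter sequence of each pair", {
  ## query longer: AF = tcov; fails if tcov low even when qcov high
  lens <- c(long = 10000L, short = 5000L)
  pairs <- data.frame(query_id = "long", target_id = "short", n_alns = 1L,
                      ani = 99, qcov = 0.5, tcov = 0.9)
  cl <- greedyCluster(pairs, lens)
  expect_identical(length(cl), 1L)
  pairs$tcov <- 0.5; pairs$qcov <- 0.9
  expect_identical(length(greedyCluster(pairs, lens)), 2L)
  ## tie: max of the two coverages
  lens_tie <- c(a = 5000L, b = 5000L)
  pairs_tie <- data.frame(query_id = "a", target_id = "b", n_alns = 1L,
                          ani = 99, qcov = 0.5, tcov = 0.9)
  expect_identical(length(greedyCluster(pairs_tie, lens_tie)), 1L)
})

test_that("greedy clustering matches the literal reference on random instances", {
  for (s in 1:60) {
    inst <- random_pair_table(sample(2:12, 1), seed = 2000 + s,
                              tieLengths = s %% 5 == 0)
    got <- clusterMembers(greedyCluster(inst$pairs, inst$lengths))
    want <- oracle_greedy(inst$pairs, inst$lengths)
    expect_identical(got, want)
  }
})

test_that("cluster sets satisfy partition and member-threshold invariants", {
  inst <- random_pair_table(12, seed = 77)
  cl <- greedyCluster(inst$pairs, inst$lengths)
  expect_setequal(unlist(clusterMembers(cl)), names(inst$lengths))
  st <- memberStats(cl)
  if (nrow(st)) {
    expect_true(all(st$ani >= 95))
    expect_true(all(st$af >= 0.85))
  }
  expect_true(validObject(cl))
})

test_that("representative FASTA is deterministic under input shuffling", {
  comm <- generateCommunity(nClusters = 5, membersPerCluster = 4,
                            lenRange = c(2000L, 5000L), seed = 3)
  lens <- setNames(Biostrings::width(comm$sequences),
                   names(comm$sequences))
  ref <- NULL
  for (s in 1:20) {
    set.seed(s)
    perm <- sample(nrow(comm$alignments))
    pairs <- computePairwiseANI(comm$alignments[perm, ],
                                lens[sample(length(lens))])
    cl <- greedyCluster(pairs, lens[sample(length(lens))])
    fasta <- selectRepresentativeFasta(cl, comm$sequences)
    sig <- paste(names(fasta), as.character(fasta), collapse = ";")
    if (is.null(ref)) ref <- sig
    expect_identical(sig, ref)
  }
  expect_identical(length(cl), 5L)
  expect_error(selectRepresentativeFasta(cl, comm$sequences[-1]),
               class = "viromics_schema_error")
})
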