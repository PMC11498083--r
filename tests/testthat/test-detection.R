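test_that("header prefixing is definitional, idempotent, and collision-safe", {
  seqs <- Biostrings::DNAStringSet(c(c1 = "ACGT", c2 = "GGCC"))
  out <- prefixHeaders(seqs, "S1")
  expect_identical(names(out), c("S1__c1", "S1__c2"))
  ## idempotence: already-prefixed IDs are untouched
  expect_identical(names(prefixHeaders(out, "S1")), names(out))
  ## disabled -> identity
  expect_identical(names(prefixHeaders(seqs, "S1", enabled = FALSE)),
                   c("c1", "c2"))
  expect_error(prefixHeaders(seqs, "bad sample"),
               class = "viromics_config_error")
  clash <- c("c1", "S1__c1")
  expect_error(prefixHeaders(clash, "S1"), "duplicate")
})

test_that("minimum-size filter keeps the inclusive boundary and order", {
  seqs <- Biostrings::DNAStringSet(c(a = strrep("A", 1000),
                                     b = strrep("C", 2500),
                                     c = strrep("G", 3000)))
  kept <- filterMinSeqSize(seqs, 2500L)
  expect_identical(names(kept), c("b", "c"))
  expect_identical(names(filterMinSeqSize(seqs, 0L)), names(seqs))
  expect_length(filterMinSeqSize(seqs[0], 100L), 0L)
})

test_that("score presets apply their printed thresholds inclusively", {
  r <- makeDetectionRecords(
    c("hi", "mid", "edge"),
    virus_score = c(0.85, 0.75, 0.80),
    length = c(3000L, 3000L, 2500L),
    n_hallmarks = c(2L, 2L, 1L), n_genes = 5L)
  expect_identical(passesPreset(r, "conservative"), c(TRUE, FALSE, TRUE))
  expect_identical(passesPreset(r, "relaxed"), c(TRUE, TRUE, TRUE))
  r$virus_score[1] <- NA
  expect_error(passesPreset(r), class = "viromics_schema_error")
})

test_that("preset passing is monotone in score, length and hallmarks", {
  set.seed(42)
  base <- makeDetectionRecords(
    sprintf("m%03d", 1:60),
    virus_score = round(runif(60, 0.5, 1), 3),
    length = sample(1000:6000, 60, replace = TRUE),
    n_hallmarks = sample(0:3, 60, replace = TRUE), n_genes = 10L)
  for (preset in c("conservative", "relaxed")) {
    before <- passesPreset(base, preset)
    bumped <- base
    bumped$virus_score <- pmin(1, bumped$virus_score + 0.1)
    bumped$length <- bumped$length + 1000L
    bumped$n_hallmarks <- bumped$n_hallmarks + 1L
    after <- passesPreset(bumped, preset)
    expect_false(any(before & !after))
  }
})

test_that("lineage scan resolves the most specific mapped rank", {
  m <- loadGenomeTypeMap()
  got <- inferGenomeType(
    c("Viruses;Duplodnaviria;Heunggongvirae;Uroviricota;Caudoviricetes",
      "",
      "Viruses;Riboviria;Orthornavirae;Lenarviricota"), m)
  expect_identical(got$genome_type, c("dsDNA", "unknown", "RNA"))
  expect_identical(got$host_domain, c("prokaryotic", "unknown", "prokaryotic"))

  ## two mapped ranks: the rightmost (more specific) one wins
  toy <- data.frame(taxon = c("Realm", "Family"),
                    genome_type = c("dsDNA", "ssDNA"),
                    host_domain = c("unknown", "eukaryotic"))
  got <- inferGenomeType("Viruses;Realm;Class;Family", toy)
  expect_identical(got$genome_type, "ssDNA")
  expect_identical(got$host_domain, "eukaryotic")
})

test_that("provirus reconciliation substitutes trimmed children for parents", {
  r1 <- makeDetectionRecords(
    c("A", "B"), is_provirus = c(FALSE, TRUE),
    parent_contig_id = c(NA, "B"),
    region_start = c(NA, 1L), region_end = c(NA, 9000L),
    length = c(4000L, 9000L), virus_score = 0.9, n_hallmarks = 1L,
    n_genes = 5L, viral_genes = 3L, host_genes = 1L)
  r2 <- makeDetectionRecords(
    "B_child", is_provirus = TRUE, parent_contig_id = "B",
    region_start = 100L, region_end = 5000L, length = 4901L,
    virus_score = 0.95, n_hallmarks = 2L, n_genes = 4L,
    viral_genes = 4L, host_genes = 0L, round = 2L)
  out <- reconcileProvirusRounds(r1, r2)
  expect_setequal(out$contig_id, c("A", "B|provirus_100_5000"))
  ## the non-provirus round-1 record is bit-identical
  expect_equal(out[out$contig_id == "A", names(r1)],
               r1[r1$contig_id == "A", ], ignore_attr = TRUE)
  ## round2 empty -> identity
  expect_equal(reconcileProvirusRounds(r1, NULL), r1)
  ## orphan child -> hard error
  r2$parent_contig_id <- "nope"
  expect_error(reconcileProvirusRounds(r1, r2), "parent",
               class = "viromics_schema_error")
})

test_that("a parent with two children yields n1 - 1 + 2 records and warns on overlap", {
  r1 <- makeDetectionRecords(
    c("A", "B", "C"), is_provirus = c(FALSE, TRUE, FALSE),
    parent_contig_id = c(NA, "B", NA),
    region_start = c(NA, 1L, NA), region_end = c(NA, 20000L, NA),
    length = c(4000L, 20000L, 3000L), virus_score = 0.9,
    n_hallmarks = 1L, n_genes = 5L, viral_genes = 3L, host_genes = 0L)
  kids <- makeDetectionRecords(
    c("k1", "k2"), is_provirus = TRUE, parent_contig_id = "B",
    region_start = c(100L, 4000L), region_end = c(5000L, 9000L),
    length = c(4901L, 5001L), virus_score = 0.9, n_hallmarks = 1L,
    n_genes = 3L, viral_genes = 2L, host_genes = 0L, round = 2L)
  expect_warning(out <- reconcileProvirusRounds(r1, kids), "overlapping")
  expect_identical(nrow(out), 3L - 1L + 2L)
  expect_true(all(c("B|provirus_100_5000", "B|provirus_4000_9000")
                  %in% out$contig_id))
  expect_false("B" %in% out$contig_id)
})

test_that("virus/provirus merge slices 1-based inclusive regions and keeps ID sets equal", {
  contigs <- Biostrings::DNAStringSet(c(parent = "AAAACGTTTT", v1 = "ACGTACGT"))
  recs <- makeDetectionRecords(
    c("v1", "parent|provirus_5_7"),
    is_provirus = c(FALSE, TRUE),
    parent_contig_id = c(NA, "parent"),
    region_start = c(NA, 5L), region_end = c(NA, 7L),
    length = c(8L, 3L), virus_score = 0.9, n_hallmarks = 1L,
    n_genes = 2L, viral_genes = 1L, host_genes = 0L)
  out <- mergeVirusProvirus(recs, contigs)
  expect_identical(names(out$sequences), out$table$contig_id)
  expect_identical(
    as.character(out$sequences[["parent|provirus_5_7"]]), "CGT")
  ## missing sequence is a hard error
  expect_error(mergeVirusProvirus(recs, contigs["parent"]),
               class = "viromics_schema_error")
})

test_that("joined detector tables become valid detection records", {
  fx <- generateDetectionFixture(5, 3, 4, seed = 9)
  gpath <- withr::local_tempfile(fileext = ".tsv")
  cpath <- withr::local_tempfile(fileext = ".tsv")
  writeViralTable(fx$genomad, gpath)
  writeViralTable(fx$checkv, cpath)
  recs <- asDetectionRecords(readDetectionTables(gpath, cpath), "S1")
  expect_identical(nrow(recs), 12L)
  expect_identical(recs$genome_type[recs$taxonomy != ""][1],
                   ifelse(grepl("Caudoviricetes",
                                recs$taxonomy[recs$taxonomy != ""][1]),
                          "dsDNA", "ssDNA"))
  expect_true(all(recs$quality %in% c("Complete", "High-quality",
                                      "Medium-quality", "Low-quality",
                                      "Not-determined")))
})
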