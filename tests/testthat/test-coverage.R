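test_that("covered_stats matches its closed-form example and guards spans", {
  st <- coveredStats(data.frame(start = c(1, 41), end = c(50, 80)), 100)
  expect_equal(st$covered_fraction, 0.8)
  expect_equal(st$mean_depth, 0.9)
  expect_identical(st$read_count, 2L)
  ## no placements
  st0 <- coveredStats(data.frame(start = integer(0), end = integer(0)), 100)
  expect_equal(unlist(st0[c("mean_depth", "covered_fraction",
                            "read_count")]),
               c(mean_depth = 0, covered_fraction = 0, read_count = 0))
  expect_error(coveredStats(data.frame(start = 90, end = 120), 100),
               class = "viromics_schema_error")
})

test_that("covered_stats equals the position-wise oracle on random placements", {
  for (s in 1:20) {
    set.seed(300 + s)
    len <- sample(2000:10000, 1)
    n <- sample(50:500, 1)
    start <- sample.int(len, n, replace = TRUE)
    end <- pmin(len, start + sample(10:300, n, replace = TRUE))
    pl <- data.frame(start = start, end = end)
    got <- coveredStats(pl, len)
    want <- oracle_covered(pl, len)
    expect_identical(got$covered_fraction, want$covered_fraction)
    expect_identical(got$mean_depth, want$mean_depth)
    expect_identical(got$read_count, want$read_count)
  }
})

test_that("matrix completion fills zeros and conserves observed depth", {
  rows <- data.frame(
    contig_id = c("v1", "v1", "v2", "v3"),
    sample_id = c("S1", "S2", "S1", "S2"),
    mean_depth = c(5, 2, 1.5, 4),
    covered_fraction = c(0.9, 0.5, 0.4, 1),
    read_count = c(50L, 20L, 10L, 40L))
  ann <- data.frame(contig_id = c("v1", "v2", "v3"),
                    length = c(9000L, 5000L, 7000L),
                    quality = "High-quality")
  mat <- buildCoverageMatrix(rows, ann)
  expect_identical(dim(mat), c(3L, 2L))
  expect_equal(sum(abundance(mat)), sum(rows$mean_depth))
  expect_equal(abundance(mat)["v2", "S2"], 0)
  ## annotation join preserves row identity
  expect_identical(rownames(mat), ann$contig_id)

  ## unknown contig skipped with warning; observed depth still conserved
  rows2 <- rbind(rows, data.frame(contig_id = "ghost", sample_id = "S1",
                                  mean_depth = 9, covered_fraction = 1,
                                  read_count = 9L))
  expect_warning(mat2 <- buildCoverageMatrix(rows2, ann), "ghost")
  expect_equal(sum(abundance(mat2)), sum(rows$mean_depth))

  ## duplicate (contig, sample) cell is a hard error
  expect_error(buildCoverageMatrix(rbind(rows, rows[1, ]), ann),
               class = "viromics_schema_error")

  ## sample with zero detections still yields an all-zero column
  mat3 <- buildCoverageMatrix(rows, ann, samples = c("S1", "S2", "S3"))
  expect_equal(unname(colSums(abundance(mat3))["S3"]), 0)
})

test_that("horizontal-coverage filtering zeroes cells then drops empty rows", {
  rows <- expand.grid(contig_id = c("v1", "v2", "v3"),
                      sample_id = c("S1", "S2"),
                      stringsAsFactors = FALSE)
  rows$mean_depth <- c(5, 3, 2, 4, 1, 6)
  rows$covered_fraction <- c(0.95, 0.2, 0.3, 0.6, 0.25, 0.05)
  rows$read_count <- 10L
  ann <- data.frame(contig_id = c("v1", "v2", "v3"), length = 5000L)
  mat <- buildCoverageMatrix(rows, ann)
  hc <- applyHorizontalCoverage(mat)
  expect_named(hc, c("0.1", "0.5", "0.9"))
  ## cell semantics at one threshold
  expect_equal(abundance(hc[["0.5"]])["v1", "S1"], 5)
  expect_false("v3" %in% rownames(hc[["0.5"]]))   # cf 0.3 / 0.05 both < 0.5
  ## nesting: row sets shrink as the threshold rises
  expect_true(all(rownames(hc[["0.5"]]) %in% rownames(hc[["0.1"]])))
  expect_true(all(rownames(hc[["0.9"]]) %in% rownames(hc[["0.5"]])))
  ## threshold 0 is the identity on rows and cells
  t0 <- applyHorizontalCoverage(mat, 0)[["0"]]
  expect_equal(abundance(t0), abundance(mat))
  ## original untouched
  expect_equal(abundance(mat)["v3", "S2"], 6)
  expect_error(applyHorizontalCoverage(mat, 1.5),
               class = "viromics_config_error")
})

test_that("horizontal-coverage nesting holds on random planted matrices", {
  for (s in 1:10) {
    set.seed(400 + s)
    n <- 25
    rows <- expand.grid(contig_id = sprintf("v%02d", 1:n),
                        sample_id = c("S1", "S2", "S3"),
                        stringsAsFactors = FALSE)
    rows$mean_depth <- runif(nrow(rows), 0, 10)
    rows$covered_fraction <- runif(nrow(rows))
    rows$read_count <- 5L
    ## enforce the zero-iff-zero invariant the builder checks
    zero <- rows$covered_fraction < 0.02
    rows$mean_depth[zero] <- 0
    rows$covered_fraction[zero] <- 0
    rows$read_count[zero] <- 0L
    ann <- data.frame(contig_id = sprintf("v%02d", 1:n), length = 4000L)
    hc <- applyHorizontalCoverage(buildCoverageMatrix(rows, ann))
    expect_true(all(rownames(hc[["0.5"]]) %in% rownames(hc[["0.1"]])))
    expect_true(all(rownames(hc[["0.9"]]) %in% rownames(hc[["0.5"]])))
  }
})

test_that("the conservative sequence filter applies its two branches strictly", {
  r <- makeDetectionRecords(
    c("long_low", "mid_med", "mid_low", "short_complete", "edge5k",
      "edge1k"),
    length = c(6000L, 2000L, 2000L, 900L, 5000L, 1001L),
    quality = c("Low-quality", "Medium-quality", "Low-quality",
                "Complete", "Low-quality", "Complete"),
    viral_genes = 2L, host_genes = 0L, n_genes = 2L)
  kept <- applySequenceFilter(r, "conservative")
  ## 5 kb branch is strict: exactly 5000 with low quality fails
  expect_setequal(kept$contig_id, c("long_low", "mid_med", "edge1k"))
  ## relaxed mode re-applies the gene filters instead
  relaxed <- applySequenceFilter(r, "relaxed")
  expect_identical(nrow(relaxed), nrow(r))
  expect_error(applySequenceFilter(r, "strictest"),
               class = "viromics_config_error")
})

test_that("coverage from placements cross-checks the fixture generator", {
  lens <- c(x = 1000L, y = 4000L, z = 2000L)
  pl <- generatePlacements(lens, c(1, 0.5, 0), seed = 2)
  cov <- coverageFromPlacements(pl, lens, sampleId = "S1")
  expect_equal(cov$covered_fraction, c(1, 0.5, 0))
  expect_identical(nrow(cov), 3L)
  expect_identical(cov$read_count[3], 0L)
  ## zero-iff-zero invariant on computed rows
  expect_true(all((cov$mean_depth == 0) == (cov$covered_fraction == 0)))
})
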