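test_that("mask_intervals masks the union of 0-based half-open intervals", {
  g <- generate_genome(10000, 0.5, 1)
  m <- mask_intervals(g, data.frame(start = 1000, end = 2000))
  expect_equal(attr(m, "masked_bp"), 1000)
  expect_equal(sum(strsplit(m$sequence, "")[[1]] == "N"), 1000)
  expect_identical(substring(m$sequence, 1, 1000), substring(g$sequence, 1, 1000))
  expect_identical(substring(m$sequence, 2001), substring(g$sequence, 2001))

  expect_identical(mask_intervals(g, data.frame(start = integer(0),
                                                end = integer(0)))$sequence,
                   g$sequence)
  ov <- mask_intervals(g, data.frame(start = c(0, 50), end = c(100, 150)))
  expect_equal(attr(ov, "masked_bp"), 150)
  expect_error(mask_intervals(g, data.frame(start = -1, end = 5)), "range")
  expect_error(mask_intervals(g, data.frame(start = 10, end = 10)), "interval")
  expect_error(mask_intervals(g, data.frame(start = 0, end = 10001)), "range")
})

test_that("subsample is deterministic, bounded and hypergeometric across seeds", {
  g <- generate_genome(5000, 0.5, 3)
  ct <- culture_truth("c", "G1", 1, n_reads = 1000, read_length = 50,
                      substitution_rate = 0, seed = 2)
  reads <- generate_reads(ct, list(G1 = g))
  expect_identical(subsample(reads[1:100, ], 1000, 1), reads[1:100, ])
  s1 <- subsample(reads, 100, seed = 7)
  s2 <- subsample(reads, 100, seed = 7)
  expect_identical(s1$read_id, s2$read_id)
  expect_equal(nrow(s1), 100)
  # two seeds overlap near the hypergeometric expectation (10 +- 3 sigma)
  s3 <- subsample(reads, 100, seed = 8)
  ov <- length(intersect(s1$read_id, s3$read_id))
  sigma <- sqrt(100 * 0.1 * 0.9 * (900 / 999))
  expect_lt(abs(ov - 10), 3 * sigma)
})

test_that("error-free reads map back to their origin (simulator oracle)", {
  g <- generate_genome(100000, 0.5, 11)
  ct <- culture_truth("c", "G1", 1, n_reads = 2000, read_length = 150,
                      substitution_rate = 0, seed = 3)
  reads <- generate_reads(ct, list(G1 = g))
  aln <- map_reads(reads, g)
  expect_gte(nrow(aln) / nrow(reads), 0.99)
  origin <- parse_read_origin(aln$read_id)
  expect_true(all(aln$start == origin$origin_start0))
  expect_true(all(aln$strand == origin$origin_strand))
  expect_true(all(aln$identity == 1))
})

test_that("reads from an unrelated genome produce no alignments", {
  g <- generate_genome(50000, 0.5, 21)
  other <- generate_genome(50000, 0.5, 22, genome_id = "other")
  ct <- culture_truth("c", "other", 1, n_reads = 1000, read_length = 150,
                      substitution_rate = 0, seed = 4)
  reads <- generate_reads(ct, list(other = other))
  expect_equal(nrow(map_reads(reads, g)), 0)
})

test_that("identity below 0.95 is rejected (boundary semantics)", {
  g <- generate_genome(10000, 0.5, 31)
  # construct one read with exactly 12/150 = 8% substitutions
  read <- substring(g$sequence, 501, 650)
  v <- strsplit(read, "")[[1]]
  # errors clustered in the back half so clean 15-mer seeds still exist
  pos <- seq(80, by = 6, length.out = 12)
  v[pos] <- chartr("ACGT", "CATG", v[pos])
  bad <- paste(v, collapse = "")
  expect_equal(nrow(map_reads(bad, g)), 0)
  # 4 substitutions (identity ~0.973) passes
  v2 <- strsplit(read, "")[[1]]
  v2[c(10, 50, 90, 130)] <- chartr("ACGT", "CATG", v2[c(10, 50, 90, 130)])
  ok <- map_reads(paste(v2, collapse = ""), g)
  expect_equal(nrow(ok), 1)
  expect_equal(ok$start, 500)
  expect_equal(ok$identity, 146 / 150)
})

test_that("coverage_stats arithmetic, masking and per-Gb invariance", {
  g <- generate_genome(10000, 0.5, 41)
  ct <- culture_truth("c", "G1", 1, n_reads = 400, read_length = 100,
                      substitution_rate = 0, seed = 5)
  reads <- generate_reads(ct, list(G1 = g))
  aln <- map_reads(reads, g)
  prof <- coverage_stats(aln, g, total_sampled_bases = 40000)
  expect_equal(prof$depth, prof$aligned_bases / 10000)
  expect_equal(prof$coverage_per_gb, prof$depth / (40000 / 1e9))
  # no alignments -> all zero
  p0 <- coverage_stats(aln[0, ], g, 1e6)
  expect_equal(p0$depth, 0)
  expect_equal(p0$breadth, 0)
  expect_equal(p0$coverage_per_gb, 0)
  # doubling reads and sampled bases leaves coverage_per_gb unchanged
  dup <- rbind(aln, aln)
  p2 <- coverage_stats(dup, g, 80000)
  expect_equal(p2$coverage_per_gb, prof$coverage_per_gb)
  # masked positions are excluded from the effective length and breadth
  gm <- mask_intervals(g, data.frame(start = 0, end = 1000))
  alnm <- map_reads(reads, gm)
  pm <- coverage_stats(alnm, gm, 40000)
  expect_equal(pm$effective_genome_length, 9000)
  expect_lte(pm$breadth, 1)
  expect_error(coverage_stats(aln, mask_intervals(
    g, data.frame(start = 0, end = 10000)), 1), "effective")
})

test_that("uniform ~5x coverage yields breadth near the Poisson bound", {
  g <- generate_genome(20000, 0.5, 51)
  n_reads <- 5 * 20000 / 100
  ct <- culture_truth("c", "G1", 1, n_reads = n_reads, read_length = 100,
                      substitution_rate = 0, seed = 6)
  reads <- generate_reads(ct, list(G1 = g))
  prof <- coverage_stats(map_reads(reads, g), g, n_reads * 100)
  expect_gte(prof$breadth, 0.98)  # 1 - exp(-5) ~ 0.993, minus edge effects
})

test_that("presence_call is strictly above the 95% breadth bar", {
  cfg <- recruit_config()
  expect_true(presence_call(data.frame(breadth = 0.96), cfg))
  expect_false(presence_call(data.frame(breadth = 0.95), cfg))
  expect_false(presence_call(data.frame(breadth = 0), cfg))
  expect_error(presence_call(data.frame(depth = 1), cfg), "breadth")
})

test_that("empty read set maps to an empty table, not an error", {
  g <- generate_genome(5000, 0.5, 61)
  empty <- data.frame(read_id = character(0), sequence = character(0))
  expect_equal(nrow(map_reads(empty, g)), 0)
})
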