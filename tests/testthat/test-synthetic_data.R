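test_that("generate_genome hits the requested GC and is seed-deterministic", {
  g <- generate_genome(100000, 0.60, 7)
  gc <- sum(strsplit(g$sequence, "")[[1]] %in% c("G", "C")) / g$length_bp
  expect_gte(gc, 0.59)
  expect_lte(gc, 0.61)
  expect_equal(g$gc, gc)
  expect_equal(g$length_bp, nchar(g$sequence))

  a <- generate_genome(1000, 0.5, 1)
  b <- generate_genome(1000, 0.5, 1)
  expect_identical(a$sequence, b$sequence)
  c <- generate_genome(1000, 0.5, 2)
  expect_false(identical(a$sequence, c$sequence))

  expect_error(generate_genome(0, 0.5, 1), "length_bp")
  expect_error(generate_genome(10000, 0, 1), "gc")
  expect_error(generate_genome(10000, 1, 1), "gc")
})

test_that("mutate_genome realizes the target identity and reports positions", {
  g <- generate_genome(100000, 0.55, 11)
  for (ident in c(0.95, 0.85)) {
    m <- mutate_genome(g, ident, seed = round(ident * 100))
    realized <- oracle_identity(g, m)
    expect_lt(abs(realized - ident), 0.002)
    # returned positions are exactly the differing sites
    ga <- strsplit(g$sequence, "")[[1]]
    gb <- strsplit(m$genome$sequence, "")[[1]]
    expect_identical(which(ga != gb), m$positions)
  }
  m1 <- mutate_genome(g, 1.0, 5)
  expect_identical(m1$genome$sequence, g$sequence)
  expect_length(m1$positions, 0)
  expect_error(mutate_genome(g, 0.4, 1), "target_identity")
})

test_that("generate_reads: exact substrings at zero error, both strands", {
  g <- generate_genome(10000, 0.5, 21)
  ct <- culture_truth("cu1", "G1", 1, n_reads = 300, read_length = 100,
                      substitution_rate = 0, seed = 4)
  reads <- generate_reads(ct, list(G1 = g))
  expect_equal(nrow(reads), 300)
  ref <- g$sequence
  ok <- vapply(seq_len(nrow(reads)), function(i) {
    s <- reads$sequence[i]
    grepl(s, ref, fixed = TRUE) ||
      grepl(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s))), ref, fixed = TRUE)
  }, logical(1))
  expect_true(all(ok))
  expect_true(all(c("+", "-") %in% reads$origin_strand))
  # origin annotation round-trips through the read name
  parsed <- parse_read_origin(reads$read_id)
  expect_identical(parsed$origin_start0, reads$origin_start0)
  expect_identical(parsed$origin_strand, reads$origin_strand)
})

test_that("generate_reads allocates by abundance x length and injects errors", {
  gA <- generate_genome(10000, 0.5, 31, genome_id = "A")
  gB <- generate_genome(10000, 0.5, 32, genome_id = "B")
  ct <- culture_truth("cu2", c("A", "B"), c(0.9, 0.1), n_reads = 10000,
                      read_length = 100, substitution_rate = 0, seed = 9)
  reads <- generate_reads(ct, list(A = gA, B = gB))
  nA <- sum(reads$origin_genome == "A")
  # equal lengths: expected split 9000/1000, 3 sigma binomial
  sigma <- sqrt(10000 * 0.9 * 0.1)
  expect_lt(abs(nA - 9000), 3 * sigma)

  ct2 <- culture_truth("cu3", "A", 1, n_reads = 10000, read_length = 150,
                       substitution_rate = 0.01, seed = 10)
  r2 <- generate_reads(ct2, list(A = gA))
  # mismatches counted against the named origin locus
  mm <- vapply(seq_len(nrow(r2)), function(i) {
    loc <- substring(gA$sequence, r2$origin_start0[i] + 1,
                     r2$origin_start0[i] + 150)
    s <- r2$sequence[i]
    if (r2$origin_strand[i] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    sum(strsplit(loc, "")[[1]] != strsplit(s, "")[[1]])
  }, numeric(1))
  expect_lt(abs(mean(mm) - 1.5), 0.1)
  expect_identical(as.integer(mm), r2$n_sub)

  expect_error(generate_reads(culture_truth("x", "Z", 1, 10, 50, 0, 1),
                              list(A = gA)), "missing genome")
})

test_that("generate_bin_gene_table plants contaminants and labels truth", {
  res <- generate_bin_gene_table(10, "Cyanobacteriia",
                                 list(list(3, "no_hit", 0.5)), seed = 1)
  tab <- res$table
  c3 <- tab[tab$contig_id == res$truth$contig_id[3], ]
  expect_equal(mean(c3$class_call == "no_hit"), 0.5)
  clean <- tab[tab$contig_id %in% res$truth$contig_id[-3], ]
  off <- tapply(clean$class_call != "Cyanobacteriia", clean$contig_id, mean)
  expect_true(all(off <= 0.10))
  expect_identical(res$truth$is_contaminant,
                   c(rep(FALSE, 2), TRUE, rep(FALSE, 7)))

  one <- generate_bin_gene_table(1, "X", list(), seed = 1)
  expect_identical(consensus_class(one$table), "X")

  res2 <- generate_bin_gene_table(5, "Cyanobacteriia",
                                  list(list(1, "Gammaproteobacteria", 1.0)),
                                  seed = 2)
  c1 <- res2$table[res2$table$contig_id == res2$truth$contig_id[1], ]
  expect_true(all(c1$class_call == "Gammaproteobacteria"))

  expect_error(generate_bin_gene_table(5, "X", list(list(9, "no_hit", 1))),
               "out of range")
})

test_that("generate_ko_table plants ecotype panels", {
  panel <- default_marker_panel()
  hn <- t(vapply(1:200, function(s) generate_ko_table("HN", panel, 0, s),
                 integer(length(panel$genes))))
  # diagnostic markers always present at dropout 0
  expect_true(all(hn[, c("cheB", "cheR", "pilA")] == 1))
  # cold-stress markers only as background noise (rate 0.05, 3 sigma)
  bg <- colMeans(hn[, c("treS", "otsA", "otsB")])
  expect_true(all(abs(bg - 0.05) < 3 * sqrt(0.05 * 0.95 / 200)))
  # pigment genes exempt from background: never present in a green ecotype
  expect_true(all(hn[, c("cpeA", "cpeB")] == 0))
  lnlt <- generate_ko_table("LNLT", panel, dropout = 0, seed = 3)
  expect_true(all(lnlt[c("treS", "otsA", "otsB", "cpeA", "cpeB")] == 1))
  expect_error(generate_ko_table("LN", panel, dropout = 1.0), "dropout")
  expect_error(generate_ko_table("XX", panel), "unknown ecotype")
})

test_that("fixed master seed gives identical collections; truth is emitted", {
  cfg <- sim_config(n_cultures = 6, heterotroph_pool_size = 3,
                    genome_length_range = c(5000, 6000), master_seed = 42)
  c1 <- simulate_culture_collection(cfg)
  c2 <- simulate_culture_collection(cfg)
  expect_identical(c1$truth, c2$truth)
  expect_identical(lapply(c1$genomes, `[[`, "sequence"),
                   lapply(c2$genomes, `[[`, "sequence"))
  r1 <- generate_reads(c1$cultures[[1]], c1$genomes)
  r2 <- generate_reads(c2$cultures[[1]], c2$genomes)
  expect_identical(r1, r2)
  # each culture holds exactly one picocyanobacterium
  picos <- tapply(c1$truth$role == "picocyanobacterium", c1$truth$culture_id, sum)
  expect_true(all(picos == 1))
})

test_that("FASTQ round-trip preserves reads and origin names", {
  g <- generate_genome(5000, 0.5, 77)
  ct <- culture_truth("cu9", "G1", 1, n_reads = 50, read_length = 80,
                      substitution_rate = 0.01, seed = 8)
  reads <- generate_reads(ct, list(G1 = g))
  path <- file.path(tempdir(), "cu9.fastq.gz")
  write_fastq(reads, path)
  back <- read_fastq(path)
  expect_identical(back$read_id, reads$read_id)
  expect_identical(back$sequence, reads$sequence)
})
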