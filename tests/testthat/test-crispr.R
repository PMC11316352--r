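mk_locus <- function(genome_id, locus_id, subtype, genes, n_spacers,
                     quality = "high") {
  n <- length(genes)
  data.frame(genome_id = rep(genome_id, n), locus_id = rep(locus_id, n),
             subtype = rep(subtype, n), gene_name = genes,
             gene_quality = rep(quality, n),
             n_spacers_in_locus = rep(n_spacers, n), stringsAsFactors = FALSE)
}

test_that("locus_completeness checks adaptation/interference modules", {
  ie <- mk_locus("g1", "L1", "I-E",
                 c("cas1", "cas2", "cas3", "cse1", "cse2", "cas7", "cas5",
                   "cas6e"), 12)
  res <- locus_completeness(ie)
  expect_true(res$adaptation_complete)
  expect_true(res$interference_complete)
  expect_false(res$cas1_less_with_spacers)

  ig <- mk_locus("g2", "L1", "I-G", c("cas2", "cas3", "csb2", "cas7", "cas5"), 8)
  res2 <- locus_completeness(ig)
  expect_false(res2$adaptation_complete)
  expect_true(res2$interference_complete)
  expect_true(res2$cas1_less_with_spacers)

  # low-quality matches still count towards completeness
  lowq <- mk_locus("g3", "L1", "I-G", c("cas1", "cas2", "cas3", "csb2",
                                        "cas7", "cas5"), 3, quality = "low")
  expect_true(locus_completeness(lowq)$adaptation_complete)

  empty <- mk_locus("g", "L", "I-E", character(0), integer(0))
  expect_identical(locus_completeness(empty),
                   list(adaptation_complete = FALSE,
                        interference_complete = FALSE,
                        cas1_less_with_spacers = FALSE))
  expect_error(locus_completeness(mk_locus("g", "L", "V-Z", "cas1", 1)),
               "I-E")
})

test_that("prevalence_by_group reproduces the printed percentages", {
  # 170 genomes, 27 with a system, 11 of those lacking cas1
  groups <- stats::setNames(rep("freshwater", 170), sprintf("g%03d", 1:170))
  loci <- do.call(rbind, lapply(1:27, function(i) {
    genes <- if (i <= 11) c("cas2", "cas3", "cas7") else c("cas1", "cas2", "cas3")
    mk_locus(sprintf("g%03d", i), "L1",
             c("I-E", "I-G", "III-B")[i %% 3 + 1], genes, i)
  }))
  rep_ <- prevalence_by_group(loci, groups)
  expect_equal(rep_$n_genomes, 170)
  expect_equal(rep_$n_with_system, 27)
  expect_equal(rep_$percent_with_system, 15.9)
  expect_equal(rep_$n_lacking_cas1, 11)
  expect_equal(rep_$percent_lacking_cas1, 40.7)
  expect_match(rep_$subtypes, "I-")
  # zero-positive group
  g2 <- stats::setNames(c(rep("marine", 5)), sprintf("m%d", 1:5))
  r2 <- prevalence_by_group(loci[0, ], g2)
  expect_equal(r2$percent_with_system, 0)
  expect_error(prevalence_by_group(loci, groups[1:5]), "without group")
})

test_that("cas1_filter_hits applies both strict boundaries", {
  hits <- data.frame(seq_id = c("a", "b", "c", "d"),
                     p_value = c(0.005, 0.01, 0.001, 0.0001),
                     length_aa = c(120, 120, 80, 300))
  expect_setequal(cas1_filter_hits(hits), c("a", "d"))
  expect_error(cas1_filter_hits(hits[0, ]), "empty")
  bad <- data.frame(seq_id = "x", p_value = 0.001, length_aa = -5)
  expect_error(cas1_filter_hits(bad), "negative")
  # monotone non-increasing as max_p_value decreases
  set.seed(7)
  tab <- data.frame(seq_id = sprintf("s%02d", 1:40),
                    p_value = runif(40, 0, 0.05),
                    length_aa = sample(60:200, 40, replace = TRUE))
  ps <- sort(runif(10, 0.001, 0.05), decreasing = TRUE)
  prev <- NULL
  for (p in ps) {
    cur <- cas1_filter_hits(tab, cas1_config(max_p_value = p))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("topk_neighbors keeps k best per query with lexicographic ties", {
  few <- data.frame(query_id = "q", target_id = c("t1", "t2", "t3"),
                    score = c(5, 3, 1))
  expect_setequal(topk_neighbors(few, 10), c("t1", "t2", "t3"))
  set.seed(3)
  many <- data.frame(query_id = "q", target_id = sprintf("t%02d", 1:20),
                     score = sample(100, 20))
  top <- topk_neighbors(many, 10)
  expect_length(top, 10)
  expect_setequal(top, many$target_id[order(-many$score)][1:10])
  # tie at the k-th rank: smaller id kept
  tie <- data.frame(query_id = "q", target_id = c("aa", "ab", "zz"),
                    score = c(9, 5, 5))
  expect_setequal(topk_neighbors(tie, 2), c("aa", "ab"))
  expect_error(topk_neighbors(tie, 0), "k")
})

test_that("greedy_cluster agrees with the Needleman-Wunsch oracle", {
  s <- random_aa(200, 1)
  identical_pair <- c(a = s, b = s)
  expect_equal(length(unique(greedy_cluster(identical_pair)$centroid)), 1)

  # ~85% identity pair: oracle confirms < 0.90 -> two clusters
  far <- mutate_aa(s, 30, 2)
  expect_lt(oracle_nw_identity(s, far), 0.90)
  cl2 <- greedy_cluster(c(a = s, b = far))
  expect_equal(length(unique(cl2$centroid)), 2)

  # ~95% identity pair clusters together; unrelated singleton stays apart
  near <- mutate_aa(s, 10, 3)
  expect_gte(oracle_nw_identity(s, near), 0.90)
  unrelated <- random_aa(180, 4)
  cl3 <- greedy_cluster(c(a = s, b = near, c = unrelated))
  expect_equal(length(unique(cl3$centroid)), 2)
  expect_identical(cl3$centroid[cl3$seq_id == "a"],
                   cl3$centroid[cl3$seq_id == "b"])

  # implementation identity matches the oracle on random pairs
  for (i in 1:5) {
    x <- random_aa(60, 10 + i)
    y <- mutate_aa(x, sample(3:20, 1), 20 + i)
    st <- picocult:::aa_align_stats(x, y)
    expect_equal(st$identity, oracle_nw_identity(x, y), tolerance = 1e-12)
  }

  expect_error(greedy_cluster(character(0)), "no sequences")
  expect_error(greedy_cluster(c(a = "")), "empty sequence")
})

test_that("greedy_cluster limit behaviors", {
  seqs <- c(a = random_aa(100, 31), b = random_aa(100, 32),
            c = random_aa(100, 33))
  # identity 1.0: one cluster per distinct sequence
  cl <- greedy_cluster(seqs, cas1_config(cluster_identity = 1.0))
  expect_equal(length(unique(cl$centroid)), 3)
  # identity ~0: single cluster (coverage satisfied at equal lengths)
  cl0 <- greedy_cluster(seqs, cas1_config(cluster_identity = 1e-9))
  expect_equal(length(unique(cl0$centroid)), 1)
})

test_that("cas1_curate chains filter, top-k and clustering", {
  set.seed(41)
  base <- random_aa(150, 51)
  seqs <- c(q1 = base,
            t1 = mutate_aa(base, 5, 52),    # clusters with q1
            t2 = random_aa(150, 53),        # distinct
            t3 = random_aa(150, 54),        # filtered out by p-value
            t4 = random_aa(60, 55))         # filtered out by length
  hits <- data.frame(seq_id = names(seqs),
                     p_value = c(0.001, 0.001, 0.001, 0.5, 0.001),
                     length_aa = nchar(seqs))
  sim <- data.frame(query_id = "q1",
                    target_id = c("t1", "t2", "t3", "t4"),
                    score = c(90, 50, 40, 30))
  out <- cas1_curate(hits, sim, seqs)
  expect_true("t2" %in% names(out))
  expect_false(any(c("t3", "t4") %in% names(out)))
  # q1/t1 collapse to one centroid
  expect_equal(sum(names(out) %in% c("q1", "t1")), 1)
})

test_that("schema JSON asset round-trips", {
  path <- system.file("extdata", "cas_subtype_schema.json",
                      package = "picocult")
  sc <- read_subtype_schema(path)
  expect_identical(sc$adaptation_genes, default_subtype_schema()$adaptation_genes)
  expect_setequal(names(sc$interference_genes), c("I-E", "I-G", "III-B"))
})
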