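#' Read-recruitment configuration
#'
#' Defaults follow the standard fragment-recruitment filters: alignments are
#' kept at >= 95% identity, covering >= 90% of the read and at least 50 bp;
#' read sets are subsampled to 20 million reads; a genome is called present
#' when its breadth of coverage exceeds 95%.
#'
#' @param min_identity minimum alignment identity (default 0.95).
#' @param min_read_coverage minimum aligned length / read length
#'   (default 0.90).
#' @param min_alignment_length minimum aligned length in bp (default 50).
#' @param subsample_reads read-subsampling bound (default 2e7).
#' @param presence_breadth presence requires breadth strictly above this
#'   (default 0.95).
#' @param map_kmer_size seed length for the mapper (default 15).
#' @param seed RNG seed for subsampling.
#' @return list of class `recruit_config`.
#' @export
recruit_config <- function(min_identity = 0.95, min_read_coverage = 0.90,
                           min_alignment_length = 50L,
                           subsample_reads = 20000000L,
                           presence_breadth = 0.95, map_kmer_size = 15L,
                           seed = 1L) {
  check_fraction(min_identity, "min_identity", 0, 1, lo_open = TRUE)
  check_fraction(min_read_coverage, "min_read_coverage", 0, 1, lo_open = TRUE)
  check_fraction(presence_breadth, "presence_breadth", 0, 1, lo_open = TRUE)
  if (min_alignment_length < 1) stop_bad_arg("min_alignment_length must be >= 1")
  structure(list(min_identity = min_identity,
                 min_read_coverage = min_read_coverage,
                 min_alignment_length = as.integer(min_alignment_length),
                 subsample_reads = as.integer(subsample_reads),
                 presence_breadth = presence_breadth,
                 map_kmer_size = as.integer(map_kmer_size),
                 seed = as.integer(seed)),
            class = "recruit_config")
}

#' Mask genome intervals (rRNA genes) with N
#'
#' Intervals are 0-based, half-open (BED dialect). Masked positions are
#' excluded from seeding and extension matches, from the breadth numerator
#' and from the effective genome length.
#'
#' @param genome a [genome_record()].
#' @param intervals data.frame/matrix with columns `start`, `end`
#'   (0-based half-open); overlapping intervals are unioned.
#' @return the masked [genome_record()]; the number of masked positions is
#'   attached as attribute `masked_bp`.
#' @export
mask_intervals <- function(genome, intervals) {
  stopifnot(inherits(genome, "genome_record"))
  iv <- as.data.frame(intervals)
  if (nrow(iv) == 0) {
    attr(genome, "masked_bp") <- 0L
    return(genome)
  }
  if (ncol(iv) < 2) stop_bad_arg("intervals need start and end columns")
  names(iv)[1:2] <- c("start", "end")
  if (any(iv$start < 0) || any(iv$end > genome$length_bp))
    stop_bad_arg("interval out of range [0, genome length)")
  if (any(iv$end <= iv$start)) stop_bad_arg("inverted or empty interval")
  merged <- IRanges::reduce(IRanges::IRanges(iv$start + 1L, iv$end))
  raw <- charToRaw(genome$sequence)
  for (i in seq_along(merged)) {
    raw[IRanges::start(merged)[i]:IRanges::end(merged)[i]] <- charToRaw("N")
  }
  out <- genome_record(genome$genome_id, rawToChar(raw), role = genome$role,
                       ecotype = genome$ecotype)
  attr(out, "masked_bp") <- sum(IRanges::width(merged))
  out
}

#' Subsample a read set without replacement
#'
#' Returns all reads when there are no more than `n`; otherwise exactly `n`
#' reads drawn without replacement, deterministically for a fixed seed
#' (original read order is preserved).
#'
#' @param reads a `read_set` data.frame.
#' @param n target number of reads.
#' @param seed RNG seed.
#' @return the subsampled `read_set`.
#' @export
subsample <- function(reads, n, seed = 1L) {
  if (n < 1) stop_bad_arg("`n` must be >= 1")
  if (nrow(reads) <= n) return(reads)
  keep <- with_seed(seed, sort(sample.int(nrow(reads), n)))
  reads[keep, , drop = FALSE]
}

#' Map reads to a genome by seed-and-extend
#'
#' Each read is placed by exact k-mer seeding (both strands) followed by
#' ungapped extension at the best-identity locus, clipped to the genome.
#' An alignment is reported iff identity >= `min_identity`, aligned length /
#' read length >= `min_read_coverage`, and aligned length >=
#' `min_alignment_length`. At most one alignment per read is kept (best
#' identity; ties resolved to the leftmost placement, plus strand first).
#'
#' @param reads a `read_set` data.frame (or character vector of sequences).
#' @param genome a (possibly masked) [genome_record()].
#' @param config a [recruit_config()].
#' @return alignment table: `read_id`, `genome_id`, `start`, `end`
#'   (0-based half-open), `strand`, `identity`, `aligned_length`.
#' @export
map_reads <- function(reads, genome, config = recruit_config()) {
  stopifnot(inherits(genome, "genome_record"))
  if (is.character(reads))
    reads <- data.frame(read_id = sprintf("r%06d", seq_along(reads)),
                        sequence = reads, stringsAsFactors = FALSE)
  if (nrow(reads) == 0)
    return(data.frame(read_id = character(0), genome_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), identity = numeric(0),
                      aligned_length = integer(0), stringsAsFactors = FALSE))
  hits <- cpp_seed_extend(reads$sequence, genome$sequence,
                          config$map_kmer_size, FALSE)
  rl <- nchar(reads$sequence)
  identity <- ifelse(hits$alen > 0, hits$matches / hits$alen, 0)
  ok <- hits$placed & identity >= config$min_identity &
    (hits$alen / rl) >= config$min_read_coverage &
    hits$alen >= config$min_alignment_length
  data.frame(read_id = reads$read_id[ok],
             genome_id = rep(genome$genome_id, sum(ok)),
             start = hits$start[ok], end = hits$start[ok] + hits$alen[ok],
             strand = as.character(hits$strand[ok]),
             identity = identity[ok], aligned_length = hits$alen[ok],
             stringsAsFactors = FALSE)
}

#' Coverage statistics for one genome in one sample
#'
#' Depth is aligned bases over the effective (unmasked) genome length;
#' breadth is the fraction of unmasked positions covered at least once;
#' coverage per Gb normalizes depth by the gigabases of reads sampled.
#'
#' @param alignments alignment table from [map_reads()] for this genome.
#' @param genome the (masked) [genome_record()] the reads were mapped to.
#' @param total_sampled_bases total bases in the sampled read set.
#' @param sample_id label stored in the profile.
#' @return one-row data.frame of class `coverage_profile`: `genome_id`,
#'   `sample_id`, `aligned_bases`, `effective_genome_length`, `breadth`,
#'   `depth`, `coverage_per_gb`.
#' @export
coverage_stats <- function(alignments, genome, total_sampled_bases,
                           sample_id = "sample") {
  stopifnot(inherits(genome, "genome_record"))
  raw <- charToRaw(genome$sequence)
  unmasked <- raw != charToRaw("N")
  eff_len <- sum(unmasked)
  if (eff_len == 0) stop_bad_arg("zero effective genome length")
  if (nrow(alignments)) {
    cov <- IRanges::coverage(
      IRanges::IRanges(alignments$start + 1L, alignments$end),
      width = genome$length_bp)
    cov <- as.integer(cov)
    aligned_bases <- sum(as.numeric(cov[unmasked]))
    covered <- sum(cov[unmasked] > 0)
  } else {
    aligned_bases <- 0
    covered <- 0L
  }
  depth <- aligned_bases / eff_len
  structure(data.frame(
    genome_id = genome$genome_id, sample_id = sample_id,
    aligned_bases = aligned_bases, effective_genome_length = eff_len,
    breadth = covered / eff_len, depth = depth,
    coverage_per_gb = depth / (total_sampled_bases / 1e9),
    stringsAsFactors = FALSE),
    class = c("coverage_profile", "data.frame"))
}

#' Breadth-based presence call
#'
#' A genome is considered present in a culture when its breadth of coverage
#' is strictly above `presence_breadth` (default 0.95).
#'
#' @param profile a `coverage_profile` row.
#' @param config a [recruit_config()].
#' @return logical.
#' @export
presence_call <- function(profile, config = recruit_config()) {
  if (!"breadth" %in% names(profile)) stop_bad_arg("profile lacks breadth")
  profile$breadth > config$presence_breadth
}

#' Presence matrix for a simulated culture collection
#'
#' Runs the full recruitment pipeline: for each culture, subsamples its read
#' set, maps it against every genome in the pool, computes coverage and
#' applies the breadth presence rule.
#'
#' @param collection output of [simulate_culture_collection()].
#' @param read_sets named list of `read_set` objects, one per culture (as
#'   from [generate_reads()]).
#' @param config a [recruit_config()].
#' @return a [presence_matrix()] object.
#' @export
presence_matrix_from_reads <- function(collection, read_sets,
                                       config = recruit_config()) {
  genomes <- collection$genomes
  cids <- names(collection$cultures)
  gids <- names(genomes)
  pres <- matrix(FALSE, length(cids), length(gids),
                 dimnames = list(cids, gids))
  for (cid in cids) {
    reads <- subsample(read_sets[[cid]], config$subsample_reads, config$seed)
    total_bases <- sum(nchar(reads$sequence))
    for (gid in gids) {
      aln <- map_reads(reads, genomes[[gid]], config)
      prof <- coverage_stats(aln, genomes[[gid]], total_bases, cid)
      pres[cid, gid] <- presence_call(prof, config)
    }
  }
  presence_matrix(pres, collection$ecotype_of_culture)
}
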