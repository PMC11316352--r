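#' Genome record
#'
#' A named nucleotide sequence with the metadata carried through the
#' pipeline: the organism's role in a culture (the picocyanobacterium or a
#' co-isolated heterotroph), an optional ecotype label, and basic sequence
#' statistics.
#'
#' @param genome_id unique identifier.
#' @param sequence nucleotide string (A/C/G/T; N allowed for masked bases).
#' @param role `"picocyanobacterium"` or `"heterotroph"`.
#' @param ecotype optional label among `"SC5.3"`, `"LN"`, `"LNLT"`, `"HN"`,
#'   `"LP"`.
#' @return an object of class `genome_record` with fields `genome_id`,
#'   `sequence`, `role`, `ecotype`, `gc`, `length_bp`.
#' @export
genome_record <- function(genome_id, sequence,
                          role = c("picocyanobacterium", "heterotroph"),
                          ecotype = NULL) {
  role <- match.arg(role)
  if (!is.character(genome_id) || length(genome_id) != 1L || !nzchar(genome_id))
    stop_bad_arg("`genome_id` must be a non-empty string")
  if (!is.character(sequence) || length(sequence) != 1L)
    stop_bad_arg("`sequence` must be a single string")
  if (!is.null(ecotype)) {
    ecotype <- match.arg(ecotype, c("SC5.3", "LN", "LNLT", "HN", "LP"))
  }
  n <- nchar(sequence)
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  acgt <- sum(bases %in% c("A", "C", "G", "T"))
  gc <- if (acgt > 0) sum(bases %in% c("G", "C")) / acgt else NA_real_
  structure(list(genome_id = genome_id, sequence = sequence, role = role,
                 ecotype = ecotype, gc = gc, length_bp = n),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, GC %.3f, role %s%s\n",
              x$genome_id, x$length_bp, x$gc, x$role,
              if (is.null(x$ecotype)) "" else paste0(", ecotype ", x$ecotype)))
  invisible(x)
}

#' Ground-truth description of one simulated culture
#'
#' Captures the composition of a non-axenic culture: which genomes are
#' present, at which relative abundances, and the sequencing parameters used
#' to simulate its read set.
#'
#' @param culture_id culture identifier.
#' @param member_genome_ids character vector of member genome ids.
#' @param relative_abundances fractions summing to 1 (one per member).
#' @param n_reads number of reads to simulate.
#' @param read_length read length in bp.
#' @param substitution_rate per-base substitution error rate.
#' @param seed RNG seed for this culture's read set.
#' @param n_picos number of members with role picocyanobacterium (only used
#'   for the multi-algal invariant check; default 1).
#' @return an object of class `culture_truth`.
#' @export
culture_truth <- function(culture_id, member_genome_ids, relative_abundances,
                          n_reads, read_length, substitution_rate, seed,
                          n_picos = 1L) {
  if (length(member_genome_ids) != length(relative_abundances))
    stop_bad_arg("one abundance per member is required")
  if (abs(sum(relative_abundances) - 1) > 1e-9)
    stop_bad_arg("relative abundances must sum to 1")
  if (anyDuplicated(member_genome_ids))
    stop_bad_arg("duplicate member genome ids")
  check_fraction(substitution_rate, "substitution_rate", 0, 1, hi_open = TRUE)
  structure(list(culture_id = culture_id,
                 member_genome_ids = as.character(member_genome_ids),
                 relative_abundances = as.numeric(relative_abundances),
                 n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 substitution_rate = substitution_rate,
                 seed = as.integer(seed),
                 n_picos = as.integer(n_picos)),
            class = "culture_truth")
}

#' Simulation configuration for a culture collection
#'
#' Defaults describe the desk-scale world the test-suite exercises: 100
#' cultures, each holding one picocyanobacterium plus 0-3 heterotrophs, one
#' planted symbiont at 8% prevalence and decoy heterotrophs below the 5%
#' prevalence bar. Genome lengths are scaled down from the megabase range of
#' real picocyanobacteria to tens of kilobases so that a full simulation runs
#' in minutes; the GC range mirrors the span observed in freshwater
#' picocyanobacteria (roughly 52-72%).
#'
#' @param n_cultures number of cultures.
#' @param heterotroph_pool_size number of distinct heterotroph genomes.
#' @param planted_symbiont_prevalence fraction of cultures carrying the
#'   planted symbiont.
#' @param genome_length_range low/high genome length in bp.
#' @param gc_range low/high GC fraction.
#' @param master_seed master RNG seed; all per-culture seeds derive from it.
#' @param n_reads reads per culture (default sized for ~6x member depth at
#'   generation time when `NULL`).
#' @param read_length read length in bp.
#' @param substitution_rate per-base substitution error rate.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_cultures = 100L, heterotroph_pool_size = 8L,
                       planted_symbiont_prevalence = 0.08,
                       genome_length_range = c(25000L, 40000L),
                       gc_range = c(0.52, 0.72), master_seed = 1L,
                       n_reads = NULL, read_length = 150L,
                       substitution_rate = 0.005) {
  check_fraction(planted_symbiont_prevalence, "planted_symbiont_prevalence")
  if (length(genome_length_range) != 2L ||
      genome_length_range[1] > genome_length_range[2])
    stop_bad_arg("`genome_length_range` must be an ordered pair")
  if (length(gc_range) != 2L || gc_range[1] > gc_range[2])
    stop_bad_arg("`gc_range` must be an ordered pair")
  structure(list(n_cultures = as.integer(n_cultures),
                 heterotroph_pool_size = as.integer(heterotroph_pool_size),
                 planted_symbiont_prevalence = planted_symbiont_prevalence,
                 genome_length_range = as.integer(genome_length_range),
                 gc_range = as.numeric(gc_range),
                 master_seed = as.integer(master_seed),
                 n_reads = if (is.null(n_reads)) NULL else as.integer(n_reads),
                 read_length = as.integer(read_length),
                 substitution_rate = substitution_rate),
            class = "sim_config")
}
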