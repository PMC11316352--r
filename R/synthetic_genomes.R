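# byte lookup tables for fast in-place sequence surgery
.BASE_BYTES <- charToRaw("ACGT")
.BYTE_TO_CODE <- local({
  v <- rep(NA_integer_, 256)
  v[as.integer(charToRaw("ACGT")) + 1L] <- 0:3
  v[as.integer(charToRaw("acgt")) + 1L] <- 0:3
  v
})

#' Generate a random genome with a target GC content
#'
#' Bases are drawn i.i.d.: G/C with probability `gc` (split evenly), A/T
#' otherwise. For genomes of 100 kb or more the empirical GC lands within
#' about 0.01 of the request.
#'
#' @param length_bp genome length (>= 1000).
#' @param gc target GC fraction, strictly between 0 and 1.
#' @param seed RNG seed; fixed seed gives an identical genome.
#' @param genome_id identifier for the record.
#' @param role,ecotype metadata passed to [genome_record()].
#' @return a [genome_record()].
#' @examples
#' g <- generate_genome(10000, 0.6, seed = 1)
#' g$gc
#' @export
generate_genome <- function(length_bp, gc, seed, genome_id = "G1",
                            role = "picocyanobacterium", ecotype = NULL) {
  if (!is.numeric(length_bp) || length(length_bp) != 1L || length_bp < 1000)
    stop_bad_arg("`length_bp` must be a single number >= 1000")
  check_fraction(gc, "gc", 0, 1, lo_open = TRUE, hi_open = TRUE)
  length_bp <- as.integer(length_bp)
  seq <- with_seed(seed, {
    is_gc <- stats::runif(length_bp) < gc
    pick <- stats::runif(length_bp) < 0.5
    # codes: A=0 C=1 G=2 T=3
    code <- ifelse(is_gc, ifelse(pick, 1L, 2L), ifelse(pick, 0L, 3L))
    rawToChar(.BASE_BYTES[code + 1L])
  })
  genome_record(genome_id, seq, role = role, ecotype = ecotype)
}

#' Introduce substitutions to reach a target identity
#'
#' Each position is substituted independently with probability
#' `1 - target_identity`; substituted bases are replaced by one of the three
#' other bases. No indels are introduced, so the returned position list is an
#' exact per-site record of divergence (the oracle used to validate the ANI
#' estimator).
#'
#' @param genome a [genome_record()].
#' @param target_identity fraction in \[0.5, 1\].
#' @param seed RNG seed.
#' @param genome_id id of the mutated record (default `<id>.mut`).
#' @return list with `genome` (the mutated [genome_record()]) and
#'   `positions` (1-based positions of the substitutions).
#' @export
mutate_genome <- function(genome, target_identity, seed,
                          genome_id = paste0(genome$genome_id, ".mut")) {
  stopifnot(inherits(genome, "genome_record"))
  check_fraction(target_identity, "target_identity", 0.5, 1)
  rate <- 1 - target_identity
  raw <- charToRaw(genome$sequence)
  positions <- with_seed(seed, {
    pos <- which(stats::runif(length(raw)) < rate)
    if (length(pos)) {
      code <- .BYTE_TO_CODE[as.integer(raw[pos]) + 1L]
      shift <- sample.int(3L, length(pos), replace = TRUE)
      raw[pos] <- .BASE_BYTES[((code + shift) %% 4L) + 1L]
    }
    pos
  })
  out <- genome_record(genome_id, rawToChar(raw), role = genome$role,
                       ecotype = genome$ecotype)
  list(genome = out, positions = positions)
}

# reverse complement of plain character vectors (delegates to Biostrings)
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
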