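#' Write genome records as FASTA (80-column wrap)
#'
#' @param genomes list of [genome_record()] or a named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path) {
  if (is.list(genomes) && all(vapply(genomes, inherits, logical(1),
                                     "genome_record"))) {
    seqs <- vapply(genomes, function(g) g$sequence, character(1))
    names(seqs) <- vapply(genomes, function(g) g$genome_id, character(1))
  } else seqs <- genomes
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read a FASTA file into genome records
#'
#' @param path FASTA file.
#' @param role role assigned to all records (default heterotroph-free
#'   `"picocyanobacterium"`).
#' @return named list of [genome_record()].
#' @export
read_fasta <- function(path, role = "picocyanobacterium") {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  out <- lapply(seq_along(x), function(i) {
    genome_record(ids[i], as.character(x[[i]]), role = role)
  })
  stats::setNames(out, ids)
}

#' Read protein FASTA as a named character vector
#' @param path FASTA file of amino-acid sequences.
#' @return named character vector.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a named character vector of proteins as FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Read a 3-column BED file of mask intervals
#'
#' @param path BED path (0-based half-open; only the first three columns are
#'   used).
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(x) < 3) stop_bad_arg("BED needs at least 3 columns")
  data.frame(chrom = x[[1]], start = as.integer(x[[2]]),
             end = as.integer(x[[3]]), stringsAsFactors = FALSE)
}
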