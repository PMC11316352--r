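#' Simulate a shotgun read set for one culture
#'
#' Reads are allocated to member genomes by a multinomial draw weighted by
#' relative abundance times genome length (mirroring shotgun sampling), start
#' positions are uniform, both strands are sampled with probability 0.5, and
#' per-base substitution errors are applied at the culture's
#' `substitution_rate`. The true origin of every read is recorded in its
#' name as `id|genome|start0|strand|n_sub` (0-based forward-strand start),
#' which is what the mapping oracle in the test-suite parses.
#'
#' @param culture a [culture_truth()].
#' @param genomes named list of [genome_record()] covering all members.
#' @return a `data.frame` of class `read_set` with columns `read_id`,
#'   `sequence` and the origin columns `origin_genome`, `origin_start0`,
#'   `origin_strand`, `n_sub`.
#' @export
generate_reads <- function(culture, genomes) {
  stopifnot(inherits(culture, "culture_truth"))
  ids <- culture$member_genome_ids
  missing <- setdiff(ids, names(genomes))
  if (length(missing))
    stop_bad_arg("missing genome(s): ", paste(missing, collapse = ", "))
  members <- genomes[ids]
  lens <- vapply(members, function(g) g$length_bp, integer(1))
  rl <- culture$read_length
  if (any(lens < rl))
    stop_bad_arg("read_length exceeds the shortest member genome")
  w <- culture$relative_abundances * lens
  res <- with_seed(culture$seed, {
    counts <- as.vector(stats::rmultinom(1, culture$n_reads, w))
    seqs <- character(0); origin <- character(0)
    starts <- integer(0); strands <- character(0)
    for (i in seq_along(members)) {
      n <- counts[i]
      if (n == 0) next
      L <- lens[i]
      s0 <- sample.int(L - rl + 1L, n, replace = TRUE) - 1L
      frag <- substring(members[[i]]$sequence, s0 + 1L, s0 + rl)
      minus <- stats::runif(n) < 0.5
      if (any(minus)) frag[minus] <- revcomp_chr(frag[minus])
      seqs <- c(seqs, frag)
      origin <- c(origin, rep(ids[i], n))
      starts <- c(starts, s0)
      strands <- c(strands, ifelse(minus, "-", "+"))
    }
    err <- cpp_inject_errors(seqs, culture$substitution_rate)
    list(seq = err$seq, n_sub = err$n_sub, origin = origin,
         start = starts, strand = strands)
  })
  n <- length(res$seq)
  read_id <- sprintf("%s.r%06d|%s|%d|%s|%d", culture$culture_id, seq_len(n),
                     res$origin, res$start, res$strand, res$n_sub)
  structure(data.frame(read_id = read_id, sequence = res$seq,
                       origin_genome = res$origin, origin_start0 = res$start,
                       origin_strand = res$strand, n_sub = res$n_sub,
                       stringsAsFactors = FALSE),
            class = c("read_set", "data.frame"))
}

#' Parse read-origin annotations out of read names
#'
#' @param read_id character vector of names as written by [generate_reads()].
#' @return `data.frame` with `origin_genome`, `origin_start0`,
#'   `origin_strand`, `n_sub`.
#' @export
parse_read_origin <- function(read_id) {
  parts <- strsplit(read_id, "|", fixed = TRUE)
  bad <- lengths(parts) != 5L
  if (any(bad)) stop_bad_arg("malformed origin annotation in read names")
  m <- matrix(unlist(parts), ncol = 5, byrow = TRUE)
  data.frame(origin_genome = m[, 2], origin_start0 = as.integer(m[, 3]),
             origin_strand = m[, 4], n_sub = as.integer(m[, 5]),
             stringsAsFactors = FALSE)
}

#' Write reads as FASTQ (Phred+33, constant Q40)
#'
#' @param reads a `read_set` (or any data.frame with `read_id`, `sequence`).
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$sequence))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                             "+", qual)), con)
  invisible(path)
}

#' Read a FASTQ file into a `read_set`
#'
#' @param path FASTQ path (plain or gzipped).
#' @return `data.frame` of class `read_set` with `read_id`, `sequence`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  if (length(lines) %% 4 != 0) stop_bad_arg("truncated FASTQ: ", path)
  ids <- sub("^@", "", lines[seq(1, length(lines), by = 4)])
  structure(data.frame(read_id = ids,
                       sequence = lines[seq(2, length(lines), by = 4)],
                       stringsAsFactors = FALSE),
            class = c("read_set", "data.frame"))
}
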