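#' Culture-by-genome presence matrix
#'
#' @param presence logical matrix, cultures in rows (rownames), genomes in
#'   columns (colnames).
#' @param ecotype_of_culture named character vector mapping every culture to
#'   the ecotype of its picocyanobacterium.
#' @return list of class `presence_matrix` with `presence`, `culture_ids`,
#'   `genome_ids`, `ecotype_of_culture`.
#' @export
presence_matrix <- function(presence, ecotype_of_culture) {
  if (!is.matrix(presence) || !is.logical(presence))
    stop_bad_arg("`presence` must be a logical matrix")
  if (is.null(rownames(presence)) || is.null(colnames(presence)))
    stop_bad_arg("`presence` needs culture rownames and genome colnames")
  missing <- setdiff(rownames(presence), names(ecotype_of_culture))
  if (length(missing))
    stop_bad_arg("cultures without ecotype label: ",
                 paste(missing, collapse = ", "))
  structure(list(presence = presence, culture_ids = rownames(presence),
                 genome_ids = colnames(presence),
                 ecotype_of_culture = ecotype_of_culture[rownames(presence)]),
            class = "presence_matrix")
}

#' Prevalence filter for repeatedly co-occurring genomes
#'
#' A genome is retained when it is present in strictly more than
#' `min_culture_fraction` of the cultures (default 5%), the operational
#' definition of "repeatedly present".
#'
#' @param matrix a [presence_matrix()].
#' @param min_culture_fraction prevalence bar in (0, 1), strict.
#' @param genome_ids optional subset of candidate genomes (e.g. only
#'   heterotrophs); defaults to all columns.
#' @return data.frame `genome_id`, `n_cultures_present`, `prevalence`,
#'   `retained`.
#' @export
prevalence_filter <- function(matrix, min_culture_fraction = 0.05,
                              genome_ids = NULL) {
  stopifnot(inherits(matrix, "presence_matrix"))
  check_fraction(min_culture_fraction, "min_culture_fraction", 0, 1,
                 lo_open = TRUE, hi_open = TRUE)
  n <- length(matrix$culture_ids)
  if (n == 0) stop_bad_arg("empty presence matrix")
  gids <- genome_ids %||% matrix$genome_ids
  cnt <- colSums(matrix$presence[, gids, drop = FALSE])
  prev <- cnt / n
  data.frame(genome_id = gids, n_cultures_present = as.integer(cnt),
             prevalence = as.numeric(prev),
             retained = as.numeric(prev) > min_culture_fraction,
             stringsAsFactors = FALSE, row.names = NULL)
}

TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
               "species")

#' Parse a semicolon-delimited taxonomy table
#'
#' @param taxonomy data.frame with `genome_id` and `lineage`
#'   (semicolon-delimited, domain to species).
#' @return data.frame with `genome_id` plus one column per rank.
#' @export
parse_taxonomy <- function(taxonomy) {
  if (!all(c("genome_id", "lineage") %in% names(taxonomy)))
    stop_bad_arg("taxonomy needs genome_id and lineage columns")
  parts <- strsplit(taxonomy$lineage, ";", fixed = TRUE)
  depth <- lengths(parts)
  if (any(depth > length(TAX_RANKS)))
    stop_bad_arg("lineage deeper than ", length(TAX_RANKS), " ranks")
  m <- t(vapply(parts, function(p) c(p, rep(NA_character_,
                                            length(TAX_RANKS) - length(p))),
                character(length(TAX_RANKS))))
  colnames(m) <- TAX_RANKS
  cbind(data.frame(genome_id = taxonomy$genome_id, stringsAsFactors = FALSE),
        as.data.frame(m, stringsAsFactors = FALSE))
}

taxon_of <- function(tax_parsed, genome_ids, level) {
  if (!level %in% TAX_RANKS) stop_bad_arg("unknown rank: ", level)
  i <- match(genome_ids, tax_parsed$genome_id)
  if (anyNA(i))
    stop_bad_arg("genome(s) missing from taxonomy: ",
                 paste(genome_ids[is.na(i)], collapse = ", "))
  tax_parsed[[level]][i]
}

#' Ecotype-by-taxon co-occurrence counts
#'
#' Counts, for each picocyanobacterial ecotype and each taxon at `level`,
#' the number of cultures of that ecotype in which at least one genome of
#' the taxon is present. Counting is culture-level: several genomes of the
#' same taxon in one culture count once.
#'
#' @param matrix a [presence_matrix()] restricted to the genomes of interest
#'   (typically the prevalence-retained heterotrophs).
#' @param taxonomy taxonomy table (`genome_id`, `lineage`).
#' @param level taxonomic rank (default `"genus"`).
#' @param genome_ids optional subset of columns to count.
#' @return integer matrix, ecotypes in rows, taxa in columns.
#' @export
cooccurrence_counts <- function(matrix, taxonomy, level = "genus",
                                genome_ids = NULL) {
  stopifnot(inherits(matrix, "presence_matrix"))
  gids <- genome_ids %||% matrix$genome_ids
  tp <- parse_taxonomy(taxonomy)
  taxa <- taxon_of(tp, gids, level)
  ecos <- sort(unique(matrix$ecotype_of_culture))
  utaxa <- sort(unique(taxa))
  out <- matrix(0L, length(ecos), length(utaxa),
                dimnames = list(ecos, utaxa))
  pres <- matrix$presence[, gids, drop = FALSE]
  for (tx in utaxa) {
    in_taxon <- pres[, taxa == tx, drop = FALSE]
    culture_has <- rowSums(in_taxon) > 0
    for (e in ecos) {
      out[e, tx] <- sum(culture_has & matrix$ecotype_of_culture == e)
    }
  }
  out
}

#' Heat-tree node table
#'
#' One row per taxon across all ranks of the lineage: the number of genomes
#' under the taxon and, per ecotype, the number of cultures of that ecotype
#' containing at least one genome under the taxon. Counts at a parent taxon
#' are the size of the union of its children's contributing culture sets,
#' so a parent's count is at least each child's.
#'
#' @param matrix a [presence_matrix()] restricted to the genomes of
#'   interest.
#' @param taxonomy taxonomy table (`genome_id`, `lineage`).
#' @param genome_ids optional subset of columns.
#' @return data.frame `taxon`, `rank`, `n_genomes`, then one count column
#'   per ecotype.
#' @export
heat_tree_table <- function(matrix, taxonomy, genome_ids = NULL) {
  stopifnot(inherits(matrix, "presence_matrix"))
  gids <- genome_ids %||% matrix$genome_ids
  if (length(gids) == 0 || nrow(taxonomy) == 0) {
    return(data.frame(taxon = character(0), rank = character(0),
                      n_genomes = integer(0), stringsAsFactors = FALSE))
  }
  tp <- parse_taxonomy(taxonomy)
  # a taxon name appearing at two ranks would make the tree cyclic/ill-formed
  all_names <- unlist(lapply(TAX_RANKS, function(r) unique(stats::na.omit(tp[[r]]))))
  if (anyDuplicated(all_names))
    stop_bad_arg("taxon name reused across ranks: ",
                 paste(unique(all_names[duplicated(all_names)]), collapse = ", "))
  ecos <- sort(unique(matrix$ecotype_of_culture))
  pres <- matrix$presence[, gids, drop = FALSE]
  rows <- list()
  for (rank in TAX_RANKS) {
    taxa <- taxon_of(tp, gids, rank)
    for (tx in sort(unique(stats::na.omit(taxa)))) {
      members <- gids[!is.na(taxa) & taxa == tx]
      culture_has <- rowSums(pres[, members, drop = FALSE]) > 0
      counts <- vapply(ecos, function(e) {
        sum(culture_has & matrix$ecotype_of_culture == e)
      }, integer(1))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(taxon = tx, rank = rank, n_genomes = length(members),
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(counts)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
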