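OFFTARGET_LABELS <- c("no_hit", "eukaryote", "virus")

#' Decontamination configuration
#'
#' @param max_offtarget_fraction contigs with a strictly greater fraction of
#'   off-target genes are dropped (default 0.30).
#' @param offtarget_labels labels counted as off-target (default
#'   `"no_hit"`, `"eukaryote"`, `"virus"`).
#' @return list of class `decontam_config`.
#' @export
decontam_config <- function(max_offtarget_fraction = 0.30,
                            offtarget_labels = OFFTARGET_LABELS) {
  check_fraction(max_offtarget_fraction, "max_offtarget_fraction",
                 0, 1, lo_open = TRUE, hi_open = TRUE)
  structure(list(max_offtarget_fraction = max_offtarget_fraction,
                 offtarget_labels = offtarget_labels,
                 consensus_rank = "class"),
            class = "decontam_config")
}

validate_bin_gene_table <- function(table) {
  need <- c("contig_id", "gene_index", "class_call")
  if (!all(need %in% names(table)))
    stop_bad_arg("bin gene table needs columns: ", paste(need, collapse = ", "))
  if (nrow(table) == 0) stop_bad_arg("bin gene table is empty")
  if (anyDuplicated(table[c("contig_id", "gene_index")]))
    stop_bad_arg("(contig_id, gene_index) must be unique")
  invisible(table)
}

#' Consensus class of a bin
#'
#' The plurality class among all classified genes in the bin (off-target
#' labels excluded); ties are broken lexicographically.
#'
#' @param table per-gene taxonomy table (`contig_id`, `gene_index`,
#'   `class_call`).
#' @param config a [decontam_config()].
#' @return the consensus class label.
#' @export
consensus_class <- function(table, config = decontam_config()) {
  validate_bin_gene_table(table)
  calls <- table$class_call[!table$class_call %in% config$offtarget_labels]
  if (length(calls) == 0)
    stop_bad_arg("no classified genes in bin: consensus undefined")
  tab <- table(calls)
  winners <- names(tab)[tab == max(tab)]
  sort(winners)[1]
}

#' Flag contigs for removal by the taxonomy rule
#'
#' A contig is dropped if strictly more than `max_offtarget_fraction` of its
#' genes are off-target (no hit / eukaryote / virus), or if the plurality
#' class of its classified genes disagrees with the bin consensus. The
#' consensus is computed once on the full bin before any removal; a contig
#' with zero classified genes is judged only by the fraction rule.
#'
#' @param table per-gene taxonomy table for one bin.
#' @param config a [decontam_config()].
#' @return data.frame with one row per contig: `contig_id`, `n_genes`,
#'   `offtarget_fraction`, `contig_class`, `keep`, `reason` (one of
#'   `"offtarget_fraction"`, `"class_disagreement"`, `"both"`, or `NA` for
#'   kept contigs); the bin consensus is attached as attribute `consensus`.
#' @export
flag_contigs <- function(table, config = decontam_config()) {
  validate_bin_gene_table(table)
  consensus <- consensus_class(table, config)
  contigs <- unique(table$contig_id)
  res <- lapply(contigs, function(cid) {
    calls <- table$class_call[table$contig_id == cid]
    off <- mean(calls %in% config$offtarget_labels)
    classified <- calls[!calls %in% config$offtarget_labels]
    cls <- if (length(classified)) {
      tab <- table(classified)
      sort(names(tab)[tab == max(tab)])[1]
    } else NA_character_
    frac_fail <- off > config$max_offtarget_fraction
    class_fail <- !is.na(cls) && cls != consensus
    reason <- if (frac_fail && class_fail) "both"
    else if (frac_fail) "offtarget_fraction"
    else if (class_fail) "class_disagreement"
    else NA_character_
    data.frame(contig_id = cid, n_genes = length(calls),
               offtarget_fraction = off, contig_class = cls,
               keep = !(frac_fail || class_fail), reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "consensus") <- consensus
  out
}

#' Bin quality gate
#'
#' Retains bins with completeness of at least `min_completeness` percent and
#' contamination of at most `max_contamination` percent (both inclusive).
#'
#' @param stats data.frame with `completeness` and `contamination` (percent),
#'   optionally `bin_id`.
#' @param min_completeness,max_contamination thresholds in percent.
#' @return logical vector, one element per row of `stats`.
#' @export
qc_gate <- function(stats, min_completeness = 80, max_contamination = 5) {
  if (!all(c("completeness", "contamination") %in% names(stats)))
    stop_bad_arg("`stats` needs completeness and contamination columns")
  if (any(is.na(stats$completeness)) || any(is.na(stats$contamination)))
    stop_bad_arg("missing completeness/contamination values")
  if (any(stats$completeness < 0 | stats$completeness > 100))
    stop_bad_arg("completeness must lie in [0, 100]")
  if (any(stats$contamination < 0))
    stop_bad_arg("contamination must be non-negative")
  stats$completeness >= min_completeness &
    stats$contamination <= max_contamination
}

#' Compose a bin name from sample, binning method and number
#'
#' Bins are renamed `<sample>.<code>.<number>` with method codes
#' mx (MaxBin), m1 (Metabat1) and m2 (Metabat2).
#'
#' @param sample_id sample of origin.
#' @param method one of `"maxbin"`, `"metabat1"`, `"metabat2"`.
#' @param number bin number (>= 1).
#' @return the bin id string.
#' @examples
#' name_bin("S01", "metabat2", 3)  # "S01.m2.3"
#' @export
name_bin <- function(sample_id, method, number) {
  codes <- c(maxbin = "mx", metabat1 = "m1", metabat2 = "m2")
  if (!method %in% names(codes))
    stop_bad_arg("unknown binning method: ", method)
  if (!is.numeric(number) || number < 1 || number != as.integer(number))
    stop_bad_arg("`number` must be a positive integer")
  sprintf("%s.%s.%d", sample_id, codes[[method]], as.integer(number))
}
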