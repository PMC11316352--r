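#' Default CRISPR-Cas subtype schema
#'
#' Adaptation module genes (cas1/cas2, shared across subtypes) and
#' subtype-specific interference module genes for the subtypes observed in
#' picocyanobacteria (I-E, I-G, III-B). The schema is a plain editable list
#' (also shipped as a JSON asset) because cas gene nomenclature is contested
#' and must not be hard-coded into the completeness logic.
#'
#' @return list of class `subtype_schema` with `adaptation_genes` and
#'   `interference_genes` (named list by subtype).
#' @export
default_subtype_schema <- function() {
  structure(list(
    adaptation_genes = c("cas1", "cas2"),
    interference_genes = list(
      "I-E" = c("cas3", "cse1", "cse2", "cas7", "cas5", "cas6e"),
      "I-G" = c("cas3", "csb2", "cas7", "cas5"),
      "III-B" = c("cas10", "cmr1", "cmr3", "cmr4", "cmr5", "cmr6"))),
    class = "subtype_schema")
}

#' Load a subtype schema from JSON
#' @param path JSON file with `adaptation_genes` and `interference_genes`.
#' @return a `subtype_schema`.
#' @export
read_subtype_schema <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "subtype_schema")
}

#' Cas1 curation configuration
#'
#' @param max_p_value hits must have p strictly below this (default 0.01).
#' @param min_length_aa hits must be strictly longer than this (default 80).
#' @param top_k neighbors kept per query (default 10).
#' @param cluster_identity greedy clustering identity threshold (default
#'   0.90).
#' @param cluster_coverage bidirectional coverage threshold (default 0.80).
#' @return list of class `cas1_config`.
#' @export
cas1_config <- function(max_p_value = 0.01, min_length_aa = 80, top_k = 10L,
                        cluster_identity = 0.90, cluster_coverage = 0.80) {
  if (max_p_value <= 0 || min_length_aa <= 0 || top_k < 1 ||
      cluster_identity <= 0 || cluster_coverage <= 0)
    stop_bad_arg("thresholds must be positive")
  structure(list(max_p_value = max_p_value, min_length_aa = min_length_aa,
                 top_k = as.integer(top_k),
                 cluster_identity = cluster_identity,
                 cluster_coverage = cluster_coverage),
            class = "cas1_config")
}

#' Module completeness of one CRISPR-Cas locus
#'
#' @param locus_rows data.frame of the locus's rows (`subtype`, `gene_name`,
#'   `gene_quality`, `n_spacers_in_locus`). Low-quality gene matches count
#'   towards completeness (they are displayed, not discarded).
#' @param schema a `subtype_schema`.
#' @return list: `adaptation_complete` (all adaptation genes present),
#'   `interference_complete` (all interference genes of the subtype
#'   present), `cas1_less_with_spacers` (cas1 absent yet spacers in the
#'   array). A locus with zero gene rows returns all `FALSE`.
#' @export
locus_completeness <- function(locus_rows, schema = default_subtype_schema()) {
  if (nrow(locus_rows) == 0) {
    return(list(adaptation_complete = FALSE, interference_complete = FALSE,
                cas1_less_with_spacers = FALSE))
  }
  subtype <- unique(locus_rows$subtype)
  if (length(subtype) != 1)
    stop_bad_arg("locus rows must share one subtype")
  if (!subtype %in% names(schema$interference_genes))
    stop_bad_arg("unknown subtype '", subtype, "' (known: ",
                 paste(names(schema$interference_genes), collapse = ", "), ")")
  genes <- unique(locus_rows$gene_name)
  n_spacers <- max(locus_rows$n_spacers_in_locus)
  list(
    adaptation_complete = all(schema$adaptation_genes %in% genes),
    interference_complete = all(schema$interference_genes[[subtype]] %in% genes),
    cas1_less_with_spacers = !("cas1" %in% genes) && n_spacers >= 1)
}

#' CRISPR-Cas prevalence per genome group
#'
#' A genome counts as CRISPR-positive when it carries at least one locus; a
#' positive genome "lacks cas1" when none of its loci contain a cas1 gene.
#' Percentages are rounded half-up to one decimal for reporting; raw
#' fractions are retained.
#'
#' @param loci cas locus table (`genome_id`, `locus_id`, `subtype`,
#'   `gene_name`, `gene_quality`, `n_spacers_in_locus`).
#' @param groups named character vector mapping every genome id to a group.
#' @return data.frame with one row per group: `group`, `n_genomes`,
#'   `n_with_system`, `fraction_with_system`, `percent_with_system`,
#'   `n_lacking_cas1`, `fraction_lacking_cas1`, `percent_lacking_cas1`,
#'   `subtypes` (e.g. `"I-E:12,I-G:9"`).
#' @export
prevalence_by_group <- function(loci, groups) {
  unassigned <- setdiff(unique(loci$genome_id), names(groups))
  if (length(unassigned))
    stop_bad_arg("genomes without group: ", paste(unassigned, collapse = ", "))
  out <- list()
  for (g in unique(groups)) {
    gids <- names(groups)[groups == g]
    if (length(gids) == 0) {
      warning("group with zero genomes omitted: ", g)
      next
    }
    sub <- loci[loci$genome_id %in% gids, , drop = FALSE]
    pos <- unique(sub$genome_id)
    npos <- length(pos)
    lacking <- vapply(pos, function(id) {
      !"cas1" %in% sub$gene_name[sub$genome_id == id]
    }, logical(1))
    sub_counts <- if (npos) {
      per <- unique(sub[c("genome_id", "subtype")])
      tab <- sort(table(per$subtype), decreasing = TRUE)
      paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = ",")
    } else ""
    out[[length(out) + 1L]] <- data.frame(
      group = g, n_genomes = length(gids), n_with_system = npos,
      fraction_with_system = npos / length(gids),
      percent_with_system = round_half_up(100 * npos / length(gids), 1),
      n_lacking_cas1 = sum(lacking),
      fraction_lacking_cas1 = if (npos) sum(lacking) / npos else NA_real_,
      percent_lacking_cas1 = if (npos)
        round_half_up(100 * sum(lacking) / npos, 1) else NA_real_,
      subtypes = sub_counts, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Filter Cas1 HMM hits
#'
#' Retains hits with p-value strictly below `max_p_value` and sequence
#' length strictly above `min_length_aa`.
#'
#' @param hits data.frame with `seq_id`, `p_value`, `length_aa`.
#' @param config a [cas1_config()].
#' @return character vector of retained seq ids.
#' @export
cas1_filter_hits <- function(hits, config = cas1_config()) {
  if (nrow(hits) == 0) stop_bad_arg("empty hit table")
  if (any(hits$length_aa < 0)) stop_bad_arg("negative sequence length")
  hits$seq_id[hits$p_value < config$max_p_value &
                hits$length_aa > config$min_length_aa]
}

#' Top-k neighbors per query
#'
#' Keeps the k highest-scoring targets for each query (ties at the k-th
#' rank resolved to the lexicographically smaller target id) and returns
#' the union over queries.
#'
#' @param similarities data.frame with `query_id`, `target_id`, `score`.
#' @param k neighbors per query (default 10).
#' @return sorted character vector of selected target ids.
#' @export
topk_neighbors <- function(similarities, k = 10L) {
  if (k < 1) stop_bad_arg("`k` must be >= 1")
  picks <- lapply(split(similarities, similarities$query_id), function(d) {
    d <- d[order(-d$score, d$target_id), , drop = FALSE]
    utils::head(d$target_id, k)
  })
  sort(unique(unlist(picks, use.names = FALSE)))
}

# global protein alignment identity/coverage; identity is
# matches / alignment columns excluding terminal gaps
# (match 1, mismatch 0, gap open -11, extend -1)
aa_align_stats <- function(a, b) {
  alpha <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
             "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "X", "*")
  mat <- diag(1, length(alpha))
  dimnames(mat) <- list(alpha, alpha)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = 11, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  gap <- p == "-" | s == "-"
  # trim terminal gap runs: keep columns between the first and last
  # all-residue column
  both <- which(!gap)
  if (length(both) == 0) return(list(identity = 0, cov_a = 0, cov_b = 0))
  cols <- both[1]:both[length(both)]
  matches <- sum(p[cols] == s[cols] & p[cols] != "-")
  list(identity = matches / length(cols),
       cov_a = sum(p[cols] != "-") / nchar(a),
       cov_b = sum(s[cols] != "-") / nchar(b))
}

#' Greedy identity-threshold protein clustering
#'
#' Sequences are sorted by decreasing length (ties by id) and processed in
#' order: a sequence joins the first existing centroid reached at
#' `cluster_identity` global-alignment identity with bidirectional coverage
#' of at least `cluster_coverage`, otherwise it founds a new cluster.
#'
#' @param sequences named character vector of amino-acid sequences.
#' @param config a [cas1_config()].
#' @return data.frame `seq_id`, `centroid`.
#' @export
greedy_cluster <- function(sequences, config = cas1_config()) {
  if (length(sequences) == 0) stop_bad_arg("no sequences")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop_bad_arg("sequences must have unique names")
  if (any(!nzchar(sequences))) stop_bad_arg("empty sequence")
  ord <- order(-nchar(sequences), names(sequences))
  centroids <- character(0)
  assign <- character(length(sequences))
  names(assign) <- names(sequences)
  for (i in ord) {
    id <- names(sequences)[i]
    hit <- NA_character_
    for (cid in centroids) {
      st <- aa_align_stats(sequences[[i]], sequences[[cid]])
      if (st$identity >= config$cluster_identity &&
          st$cov_a >= config$cluster_coverage &&
          st$cov_b >= config$cluster_coverage) {
        hit <- cid
        break
      }
    }
    if (is.na(hit)) {
      centroids <- c(centroids, id)
      assign[id] <- id
    } else assign[id] <- hit
  }
  data.frame(seq_id = names(sequences), centroid = unname(assign[names(sequences)]),
             stringsAsFactors = FALSE)
}

#' Cas1 curation chain
#'
#' Applies the full curation used before tree building: filter HMM hits
#' (p < 0.01, length > 80 aa), keep the top-k neighbors of each
#' picocyanobacterial query among the retained sequences, then collapse the
#' union at 90% identity by greedy clustering. Returns the centroid
#' sequences.
#'
#' @param hits data.frame `seq_id`, `p_value`, `length_aa`.
#' @param similarities data.frame `query_id`, `target_id`, `score`.
#' @param sequences named character vector of amino-acid sequences.
#' @param config a [cas1_config()].
#' @return named character vector of curated (centroid) sequences.
#' @export
cas1_curate <- function(hits, similarities, sequences,
                        config = cas1_config()) {
  retained <- cas1_filter_hits(hits, config)
  sim <- similarities[similarities$target_id %in% retained, , drop = FALSE]
  selected <- topk_neighbors(sim, config$top_k)
  selected <- union(selected, intersect(unique(similarities$query_id), retained))
  seqs <- sequences[intersect(names(sequences), selected)]
  if (length(seqs) == 0) return(character(0))
  cl <- greedy_cluster(seqs, config)
  sequences[unique(cl$centroid)]
}
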