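#' Simulate a per-gene taxonomy table for one bin
#'
#' Emulates the table a gene-level taxonomic classifier produces for a
#' genome bin: clean contigs carry at least 90% of genes labeled with the
#' bin's consensus class (the remainder are "no_hit"), while planted
#' contaminant contigs carry a requested fraction of off-target labels
#' (a foreign class, `"no_hit"`, `"eukaryote"` or `"virus"`).
#'
#' @param n_contigs number of contigs in the bin.
#' @param consensus_class the class label of the true organism.
#' @param contaminant_spec list of `list(contig, label, fraction)` entries;
#'   `contig` is a 1-based contig index, `fraction` the fraction of that
#'   contig's genes carrying `label`.
#' @param seed RNG seed.
#' @param genes_per_contig genes per contig (default 10).
#' @param bin_id bin identifier.
#' @return list with `table` (data.frame `bin_id`, `contig_id`,
#'   `gene_index`, `class_call`) and `truth` (per-contig data.frame with
#'   `contig_id`, `is_contaminant`, `planted_label`, `planted_fraction`).
#' @export
generate_bin_gene_table <- function(n_contigs, consensus_class,
                                    contaminant_spec = list(), seed = 1L,
                                    genes_per_contig = 10L, bin_id = "bin1") {
  if (n_contigs < 1) stop_bad_arg("`n_contigs` must be >= 1")
  idx <- vapply(contaminant_spec, function(s) as.integer(s[[1]]), integer(1))
  if (length(idx) && (any(idx < 1) || any(idx > n_contigs)))
    stop_bad_arg("contaminant contig index out of range")
  if (anyDuplicated(idx)) stop_bad_arg("duplicate contaminant contig index")
  for (s in contaminant_spec) check_fraction(s[[3]], "fraction")
  contig_ids <- sprintf("%s.c%03d", bin_id, seq_len(n_contigs))
  planted_label <- rep(NA_character_, n_contigs)
  planted_frac <- rep(0, n_contigs)
  for (s in contaminant_spec) {
    planted_label[s[[1]]] <- s[[2]]
    planted_frac[s[[1]]] <- s[[3]]
  }
  rows <- with_seed(seed, {
    out <- vector("list", n_contigs)
    for (ci in seq_len(n_contigs)) {
      ng <- genes_per_contig
      calls <- rep(consensus_class, ng)
      if (!is.na(planted_label[ci])) {
        k <- round(planted_frac[ci] * ng)
        if (k > 0) calls[sample.int(ng, k)] <- planted_label[ci]
      } else {
        # clean contigs: at most 10% off-target, labelled no_hit
        k <- min(stats::rbinom(1, ng, 0.05), floor(0.1 * ng))
        if (k > 0) calls[sample.int(ng, k)] <- "no_hit"
      }
      out[[ci]] <- data.frame(bin_id = bin_id, contig_id = contig_ids[ci],
                              gene_index = seq_len(ng), class_call = calls,
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  truth <- data.frame(contig_id = contig_ids,
                      is_contaminant = !is.na(planted_label),
                      planted_label = planted_label,
                      planted_fraction = planted_frac,
                      stringsAsFactors = FALSE)
  list(table = rows, truth = truth)
}

#' Default marker panel for ecotype contrasts
#'
#' Gene groups implicated in the symbiotic-interaction and niche-adaptation
#' repertoire of freshwater picocyanobacteria: nitrogen assimilation
#' (narB/nirA reductases, nrtABC nitrate transport, amt, urtA), assimilatory
#' sulfate reduction (cysDNC/cysH/sir), ROS detoxification (katE, sod1),
#' phycoerythrin pigmentation (cpeA/cpeB), pili-mediated chemotaxis
#' (pilA, cheB, cheR), trehalose biosynthesis under cold stress
#' (treS/otsA/otsB) and lactone degradation in humic waters (mlhB).
#'
#' The panel also records which genes diagnose each ecotype (used by the
#' table generator and recovered by [ecotype_contrast()]) and the pigment
#' phenotype of each ecotype. The pigment genes cpeA/cpeB are exempt from
#' background annotation noise in the generator: pigmentation is
#' genotype-determined, so green strains simply lack the operon.
#'
#' @return a list of class `marker_panel` with elements `groups`,
#'   `genes`, `ecotype_markers`, `pigment`, `background_rate`,
#'   `background_exempt`.
#' @export
default_marker_panel <- function() {
  groups <- list(
    nitrogen = c("narB", "nirA", "nrtA", "nrtB", "nrtC", "amt", "urtA"),
    sulfur = c("cysD", "cysN", "cysC", "cysH", "sir"),
    ros = c("katE", "sod1"),
    pigment = c("cpeA", "cpeB"),
    motility_chemotaxis = c("pilA", "cheB", "cheR"),
    cold = c("treS", "otsA", "otsB"),
    humic = c("mlhB"))
  structure(list(
    groups = groups,
    genes = unique(unlist(groups, use.names = FALSE)),
    ecotype_markers = list(
      "SC5.3" = c("cpeA", "cpeB"),
      "LN" = c("cpeA", "cpeB"),
      "LNLT" = c("treS", "otsA", "otsB", "cpeA", "cpeB"),
      "HN" = c("cheB", "cheR", "pilA"),
      "LP" = c("mlhB")),
    pigment = c("SC5.3" = "red", "LN" = "red", "LNLT" = "red",
                "HN" = "green", "LP" = "green"),
    background_rate = 0.05,
    background_exempt = c("cpeA", "cpeB")),
    class = "marker_panel")
}

#' Load a marker panel from a JSON asset
#'
#' @param path JSON file with the fields of [default_marker_panel()].
#' @return a `marker_panel`.
#' @export
read_marker_panel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$genes <- unique(unlist(x$groups, use.names = FALSE))
  x$pigment <- unlist(x$pigment)
  structure(x, class = "marker_panel")
}

#' Simulate the KO/marker presence profile of one genome
#'
#' Diagnostic markers of the genome's ecotype are present (copy number 1)
#' except for random dropout; all other panel genes appear at the panel's
#' background rate (default 0.05), emulating annotation noise, except genes
#' listed as `background_exempt`.
#'
#' @param ecotype one of the panel's ecotypes.
#' @param panel a `marker_panel` (default [default_marker_panel()]).
#' @param dropout per-marker dropout probability in \[0, 1).
#' @param seed RNG seed.
#' @return named integer vector of copy numbers over the panel genes.
#' @export
generate_ko_table <- function(ecotype, panel = default_marker_panel(),
                              dropout = 0, seed = 1L) {
  if (!ecotype %in% names(panel$ecotype_markers))
    stop_bad_arg("unknown ecotype: ", ecotype, " (known: ",
                 paste(names(panel$ecotype_markers), collapse = ", "), ")")
  check_fraction(dropout, "dropout", 0, 1, hi_open = TRUE)
  diag_genes <- panel$ecotype_markers[[ecotype]]
  with_seed(seed, {
    present <- stats::setNames(integer(length(panel$genes)), panel$genes)
    bg <- setdiff(panel$genes, c(diag_genes, panel$background_exempt))
    present[bg] <- as.integer(stats::runif(length(bg)) < panel$background_rate)
    keep <- stats::runif(length(diag_genes)) >= dropout
    present[diag_genes[keep]] <- 1L
    present
  })
}

#' Simulate a culture collection with known ground truth
#'
#' Builds the genome pool (one picocyanobacterium genome per ecotype plus a
#' heterotroph pool containing one planted symbiont and decoys), assigns each
#' culture a picocyanobacterium (round robin over ecotypes) and 0-3
#' heterotrophs, plants the symbiont in
#' `round(planted_symbiont_prevalence * n_cultures)` cultures and each decoy
#' in at most 4, and sizes the read sets so every member genome is sampled at
#' ~6x depth (members share reads in proportion to abundance x length;
#' abundances are equal, so depth is uniform across members).
#'
#' @param config a [sim_config()].
#' @return list with `genomes` (named list of [genome_record()]),
#'   `cultures` (list of [culture_truth()]), `ecotype_of_culture` (named
#'   character), and `truth` (data.frame `culture_id`, `genome_id`,
#'   `role`, `planted_symbiont`).
#' @export
simulate_culture_collection <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  ecos <- c("SC5.3", "LN", "LNLT", "HN", "LP")
  ms <- config$master_seed
  lr <- config$genome_length_range
  gr <- config$gc_range
  rand_len <- function(seed) with_seed(seed, sample(lr[1]:lr[2], 1))
  rand_gc <- function(seed) with_seed(seed, stats::runif(1, gr[1], gr[2]))
  genomes <- list()
  for (i in seq_along(ecos)) {
    id <- sprintf("pico_%s", ecos[i])
    s <- derive_seed(ms, id)
    genomes[[id]] <- generate_genome(rand_len(s), rand_gc(s + 1L), s + 2L,
                                     genome_id = id,
                                     role = "picocyanobacterium",
                                     ecotype = ecos[i])
  }
  het_ids <- c("het_symbiont",
               sprintf("het_decoy%02d", seq_len(config$heterotroph_pool_size - 1L)))
  for (id in het_ids) {
    s <- derive_seed(ms, id)
    genomes[[id]] <- generate_genome(rand_len(s), rand_gc(s + 1L), s + 2L,
                                     genome_id = id, role = "heterotroph")
  }
  n <- config$n_cultures
  cids <- sprintf("cu%03d", seq_len(n))
  pico_of <- stats::setNames(sprintf("pico_%s", ecos[(seq_len(n) - 1L) %% 5L + 1L]),
                             cids)
  n_symb <- round(config$planted_symbiont_prevalence * n)
  membership <- with_seed(derive_seed(ms, "membership"), {
    m <- lapply(cids, function(cid) pico_of[[cid]])
    names(m) <- cids
    symb_cultures <- sample(cids, n_symb)
    for (cid in symb_cultures) m[[cid]] <- c(m[[cid]], "het_symbiont")
    for (hid in setdiff(het_ids, "het_symbiont")) {
      k <- sample(0:4, 1)
      for (cid in sample(cids, k)) {
        if (length(m[[cid]]) < 4L) m[[cid]] <- c(m[[cid]], hid)
      }
    }
    m
  })
  cultures <- lapply(cids, function(cid) {
    members <- membership[[cid]]
    lens <- vapply(genomes[members], function(g) g$length_bp, integer(1))
    n_reads <- config$n_reads %||%
      as.integer(ceiling(6 * sum(lens) / config$read_length))
    culture_truth(cid, members, rep(1 / length(members), length(members)),
                  n_reads = n_reads, read_length = config$read_length,
                  substitution_rate = config$substitution_rate,
                  seed = derive_seed(ms, paste0("reads_", cid)))
  })
  names(cultures) <- cids
  eco_of_culture <- stats::setNames(
    vapply(cids, function(cid) genomes[[pico_of[[cid]]]]$ecotype, character(1)),
    cids)
  truth <- do.call(rbind, lapply(cids, function(cid) {
    members <- membership[[cid]]
    data.frame(culture_id = cid, genome_id = members,
               role = vapply(genomes[members], function(g) g$role, character(1)),
               planted_symbiont = members == "het_symbiont",
               stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  list(genomes = genomes, cultures = cultures,
       ecotype_of_culture = eco_of_culture, truth = truth)
}

#' Write a data.frame as a TSV truth/table file
#'
#' One header line, tab-separated, no quoting: diffable fixtures.
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
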