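#' ANI estimator configuration
#'
#' The estimator cuts the query into non-overlapping fragments, places each
#' fragment on the reference by exact k-mer seeding plus ungapped extension,
#' and averages the identities of the fragments that align at or above
#' `min_fragment_identity`. Species and population delineation use the
#' conventional 95% cutoff and the 85% population boundary.
#'
#' @param fragment_length fragment size in bp (default 1000).
#' @param kmer_size seed length (default 16).
#' @param min_fragment_identity fragments below this identity do not count
#'   as aligned (default 0.80).
#' @param min_aligned_fraction below this aligned fraction the estimate is
#'   reported as missing (default 0.20).
#' @param species_cutoff,population_cutoff clustering cutoffs (defaults
#'   0.95 and 0.85; the population cutoff must be the smaller).
#' @return list of class `ani_config`.
#' @export
ani_config <- function(fragment_length = 1000L, kmer_size = 16L,
                       min_fragment_identity = 0.80,
                       min_aligned_fraction = 0.20,
                       species_cutoff = 0.95, population_cutoff = 0.85) {
  check_fraction(min_fragment_identity, "min_fragment_identity", 0, 1, lo_open = TRUE)
  check_fraction(min_aligned_fraction, "min_aligned_fraction", 0, 1, lo_open = TRUE)
  check_fraction(species_cutoff, "species_cutoff", 0, 1, lo_open = TRUE)
  check_fraction(population_cutoff, "population_cutoff", 0, 1, lo_open = TRUE)
  if (population_cutoff >= species_cutoff)
    stop_bad_arg("population_cutoff must be below species_cutoff")
  if (kmer_size < 8 || kmer_size > 31)
    stop_bad_arg("`kmer_size` must lie in [8, 31]")
  structure(list(fragment_length = as.integer(fragment_length),
                 kmer_size = as.integer(kmer_size),
                 min_fragment_identity = min_fragment_identity,
                 min_aligned_fraction = min_aligned_fraction,
                 species_cutoff = species_cutoff,
                 population_cutoff = population_cutoff),
            class = "ani_config")
}

#' Directed fragment-based ANI
#'
#' The query is cut into non-overlapping `fragment_length` windows (a
#' trailing partial window is dropped). Each fragment is placed on the
#' reference, either strand, by exact k-mer seeding followed by ungapped
#' extension over the full fragment; fragment identity is
#' matches / fragment_length at the best placement (overhangs count as
#' mismatches). Fragments at or above `min_fragment_identity` are "aligned";
#' the ANI is the mean identity of aligned fragments, reported as `NA` when
#' the aligned fraction falls below `min_aligned_fraction`.
#'
#' @param query,reference [genome_record()] objects.
#' @param config an [ani_config()].
#' @return list with `ani` (fraction or `NA`), `aligned_fraction`,
#'   `n_fragments`, and per-fragment `fragment_identity`.
#' @export
directed_ani <- function(query, reference, config = ani_config()) {
  stopifnot(inherits(query, "genome_record"),
            inherits(reference, "genome_record"))
  flen <- config$fragment_length
  if (query$length_bp < flen || reference$length_bp < flen)
    stop_bad_arg("both sequences must be at least fragment_length long")
  n_frag <- query$length_bp %/% flen
  starts <- (seq_len(n_frag) - 1L) * flen + 1L
  frags <- substring(query$sequence, starts, starts + flen - 1L)
  hits <- cpp_seed_extend(frags, reference$sequence, config$kmer_size, TRUE)
  ident <- ifelse(hits$placed, hits$matches / flen, 0)
  aligned <- ident >= config$min_fragment_identity
  af <- mean(aligned)
  ani <- if (af < config$min_aligned_fraction || !any(aligned)) NA_real_
  else mean(ident[aligned])
  list(ani = ani, aligned_fraction = af, n_fragments = n_frag,
       fragment_identity = ident)
}

#' Pairwise ANI matrix
#'
#' Computes all ordered pairs with [directed_ani()] and symmetrizes each
#' pair as the arithmetic mean of the two directions (the mean of the
#' available direction when only one is non-missing). The diagonal is
#' exactly 1.
#'
#' @param genomes list of [genome_record()] (at least two, unique ids).
#' @param config an [ani_config()].
#' @return list of class `ani_matrix` with `genome_ids`, `ani` (symmetric
#'   matrix, `NA` where no estimate), `aligned_fraction`.
#' @export
ani_matrix <- function(genomes, config = ani_config()) {
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  if (length(genomes) < 2) stop_bad_arg("need at least two genomes")
  if (anyDuplicated(ids)) stop_bad_arg("duplicate genome_id")
  n <- length(genomes)
  ani <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  af <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(ani) <- 1
  diag(af) <- 1
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dij <- directed_ani(genomes[[i]], genomes[[j]], config)
      dji <- directed_ani(genomes[[j]], genomes[[i]], config)
      vals <- c(dij$ani, dji$ani)
      ani[i, j] <- ani[j, i] <-
        if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
      af[i, j] <- af[j, i] <- mean(c(dij$aligned_fraction,
                                     dji$aligned_fraction))
    }
  }
  structure(list(genome_ids = ids, ani = ani, aligned_fraction = af),
            class = "ani_matrix")
}

#' Cluster genomes at an ANI cutoff
#'
#' Single-linkage delineation: genomes are nodes, pairs with
#' `ani >= cutoff` are edges (missing estimates contribute no edge), and
#' clusters are connected components, so chains merge by transitive closure.
#' Cluster labels are the lexicographically smallest member id. Partitions
#' at the 85% population cutoff are therefore always coarsenings of the
#' partitions at the 95% species cutoff. A greedy centroid alternative
#' (`method = "greedy"`) assigns each genome, in lexicographic order, to the
#' first centroid within the cutoff.
#'
#' @param matrix an [ani_matrix()].
#' @param cutoff ANI cutoff in (0, 1].
#' @param method `"single"` (connected components, default) or `"greedy"`.
#' @return data.frame with `genome_id` and `cluster`.
#' @export
cluster_at <- function(matrix, cutoff, method = c("single", "greedy")) {
  stopifnot(inherits(matrix, "ani_matrix"))
  method <- match.arg(method)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0 || cutoff > 1)
    stop_bad_arg("`cutoff` must lie in (0, 1]")
  ids <- matrix$genome_ids
  n <- length(ids)
  adj <- !is.na(matrix$ani) & matrix$ani >= cutoff
  if (method == "single") {
    comp <- rep(NA_integer_, n)
    cur <- 0L
    for (s in seq_len(n)) {
      if (!is.na(comp[s])) next
      cur <- cur + 1L
      queue <- s
      comp[s] <- cur
      while (length(queue)) {
        v <- queue[[1]]
        queue <- queue[-1]
        nb <- which(adj[v, ] & is.na(comp))
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
    cluster <- vapply(seq_len(n),
                      function(i) sort(ids[comp == comp[i]])[1], character(1))
  } else {
    ord <- order(ids)
    centroids <- integer(0)
    assign <- rep(NA_integer_, n)
    for (i in ord) {
      hit <- centroids[which(adj[i, centroids])[1]]
      if (length(centroids) && !is.na(hit)) {
        assign[i] <- hit
      } else {
        centroids <- c(centroids, i)
        assign[i] <- i
      }
    }
    cluster <- ids[assign]
  }
  data.frame(genome_id = ids, cluster = cluster, stringsAsFactors = FALSE)
}

#' Heatmap row order for an ANI matrix
#'
#' Average-linkage hierarchical clustering on 1 - ANI (missing estimates
#' treated as distance 1); returns genome ids in leaf order, a stand-in for
#' ordering by a phylogenomic tree.
#'
#' @param matrix an [ani_matrix()].
#' @return character vector of genome ids.
#' @export
ani_heatmap_order <- function(matrix) {
  stopifnot(inherits(matrix, "ani_matrix"))
  d <- 1 - matrix$ani
  d[is.na(d)] <- 1
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  matrix$genome_ids[hc$order]
}

#' Long-form export of an ANI matrix
#'
#' @param matrix an [ani_matrix()].
#' @return data.frame `id_a`, `id_b`, `ani`, `aligned_fraction` (upper
#'   triangle).
#' @export
ani_long <- function(matrix) {
  stopifnot(inherits(matrix, "ani_matrix"))
  ids <- matrix$genome_ids
  pairs <- which(upper.tri(matrix$ani), arr.ind = TRUE)
  data.frame(id_a = ids[pairs[, 1]], id_b = ids[pairs[, 2]],
             ani = matrix$ani[pairs],
             aligned_fraction = matrix$aligned_fraction[pairs],
             stringsAsFactors = FALSE)
}
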