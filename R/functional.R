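as_ko_matrix <- function(ko) {
  if (is.data.frame(ko)) {
    if ("genome_id" %in% names(ko)) {
      ids <- ko$genome_id
      ko <- as.matrix(ko[setdiff(names(ko), "genome_id")])
      rownames(ko) <- ids
    } else ko <- as.matrix(ko)
  }
  if (!is.matrix(ko) || is.null(rownames(ko)) || is.null(colnames(ko)))
    stop_bad_arg("KO table must have genome rownames and gene colnames")
  if (anyDuplicated(rownames(ko))) stop_bad_arg("duplicate genome_id rows")
  if (any(ko < 0) || any(ko != round(ko)))
    stop_bad_arg("copy numbers must be non-negative integers")
  ko
}

#' Marker copy-number matrix restricted to a panel
#'
#' One row per genome and one column per panel gene; copy numbers are
#' preserved and genes absent from the KO table become 0.
#'
#' @param ko genome-by-gene copy-number table (matrix with dimnames, or
#'   data.frame with a `genome_id` column).
#' @param panel a `marker_panel` (default [default_marker_panel()]).
#' @return integer matrix, genomes x panel genes.
#' @export
marker_matrix <- function(ko, panel = default_marker_panel()) {
  ko <- as_ko_matrix(ko)
  if (nrow(ko) == 0) stop_bad_arg("empty KO table")
  genes <- panel$genes
  if (length(genes) == 0) stop_bad_arg("empty marker panel")
  out <- matrix(0L, nrow(ko), length(genes),
                dimnames = list(rownames(ko), genes))
  shared <- intersect(colnames(ko), genes)
  out[, shared] <- ko[, shared]
  out
}

#' Pigmentation call from the phycoerythrin genes
#'
#' A strain is called red when both cpeA and cpeB (the phycoerythrin
#' subunits) are present; otherwise green.
#'
#' @param row named numeric vector or one-row data.frame containing `cpeA`
#'   and `cpeB` copy numbers.
#' @return `"red"` or `"green"`.
#' @export
pigment_call <- function(row) {
  row <- unlist(row)
  if (!all(c("cpeA", "cpeB") %in% names(row)))
    stop_bad_arg("row must contain cpeA and cpeB")
  if (row[["cpeA"]] >= 1 && row[["cpeB"]] >= 1) "red" else "green"
}

#' Ecotype-diagnostic genes by presence contrast
#'
#' A gene is diagnostic for the focal ecotype when it is present in at least
#' `min_focal` of the focal genomes and in at most `max_other` of the
#' genomes of every other ecotype — the operational formalization of
#' "selective presence".
#'
#' @param matrix marker copy-number matrix (genomes x genes).
#' @param ecotypes character vector of ecotype labels, one per genome row.
#' @param focal the focal ecotype.
#' @param min_focal minimum presence fraction among focal genomes
#'   (default 0.8).
#' @param max_other maximum presence fraction in each other ecotype
#'   (default 0.2).
#' @return character vector of diagnostic gene names.
#' @export
ecotype_contrast <- function(matrix, ecotypes, focal, min_focal = 0.8,
                             max_other = 0.2) {
  if (length(ecotypes) != nrow(matrix))
    stop_bad_arg("one ecotype label per genome row is required")
  if (length(unique(ecotypes)) < 2)
    stop_bad_arg("need at least two ecotypes to contrast")
  if (!focal %in% ecotypes) stop_bad_arg("focal ecotype absent: ", focal)
  pres <- matrix >= 1
  in_focal <- ecotypes == focal
  focal_frac <- colMeans(pres[in_focal, , drop = FALSE])
  others <- setdiff(unique(ecotypes), focal)
  other_ok <- rep(TRUE, ncol(matrix))
  for (e in others) {
    frac <- colMeans(pres[ecotypes == e, , drop = FALSE])
    other_ok <- other_ok & frac <= max_other
  }
  colnames(matrix)[focal_frac >= min_focal & other_ok]
}

#' Gene-content ordination (Jaccard + PCoA)
#'
#' Binarizes the KO table, computes pairwise Jaccard distances and embeds
#' the genomes by classical principal-coordinates analysis. The embedding is
#' made deterministic by fixing each axis's sign so that its
#' largest-magnitude loading is positive.
#'
#' @param ko genome-by-gene copy-number table (at least 3 genomes).
#' @param k number of ordination axes (default 2).
#' @return list with `points` (genomes x k coordinate matrix), `distance`
#'   (the Jaccard `dist`), `eig` (eigenvalues).
#' @export
gene_content_ordination <- function(ko, k = 2) {
  ko <- as_ko_matrix(ko)
  if (nrow(ko) < 3) stop_bad_arg("need at least 3 genomes")
  pres <- (ko >= 1) * 1
  if (any(rowSums(pres) == 0))
    stop_bad_arg("genome(s) with all-zero profiles: Jaccard undefined")
  d <- vegan::vegdist(pres, method = "jaccard", binary = TRUE)
  pc <- stats::cmdscale(d, k = k, eig = TRUE)
  pts <- pc$points
  if (ncol(pts) < k)  # degenerate geometry: pad with zero axes
    pts <- cbind(pts, matrix(0, nrow(pts), k - ncol(pts)))
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  list(points = pts, distance = d, eig = pc$eig)
}
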