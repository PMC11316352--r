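#' Summary statistics of a genome catalogue
#'
#' Recomputes, from a per-genome statistics table, the headline numbers a
#' catalogue reports: per-subcluster genome shares, mean genome size and GC
#' for each subcluster, and size/GC extrema. This is the consistency check
#' applied to a published supplementary table when one is available; the
#' test-suite exercises it on a synthetic stand-in.
#'
#' @param stats data.frame with `genome_id`, `subcluster` (e.g. `"SC5.2"`,
#'   `"SC5.3"`), `genome_size_mb`, `gc_percent`.
#' @return data.frame with one row per subcluster: `subcluster`, `n`,
#'   `share_percent` (rounded half-up to 1 decimal), `mean_size_mb`,
#'   `mean_gc_percent`, `min_size_mb`, `max_size_mb`, `min_gc_percent`,
#'   `max_gc_percent`.
#' @export
genome_stats_summary <- function(stats) {
  need <- c("genome_id", "subcluster", "genome_size_mb", "gc_percent")
  if (!all(need %in% names(stats)))
    stop_bad_arg("stats needs columns: ", paste(need, collapse = ", "))
  n_total <- nrow(stats)
  out <- lapply(split(stats, stats$subcluster), function(d) {
    data.frame(subcluster = d$subcluster[1], n = nrow(d),
               share_percent = round_half_up(100 * nrow(d) / n_total, 1),
               mean_size_mb = round_half_up(mean(d$genome_size_mb), 1),
               mean_gc_percent = round_half_up(mean(d$gc_percent), 1),
               min_size_mb = round_half_up(min(d$genome_size_mb), 1),
               max_size_mb = round_half_up(max(d$genome_size_mb), 1),
               min_gc_percent = round_half_up(min(d$gc_percent), 1),
               max_gc_percent = round_half_up(max(d$gc_percent), 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
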