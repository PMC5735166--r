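#' Simulate ChIP IP/input coverage and binding summits
#'
#' Input coverage is Poisson noise around a constant depth in fixed bins.
#' IP coverage equals input times `chip_enrichment_factor` over the planted
#' motif arrays of the targeted family and equals input elsewhere. One summit
#' is emitted at the midpoint of each targeted array.
#'
#' @param genome,annotation,truth Output of [simulate_genome()].
#' @param config The same [sim_config()].
#' @return List with `ip` and `input` coverage tracks (see
#'   [coverage_track()]) and `summits` (data.table: chrom, start, end, name,
#'   score, strand; 1-based closed, single-bp).
#' @export
simulate_chip <- function(genome, annotation, truth, config) {
  set.seed(stage_seed(config$seed, "chip"))
  glen <- Biostrings::width(genome)
  chroms <- names(genome)
  bw <- config$chip_bin
  tgt_arrays <- truth$arrays[family == truth$target_family]

  tracks_ip <- vector("list", length(chroms))
  tracks_in <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    L <- glen[ci]
    starts <- seq(1L, L, by = bw)
    ends <- pmin(starts + bw - 1L, L)
    depth_in <- stats::rpois(length(starts), config$chip_input_depth)
    mids <- (starts + ends) / 2
    arr <- tgt_arrays[chrom == chroms[ci]]
    enriched <- rep(FALSE, length(starts))
    if (nrow(arr)) {
      for (k in seq_len(nrow(arr)))
        enriched <- enriched | (mids >= arr$start[k] & mids <= arr$end[k])
    }
    depth_ip <- depth_in * ifelse(enriched, config$chip_enrichment_factor, 1)
    tracks_in[[ci]] <- data.table::data.table(chrom = chroms[ci],
                                              start = starts, end = ends,
                                              depth = as.numeric(depth_in))
    tracks_ip[[ci]] <- data.table::data.table(chrom = chroms[ci],
                                              start = starts, end = ends,
                                              depth = as.numeric(depth_ip))
  }
  ip <- coverage_track(data.table::rbindlist(tracks_ip))
  input <- coverage_track(data.table::rbindlist(tracks_in))

  summits <- tgt_arrays[, .(chrom, pos = as.integer((start + end) %/% 2),
                            te_id)]
  summits <- summits[, .(chrom, start = pos, end = pos,
                         name = paste0("summit_", te_id), score = 0L,
                         strand = ".")]
  data.table::setorder(summits, chrom, start)
  list(ip = ip, input = input, summits = summits)
}
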