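#' Construct a coverage track
#'
#' Thin container for bedGraph-style coverage: sorted, non-overlapping
#' intervals with non-negative depth, plus a library size (mapped reads)
#' used for counts-per-million normalisation.
#'
#' @param data data.table: chrom, start, end (1-based closed), depth.
#' @param library_size Mapped reads; when `NULL`, estimated as total
#'   coverage mass divided by a nominal 100-bp read length.
#' @return List of class `coverage_track` with elements `data` and
#'   `library_size`.
#' @export
coverage_track <- function(data, library_size = NULL) {
  dt <- data.table::as.data.table(data)
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(dt)))
  if (any(dt$depth < 0)) stop("coverage depths must be non-negative")
  data.table::setorder(dt, chrom, start)
  ovl <- dt[, any(start[-1L] <= end[-.N]), by = chrom]$V1
  if (any(ovl)) stop("coverage intervals overlap")
  if (is.null(library_size))
    library_size <- max(1, round(sum(dt$depth * (dt$end - dt$start + 1)) / 100))
  structure(list(data = dt[], library_size = library_size),
            class = "coverage_track")
}

#' Normalise a coverage track to counts per million mapped reads
#'
#' @param track A [coverage_track()].
#' @return A `coverage_track` with depths scaled by `1e6 / library_size`
#'   (library size reset to 1e6).
#' @export
normalize_cpm <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$library_size <= 0) stop("library_size must be positive")
  dt <- data.table::copy(track$data)
  dt[, depth := depth * 1e6 / track$library_size]
  coverage_track(dt, library_size = 1e6)
}

## mean depth of a track within fixed tiles (weighted by overlap width)
tile_means <- function(track, tiles) {
  q <- GenomicRanges::GRanges(track$data$chrom,
                              IRanges::IRanges(track$data$start,
                                               track$data$end))
  s <- GenomicRanges::GRanges(tiles$chrom, IRanges::IRanges(tiles$start,
                                                            tiles$end))
  ov <- GenomicRanges::findOverlaps(q, s)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  w <- pmin(track$data$end[qi], tiles$end[si]) -
    pmax(track$data$start[qi], tiles$start[si]) + 1
  mass <- tapply(track$data$depth[qi] * w,
                 factor(si, levels = seq_len(nrow(tiles))), sum, default = 0)
  as.numeric(mass) / (tiles$end - tiles$start + 1)
}

#' ChIP enrichment in fixed genomic bins
#'
#' CPM-normalises both tracks, averages each over non-overlapping tiles of
#' `bin` bp (tiled from coordinate 0; the terminal bin may be shorter and is
#' flagged), and reports the pseudocounted IP/input ratio per tile. Tiles
#' overlapping `mask` intervals are dropped.
#'
#' @param ip,input [coverage_track()] objects on the same genome.
#' @param bin Tile width in bp (default 10000).
#' @param pseudocount Added to both CPM means before the ratio (default
#'   0.5).
#' @param mask Optional data.table of intervals (chrom, start, end) to
#'   exclude, e.g. centromeric satellite repeats.
#' @return data.table: chrom, start, end, ip_signal, input_signal, ratio,
#'   partial (TRUE for a truncated terminal bin).
#' @export
bin_enrichment <- function(ip, input, bin = 10000L, pseudocount = 0.5,
                           mask = NULL) {
  stopifnot(inherits(ip, "coverage_track"), inherits(input, "coverage_track"))
  if (!setequal(unique(ip$data$chrom), unique(input$data$chrom)))
    stop("IP and input tracks cover different chromosomes")
  ipn <- normalize_cpm(ip); inn <- normalize_cpm(input)
  ends <- ipn$data[, .(len = max(end)), by = chrom]
  ends2 <- inn$data[, .(len = max(end)), by = chrom]
  lens <- merge(ends, ends2, by = "chrom")[, .(chrom, len = pmax(len.x, len.y))]
  tiles <- lens[, .(start = seq(1L, len, by = as.integer(bin))), by = chrom]
  tiles <- merge(tiles, lens, by = "chrom")
  tiles[, end := pmin(start + as.integer(bin) - 1L, len)][, len := NULL]
  data.table::setorder(tiles, chrom, start)
  if (!is.null(mask) && nrow(mask))
    tiles <- tiles[!pos_in_tiles_mask(tiles, mask)]
  tiles[, ip_signal := tile_means(ipn, tiles)]
  tiles[, input_signal := tile_means(inn, tiles)]
  tiles[, ratio := (ip_signal + pseudocount) / (input_signal + pseudocount)]
  tiles[, partial := (end - start + 1L) < bin]
  tiles[]
}

pos_in_tiles_mask <- function(tiles, mask) {
  q <- GenomicRanges::GRanges(tiles$chrom, IRanges::IRanges(tiles$start,
                                                            tiles$end))
  m <- data.table::as.data.table(mask)
  s <- GenomicRanges::GRanges(m$chrom, IRanges::IRanges(m$start, m$end))
  IRanges::overlapsAny(q, s)
}

#' Annotate ChIP summits by containing TE segment
#'
#' Labels each summit with the TE copy, family and coding/non-coding segment
#' containing it, or `none` when it falls outside every annotated TE.
#'
#' @param summits data.table with chrom and `pos` (or single-bp `start`).
#' @param annotation TE segment annotation (see [simulate_genome()]).
#' @return data.table: chrom, pos, te_id, family, segment_type (`none` rows
#'   for background summits).
#' @export
annotate_summits <- function(summits, annotation) {
  spos <- if ("pos" %in% names(summits)) summits$pos else summits$start
  out <- data.table::data.table(chrom = summits$chrom, pos = spos,
                                te_id = "none", family = "none",
                                segment_type = "none")
  if (nrow(annotation)) {
    q <- GenomicRanges::GRanges(out$chrom, IRanges::IRanges(out$pos, out$pos))
    s <- GenomicRanges::GRanges(annotation$chrom,
                                IRanges::IRanges(annotation$start,
                                                 annotation$end))
    hit <- GenomicRanges::findOverlaps(q, s, select = "first")
    ok <- !is.na(hit)
    out$te_id[ok] <- annotation$te_id[hit[ok]]
    out$family[ok] <- annotation$family[hit[ok]]
    out$segment_type[ok] <- annotation$segment_type[hit[ok]]
  }
  out[]
}
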