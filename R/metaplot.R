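#' Summit-centred methylation metaplot
#'
#' Averages methylation around a set of anchor points (ChIP summits): for
#' every offset from `-span` to `+span` in steps of `step`, pools
#' methylated/total counts over the window `[offset - bin/2, offset + bin/2)`
#' relative to every summit, separately per context.
#'
#' @param records Cytosine report data.table.
#' @param summits data.table with chrom and either `pos` or single-bp
#'   `start`/`end` columns (e.g. from [simulate_chip()] or [read_bed()]).
#' @param bin Window width in bp (default 500).
#' @param step Offset step in bp (default 50).
#' @param span Maximum absolute offset in bp (default 5000).
#' @param contexts Contexts to profile.
#' @return data.table: context, offset, meth, total, level (`NA` where no
#'   counts fall in a window). Zero rows when `summits` is empty.
#' @export
summit_metaplot <- function(records, summits, bin = 500L, step = 50L,
                            span = 5000L, contexts = c("CG", "CHG", "CHH")) {
  half <- bin / 2
  ## offsets are bin centres; the full bin stays within [-span, span],
  ## giving (2*span - bin)/step + 1 positions
  offsets <- seq(-span + half, span - half, by = step)
  if (is.null(summits) || nrow(summits) == 0L)
    return(data.table::data.table(context = character(), offset = integer(),
                                  meth = numeric(), total = numeric(),
                                  level = numeric()))
  spos <- if ("pos" %in% names(summits)) summits$pos else summits$start
  ## pair records with summits within reach, then bin by distance
  q <- GenomicRanges::GRanges(records$chrom,
                              IRanges::IRanges(records$pos, records$pos))
  s <- GenomicRanges::GRanges(summits$chrom,
                              IRanges::IRanges(spos - span - half,
                                               spos + span + half))
  ov <- GenomicRanges::findOverlaps(q, s)
  dt <- records[S4Vectors::queryHits(ov),
                .(context, meth, total = meth + unmeth)]
  dt[, d := records$pos[S4Vectors::queryHits(ov)] -
       spos[S4Vectors::subjectHits(ov)]]
  dt <- dt[context %in% contexts]
  ## a cytosine at distance d contributes to offsets o with
  ## o - half <= d < o + half  <=>  d - half < o <= d + half
  res <- vector("list", length(offsets))
  for (i in seq_along(offsets)) {
    o <- offsets[i]
    sub <- dt[d >= o - half & d < o + half,
              .(meth = sum(meth), total = sum(total)), by = context]
    miss <- setdiff(contexts, sub$context)
    if (length(miss))
      sub <- rbind(sub, data.table::data.table(context = miss, meth = 0,
                                               total = 0))
    sub[, offset := o]
    res[[i]] <- sub
  }
  out <- data.table::rbindlist(res)
  out[, level := ifelse(total > 0, meth / total, NA_real_)]
  data.table::setorder(out, context, offset)
  data.table::setcolorder(out, c("context", "offset", "meth", "total",
                                 "level"))
  out[]
}
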