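#' Call CG differentially methylated regions (DMRs)
#'
#' The genome is tiled with non-overlapping fixed-width windows from
#' coordinate 0 of each chromosome. A window seeds a DMR when both conditions
#' cover at least `min_covered_sites` CG positions there and the methylation
#' level (pooled meth / pooled total) drops by at least `min_diff` from `wt`
#' to `treated`. Runs of seed windows separated by at most one non-seed
#' window are merged into a single DMR spanning the seed windows and the
#' bridged gap.
#'
#' @param wt,treated Cytosine report data.tables; non-CG records are ignored.
#' @param window Window width in bp (default 100).
#' @param min_diff Minimum per-window methylation-level drop (default 0.5).
#' @param min_covered_sites Minimum covered CG positions per window per
#'   condition (default 4; coverage filter, configurable).
#' @return data.table: chrom, start, end (1-based closed, multiples of the
#'   window width), context, n_windows (seed windows), wt_level,
#'   treated_level, diff (levels pooled over seed windows).
#' @export
call_cg_dmrs <- function(wt, treated, window = 100L, min_diff = 0.5,
                         min_covered_sites = 4L) {
  if (window <= 0L) stop("window size must be positive")
  winstat <- function(records) {
    dt <- records[context == "CG"]
    dt <- dt[, .(chrom, win = (pos - 1L) %/% as.integer(window),
                 meth, total = meth + unmeth)]
    dt[, .(m = sum(meth), t = sum(total), covered = sum(total > 0L)),
       by = .(chrom, win)]
  }
  a <- winstat(wt); b <- winstat(treated)
  ws <- merge(a, b, by = c("chrom", "win"), suffixes = c("_wt", "_tr"))
  ws <- ws[covered_wt >= min_covered_sites & covered_tr >= min_covered_sites &
             t_wt > 0L & t_tr > 0L]
  empty <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), context = character(),
                                  n_windows = integer(), wt_level = numeric(),
                                  treated_level = numeric(), diff = numeric())
  if (nrow(ws) == 0L) return(empty)
  ws[, `:=`(level_wt = m_wt / t_wt, level_tr = m_tr / t_tr)]
  seeds <- ws[level_wt - level_tr >= min_diff]
  if (nrow(seeds) == 0L) return(empty)
  data.table::setorder(seeds, chrom, win)
  ## merge seed windows whose indices differ by <= 2 (<= one-window gap)
  seeds[, run := cumsum(c(1L, (diff(win) > 2L) | (chrom[-1L] != chrom[-.N]))),
        by = NULL]
  out <- seeds[, .(chrom = chrom[1L],
                   start = min(win) * as.integer(window) + 1L,
                   end = (max(win) + 1L) * as.integer(window),
                   context = "CG", n_windows = .N,
                   wt_level = sum(m_wt) / sum(t_wt),
                   treated_level = sum(m_tr) / sum(t_tr)),
               by = run][, run := NULL]
  out[, diff := wt_level - treated_level]
  data.table::setorder(out, chrom, start)
  out[]
}
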