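#' Count-weighted hypomethylation significance statistic
#'
#' `(Mn/Cn - Mt/Ct) / (1/sqrt(Cn) + 1/sqrt(Ct))`, where `Mn`/`Cn` are
#' methylated and total cytosine read counts in the non-transgenic condition
#' and `Mt`/`Ct` in the transgenic one. Positive values mean methylation is
#' lower in the transgenic condition; at fixed ratios the magnitude grows
#' with the square root of the counts.
#'
#' @param Mn,Cn,Mt,Ct Non-negative counts (vectorised).
#' @return Numeric vector; `NA` where `Cn` or `Ct` is zero (undefined, never
#'   silently 0).
#' @export
significance_value <- function(Mn, Cn, Mt, Ct) {
  if (any(Mn > Cn, na.rm = TRUE) || any(Mt > Ct, na.rm = TRUE))
    stop("methylated counts exceed totals")
  if (any(c(Mn, Cn, Mt, Ct) < 0, na.rm = TRUE)) stop("negative counts")
  out <- rep(NA_real_, length(Cn))
  ok <- !is.na(Cn) & !is.na(Ct) & Cn > 0 & Ct > 0
  out[ok] <- (Mn[ok] / Cn[ok] - Mt[ok] / Ct[ok]) /
    (1 / sqrt(Cn[ok]) + 1 / sqrt(Ct[ok]))
  out
}

## pooled per-window counts over n_fractions fractions of [rstart, rend],
## oriented 5'->3' (reverse = TRUE flips fraction order before windowing)
frac_windows <- function(records, chr, rstart, rend, n_fractions, window,
                         reverse, contexts) {
  Lr <- rend - rstart + 1
  sub <- records[chrom == chr & pos >= rstart & pos <= rend &
                   context %in% contexts]
  nwin <- n_fractions - window + 1L
  out <- vector("list", length(contexts))
  for (ci in seq_along(contexts)) {
    m <- numeric(n_fractions); tot <- numeric(n_fractions)
    s <- sub[context == contexts[ci]]
    if (nrow(s)) {
      fr <- pmin(floor((s$pos - rstart) * n_fractions / Lr), n_fractions - 1L) + 1L
      m <- as.numeric(tapply(s$meth, factor(fr, levels = seq_len(n_fractions)),
                             sum, default = 0))
      tot <- as.numeric(tapply(s$meth + s$unmeth,
                               factor(fr, levels = seq_len(n_fractions)),
                               sum, default = 0))
    }
    if (reverse) { m <- rev(m); tot <- rev(tot) }
    cm <- c(0, cumsum(m)); ct <- c(0, cumsum(tot))
    wm <- cm[(window + 1L):(n_fractions + 1L)] - cm[seq_len(nwin)]
    wt <- ct[(window + 1L):(n_fractions + 1L)] - ct[seq_len(nwin)]
    out[[ci]] <- data.table::data.table(
      context = contexts[ci], window = seq_len(nwin), meth = wm, total = wt,
      level = ifelse(wt > 0, wm / wt, NA_real_))
  }
  data.table::rbindlist(out)
}

#' Fractional methylation profile of one TE and its flanks
#'
#' The TE body is divided into `n_fractions` equal fractions; each reported
#' value pools methylated/total counts over a sliding window of `window`
#' consecutive fractions, giving `n_fractions - window + 1` values oriented
#' 5'->3' on the TE strand. Flanking regions of the TE's own length are
#' profiled under the same conditions.
#'
#' @param records Cytosine report data.table.
#' @param te One-row TE interval (chrom, start, end, strand, te_id).
#' @param n_fractions,window Profile geometry (defaults 100 and 7).
#' @param flank Include flanking regions (`flank_left` is the 5' flank in TE
#'   orientation).
#' @param contexts Contexts to profile.
#' @return data.table: te_id, region (flank_left/body/flank_right), context,
#'   window, meth, total, level. Zero rows with attribute `skipped = TRUE`
#'   when the TE is shorter than `n_fractions` bp.
#' @export
fractional_profile <- function(records, te, n_fractions = 100L, window = 7L,
                               flank = TRUE,
                               contexts = c("CG", "CHG", "CHH")) {
  stopifnot(nrow(te) == 1L)
  L <- te$end - te$start + 1L
  if (L < n_fractions) {
    out <- data.table::data.table(te_id = character(), region = character(),
                                  context = character(), window = integer(),
                                  meth = numeric(), total = numeric(),
                                  level = numeric())
    data.table::setattr(out, "skipped", TRUE)
    return(out)
  }
  rev_body <- te$strand == "-"
  body <- frac_windows(records, te$chrom, te$start, te$end, n_fractions,
                       window, rev_body, contexts)
  body[, region := "body"]
  pieces <- list(body)
  if (flank) {
    up <- frac_windows(records, te$chrom, te$start - L, te$start - 1L,
                       n_fractions, window, rev_body, contexts)
    dn <- frac_windows(records, te$chrom, te$end + 1L, te$end + L,
                       n_fractions, window, rev_body, contexts)
    if (rev_body) { tmp <- up; up <- dn; dn <- tmp }
    up[, region := "flank_left"]; dn[, region := "flank_right"]
    pieces <- list(up, body, dn)
  }
  out <- data.table::rbindlist(pieces)
  out[, te_id := te$te_id]
  data.table::setcolorder(out, c("te_id", "region", "context", "window",
                                 "meth", "total", "level"))
  out[]
}

#' Running methylation proportion over successive cytosines
#'
#' For each cytosine, pools methylated/total counts over that cytosine and
#' its `k - 1` successors in the same context on the same chromosome (browser
#' -style profile at 5-cytosine resolution). The last `k - 1` cytosines of
#' each (chrom, context) series are undefined.
#'
#' @param records Cytosine report data.table (subset to a span of interest
#'   first if desired).
#' @param k Number of successive cytosines pooled (default 5).
#' @return data.table: chrom, pos, context, meth, total, level (`NA` at the
#'   tail).
#' @export
running_profile <- function(records, k = 5L) {
  stopifnot(k >= 1L)
  dt <- data.table::copy(records)[, total := meth + unmeth]
  data.table::setorder(dt, chrom, context, pos)
  roll <- function(x, n, kk) {
    cs <- c(0, cumsum(x))
    if (n < kk) return(rep(NA_real_, n))
    c(cs[(kk + 1L):(n + 1L)] - cs[seq_len(n - kk + 1L)],
      rep(NA_real_, kk - 1L))
  }
  dt[, `:=`(wm = roll(meth, .N, k), wt = roll(total, .N, k)),
     by = .(chrom, context)]
  out <- dt[, .(chrom, pos, context, meth = wm, total = wt,
                level = ifelse(!is.na(wt) & wt > 0, wm / wt, NA_real_))]
  data.table::setorder(out, chrom, pos)
  out[]
}

#' Per-TE methylation change between two conditions
#'
#' Pools methylated/total counts over each TE interval per context in both
#' conditions and evaluates the hypomethylation significance statistic
#' ([significance_value()]). TEs shorter than `min_length` are excluded (the
#' headline comparisons consider TEs over 1 kb).
#'
#' @param wt,treated Cytosine report data.tables (same genome).
#' @param annotation TE segment annotation (see [simulate_genome()]) or a
#'   TE-level interval table.
#' @param contexts Contexts to evaluate.
#' @param min_length Minimum TE length in bp (default 1000).
#' @return data.table: te_id, family, context, Mn, Cn, Mt, Ct, value
#'   (`NA` value where a condition has no covered cytosines).
#' @export
per_te_changes <- function(wt, treated, annotation,
                           contexts = c("CG", "CHG", "CHH"),
                           min_length = 1000L) {
  tes <- if ("segment_type" %in% names(annotation))
    te_intervals(annotation) else data.table::as.data.table(annotation)
  tes <- tes[end - start + 1L >= min_length]
  pool <- function(records, mcol, ccol) {
    q <- GenomicRanges::GRanges(records$chrom,
                                IRanges::IRanges(records$pos, records$pos))
    s <- GenomicRanges::GRanges(tes$chrom, IRanges::IRanges(tes$start, tes$end))
    ov <- GenomicRanges::findOverlaps(q, s)
    dt <- records[S4Vectors::queryHits(ov),
                  .(context, meth, total = meth + unmeth)]
    dt[, te_id := tes$te_id[S4Vectors::subjectHits(ov)]]
    dt <- dt[context %in% contexts,
             .(M = sum(meth), C = sum(total)), by = .(te_id, context)]
    data.table::setnames(dt, c("M", "C"), c(mcol, ccol))
    dt
  }
  grid <- data.table::CJ(te_id = tes$te_id, context = contexts)
  out <- merge(grid, pool(wt, "Mn", "Cn"), by = c("te_id", "context"),
               all.x = TRUE)
  out <- merge(out, pool(treated, "Mt", "Ct"), by = c("te_id", "context"),
               all.x = TRUE)
  for (cl in c("Mn", "Cn", "Mt", "Ct"))
    data.table::set(out, which(is.na(out[[cl]])), cl, 0L)
  out[, value := significance_value(Mn, Cn, Mt, Ct)]
  if ("family" %in% names(tes))
    out <- merge(out, tes[, .(te_id, family)], by = "te_id")
  data.table::setorder(out, te_id, context)
  out[]
}
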