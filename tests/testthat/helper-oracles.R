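## Independent reference implementations used as oracles. These deliberately
## take the dumbest correct route (regex, per-base loops, exhaustive
## enumeration) so they share no code path with the package.

## regex-based degenerate motif scanner (overlapping, both strands)
naive_scan <- function(seq, pattern, both_strands = TRUE) {
  seq <- toupper(seq)
  find <- function(pat) {
    rx <- paste0("(?=", iupac_to_regex(pat), ")")
    st <- unlist(gregexpr(rx, seq, perl = TRUE))
    st[st > 0]
  }
  w <- nchar(pattern)
  fs <- find(pattern)
  out <- data.table::data.table(start = fs, end = fs + w - 1L,
                                strand = rep("+", length(fs)))
  if (both_strands) {
    rs <- find(revcomp(pattern))
    out <- rbind(out, data.table::data.table(start = rs, end = rs + w - 1L,
                                             strand = rep("-", length(rs))))
  }
  data.table::setorder(out, start, strand)
  out[]
}

## per-base pooled methylation counts over an interval (loop accumulation)
naive_pool <- function(records, chr, a, b, ctx) {
  m <- 0L; tot <- 0L
  for (i in seq_len(nrow(records))) {
    if (records$chrom[i] == chr && records$pos[i] >= a &&
        records$pos[i] <= b && records$context[i] == ctx) {
      m <- m + records$meth[i]
      tot <- tot + records$meth[i] + records$unmeth[i]
    }
  }
  c(meth = m, total = tot)
}

## exhaustive window-by-window DMR caller with explicit merge scanning
brute_dmr <- function(wt, treated, window = 100L, min_diff = 0.5,
                      min_covered = 4L) {
  wt <- wt[wt$context == "CG", ]
  treated <- treated[treated$context == "CG", ]
  res <- list()
  for (chr in union(unique(wt$chrom), unique(treated$chrom))) {
    w1 <- wt[wt$chrom == chr, ]; t1 <- treated[treated$chrom == chr, ]
    if (!nrow(w1) || !nrow(t1)) next
    maxw <- max((c(w1$pos, t1$pos) - 1L) %/% window)
    seed <- rep(FALSE, maxw + 1L)
    for (w in 0:maxw) {
      a <- w * window + 1L; b <- (w + 1L) * window
      sw <- w1[w1$pos >= a & w1$pos <= b, ]
      st <- t1[t1$pos >= a & t1$pos <= b, ]
      cov_w <- sum(sw$meth + sw$unmeth > 0L)
      cov_t <- sum(st$meth + st$unmeth > 0L)
      if (cov_w < min_covered || cov_t < min_covered) next
      tw <- sum(sw$meth + sw$unmeth); tt <- sum(st$meth + st$unmeth)
      if (tw == 0L || tt == 0L) next
      if (sum(sw$meth) / tw - sum(st$meth) / tt >= min_diff)
        seed[w + 1L] <- TRUE
    }
    idx <- which(seed) - 1L
    if (!length(idx)) next
    first <- idx[1L]; last <- idx[1L]; nwin <- 1L
    for (w in idx[-1L]) {
      if (w - last <= 2L) { last <- w; nwin <- nwin + 1L }
      else {
        res[[length(res) + 1L]] <- data.frame(
          chrom = chr, start = first * window + 1L,
          end = (last + 1L) * window, n_windows = nwin)
        first <- w; last <- w; nwin <- 1L
      }
    }
    res[[length(res) + 1L]] <- data.frame(
      chrom = chr, start = first * window + 1L, end = (last + 1L) * window,
      n_windows = nwin)
  }
  if (!length(res))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer()))
  out <- do.call(rbind, res)
  out[order(out$chrom, out$start), , drop = FALSE]
}

## random CG-only cytosine report pair with per-window methylation levels
random_cg_pair <- function(L, window = 100L, n_sites = 600L, cov = 12L,
                          p_hypo = 0.3) {
  pos <- sort(sample.int(L, n_sites))
  nwin <- L %/% window + 1L
  wt_level <- runif(nwin, 0.55, 0.95)
  dropped <- runif(nwin) < p_hypo
  tr_level <- ifelse(dropped, pmax(wt_level - runif(nwin, 0.45, 0.75), 0.01),
                     wt_level + runif(nwin, -0.05, 0.05))
  tr_level <- pmin(pmax(tr_level, 0), 1)
  widx <- (pos - 1L) %/% window + 1L
  mk <- function(level) {
    total <- rpois(n_sites, cov)
    meth <- rbinom(n_sites, total, level[widx])
    data.table::data.table(chrom = "toy", pos = pos,
                           strand = sample(c("+", "-"), n_sites, TRUE),
                           meth = meth, unmeth = total - meth,
                           context = "CG", trinucleotide = "CGA")
  }
  list(wt = mk(wt_level), treated = mk(tr_level))
}

## same-strand run segmentation of motif hits, loop form
brute_arrays <- function(hits, min_run = 3L, max_gap = 200L) {
  hits <- hits[order(hits$seq_id, hits$start), ]
  out <- list()
  cur <- NULL
  flush <- function(cur) {
    if (!is.null(cur) && nrow(cur) >= min_run)
      out[[length(out) + 1L]] <<- data.frame(
        seq_id = cur$seq_id[1L], start = min(cur$start), end = max(cur$end),
        strand = cur$strand[1L], n_hits = nrow(cur))
  }
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, , drop = FALSE]
    if (is.null(cur)) cur <- h
    else if (h$seq_id == cur$seq_id[nrow(cur)] &&
             h$strand == cur$strand[nrow(cur)] &&
             h$start - cur$start[nrow(cur)] <= max_gap) cur <- rbind(cur, h)
    else { flush(cur); cur <- h }
  }
  flush(cur)
  if (!length(out))
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_hits = integer()))
  do.call(rbind, out)
}

## tiny sim config for fast construction-level tests
small_config <- function(seed = 1L, genome_length = 60000L, ...) {
  sim_config(seed = seed, genome_length = genome_length, n_te_families = 2L,
             copies_per_family = 3L, te_length_range = c(1500L, 2200L),
             ...)
}
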