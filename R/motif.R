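#' Scan sequences for a degenerate (IUPAC) motif
#'
#' Reports every occurrence, including overlapping ones, on the forward
#' strand and (optionally) the reverse strand. Coordinates are 1-based
#' closed on the forward sequence; `matched` is the motif-oriented concrete
#' instance (reverse-complemented for minus-strand hits). `N` in the subject
#' never matches any pattern symbol.
#'
#' @param sequences Named character vector or [Biostrings::DNAStringSet].
#' @param pattern IUPAC motif string.
#' @param both_strands Also scan the reverse strand (default TRUE).
#' @return data.table: seq_id, start, end, strand, matched, motif_type.
#' @export
scan_motifs <- function(sequences, pattern, both_strands = TRUE) {
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  iupac_to_regex(pattern)  # validates symbols
  pat_f <- Biostrings::DNAString(toupper(pattern))
  pat_r <- Biostrings::reverseComplement(pat_f)
  w <- nchar(pattern)
  out <- vector("list", 2L * length(sequences))
  for (i in seq_along(sequences)) {
    subj <- Biostrings::DNAString(toupper(sequences[[i]]))
    mf <- Biostrings::matchPattern(pat_f, subj, fixed = "subject")
    if (length(mf))
      out[[2L * i - 1L]] <- data.table::data.table(
        seq_id = names(sequences)[i],
        start = Biostrings::start(mf), end = Biostrings::end(mf),
        strand = "+", matched = as.character(mf))
    if (both_strands) {
      mr <- Biostrings::matchPattern(pat_r, subj, fixed = "subject")
      if (length(mr))
        out[[2L * i]] <- data.table::data.table(
          seq_id = names(sequences)[i],
          start = Biostrings::start(mr), end = Biostrings::end(mr),
          strand = "-",
          matched = revcomp(as.character(mr)))
    }
  }
  hits <- data.table::rbindlist(out)
  if (nrow(hits) == 0L)
    return(data.table::data.table(seq_id = character(), start = integer(),
                                  end = integer(), strand = character(),
                                  matched = character(),
                                  motif_type = character()))
  hits[, motif_type := classify_motif(matched)]
  data.table::setorder(hits, seq_id, start, strand)
  hits[]
}

#' Type a concrete motif instance
#'
#' Instances of the VANC21 target consensus YAGTATTAY are typed by their
#' terminal base: C-type (YAGTATTAC) or T-type (YAGTATTAT). The VANC6 target
#' motifs AGTTGTCC and AGTTGTAC are typed CC and AC. Anything else is
#' `other`.
#'
#' @param matched Character vector of motif-oriented concrete instances.
#' @return Character vector over C, T, CC, AC, other.
#' @export
classify_motif <- function(matched) {
  m <- toupper(matched)
  out <- rep("other", length(m))
  out[grepl("^[CT]AGTATTAC$", m)] <- "C"
  out[grepl("^[CT]AGTATTAT$", m)] <- "T"
  out[m == "AGTTGTCC"] <- "CC"
  out[m == "AGTTGTAC"] <- "AC"
  out
}

#' Count motif hits per TE and type
#'
#' Hits are assigned to the TE interval containing their start coordinate;
#' hits outside every TE are pooled into a `background` row.
#'
#' @param hits Hit table from [scan_motifs()] (seq_id must match the
#'   annotation's chrom).
#' @param annotation TE segment annotation or TE-level interval table.
#' @param types Motif types tabulated (columns of the result).
#' @return data.table: te_id, family, one count column per type.
#' @export
count_motifs_per_te <- function(hits, annotation,
                                types = c("C", "T", "CC", "AC", "other")) {
  tes <- if ("segment_type" %in% names(annotation))
    te_intervals(annotation) else data.table::as.data.table(annotation)
  base <- data.table::data.table(te_id = c(tes$te_id, "background"),
                                 family = c(tes$family, "background"))
  counts <- data.table::CJ(te_id = base$te_id, motif_type = types)
  if (nrow(hits)) {
    h <- data.table::copy(hits)
    q <- GenomicRanges::GRanges(h$seq_id, IRanges::IRanges(h$start, h$start))
    s <- GenomicRanges::GRanges(tes$chrom, IRanges::IRanges(tes$start, tes$end))
    ov <- GenomicRanges::findOverlaps(q, s, select = "first")
    h[, te_id := ifelse(is.na(ov), "background", tes$te_id[ov])]
    tab <- h[motif_type %in% types, .N, by = .(te_id, motif_type)]
    counts <- merge(counts, tab, by = c("te_id", "motif_type"), all.x = TRUE)
  } else counts[, N := 0L]
  counts[is.na(N), N := 0L]
  wide <- data.table::dcast(counts, te_id ~ motif_type, value.var = "N")
  data.table::setcolorder(wide, c("te_id", intersect(types, names(wide))))
  out <- merge(base, wide, by = "te_id", sort = FALSE)
  data.table::setorder(out, te_id)
  out[]
}

#' Detect same-orientation motif arrays
#'
#' Maximal runs of at least `min_run` hits on the same strand of the same
#' sequence with successive start positions at most `max_gap_bp` apart.
#' Density is reported in hits per kb of array span.
#'
#' @param hits Hit table from [scan_motifs()].
#' @param min_run Minimum hits per array (default 3).
#' @param max_gap_bp Maximum start-to-start gap within an array (default
#'   200).
#' @return data.table: seq_id, start, end, strand, n_hits, density.
#' @export
find_motif_arrays <- function(hits, min_run = 3L, max_gap_bp = 200L) {
  empty <- data.table::data.table(seq_id = character(), start = integer(),
                                  end = integer(), strand = character(),
                                  n_hits = integer(), density = numeric())
  if (nrow(hits) == 0L) return(empty)
  h <- data.table::copy(hits)
  data.table::setorder(h, seq_id, start, end)
  brk <- c(TRUE, h$seq_id[-1L] != h$seq_id[-nrow(h)] |
             h$strand[-1L] != h$strand[-nrow(h)] |
             (h$start[-1L] - h$start[-nrow(h)]) > max_gap_bp)
  h[, run := cumsum(brk)]
  out <- h[, .(seq_id = seq_id[1L], start = min(start), end = max(end),
               strand = strand[1L], n_hits = .N), by = run][, run := NULL]
  out <- out[n_hits >= min_run]
  if (nrow(out) == 0L) return(empty)
  out[, density := n_hits / ((end - start + 1L) / 1000)]
  data.table::setorder(out, seq_id, start)
  out[]
}

#' Minimum mismatch count between two degenerate motifs
#'
#' Minimum Hamming distance over all concrete instance pairs and all
#' ungapped offsets of the shorter pattern within the longer, forward
#' orientation only.
#'
#' @param query,target IUPAC motif strings.
#' @return Integer mismatch count.
#' @export
motif_min_mismatch <- function(query, target) {
  if (!nzchar(query) || !nzchar(target)) stop("empty pattern")
  a <- iupac_instances(query); b <- iupac_instances(target)
  if (nchar(query) > nchar(target)) { tmp <- a; a <- b; b <- tmp }
  wa <- nchar(a[1L]); wb <- nchar(b[1L])
  best <- wa
  for (off in 0:(wb - wa)) {
    for (x in a) {
      xs <- strsplit(x, "")[[1]]
      for (y in b) {
        ys <- strsplit(substr(y, off + 1L, off + wa), "")[[1]]
        best <- min(best, sum(xs != ys))
      }
    }
  }
  as.integer(best)
}
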