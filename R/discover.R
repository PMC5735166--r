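## one-sided (enrichment) Fisher p-value for presence counts, vectorised:
## P(X >= x) with X hypergeometric — x of pos_total positive sequences and
## y of neg_total negative sequences contain the word
fisher_greater <- function(x, pos_total, y, neg_total) {
  stats::phyper(x - 1, x + y, pos_total + neg_total - x - y, pos_total,
                lower.tail = FALSE)
}

## number of distinct sequences (by index) containing each word at least
## once on either strand, for all exact words of the given widths
seq_word_presence <- function(seqs, widths) {
  pieces <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- toupper(seqs[[i]]); r <- revcomp(s)
    ws <- character(0)
    for (w in widths) {
      n <- nchar(s) - w + 1L
      if (n < 1L) next
      ws <- c(ws, substring(s, 1:n, w:(n + w - 1L)),
              substring(r, 1:n, w:(n + w - 1L)))
    }
    ws <- unique(ws[!grepl("[^ACGT]", ws)])
    pieces[[i]] <- data.table::data.table(word = ws)
  }
  dt <- data.table::rbindlist(pieces)
  dt[, .(count = .N), by = word]
}

## sequences containing >= 1 match of an IUPAC pattern on either strand
pattern_presence <- function(pattern, seqs, seqs_rc) {
  rx <- iupac_to_regex(pattern)
  sum(grepl(rx, seqs, perl = TRUE) | grepl(rx, seqs_rc, perl = TRUE))
}

## degenerate codes that are strict supersets of a concrete base
iupac_supersets <- function(base) {
  names(IUPAC_CODES)[vapply(IUPAC_CODES, function(s)
    grepl(base, s, fixed = TRUE) && nchar(s) > 1L, logical(1))]
}

#' Discriminative degenerate motif discovery
#'
#' Exhaustively enumerates every exact word of width `min_w` to `max_w`
#' present in at least one positive sequence (either strand), scores each by
#' a one-sided Fisher exact test on the number of positive vs negative
#' sequences containing it, then greedily generalises the best words one
#' position at a time to degenerate IUPAC symbols whenever that lowers the
#' p-value. E-values are Bonferroni-style: p times the number of exact words
#' tested.
#'
#' @param pos_seqs,neg_seqs Character vectors (or DNAStringSets) of positive
#'   and negative sequence sets; both must be non-empty.
#' @param min_w,max_w Word width range (defaults 6 and 9; discovery output
#'   is capped at width 9).
#' @param e_threshold Report candidates with E-value at or below this
#'   (default 0.05).
#' @param top_generalize Number of top exact words seeding IUPAC
#'   generalisation (default 30).
#' @return data.table ranked by ascending E-value: pattern, width, pos_with,
#'   pos_total, neg_with, neg_total, p, e, n_words_tested.
#' @export
discover_motifs <- function(pos_seqs, neg_seqs, min_w = 6L, max_w = 9L,
                            e_threshold = 0.05, top_generalize = 30L) {
  if (methods::is(pos_seqs, "DNAStringSet")) pos_seqs <- as.character(pos_seqs)
  if (methods::is(neg_seqs, "DNAStringSet")) neg_seqs <- as.character(neg_seqs)
  if (length(pos_seqs) == 0L || length(neg_seqs) == 0L)
    stop("both sequence sets must be non-empty")
  if (max_w > 9L) stop("maximum core width is 9")
  pos_seqs <- toupper(pos_seqs); neg_seqs <- toupper(neg_seqs)
  widths <- seq(min_w, max_w)

  pw <- seq_word_presence(pos_seqs, widths)
  data.table::setnames(pw, "count", "pos_with")
  nw <- seq_word_presence(neg_seqs, widths)
  data.table::setnames(nw, "count", "neg_with")
  tab <- merge(pw, nw, by = "word", all.x = TRUE)
  tab[is.na(neg_with), neg_with := 0L]
  n_tested <- nrow(tab)
  P <- length(pos_seqs); N <- length(neg_seqs)
  tab[, p := fisher_greater(pos_with, P, neg_with, N)]
  data.table::setorder(tab, p, word)

  pos_rc <- revcomp(pos_seqs); neg_rc <- revcomp(neg_seqs)
  cand <- utils::head(tab, top_generalize)
  res <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    pat <- cand$word[i]
    best_p <- cand$p[i]
    best_x <- cand$pos_with[i]; best_y <- cand$neg_with[i]
    repeat {
      improved <- FALSE
      ch <- strsplit(pat, "")[[1]]
      for (j in seq_along(ch)) {
        if (nchar(IUPAC_CODES[[ch[j]]]) > 1L) next  # generalise once per slot
        for (sym in iupac_supersets(ch[j])) {
          trial <- ch; trial[j] <- sym
          tp <- paste(trial, collapse = "")
          x <- pattern_presence(tp, pos_seqs, pos_rc)
          y <- pattern_presence(tp, neg_seqs, neg_rc)
          pv <- fisher_greater(x, P, y, N)
          if (pv < best_p) {
            best_p <- pv; pat <- tp; best_x <- x; best_y <- y
            improved <- TRUE
          }
        }
        if (improved) break
      }
      if (!improved) break
    }
    res[[i]] <- data.table::data.table(pattern = pat, width = nchar(pat),
                                       pos_with = best_x, pos_total = P,
                                       neg_with = best_y, neg_total = N,
                                       p = best_p)
  }
  out <- data.table::rbindlist(res)
  out <- unique(out, by = "pattern")
  out[, e := pmin(p * n_tested, Inf)]
  out[, n_words_tested := n_tested]
  out <- out[e <= e_threshold]
  data.table::setorder(out, e, p, pattern)
  out[]
}
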