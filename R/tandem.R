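#' Detect tandem repeats by diagonal periodicity
#'
#' Simplified tandem-repeat finder: for every candidate unit length `u`, the
#' sequence is compared against itself shifted by `u`; maximal stretches
#' where the positionwise identity stays at or above `min_identity` mark a
#' repeat of period `u` spanning the stretch plus one unit. The consensus
#' unit is the column-majority over full copies. Overlapping calls at
#' different periods are resolved by keeping the longest spanning region.
#'
#' @param seq DNA (or protein) string.
#' @param min_unit,max_unit Candidate unit-length range in residues
#'   (defaults 10 and 100).
#' @param min_copies Minimum copy number (default 2).
#' @param min_identity Minimum identity of the shifted self-comparison
#'   (default 0.9).
#' @return data.table: start, end (1-based closed), unit_length,
#'   copy_number, consensus_unit, percent_identity (mean identity of full
#'   copies to the consensus).
#' @export
find_tandem_repeats <- function(seq, min_unit = 10L, max_unit = 100L,
                                min_copies = 2, min_identity = 0.9) {
  if (min_unit < 1L) stop("min_unit must be >= 1")
  s <- strsplit(toupper(seq), "")[[1]]
  L <- length(s)
  calls <- list()
  for (u in min_unit:min(max_unit, max(1L, L - 1L))) {
    n <- L - u
    if (n < 1L) break
    m <- s[seq_len(n)] == s[seq_len(n) + u]
    segs <- merge_match_runs(m, min_identity)
    for (k in seq_len(nrow(segs))) {
      a <- segs$start[k]; b <- segs$end[k]
      span <- b + u - a + 1L
      cn <- span / u
      if (cn < min_copies) next
      calls[[length(calls) + 1L]] <-
        data.table::data.table(start = a, end = b + u, unit_length = u,
                               copy_number = cn)
    }
  }
  empty <- data.table::data.table(start = integer(), end = integer(),
                                  unit_length = integer(),
                                  copy_number = numeric(),
                                  consensus_unit = character(),
                                  percent_identity = numeric())
  if (!length(calls)) return(empty)
  cand <- data.table::rbindlist(calls)
  cand[, span := end - start + 1L]
  data.table::setorder(cand, -span, unit_length, start)
  keep <- logical(nrow(cand))
  taken <- data.table::data.table(start = integer(), end = integer())
  for (i in seq_len(nrow(cand))) {
    if (!nrow(taken) ||
        all(cand$end[i] < taken$start | cand$start[i] > taken$end)) {
      keep[i] <- TRUE
      taken <- rbind(taken, cand[i, .(start, end)])
    }
  }
  out <- cand[keep][, span := NULL]
  ## consensus over full copies + identity of copies to it
  out[, c("consensus_unit", "percent_identity") := {
    cons <- character(.N); pid <- numeric(.N)
    for (i in seq_len(.N)) {
      u <- unit_length[i]
      ncopy <- (end[i] - start[i] + 1L) %/% u
      mat <- matrix(s[start[i] + seq_len(ncopy * u) - 1L], nrow = ncopy,
                    ncol = u, byrow = TRUE)
      cu <- apply(mat, 2L, function(col)
        names(sort(table(col), decreasing = TRUE))[1L])
      cons[i] <- paste(cu, collapse = "")
      pid[i] <- mean(t(mat) == cu)
    }
    list(cons, pid)
  }]
  data.table::setorder(out, start)
  out[]
}

## maximal segments of a logical match vector with identity >= min_identity:
## start from runs of TRUE, then greedily absorb following TRUE-runs while
## the pooled identity stays at or above the threshold
merge_match_runs <- function(m, min_identity) {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tr <- which(r$values)
  if (!length(tr))
    return(data.table::data.table(start = integer(), end = integer()))
  seg_s <- integer(); seg_e <- integer()
  i <- 1L
  while (i <= length(tr)) {
    a <- starts[tr[i]]; b <- ends[tr[i]]
    matches <- r$lengths[tr[i]]
    j <- i + 1L
    while (j <= length(tr)) {
      b2 <- ends[tr[j]]
      matches2 <- matches + r$lengths[tr[j]]
      if (matches2 / (b2 - a + 1L) >= min_identity) {
        b <- b2; matches <- matches2; j <- j + 1L
      } else break
    }
    seg_s <- c(seg_s, a); seg_e <- c(seg_e, b)
    i <- j
  }
  data.table::data.table(start = seg_s, end = seg_e)
}
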