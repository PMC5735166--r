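## assemble maximal diagonal runs from a set of (x, y) match points
diagonal_runs <- function(points) {
  if (nrow(points) == 0L)
    return(data.table::data.table(offset = integer(), x_start = integer(),
                                  y_start = integer(), length = integer()))
  pts <- data.table::copy(points)[, offset := x - y]
  data.table::setorder(pts, offset, x)
  brk <- c(TRUE, diff(pts$x) != 1L | diff(pts$offset) != 0L)
  pts[, run := cumsum(brk)]
  out <- pts[, .(offset = offset[1L], x_start = min(x), y_start = min(y),
                 length = .N), by = run][, run := NULL]
  data.table::setorder(out, offset, x_start)
  out[]
}

#' DNA dot plot by exact word match
#'
#' A point is placed at (x, y) whenever the `word`-length substrings of the
#' two sequences starting at x and y are identical. Tandem repeats appear as
#' parallel off-main diagonals; maximal diagonal runs are reported alongside
#' the raw points.
#'
#' @param seq_x,seq_y DNA strings (x: horizontal axis, y: vertical).
#' @param word Exact-match word length in bp (default 10).
#' @return List of class `dotplot`: mode, params, `points` (data.table x, y;
#'   1-based word start positions) and `diagonals` (offset = x - y, x_start,
#'   y_start, length).
#' @export
dotplot_dna <- function(seq_x, seq_y, word = 10L) {
  seq_x <- toupper(seq_x); seq_y <- toupper(seq_y)
  if (word > min(nchar(seq_x), nchar(seq_y)))
    stop("word length exceeds a sequence length")
  nx <- nchar(seq_x) - word + 1L
  ny <- nchar(seq_y) - word + 1L
  wx <- data.table::data.table(word_s = substring(seq_x, 1:nx,
                                                  word:(nx + word - 1L)),
                               x = 1:nx)
  wy <- data.table::data.table(word_s = substring(seq_y, 1:ny,
                                                  word:(ny + word - 1L)),
                               y = 1:ny)
  pts <- merge(wx, wy, by = "word_s", allow.cartesian = TRUE)[, .(x, y)]
  data.table::setorder(pts, x, y)
  structure(list(mode = "dna_word", params = list(word = word),
                 seq_x_len = nchar(seq_x), seq_y_len = nchar(seq_y),
                 points = pts[], diagonals = diagonal_runs(pts)),
            class = "dotplot")
}

#' Protein dot plot by windowed substitution score
#'
#' A point is placed at (x, y) whenever the summed substitution score of the
#' ungapped `window`-residue comparison starting at (x, y) reaches
#' `threshold` (dotmatcher-style; default window 10, threshold 23,
#' BLOSUM62).
#'
#' @param seq_x,seq_y Amino-acid strings.
#' @param window Window length in residues.
#' @param threshold Minimum window score.
#' @param matrix Substitution matrix name available in Biostrings (default
#'   `"BLOSUM62"`).
#' @return List of class `dotplot` as in [dotplot_dna()].
#' @export
dotplot_protein <- function(seq_x, seq_y, window = 10L, threshold = 23,
                            matrix = "BLOSUM62") {
  M <- get_submatrix(matrix)
  xs <- strsplit(toupper(seq_x), "")[[1]]
  ys <- strsplit(toupper(seq_y), "")[[1]]
  bad <- setdiff(unique(c(xs, ys)), rownames(M))
  if (length(bad))
    stop("residue(s) outside substitution-matrix alphabet: ",
         paste(bad, collapse = ", "))
  nx <- length(xs); ny <- length(ys)
  if (window > min(nx, ny)) stop("window exceeds a sequence length")
  pts <- vector("list", nx + ny - 1L)
  k <- 0L
  for (off in (-(ny - window)):(nx - window)) {
    x0 <- max(1L, 1L + off); y0 <- x0 - off
    len <- min(nx - x0, ny - y0) + 1L
    if (len < window) next
    sc <- M[cbind(xs[x0:(x0 + len - 1L)], ys[y0:(y0 + len - 1L)])]
    cs <- c(0, cumsum(sc))
    wsum <- cs[(window + 1L):(len + 1L)] - cs[seq_len(len - window + 1L)]
    hit <- which(wsum >= threshold)
    if (length(hit)) {
      k <- k + 1L
      pts[[k]] <- data.table::data.table(x = x0 + hit - 1L, y = y0 + hit - 1L)
    }
  }
  pts <- if (k) data.table::rbindlist(pts[seq_len(k)]) else
    data.table::data.table(x = integer(), y = integer())
  data.table::setorder(pts, x, y)
  structure(list(mode = "protein_window",
                 params = list(window = window, threshold = threshold,
                               matrix = matrix),
                 seq_x_len = nx, seq_y_len = ny,
                 points = pts[], diagonals = diagonal_runs(pts)),
            class = "dotplot")
}

get_submatrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' @export
print.dotplot <- function(x, ...) {
  cat("dotplot (", x$mode, "), ", nrow(x$points), " points, ",
      nrow(x$diagonals), " diagonal runs\n", sep = "")
  invisible(x)
}
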