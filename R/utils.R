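#' IUPAC nucleotide code table
#'
#' Maps each IUPAC symbol to the set of concrete bases it stands for.
#' `N` in a *subject* sequence never matches any pattern symbol; the codes
#' here describe pattern degeneracy only.
#'
#' @return Named character vector, e.g. `IUPAC_CODES[["Y"]] == "CT"`.
#' @export
IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

#' Reverse complement of a nucleotide string (IUPAC-aware)
#'
#' @param x Character vector of DNA strings (IUPAC symbols allowed).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", D = "H", H = "D", V = "B", N = "N")
  vapply(x, function(s) {
    ch <- rev(strsplit(toupper(s), "", fixed = TRUE)[[1]])
    bad <- !ch %in% names(comp)
    if (any(bad)) stop("illegal nucleotide symbol(s): ",
                       paste(unique(ch[bad]), collapse = ", "))
    paste(comp[ch], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Enumerate all concrete instances of an IUPAC pattern
#'
#' @param pattern Single IUPAC string.
#' @return Character vector of all concrete ACGT words matching `pattern`.
#' @export
iupac_instances <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  ch <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- !ch %in% names(IUPAC_CODES)
  if (any(bad)) stop("illegal IUPAC symbol(s): ",
                     paste(unique(ch[bad]), collapse = ", "))
  sets <- lapply(ch, function(s) strsplit(IUPAC_CODES[[s]], "")[[1]])
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste, collapse = "")
}

#' Convert an IUPAC pattern to a character-class regex
#'
#' @param pattern Single IUPAC string.
#' @return Regex string where each degenerate symbol becomes `[...]`.
#' @export
iupac_to_regex <- function(pattern) {
  ch <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- !ch %in% names(IUPAC_CODES)
  if (any(bad)) stop("illegal IUPAC symbol(s): ",
                     paste(unique(ch[bad]), collapse = ", "))
  paste(vapply(ch, function(s) {
    set <- IUPAC_CODES[[s]]
    if (nchar(set) == 1L) set else paste0("[", set, "]")
  }, character(1)), collapse = "")
}

#' Uniform-random DNA sequence
#'
#' @param n Length in bp.
#' @return Single DNA string drawn uniformly over ACGT (uses the current RNG
#'   stream; seed upstream for reproducibility).
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## sample() that never interprets a length-1 x as 1:x
resample <- function(x, size = 1L, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

## Deterministic child seed for a named pipeline stage. Keeps each stage
## individually reproducible regardless of what ran before it.
stage_seed <- function(seed, stage) {
  offs <- c(genome = 11L, methylome = 23L, chip = 37L, evolution = 41L,
            analysis = 53L)
  if (!stage %in% names(offs)) stop("unknown stage: ", stage)
  (as.integer(seed) * 101L + offs[[stage]]) %% 2147483629L
}

## last observation carried forward for internal NA handling
na_locf <- function(x) {
  idx <- cumsum(!is.na(x))
  x[!is.na(x)][pmax(idx, 1L)]
}
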