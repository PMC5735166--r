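#' Poisson-correction distance between two aligned sequences
#'
#' Columns with a gap (`-` or `.`) in either sequence are excluded; for the
#' proportion `p` of differing ungapped columns the distance is
#' `d = -ln(1 - p)`, correcting for multiple substitutions at a site.
#'
#' @param aligned_a,aligned_b Equal-length aligned sequence strings.
#' @return Non-negative distance; `NaN` with a warning when `p = 1` or no
#'   ungapped columns remain.
#' @export
poisson_distance <- function(aligned_a, aligned_b) {
  a <- strsplit(toupper(aligned_a), "")[[1]]
  b <- strsplit(toupper(aligned_b), "")[[1]]
  if (length(a) != length(b)) stop("aligned sequences differ in length")
  keep <- !(a %in% c("-", ".")) & !(b %in% c("-", "."))
  if (!any(keep)) {
    warning("no ungapped columns; distance undefined")
    return(NaN)
  }
  p <- mean(a[keep] != b[keep])
  if (p >= 1) {
    warning("all ungapped columns differ; Poisson correction undefined")
    return(NaN)
  }
  -log(1 - p)
}

#' Pairwise Poisson-correction distance matrix
#'
#' @param alignment Named character vector of aligned sequences.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = sequence
#'   names.
#' @export
poisson_dist_matrix <- function(alignment) {
  n <- length(alignment)
  labs <- names(alignment)
  if (is.null(labs)) labs <- paste0("seq", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- poisson_distance(alignment[[i]], alignment[[j]])
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration; consistent on additive matrices (recovers the
#' generating tree's topology and branch lengths exactly). Delegates to the
#' reference implementation in \pkg{ape}, which is deterministic for a given
#' matrix.
#'
#' @param d Symmetric zero-diagonal distance matrix (or `dist`), n >= 3.
#' @return An [ape::nj()] `phylo` tree (unrooted).
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be square")
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (any(is.na(d)) || any(!is.finite(d))) stop("NaN/NA entries in d")
  if (max(abs(d - t(d))) > 1e-8) stop("d must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("d must have a zero diagonal")
  ape::nj(stats::as.dist(d))
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement; each replicate is run
#' through Poisson-correction distances plus NJ, and the support of an
#' internal edge is the fraction of replicates containing its bipartition.
#'
#' @param alignment Named character vector of aligned sequences.
#' @param n_replicates Bootstrap replicates (>= 1).
#' @param seed RNG seed for the resampling.
#' @return List: `tree` (the NJ tree of the full alignment), `supports`
#'   (per-internal-node bootstrap proportions, in the tree's internal-node
#'   order; the trivial bipartition at the unrooted tree's basal node is
#'   `NA`).
#' @export
bootstrap_tree <- function(alignment, n_replicates = 100L, seed = 1L) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  x <- do.call(rbind, strsplit(toupper(unname(alignment)), ""))
  rownames(x) <- names(alignment)
  fun <- function(mat) {
    aln <- apply(mat, 1L, paste, collapse = "")
    neighbor_joining(poisson_dist_matrix(aln))
  }
  ref <- fun(x)
  set.seed(seed)
  counts <- ape::boot.phylo(ref, x, fun, B = n_replicates, quiet = TRUE,
                            rooted = FALSE)
  list(tree = ref, supports = counts / n_replicates)
}
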