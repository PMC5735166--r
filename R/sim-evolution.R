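AA_ALPHABET20 <- c("A","R","N","D","C","Q","E","G","H","I",
                   "L","K","M","F","P","S","T","W","Y","V")

#' Simulate an aligned protein family evolved along a known tree
#'
#' Sites substitute independently along each branch with probability
#' `1 - exp(-rate * t)` (new residue drawn uniformly from the other 19), so
#' two leaves separated by total branch length `t` differ at a proportion of
#' sites close to `1 - exp(-t)` for unit rate. When no root sequence is
#' supplied, the root is generated with two conserved domains evolving at a
#' reduced rate and a C-terminal variable region holding an expandable
#' peptide repeat; repeat copy number drifts along branches and absent units
#' appear as gap columns in the returned alignment.
#'
#' @param tree Newick string with branch lengths.
#' @param root_protein Optional root amino-acid string; if supplied it is
#'   evolved as-is (uniform rate, no repeat region).
#' @param config A [sim_config()] providing `seed` and `substitution_rate`.
#' @param n_core Core length (aa) of the generated root.
#' @param repeat_unit_aa,max_repeat_copies Peptide repeat geometry.
#' @param conserved_scale Rate multiplier inside conserved domains.
#' @return List: `alignment` (named character vector of equal-width aligned
#'   sequences, `-` = gap) and `truth` (tree string, per-leaf repeat copy
#'   number, conserved/repeat column indices, root sequence).
#' @export
simulate_family_evolution <- function(tree, root_protein = NULL, config,
                                      n_core = 240L, repeat_unit_aa = 10L,
                                      max_repeat_copies = 6L,
                                      conserved_scale = 0.05) {
  set.seed(stage_seed(config$seed, "evolution"))
  phy <- tryCatch(ape::read.tree(text = tree),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || is.null(phy$edge.length))
    stop("malformed newick tree (branch lengths required)")
  rate <- config$substitution_rate

  if (is.null(root_protein)) {
    root <- c(sample(AA_ALPHABET20, n_core, replace = TRUE),
              rep(sample(AA_ALPHABET20, repeat_unit_aa, replace = TRUE),
                  max_repeat_copies))
    ncolumns <- n_core + repeat_unit_aa * max_repeat_copies
    conserved <- c(seq_len(floor(n_core / 3)),
                   seq(2L * floor(n_core / 3) + 1L, n_core))
    repeat_cols <- seq(n_core + 1L, ncolumns)
    k0 <- max(2L, max_repeat_copies - 2L)
  } else {
    root <- strsplit(toupper(root_protein), "")[[1]]
    if (any(!root %in% AA_ALPHABET20))
      stop("root_protein contains non-standard residues")
    ncolumns <- length(root)
    conserved <- integer(0)
    repeat_cols <- integer(0)
    k0 <- 0L
  }
  col_rate <- rep(rate, ncolumns)
  col_rate[conserved] <- rate * conserved_scale

  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  seqs <- vector("list", nnode)
  kcopy <- integer(nnode)
  root_node <- ntip + 1L
  seqs[[root_node]] <- root
  kcopy[root_node] <- k0

  evolve_branch <- function(s, k, t) {
    psub <- 1 - exp(-col_rate * t)
    hit <- which(stats::runif(length(s)) < psub)
    for (i in hit) s[i] <- sample(setdiff(AA_ALPHABET20, s[i]), 1L)
    if (length(repeat_cols)) {
      pk <- 1 - exp(-0.5 * rate * t)
      if (stats::runif(1) < pk)
        k <- min(max(k + sample(c(-1L, 1L), 1L), 2L), max_repeat_copies)
    }
    list(s = s, k = k)
  }

  ## preorder traversal so parents are evolved before children
  edges <- phy$edge[order(phy$edge[, 1L]), , drop = FALSE]
  ord <- ape::reorder.phylo(phy, "cladewise")$edge
  lens <- phy$edge.length[match(paste(ord[, 1], ord[, 2]),
                                paste(phy$edge[, 1], phy$edge[, 2]))]
  for (e in seq_len(nrow(ord))) {
    par <- ord[e, 1L]; chd <- ord[e, 2L]
    res <- evolve_branch(seqs[[par]], kcopy[par], lens[e])
    seqs[[chd]] <- res$s
    kcopy[chd] <- res$k
  }

  aln <- character(ntip)
  for (i in seq_len(ntip)) {
    s <- seqs[[i]]
    if (length(repeat_cols) && kcopy[i] < max_repeat_copies) {
      gap_units <- seq(kcopy[i] * repeat_unit_aa + 1L,
                       max_repeat_copies * repeat_unit_aa)
      s[repeat_cols[gap_units]] <- "-"
    }
    aln[i] <- paste(s, collapse = "")
  }
  names(aln) <- phy$tip.label
  list(alignment = aln,
       truth = list(tree = tree,
                    copy_number = stats::setNames(kcopy[seq_len(ntip)],
                                                  phy$tip.label),
                    conserved_columns = conserved,
                    repeat_columns = repeat_cols,
                    root = paste(root, collapse = "")))
}
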