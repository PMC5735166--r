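#!/usr/bin/env Rscript
## Evolution toolkit: DNA dot plots of planted tandem arrays (copy-number
## geometry), tandem-repeat detection, a simulated protein family evolved
## along a known tree, protein dot plots, Poisson-correction distances and
## an NJ tree with bootstrap support.
source("analysis/00_params.R")

genome <- read_genome_fasta(p_pipe("genome.fa"))
truth <- read_truth(p_pipe("truth.json"))

## dot plot of the two most copy-rich targeted arrays (plus flanks)
arr <- truth$arrays[truth$arrays$family == truth$target_family, ]
arr <- arr[order(-arr$n_copies), ]
get_seq <- function(iv, pad = 50L)
  as.character(Biostrings::subseq(genome[[iv$chrom]],
                                  max(iv$start - pad, 1L), iv$end + pad))
dp <- dotplot_dna(get_seq(arr[1, ]), get_seq(arr[2, ]), word = 10L)
fwrite(dp$points, p_res("dotplot_arrays_points.tsv"), sep = "\t")
fwrite(dp$diagonals, p_res("dotplot_arrays_diagonals.tsv"), sep = "\t")
cat(sprintf("Array dot plot (%d vs %d copies): %d parallel diagonals\n",
            arr$n_copies[1], arr$n_copies[2], nrow(dp$diagonals)))

reps <- find_tandem_repeats(get_seq(arr[1, ]), min_unit = 10L,
                            max_unit = 60L)
fwrite(reps, p_res("tandem_repeats.tsv"), sep = "\t")
cat(sprintf("Tandem repeats in the top array region: unit %d bp x %.1f copies (identity %.2f)\n",
            reps$unit_length[1], reps$copy_number[1],
            reps$percent_identity[1]))

## protein family along the configured tree
fe <- simulate_family_evolution(CFG$tree, config = CFG)
write_aligned_fasta(fe$alignment, p_res("vanc_alignment.fa"))
d <- poisson_dist_matrix(fe$alignment)
fwrite(as.data.table(d, keep.rownames = "label"),
       p_res("poisson_distances.tsv"), sep = "\t")
cat("\nPoisson-correction distances:\n")
print(round(d, 3))

first2 <- gsub("-", "", fe$alignment[1:2])
dpp <- dotplot_protein(first2[1], first2[2])
fwrite(dpp$points, p_res("dotplot_protein_points.tsv"), sep = "\t")
cat(sprintf("Protein dot plot (%s vs %s): %d points, %d diagonals\n",
            names(first2)[1], names(first2)[2], nrow(dpp$points),
            nrow(dpp$diagonals)))

bt <- bootstrap_tree(fe$alignment, n_replicates = 100L, seed = PARAMS$seed)
ape::write.tree(bt$tree, p_res("nj_tree.nwk"))
fwrite(data.table(node = seq_along(bt$supports) +
                    length(bt$tree$tip.label), support = bt$supports),
       p_res("nj_bootstrap.tsv"), sep = "\t")
cat(sprintf("NJ tree: %s  (bootstrap supports: %s)\n",
            ape::write.tree(bt$tree),
            paste(stats::na.omit(bt$supports), collapse = ", ")))
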