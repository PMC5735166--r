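#!/usr/bin/env Rscript
## Motif analyses: scan the genome for the targeted family's degenerate
## motif, type the hits (C/T), count them per TE, detect same-orientation
## arrays, discover motifs de novo from the CG-DMR sequences, and compute
## the mismatch distance between the two protein families' target motifs.
source("analysis/00_params.R")

genome <- read_genome_fasta(p_pipe("genome.fa"))
ann <- read_te_annotation(p_pipe("annotation.tsv"))
truth <- read_truth(p_pipe("truth.json"))
target_motif <- truth$families$motif[
  truth$families$family == truth$target_family]

hits <- scan_motifs(genome, target_motif)
fwrite(hits, p_res("motif_hits.tsv"), sep = "\t")
counts <- count_motifs_per_te(hits, ann)
fwrite(counts, p_res("motif_counts.tsv"), sep = "\t")
cat(sprintf("Scanned %s: %d hits (%s)\n", target_motif, nrow(hits),
            paste(sprintf("%s-type %d", names(table(hits$motif_type)),
                          table(hits$motif_type)), collapse = ", ")))
tgt_counts <- merge(counts, truth$te[, .(te_id, targeted)], by = "te_id")
cat(sprintf("Mean hits per targeted TE %.1f vs non-targeted %.1f\n",
            tgt_counts[targeted == TRUE, mean(C + T + CC + AC + other)],
            tgt_counts[targeted == FALSE, mean(C + T + CC + AC + other)]))

arrays <- find_motif_arrays(hits)
fwrite(arrays, p_res("motif_arrays.tsv"), sep = "\t")
cat(sprintf("%d same-orientation arrays (median density %.1f hits/kb)\n",
            nrow(arrays), median(arrays$density)))

## discovery: DMR sequences vs length-matched non-TE background
set.seed(PARAMS$seed)
dmrs <- fread(p_res("cg_dmrs.tsv"))
pos <- vapply(seq_len(nrow(dmrs)), function(i)
  as.character(Biostrings::subseq(genome[[dmrs$chrom[i]]], dmrs$start[i],
                                  dmrs$end[i])), character(1))
tes <- te_intervals(ann)
neg <- character(0)
glen <- Biostrings::width(genome)[1]
while (length(neg) < 50L) {
  len <- sample(nchar(pos), 1L)
  s0 <- sample.int(glen - len, 1L)
  if (!any(tes$start <= s0 + len - 1L & tes$end >= s0))
    neg <- c(neg, as.character(Biostrings::subseq(genome[[1]], s0,
                                                  s0 + len - 1L)))
}
disc <- discover_motifs(pos, neg)
fwrite(disc, p_res("discovered_motifs.tsv"), sep = "\t")
cat(sprintf("\nDiscovery on %d DMR vs %d background sequences: %d candidates (E <= 0.05)\n",
            length(pos), length(neg), nrow(disc)))
print(disc[1:min(5, .N), .(pattern, pos_with, neg_with, e = signif(e, 3))])

cat(sprintf("\nMismatch distance to %s: AGTTGTAC %d nt, AGTTGTCC %d nt\n",
            "YAGTATTAY", motif_min_mismatch("AGTTGTAC", "YAGTATTAY"),
            motif_min_mismatch("AGTTGTCC", "YAGTATTAY")))
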