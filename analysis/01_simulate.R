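#!/usr/bin/env Rscript
## Simulate the study system: a genome carrying four VANDAL-like TE
## families whose non-coding regions hold tandem arrays of a
## family-specific motif, paired WT/transgenic methylomes in which the
## targeted family loses CG methylation locally around its arrays and
## non-CG methylation element-wide, and ChIP coverage enriched over the
## arrays. All files and the ground truth go to results/pipeline/.
source("analysis/00_params.R")

sim <- simulate_genome(CFG)
write_genome_fasta(sim$genome, p_pipe("genome.fa"))
write_te_annotation(sim$annotation, p_pipe("annotation.tsv"))
write_truth(sim$truth, p_pipe("truth.json"))

meth <- simulate_methylomes(sim$genome, sim$annotation, sim$truth, CFG)
write_cx_report(meth$wt, p_pipe("wt.CX_report.txt"))
write_cx_report(meth$treated, p_pipe("treated.CX_report.txt"))

chip <- simulate_chip(sim$genome, sim$annotation, sim$truth, CFG)
write_bedgraph(chip$ip, p_pipe("chip_ip.bedgraph"))
write_bedgraph(chip$input, p_pipe("chip_input.bedgraph"))
write_bed(chip$summits, p_pipe("summits.bed"))

tes <- te_intervals(sim$annotation)
cat(sprintf(
  "Simulated %d bp genome (seed %d): %d TEs in %d families; %d targeted\n",
  CFG$genome_length, CFG$seed, nrow(tes), CFG$n_te_families,
  sum(sim$truth$te$targeted)))
cat(sprintf("Planted %d motif arrays (%d motif instances); %d ChIP summits\n",
            nrow(sim$truth$arrays), nrow(sim$truth$motifs),
            nrow(chip$summits)))
cat(sprintf("Methylomes: %d cytosines per condition at ~%gx coverage\n",
            nrow(meth$wt), CFG$mean_coverage))
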