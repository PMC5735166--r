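#!/usr/bin/env Rscript
## Score the whole analysis against the planted ground truth: DMR
## sensitivity/precision, CHH significance separation between targeted and
## non-targeted families, discovery rank of the planted motif, and summit
## annotation accuracy.
source("analysis/00_params.R")

truth <- read_truth(p_pipe("truth.json"))
ann <- read_te_annotation(p_pipe("annotation.tsv"))
summits <- read_bed(p_pipe("summits.bed"))

outputs <- list(
  sim = list(truth = truth, annotation = ann),
  dmrs = fread(p_res("cg_dmrs.tsv")),
  changes = fread(p_res("te_changes.tsv")),
  discovered = fread(p_res("discovered_motifs.tsv")),
  chip = list(summits = summits))

genome <- read_genome_fasta(p_pipe("genome.fa"))
report <- validate_against_truth(outputs, truth = truth, genome = genome)
fwrite(report, p_res("validation_report.tsv"), sep = "\t")
cat("Recovery against planted ground truth:\n")
print(report[, .(metric, value = signif(value, 4))])

stopifnot(report[metric == "dmr_window_sensitivity", value] >= 0.9,
          report[metric == "dmr_base_precision", value] >= 0.9,
          report[metric == "chh_significance_separation", value] > 0)
cat("\nAll recovery targets met.\n")
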