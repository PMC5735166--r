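#!/usr/bin/env Rscript
## Differential methylation: per-TE hypomethylation significance in all
## three contexts, CG-DMR calling with the one-gap merge rule, and a
## fractional profile of the most strongly affected TE.
source("analysis/00_params.R")

wt <- read_cx_report(p_pipe("wt.CX_report.txt"))
tr <- read_cx_report(p_pipe("treated.CX_report.txt"))
ann <- read_te_annotation(p_pipe("annotation.tsv"))

changes <- per_te_changes(wt, tr, ann)
fwrite(changes, p_res("te_changes.tsv"), sep = "\t")
top <- changes[context == "CHH"][order(-value)]
cat("Per-TE CHH hypomethylation significance, top 5:\n")
print(top[1:5, .(te_id, family, value = round(value, 2))])

dmrs <- call_cg_dmrs(wt, tr)
fwrite(dmrs, p_res("cg_dmrs.tsv"), sep = "\t")
write_bed(dmrs[, .(chrom, start, end, name = sprintf("DMR%02d", .I),
                   score = n_windows, strand = ".")],
          p_res("cg_dmrs.bed"))
cat(sprintf("\nCalled %d CG-DMRs covering %d bp (mean drop %.2f)\n",
            nrow(dmrs), sum(dmrs$end - dmrs$start + 1L), mean(dmrs$diff)))

tes <- te_intervals(ann)
best <- tes[te_id == top$te_id[1]]
prof <- fractional_profile(rbind(wt), best)
prof[, condition := "wt"]
prof_t <- fractional_profile(rbind(tr), best)
prof_t[, condition := "treated"]
fwrite(rbind(prof, prof_t), p_res("fractional_profile_top_te.tsv"),
       sep = "\t")
body_cg <- rbind(prof, prof_t)[region == "body" & context == "CG"]
cat(sprintf("Fractional profile of %s: mean body CG level wt %.2f vs treated %.2f\n",
            best$te_id,
            body_cg[condition == "wt", mean(level, na.rm = TRUE)],
            body_cg[condition == "treated", mean(level, na.rm = TRUE)]))
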