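#!/usr/bin/env Rscript
## ChIP enrichment: 10-kb binned IP/input ratios, summit annotation by TE
## segment, and summit-centred methylation metaplots for both conditions.
source("analysis/00_params.R")

ip <- read_bedgraph(p_pipe("chip_ip.bedgraph"))
input <- read_bedgraph(p_pipe("chip_input.bedgraph"))
summits <- read_bed(p_pipe("summits.bed"))
ann <- read_te_annotation(p_pipe("annotation.tsv"))
truth <- read_truth(p_pipe("truth.json"))

bins <- bin_enrichment(ip, input, bin = 10000L)
fwrite(bins, p_res("chip_bins.tsv"), sep = "\t")
top_decile <- bins[ratio >= quantile(ratio, 0.9)]
tes <- te_intervals(ann)
tgt <- tes[te_id %in% truth$te$te_id[truth$te$targeted]]
in_tgt <- vapply(seq_len(nrow(top_decile)), function(i)
  any(tgt$start <= top_decile$end[i] & tgt$end >= top_decile$start[i]),
  logical(1))
cat(sprintf("10-kb bins: %d; top-decile ratio bins overlapping targeted TEs: %d/%d\n",
            nrow(bins), sum(in_tgt), nrow(top_decile)))

annotated <- annotate_summits(summits, ann)
fwrite(annotated, p_res("summit_annotation.tsv"), sep = "\t")
cat(sprintf("Summits in targeted non-coding segments: %d/%d\n",
            annotated[family == truth$target_family &
                        segment_type == "noncoding", .N], nrow(annotated)))

wt <- read_cx_report(p_pipe("wt.CX_report.txt"))
tr <- read_cx_report(p_pipe("treated.CX_report.txt"))
mp_wt <- summit_metaplot(wt, summits)
mp_tr <- summit_metaplot(tr, summits)
mp_wt[, condition := "wt"]; mp_tr[, condition := "treated"]
mp <- rbind(mp_wt, mp_tr)
fwrite(mp, p_res("metaplot.tsv"), sep = "\t")
cg <- dcast(mp[context == "CG"], offset ~ condition, value.var = "level")
cg[, drop := wt - treated]
cat(sprintf("CG methylation loss (wt - treated) peaks at offset %d bp: %.2f (vs %.2f at +/-4 kb)\n",
            cg[which.max(drop), offset], max(cg$drop, na.rm = TRUE),
            cg[abs(offset) >= 4000, mean(drop, na.rm = TRUE)]))
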