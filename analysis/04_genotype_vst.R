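#!/usr/bin/env Rscript
# Genotype normalized copy number per CNVR and sample from the filtered
# calls, classify states on the Redon scale, scan for between-group
# differentiation with Vst, and select the top-1% candidate CNVRs.

library(cnvrscan)

filtered <- read.table("results/filtered_calls.tsv", header = TRUE,
                       comment.char = "#", stringsAsFactors = FALSE)
group_map <- read.table("results/cohort/input/groups.tsv", header = TRUE,
                        comment.char = "#", stringsAsFactors = FALSE)

cnvrs <- merge_cnv_calls(filtered)
cn <- genotype_calls(cnvrs, filtered, samples = group_map$sample_id)
write.table(data.frame(cnvr_id = rownames(cn), cn, check.names = FALSE),
            "results/cn_matrix.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cls <- apply(cn, 2, classify_cn)
write.table(data.frame(cnvr_id = rownames(cn), cls, check.names = FALSE),
            "results/cn_class.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

scan <- vst_scan(cn, group_map)
top <- select_top(scan, fraction = 0.01)
scan$candidate <- scan$vst >= top$threshold
write.table(scan, "results/vst.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("genotyped %d CNVRs x %d samples\n", nrow(cn), ncol(cn)))
cat(sprintf("top-1%% Vst threshold %.4f; %d candidate CNVR(s):\n",
            top$threshold, nrow(top$candidates)))
print(top$candidates[, c("cnvr_id", "vst")], row.names = FALSE)
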