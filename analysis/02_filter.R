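#!/usr/bin/env Rscript
# Parse the cohort call files and apply the standard read-depth call
# filter (p < 0.01, size > 1 kb, q0 < 0.5). Writes the retained calls and
# the per-group CNV summary under results/.

library(cnvrscan)

indir <- "results/cohort/input"
group_map <- read.table(file.path(indir, "groups.tsv"), header = TRUE,
                        comment.char = "#", stringsAsFactors = FALSE)

calls <- read_cohort_calls(indir, group_map)
filtered <- filter_calls(calls, filter_spec())

dir.create("results", showWarnings = FALSE)
write.table(filtered, "results/filtered_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
summary <- summarize_groups(filtered, group_map)
write.table(summary, "results/group_cnv_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("parsed %d calls, retained %d after filtering (%d removed)\n",
            nrow(calls), nrow(filtered), nrow(calls) - nrow(filtered)))
print(summary[summary$group == "Total", ], row.names = FALSE)
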