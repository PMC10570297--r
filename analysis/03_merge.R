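#!/usr/bin/env Rscript
# Merge the filtered calls into CNVRs (strict >= 1 bp overlap, transitive
# closure per chromosome), type them, and write the region-level tables:
# CNVR BED, type/size summary, genome coverage, presence/specific counts.

library(cnvrscan)

filtered <- read.table("results/filtered_calls.tsv", header = TRUE,
                       comment.char = "#", stringsAsFactors = FALSE)
group_map <- read.table("results/cohort/input/groups.tsv", header = TRUE,
                        comment.char = "#", stringsAsFactors = FALSE)
cfg <- read_sim_config("results/cohort/input/config.yaml")

cnvrs <- merge_cnv_calls(filtered)
write_cnvr_bed(cnvrs, "results/cnvrs.bed")
write.table(table2_report(cnvrs), "results/cnvr_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cov <- coverage_percent(cnvrs, cfg$chromosomes)
write.table(cov$per_chromosome, "results/cnvr_coverage.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

pres <- presence_and_specific(cnvrs, group_map)
write.table(
  data.frame(group = c(names(pres$specific), "shared_all"),
             cnvr_count = c(as.integer(pres$specific), pres$shared)),
  "results/specific_shared.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)

sd <- size_distribution(cnvrs)
cat(sprintf("%d CNVRs (%s); total %.3f Mb, mean %.2f kb, %.2f%% of genome\n",
            nrow(cnvrs),
            paste(sprintf("%d %s", table(cnvrs$cnvr_type),
                          names(table(cnvrs$cnvr_type))), collapse = ", "),
            sd$total_length_mb, sd$mean_length_kb, cov$genome_percent))
cat(sprintf("shared in all groups: %d; group-specific: %s\n", pres$shared,
            paste(sprintf("%s=%d", names(pres$specific), pres$specific),
                  collapse = " ")))
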