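#!/usr/bin/env Rscript
# Classify every CNVR by genomic context against the cohort's gene models
# (exonic > intronic > upstream > downstream > intergenic, 1.9 kb flanks)
# and list the genes each CNVR overlaps.

library(cnvrscan)

filtered <- read.table("results/filtered_calls.tsv", header = TRUE,
                       comment.char = "#", stringsAsFactors = FALSE)
cnvrs <- merge_cnv_calls(filtered)
models <- read_gene_models("results/cohort/input/genes.gff3")

region <- classify_regions(cnvrs, models, flank_bp = 1900)
genes <- overlap_genes(cnvrs, models)
annotation <- data.frame(
  cnvr_id = cnvrs$cnvr_id, region_class = region,
  gene_ids = vapply(genes, paste, "", collapse = ";"))
write.table(annotation, "results/annotation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

fr <- region_distribution(cnvrs, models, flank_bp = 1900)
write.table(data.frame(region_class = names(fr), fraction = fr,
                       row.names = NULL),
            "results/region_distribution.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("fraction of CNVRs per genomic-context class:\n")
print(round(fr, 4))
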