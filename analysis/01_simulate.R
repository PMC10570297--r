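#!/usr/bin/env Rscript
# Simulate the study-shaped cohort (7 groups x 4 samples, 100-bp bins,
# ~20x coverage) and write caller-style inputs under results/cohort/input:
# per-sample call files, truth sidecars, toy gene models, group map.

library(cnvrscan)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L

outdir <- "results/cohort/input"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- default_sim_config(seed = seed)
truth <- generate_truth(cfg)
sidecar <- emit_callset(truth, cfg, outdir)
genes <- emit_genes(cfg, outdir)
emit_group_map(cfg, file.path(outdir, "groups.tsv"))
write_sim_config(cfg, file.path(outdir, "config.yaml"))

cat(sprintf("cohort: %d samples in %d groups, %d loci\n",
            nrow(sim_samples(cfg)), nrow(cfg$groups), length(cfg$loci)))
cat(sprintf("emitted %d call records (%d real, %d junk) into %s\n",
            nrow(sidecar), sum(sidecar$status == "real"),
            sum(sidecar$status == "junk"), outdir))
cat(sprintf("gene models plant %d genomic-context classes\n",
            length(unique(genes$planted_class))))
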