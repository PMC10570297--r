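#' Run the full simulate-to-annotate pipeline
#'
#' One reproducible end-to-end run over a simulated cohort: the simulator
#' writes caller-style inputs (call files, gene models, group map) into
#' `<outdir>/input`, and the analysis stages — parse, quality-filter,
#' CNVR merge, copy-number genotyping, Redon classification, Vst scan with
#' top-quantile candidate selection, and genomic-context annotation — read
#' them back and write their tables into `outdir`. A run manifest records
#' the configuration, software version, input checksums and per-stage
#' record counts. Identical config and seed give identical outputs.
#'
#' An existing manifest in `outdir` aborts the run unless
#' `overwrite = TRUE`.
#'
#' @param config a [simulation_config()].
#' @param outdir output directory.
#' @param filter a [filter_spec()].
#' @param min_overlap_frac reciprocal overlap fraction for the merge.
#' @param contrast optional two-sided group contrast for the Vst scan
#'   (see [vst_scan()]); default all-groups.
#' @param top_fraction top quantile for candidate selection.
#' @param flank_bp flank width for region classification.
#' @param var_type variance convention for Vst.
#' @param overwrite allow writing over a previous run's outputs.
#' @return invisibly, a list with every intermediate object (`truth`,
#'   `sidecar`, `calls`, `filtered`, `cnvrs`, `cn_matrix`, `vst`,
#'   `candidates`, `annotation`, `region_fractions`, `manifest`).
#' @export
run_pipeline <- function(config, outdir, filter = filter_spec(),
                         min_overlap_frac = 0, contrast = NULL,
                         top_fraction = 0.01, flank_bp = 1900,
                         var_type = "population", overwrite = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  manifest_path <- file.path(outdir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite) {
    stop("output directory already holds a run (", manifest_path,
         "); use overwrite = TRUE to replace it")
  }
  input_dir <- file.path(outdir, "input")
  dir.create(input_dir, showWarnings = FALSE, recursive = TRUE)

  # --- simulate inputs
  truth <- generate_truth(config)
  sidecar <- emit_callset(truth, config, input_dir)
  gene_sidecar <- emit_genes(config, input_dir)
  emit_group_map(config, file.path(input_dir, "groups.tsv"))
  write_sim_config(config, file.path(input_dir, "config.yaml"))
  group_map <- sim_samples(config)

  # --- parse and filter
  calls <- read_cohort_calls(input_dir, group_map)
  filtered <- filter_calls(calls, filter)
  filtered_path <- file.path(outdir, "filtered_calls.tsv")
  write_tsv_commented(filtered, filtered_path,
                      "filtered CNV calls; coordinates 1-based inclusive")

  # --- merge
  cnvrs <- merge_cnv_calls(filtered, min_overlap_frac)
  write_cnvr_bed(cnvrs, file.path(outdir, "cnvrs.bed"))
  t2 <- table2_report(cnvrs)
  write_tsv_commented(t2, file.path(outdir, "cnvr_table.tsv"),
                      "CNVR summary by type and size bin")
  t1 <- table1_report(filtered, group_map, config$chromosomes,
                      min_overlap_frac)
  write_tsv_commented(t1$cnv, file.path(outdir, "group_cnv_table.tsv"),
                      "per-group CNV summary")
  write_tsv_commented(t1$cnvr, file.path(outdir, "group_cnvr_table.tsv"),
                      "per-group CNVR summary (within-group merge)")
  pres <- presence_and_specific(cnvrs, group_map)
  write_tsv_commented(
    data.frame(cnvr_id = rownames(pres$presence), pres$presence,
               check.names = FALSE),
    file.path(outdir, "presence_matrix.tsv"),
    "CNVR presence by group (1 = >=1 supporting sample)")
  write_tsv_commented(
    data.frame(group = c(names(pres$specific), "shared_all"),
               cnvr_count = c(as.integer(pres$specific), pres$shared)),
    file.path(outdir, "specific_shared.tsv"),
    "group-specific CNVR counts and all-group shared count")

  # --- genotype, classify, Vst
  cn <- genotype_calls(cnvrs, filtered, samples = group_map$sample_id)
  write_tsv_commented(
    data.frame(cnvr_id = rownames(cn), cn, check.names = FALSE),
    file.path(outdir, "cn_matrix.tsv"),
    "normalized copy number (diploid = 1.0), CNVR x sample")
  cls <- apply(cn, 2L, classify_cn)
  write_tsv_commented(
    data.frame(cnvr_id = rownames(cn), cls, check.names = FALSE),
    file.path(outdir, "cn_class.tsv"),
    "Redon class per CNVR and sample (deleted < 0.4 <= conserved <= 1.6 < duplicated)")
  vst <- vst_scan(cn, group_map, contrast = contrast, var_type = var_type)
  top <- select_top(vst, top_fraction)
  vst$candidate <- vst$vst >= top$threshold
  write_tsv_commented(vst, file.path(outdir, "vst.tsv"),
                      sprintf("Vst scan; threshold (top %.3g quantile) = %.6g",
                              top_fraction, top$threshold))
  cand_cnvrs <- cnvrs[match(top$candidates$cnvr_id, cnvrs$cnvr_id), ,
                      drop = FALSE]
  write_cnvr_bed(cand_cnvrs, file.path(outdir, "candidates.bed"))

  # --- annotate
  models <- read_gene_models(file.path(input_dir, "genes.gff3"))
  region <- classify_regions(cnvrs, models, flank_bp)
  genes <- overlap_genes(cnvrs, models)
  annotation <- data.frame(
    cnvr_id = cnvrs$cnvr_id, region_class = region,
    gene_ids = vapply(genes, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  write_tsv_commented(annotation, file.path(outdir, "annotation.tsv"),
                      "genomic-context class and overlapping genes per CNVR")
  fractions <- region_distribution(cnvrs, models, flank_bp)
  write_tsv_commented(
    data.frame(region_class = names(fractions), fraction = fractions,
               row.names = NULL),
    file.path(outdir, "region_distribution.tsv"),
    "fraction of CNVRs per genomic-context class")

  # --- manifest
  input_files <- list.files(input_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("cnvrscan")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    parameters = list(max_p = filter$max_p, min_size = filter$min_size,
                      max_q0 = filter$max_q0,
                      min_overlap_frac = min_overlap_frac,
                      top_fraction = top_fraction, flank_bp = flank_bp,
                      var_type = var_type),
    input_md5 = as.list(tools::md5sum(input_files)),
    counts = list(calls_parsed = nrow(calls),
                  calls_filtered = nrow(filtered),
                  calls_removed = nrow(calls) - nrow(filtered),
                  cnvrs = nrow(cnvrs),
                  matrix_cells = length(cn),
                  vst_records = nrow(vst),
                  candidates = nrow(top$candidates)))
  stopifnot(manifest$counts$calls_filtered <= manifest$counts$calls_parsed,
            sum(cnvrs$n_calls) == nrow(filtered),
            manifest$counts$matrix_cells ==
              nrow(cnvrs) * nrow(group_map))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(truth = truth, sidecar = sidecar,
                 gene_sidecar = gene_sidecar, calls = calls,
                 filtered = filtered, cnvrs = cnvrs, cn_matrix = cn,
                 cn_class = cls, vst = vst, threshold = top$threshold,
                 candidates = top$candidates, annotation = annotation,
                 region_fractions = fractions, manifest = manifest))
}
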