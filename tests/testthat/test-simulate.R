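test_that("config validation rejects bad distributions and stray loci", {
  expect_error(locus_spec("chr1", 100, 200,
                          list(A = c("0.5" = 0.6, "1" = 0.5))),
               "sum to")
  expect_error(locus_spec("chr1", 100, 200, list(A = c("-1" = 1))),
               "non-negative")
  loci <- list(locus_spec("chr1", 1e5, 2e5, list(A = c("1" = 1))))
  expect_error(
    simulation_config(data.frame(chrom = "chr1", length = 1.5e5),
                      data.frame(group = "A", n_samples = 2), loci),
    "exceeds chromosome")
})

test_that("truth draws follow the per-group state distributions", {
  # degenerate: everyone diploid
  cfg <- two_group_config(list(locus_spec("chr1", 10001, 12000, list(
    A = c("1" = 1), B = c("1" = 1)))))
  expect_true(all(generate_truth(cfg)$cn == 1.0))

  # group-fixed states
  cfg2 <- two_group_config(list(locus_spec("chr1", 10001, 12000, list(
    A = c("0.5" = 1), B = c("1.5" = 1)))))
  tr <- generate_truth(cfg2)
  expect_true(all(tr$cn[tr$group == "A"] == 0.5))
  expect_true(all(tr$cn[tr$group == "B"] == 1.5))

  # law of large numbers on a mixture: mean within 3 SE of 0.75
  cfg3 <- simulation_config(
    data.frame(chrom = "chr1", length = 1e5),
    data.frame(group = "A", n_samples = 10000),
    list(locus_spec("chr1", 10001, 12000,
                    list(A = c("0.5" = 0.5, "1" = 0.5)))),
    seed = 9)
  cn <- generate_truth(cfg3)$cn
  se <- 0.25 / sqrt(10000)
  expect_lt(abs(mean(cn) - 0.75), 3 * se)
})

test_that("identical seeds reproduce byte-identical simulation outputs", {
  cfg <- default_sim_config(seed = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  t1 <- generate_truth(cfg); t2 <- generate_truth(cfg)
  expect_identical(t1, t2)
  emit_callset(t1, cfg, d1); emit_callset(t2, cfg, d2)
  emit_genes(cfg, d1); emit_genes(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the truth
  t3 <- generate_truth(default_sim_config(seed = 6))
  expect_false(identical(t1$cn, t3$cn))
})

test_that("emitted calls mirror the truth and round-trip through the reader", {
  loci <- list(
    locus_spec("chr1", 10001, 13000, list(A = c("0.5" = 1), B = c("1" = 1))),
    locus_spec("chr1", 50001, 53000, list(A = c("1" = 1), B = c("2" = 1))))
  cfg <- two_group_config(loci, n_per_group = 3, rd_noise_sd = 0)
  tr <- generate_truth(cfg)
  dir <- withr::local_tempdir()
  sidecar <- emit_callset(tr, cfg, dir)
  gm <- sim_samples(cfg)
  calls <- read_cohort_calls(dir, gm)
  # one record per non-diploid truth entry: 3 deletions (A) + 3 dups (B)
  expect_equal(nrow(calls), 6L)
  expect_equal(nrow(calls), sum(sidecar$status == "real"))
  expect_equal(sort(unique(calls$cnv_type)), c("deletion", "duplication"))
  # with zero jitter the emitted RD is the true copy number
  a1 <- calls[calls$sample_id == "A_1", ]
  expect_equal(a1$normalized_rd, 0.5)
  expect_equal(c(a1$start, a1$end), c(10001, 13000))
  # all-diploid truth, no junk: empty callset
  cfg0 <- two_group_config(list(locus_spec("chr1", 10001, 13000, list(
    A = c("1" = 1), B = c("1" = 1)))))
  d0 <- withr::local_tempdir()
  emit_callset(generate_truth(cfg0), cfg0, d0)
  expect_equal(nrow(read_cohort_calls(d0, sim_samples(cfg0))), 0L)
})

test_that("junk calls fail exactly one filter criterion and are all removed", {
  loci <- lapply(seq(10001, 200000, by = 20000), function(s) {
    locus_spec("chr1", s, s + 2999,
               list(A = c("0.5" = 1), B = c("2" = 1)))
  })
  cfg <- two_group_config(loci, n_per_group = 4, junk_call_rate = 0.3,
                          seed = 17)
  tr <- generate_truth(cfg)
  dir <- withr::local_tempdir()
  sidecar <- emit_callset(tr, cfg, dir)
  expect_gt(sum(sidecar$status == "junk"), 0)
  calls <- read_cohort_calls(dir, sim_samples(cfg))
  expect_equal(nrow(calls), nrow(sidecar))
  kept <- filter_calls(calls, filter_spec())
  # removed count equals the sidecar's junk count
  expect_equal(nrow(calls) - nrow(kept), sum(sidecar$status == "junk"))
  expect_true(all(table(sidecar$junk_reason[sidecar$status == "junk"]) > 0))
})

test_that("depth tracks have Poisson means scaled by copy number", {
  loci <- list(
    locus_spec("chr1", 100001, 200000, list(A = c("2" = 1))),
    locus_spec("chr1", 300001, 400000, list(A = c("0" = 1))))
  cfg <- simulation_config(
    data.frame(chrom = "chr1", length = 1e6),
    data.frame(group = "A", n_samples = 1), loci,
    mean_coverage = 20, bin_size = 100, seed = 23)
  tr <- generate_truth(cfg)
  dir <- withr::local_tempdir()
  emit_depth(tr, cfg, dir)
  depth <- read.table(file.path(dir, "A_1.depth.tsv"), header = TRUE,
                      comment.char = "#")
  base <- depth$depth[depth$bin_start < 1e5]
  se <- sqrt(20 / length(base))
  expect_lt(abs(mean(base) - 20) / se, 3)
  dup <- depth$depth[depth$bin_start >= 1e5 & depth$bin_start < 2e5]
  expect_lt(abs(mean(dup) - 40) / sqrt(40 / length(dup)), 3)
  del <- depth$depth[depth$bin_start >= 3e5 & depth$bin_start < 4e5]
  expect_true(all(del == 0))
})

test_that("simulated gene models round-trip and realize every region class", {
  cfg <- default_sim_config(seed = 3)
  dir <- withr::local_tempdir()
  sidecar <- emit_genes(cfg, dir)
  expect_setequal(unique(sidecar$planted_class),
                  c("exonic", "intronic", "upstream", "downstream",
                    "intergenic"))
  models <- read_gene_models(file.path(dir, "genes.gff3"))
  expect_gt(nrow(models$genes), 0)
  expect_true(all(models$genes$strand %in% c("+", "-")))
  # exons lie within their gene spans
  gi <- match(models$exons$gene_id, models$genes$gene_id)
  expect_true(all(models$exons$start >= models$genes$start[gi]))
  expect_true(all(models$exons$end <= models$genes$end[gi]))
  # loci classified against the emitted models match the plan
  loci_df <- data.frame(cnvr_id = sidecar$locus_id, chrom = sidecar$chrom,
                        start = sidecar$start, end = sidecar$end,
                        length = sidecar$end - sidecar$start + 1)
  expect_equal(classify_regions(loci_df, models, flank_bp = 1900),
               sidecar$planted_class)
})

test_that("empirical Vst from sampled truth converges to the analytic value", {
  dist <- list(A = c("0.5" = 0.5, "1" = 0.5), B = c("1" = 0.7, "1.5" = 0.3))
  loci <- lapply(seq(10001, 400000, by = 20000)[1:20], function(s) {
    locus_spec("chr1", s, s + 1999, dist)
  })
  cfg <- two_group_config(loci, n_per_group = 100, seed = 29)
  tr <- generate_truth(cfg)
  exp_v <- expected_vst(loci[[1]], c(100, 100))
  diffs <- vapply(split(tr, tr$locus_id), function(sub) {
    compute_vst(sub$cn, sub$group)$vst - exp_v
  }, numeric(1))
  expect_lt(mean(abs(diffs)), 0.05)
})

test_that("a configuration survives the YAML round trip", {
  cfg <- default_sim_config(seed = 11)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$chromosomes$length, cfg$chromosomes$length)
  expect_equal(back$groups$group, cfg$groups$group)
  expect_equal(length(back$loci), length(cfg$loci))
  expect_equal(back$loci[[5]]$dist, cfg$loci[[5]]$dist)
  expect_identical(generate_truth(back), generate_truth(cfg))
})
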