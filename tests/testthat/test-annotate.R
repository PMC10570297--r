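models_fixture <- function() {
  genes <- data.frame(
    gene_id = c("g1", "g2"),
    chrom = c("chr1", "chr1"),
    start = c(10000, 50000), end = c(20000, 60000),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("g1", "g1", "g2"),
    chrom = "chr1",
    start = c(10000, 18000, 50000), end = c(12000, 20000, 60000),
    stringsAsFactors = FALSE)
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

region_of <- function(start, end, models = models_fixture(), flank = 1900) {
  df <- data.frame(cnvr_id = "x", chrom = "chr1", start = start, end = end,
                   length = end - start + 1)
  classify_regions(df, models, flank)
}

test_that("region classes follow the exon/intron/flank precedence", {
  m <- models_fixture()
  expect_equal(region_of(11500, 13000), "exonic")     # exon + intron
  expect_equal(region_of(13000, 14000), "intronic")   # inside g1 intron
  expect_equal(region_of(9000, 9500), "upstream")     # 500 bp 5' of +gene
  expect_equal(region_of(20500, 21000), "downstream") # 3' of +gene
  expect_equal(region_of(60500, 61000), "upstream")   # above end of -gene
  expect_equal(region_of(48500, 49000), "downstream") # below start of -gene
  expect_equal(region_of(30000, 31000), "intergenic") # ~10 kb from genes
})

test_that("a region upstream of one gene and downstream of another is upstream", {
  genes <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                      start = c(1000, 9000), end = c(7000, 12000),
                      strand = "+", stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                      start = c(1000, 9000), end = c(7000, 12000),
                      stringsAsFactors = FALSE)
  m <- structure(list(genes = genes, exons = exons), class = "gene_models")
  # 7500-8000 sits in a's downstream flank and b's upstream flank
  df <- data.frame(cnvr_id = "x", chrom = "chr1", start = 7500, end = 8000,
                   length = 501)
  expect_equal(classify_regions(df, m, 1900), "upstream")
})

test_that("shrinking the flank only moves flank classes to intergenic", {
  set.seed(41)
  m <- models_fixture()
  starts <- sample.int(70000, 300)
  df <- data.frame(cnvr_id = sprintf("r%d", seq_along(starts)),
                   chrom = "chr1", start = starts,
                   end = starts + sample(100:3000, 300, replace = TRUE))
  df$length <- df$end - df$start + 1
  flanks <- c(500, 1000, 1900, 5000)
  cls <- lapply(flanks, function(f) classify_regions(df, m, f))
  for (k in seq_len(length(flanks) - 1L)) {
    small <- cls[[k]]; big <- cls[[k + 1L]]
    moved <- small != big
    expect_true(all(small[moved] == "intergenic"))
    expect_true(all(big[moved] %in% c("upstream", "downstream")))
    expect_identical(small[!moved], big[!moved])
  }
})

test_that("gene overlap lists match a brute-force all-pairs check", {
  set.seed(43)
  m <- models_fixture()
  starts <- sample.int(70000, 100)
  df <- data.frame(cnvr_id = sprintf("r%d", 1:100), chrom = "chr1",
                   start = starts, end = starts + 500)
  got <- overlap_genes(df, m)
  for (i in seq_len(nrow(df))) {
    want <- m$genes$gene_id[vapply(seq_len(nrow(m$genes)), function(j) {
      overlaps_1based(df$start[i], df$end[i],
                      m$genes$start[j], m$genes$end[j])
    }, logical(1))]
    expect_identical(got[[i]], sort(want))
  }
  desert <- data.frame(cnvr_id = "d", chrom = "chr1", start = 30000,
                       end = 30100)
  expect_identical(overlap_genes(desert, m)[[1]], character(0))
})

test_that("region fractions sum to one and empty input is rejected", {
  m <- models_fixture()
  set.seed(47)
  starts <- sample.int(70000, 50)
  df <- data.frame(cnvr_id = sprintf("r%d", 1:50), chrom = "chr1",
                   start = starts, end = starts + 1000)
  fr <- region_distribution(df, m)
  expect_equal(sum(fr), 1)
  expect_named(fr, c("exonic", "intronic", "upstream", "downstream",
                     "intergenic"))
  desert <- data.frame(cnvr_id = "d", chrom = "chr1", start = 30000,
                       end = 30500)
  expect_equal(unname(region_distribution(desert, m)["intergenic"]), 1)
  expect_error(region_distribution(df[0, ], m), "empty")
})

test_that("GFF3 parsing links exons through mRNA and flags orphans", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1000\t5000\t.\t+\t.\tID=geneA",
    "chr1\ttest\tmRNA\t1000\t5000\t.\t+\t.\tID=geneA.t1;Parent=geneA",
    "chr1\ttest\texon\t1000\t2000\t.\t+\t.\tID=geneA.e1;Parent=geneA.t1",
    "chr1\ttest\texon\t1800\t2500\t.\t+\t.\tID=geneA.e2;Parent=geneA.t1",
    "chr1\ttest\texon\t4000\t5000\t.\t+\t.\tID=geneA.e3;Parent=geneA.t1",
    "chr1\ttest\tgene\t8000\t9000\t.\t-\t.\tID=geneB"
  ), path)
  m <- read_gene_models(path)
  expect_equal(m$genes$gene_id, c("geneA", "geneB"))
  a <- m$exons[m$exons$gene_id == "geneA", ]
  # first two exons overlap and are merged in normalization
  expect_equal(nrow(a), 2L)
  expect_equal(a$start, c(1000, 4000))
  expect_equal(a$end, c(2500, 5000))
  # exon-less gene becomes one exon over its span
  b <- m$exons[m$exons$gene_id == "geneB", ]
  expect_equal(c(b$start, b$end), c(8000, 9000))

  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\texon\t100\t200\t.\t+\t.\tID=lost;Parent=nowhere"
  ), path)
  expect_error(read_gene_models(path), "orphan")
})
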