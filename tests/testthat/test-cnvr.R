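make_calls <- function(starts, ends, types = "deletion", samples = "s1",
                       chrom = "chr1") {
  n <- length(starts)
  data.frame(sample_id = rep_len(samples, n), chrom = rep_len(chrom, n),
             start = starts, end = ends,
             cnv_type = rep_len(types, n), size = ends - starts + 1,
             normalized_rd = 0.5, p_value = 1e-5, eval2 = 0, eval3 = 0,
             eval4 = 0, q0 = 0, stringsAsFactors = FALSE)
}

test_that("overlapping calls merge to the envelope, book-ended calls do not", {
  m <- merge_cnv_calls(make_calls(c(100, 150), c(200, 300),
                                  samples = c("s1", "s2")))
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 100)
  expect_equal(m$end, 300)
  expect_equal(m$length, 201)
  expect_equal(m$n_samples, 2L)

  m2 <- merge_cnv_calls(make_calls(c(100, 201), c(200, 300)))
  expect_equal(nrow(m2), 2L)
})

test_that("a merged region with deletions and duplications is typed 'both'", {
  m <- merge_cnv_calls(make_calls(c(100, 150), c(200, 300),
                                  types = c("deletion", "duplication")))
  expect_equal(m$cnvr_type, "both")
  m1 <- merge_cnv_calls(make_calls(c(100, 150), c(200, 300)))
  expect_equal(m1$cnvr_type, "deletion")
})

test_that("merge chains overlaps transitively within a chromosome only", {
  # a-b overlap, b-c overlap, a-c do not: still one component
  m <- merge_cnv_calls(make_calls(c(100, 180, 260), c(200, 280, 360)))
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(100, 360))
  # identical coordinates on different chromosomes stay apart
  calls <- make_calls(c(100, 100), c(200, 200), chrom = c("chr1", "chr2"))
  expect_equal(nrow(merge_cnv_calls(calls)), 2L)
})

test_that("merge is idempotent, order-independent, and conserves calls", {
  set.seed(7)
  for (i in 1:30) {
    calls <- random_calls(sample(1:40, 1))
    m <- merge_cnv_calls(calls)
    # every call in exactly one CNVR
    idx <- sort(unlist(m$call_idx))
    expect_identical(idx, seq_len(nrow(calls)))
    # permutation invariance of spans
    perm <- sample(nrow(calls))
    m2 <- merge_cnv_calls(calls[perm, , drop = FALSE])
    expect_identical(m2[, c("cnvr_id", "chrom", "start", "end", "cnvr_type")],
                     m[, c("cnvr_id", "chrom", "start", "end", "cnvr_type")])
    # re-merging the CNVRs themselves is a fixed point
    as_calls <- make_calls(m$start, m$end, chrom = m$chrom)
    m3 <- merge_cnv_calls(as_calls)
    expect_equal(m3$start, m$start)
    expect_equal(m3$end, m$end)
    # union length never exceeds summed call length
    expect_lte(sum(m$length), sum(calls$size))
    expect_lte(nrow(m), nrow(calls))
    # type partition
    expect_equal(sum(m$cnvr_type == "duplication") +
                   sum(m$cnvr_type == "deletion") +
                   sum(m$cnvr_type == "both"), nrow(m))
  }
})

test_that("reciprocal overlap fraction separates slightly-touching calls", {
  # 10 bp overlap between a 101 bp and a 1001 bp call
  calls <- make_calls(c(1000, 1091), c(1100, 2091))
  expect_equal(nrow(merge_cnv_calls(calls, min_overlap_frac = 0)), 1L)
  expect_equal(nrow(merge_cnv_calls(calls, min_overlap_frac = 0.5)), 2L)
})

test_that("size bins are left-closed on the published boundaries", {
  m <- data.frame(length = c(9999, 10000, 49999, 50000, 1e5, 5e5, 1e6))
  sd <- size_distribution(m)
  expect_equal(sd$bins$count, c(1L, 2L, 1L, 1L, 1L, 1L))
  expect_equal(sum(sd$bins$count), nrow(m))
})

test_that("size distribution reproduces published percentages from counts", {
  counts <- c(6228, 626, 132, 199, 38, 7)
  lens <- c(5000, 20000, 60000, 200000, 600000, 1.5e6)
  cnvrs <- data.frame(length = rep(lens, counts))
  sd <- size_distribution(cnvrs)
  expect_equal(sd$bins$count, counts)
  expect_equal(sd$bins$percent, c(86.14, 8.66, 1.83, 2.75, 0.53, 0.10))
})

test_that("genome coverage uses union length over chromosome totals", {
  lens <- data.frame(chrom = c("chr1", "chr2"), length = c(1e6, 1e6))
  one <- data.frame(chrom = "chr1", start = 1, end = 10000,
                    length = 10000)
  cov <- coverage_percent(one, lens)
  expect_equal(cov$per_chromosome$percent, c(1.0, 0.0))
  expect_equal(cov$genome_percent, 0.5)
  # unmerged overlapping intervals count once
  two <- rbind(one, data.frame(chrom = "chr1", start = 5000, end = 10000,
                               length = 5001))
  expect_equal(coverage_percent(two, lens)$genome_percent, 0.5)
  none <- one[0, ]
  expect_equal(coverage_percent(none, lens)$genome_percent, 0)
  expect_error(coverage_percent(data.frame(chrom = "chrX", start = 1,
                                           end = 10, length = 10), lens),
               "chrX")
})

test_that("presence matrix yields group-specific and all-group shared counts", {
  gm <- data.frame(sample_id = c("a1", "a2", "b1", "b2"),
                   group = c("A", "A", "B", "B"))
  cnvrs <- data.frame(cnvr_id = c("r1", "r2", "r3"),
                      stringsAsFactors = FALSE)
  cnvrs$samples <- list(c("a1"), c("a1", "b2"), c("b1", "b2"))
  ps <- presence_and_specific(cnvrs, gm)
  expect_equal(ps$presence["r1", ], c(A = 1L, B = 0L))
  expect_equal(ps$specific, c(A = 1L, B = 1L))
  expect_equal(ps$shared, 1L)
})
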