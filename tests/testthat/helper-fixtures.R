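# Shared fixtures and independent oracles for the suite.

# Independent two-pass Vst oracle: explicit loops, population variances.
vst_oracle <- function(values, labels) {
  pop_var <- function(x) {
    m <- 0
    for (v in x) m <- m + v
    m <- m / length(x)
    s <- 0
    for (v in x) s <- s + (v - m)^2
    s / length(x)
  }
  vt <- pop_var(values)
  groups <- unique(labels)
  vs <- 0
  for (g in groups) {
    xg <- values[labels == g]
    vs <- vs + length(xg) * pop_var(xg)
  }
  vs <- vs / length(values)
  if (vt == 0) 0 else (vt - vs) / vt
}

# Brute-force all-pairs interval overlap (1-based inclusive).
overlaps_1based <- function(s1, e1, s2, e2) s1 <= e2 && s2 <= e1

# Random call table on one or more chromosomes for fuzzing.
random_calls <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e5) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample(50:5000, n, replace = TRUE)
  data.frame(
    sample_id = sample(sprintf("s%d", 1:6), n, replace = TRUE),
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + len - 1,
    cnv_type = sample(c("deletion", "duplication"), n, replace = TRUE),
    size = len,
    normalized_rd = runif(n, 0.1, 2.5),
    p_value = runif(n, 0, 0.05),
    eval2 = runif(n), eval3 = runif(n), eval4 = runif(n),
    q0 = ifelse(runif(n) < 0.1, -1, runif(n, 0, 0.8)),
    stringsAsFactors = FALSE)
}

# Write one call line in the caller dialect.
call_line <- function(type = "deletion", chrom = "chr1", start = 1001,
                      end = 5000, size = end - start + 1, rd = 0.31,
                      p = 1e-5, q0 = 0.1) {
  sprintf("%s\t%s:%d-%d\t%d\t%g\t%g\t%g\t%g\t%g\t%g",
          type, chrom, start, end, size, rd, p, p, p, p, q0)
}

# Tiny two-group config around explicit loci.
two_group_config <- function(loci, n_per_group = 4, seed = 1,
                             chrom_len = 1e6, rd_noise_sd = 0,
                             junk_call_rate = 0) {
  simulation_config(
    chromosomes = data.frame(chrom = "chr1", length = chrom_len),
    groups = data.frame(group = c("A", "B"), n_samples = n_per_group),
    loci = loci, rd_noise_sd = rd_noise_sd,
    junk_call_rate = junk_call_rate, seed = seed)
}
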