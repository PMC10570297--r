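# Internal helpers shared across modules.

# Round half away from zero to `digits` decimals (table style: 0.005 -> 0.01).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# GRanges from 1-based inclusive columns of a data.frame.
df_to_gr <- function(df, chrom = "chrom", start = "start", end = "end") {
  GenomicRanges::GRanges(
    seqnames = as.character(df[[chrom]]),
    ranges = IRanges::IRanges(start = df[[start]], end = df[[end]])
  )
}

# Population (denominator n) or sample (n - 1) variance of a numeric vector.
variance_of <- function(x, var_type = "population") {
  n <- length(x)
  if (n == 0L) stop("variance of an empty vector is undefined")
  if (var_type == "population") {
    m <- mean(x)
    sum((x - m)^2) / n
  } else if (var_type == "sample") {
    if (n < 2L) return(0)
    stats::var(x)
  } else {
    stop("var_type must be 'population' or 'sample'")
  }
}

# Deterministic per-sample RNG sub-stream seed derived from a global seed.
# Kept strictly below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 1009) %% 2147483647)
}

# Write a data.frame as TSV with a '#'-prefixed convention/header comment.
write_tsv_commented <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_commented <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, ...)
}

# Validate a sample -> group map data.frame.
check_group_map <- function(group_map) {
  stopifnot(is.data.frame(group_map),
            all(c("sample_id", "group") %in% names(group_map)))
  if (anyDuplicated(group_map$sample_id)) {
    stop("duplicated sample ids in group map")
  }
  group_map
}
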