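#' Merge filtered CNV calls across samples into CNVRs
#'
#' CNVRs are the connected components of the overlap relation among calls
#' on the same chromosome (transitive closure), each spanning the envelope
#' `[min start, max end]` of its member calls. Overlap means at least one
#' shared base: book-ended calls are not merged. With
#' `min_overlap_frac > 0`, two calls are linked only if their shared length
#' is at least that fraction of both call lengths (reciprocal overlap);
#' components are still closed transitively.
#'
#' A CNVR is typed `duplication` or `deletion` when all member calls agree,
#' and `both` when it contains at least one of each.
#'
#' @param calls filtered call data.frame (columns `sample_id`, `chrom`,
#'   `start`, `end`, `cnv_type` at minimum).
#' @param min_overlap_frac reciprocal overlap fraction required to link two
#'   calls; default 0 (any shared base links).
#' @return data.frame of CNVRs sorted by (chrom, start): `cnvr_id`,
#'   `chrom`, `start`, `end`, `length`, `cnvr_type`, `n_calls`,
#'   `n_samples`, and list-columns `samples` and `call_idx` (row indices of
#'   `calls` supporting each CNVR).
#' @export
merge_cnv_calls <- function(calls, min_overlap_frac = 0) {
  stopifnot(min_overlap_frac >= 0, min_overlap_frac < 1)
  if (nrow(calls) == 0L) {
    return(data.frame(cnvr_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), length = numeric(),
                      cnvr_type = character(), n_calls = integer(),
                      n_samples = integer(), stringsAsFactors = FALSE))
  }
  gr <- df_to_gr(calls)
  hits <- GenomicRanges::findOverlaps(gr, gr, minoverlap = 1L)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  if (min_overlap_frac > 0) {
    ov <- IRanges::width(GenomicRanges::pintersect(gr[q], gr[s]))
    keep <- ov >= min_overlap_frac * IRanges::width(gr[q]) &
      ov >= min_overlap_frac * IRanges::width(gr[s])
    q <- q[keep]; s <- s[keep]
  }
  comp <- union_find_components(nrow(calls), q, s)
  idx_by_comp <- unname(split(seq_len(nrow(calls)), comp))
  rows <- lapply(idx_by_comp, function(idx) {
    sub <- calls[idx, , drop = FALSE]
    start <- min(sub$start); end <- max(sub$end)
    types <- unique(sub$cnv_type)
    data.frame(
      chrom = sub$chrom[1L], start = start, end = end,
      length = end - start + 1,
      cnvr_type = if (length(types) > 1L) "both" else types,
      n_calls = nrow(sub), n_samples = length(unique(sub$sample_id)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$samples <- lapply(idx_by_comp, function(idx) {
    sort(unique(calls$sample_id[idx]))
  })
  out$call_idx <- idx_by_comp
  ord <- order(out$chrom, out$start, out$end)
  out <- out[ord, , drop = FALSE]
  out$cnvr_id <- paste0(out$chrom, ":", out$start, "-", out$end)
  rownames(out) <- NULL
  out[, c("cnvr_id", "chrom", "start", "end", "length", "cnvr_type",
          "n_calls", "n_samples", "samples", "call_idx")]
}

# Union-find over n elements given linked pairs (q, s). Path-halving.
union_find_components <- function(n, q, s) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(q)) {
    a <- find(q[k]); b <- find(s[k])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  vapply(seq_len(n), find, integer(1))
}

#' Per-group CNVR tables by merging within each group's samples
#'
#' @param calls filtered call data.frame.
#' @param group_map sample-to-group map.
#' @param min_overlap_frac passed to [merge_cnv_calls()].
#' @return named list of CNVR data.frames, one per group.
#' @export
merge_by_group <- function(calls, group_map, min_overlap_frac = 0) {
  check_group_map(group_map)
  groups <- unique(group_map$group)
  out <- lapply(groups, function(g) {
    keep <- calls$sample_id %in% group_map$sample_id[group_map$group == g]
    merge_cnv_calls(calls[keep, , drop = FALSE], min_overlap_frac)
  })
  stats::setNames(out, groups)
}

# Size bin edges (bp), left-closed right-open, and printable labels.
cnvr_size_breaks <- c(0, 1e4, 5e4, 1e5, 5e5, 1e6, Inf)
cnvr_size_labels <- c("<10Kb", "10Kb-50Kb", "50Kb-100Kb", "100Kb-500Kb",
                      "500Kb-1Mb", ">=1Mb")

#' CNVR size distribution (Table-2 style)
#'
#' Bins CNVR lengths into `[0,10kb)`, `[10,50kb)`, `[50,100kb)`,
#' `[100,500kb)`, `[500kb,1Mb)`, `[1Mb,Inf)` (left-closed, right-open) and
#' reports counts and percentages, plus total length (Mb) and mean length
#' (kb).
#'
#' @param cnvrs CNVR data.frame from [merge_cnv_calls()] (or any frame with
#'   a `length` column in bp).
#' @return list with `bins` (data.frame: bin, count, percent),
#'   `n`, `total_length_mb`, `mean_length_kb`.
#' @export
size_distribution <- function(cnvrs) {
  n <- nrow(cnvrs)
  counts <- if (n == 0L) {
    rep(0L, length(cnvr_size_labels))
  } else {
    as.integer(table(cut(cnvrs$length, breaks = cnvr_size_breaks,
                         labels = cnvr_size_labels, right = FALSE)))
  }
  list(
    bins = data.frame(
      bin = cnvr_size_labels,
      count = counts,
      percent = if (n > 0L) round_half_up(100 * counts / n, 2) else
        rep(NA_real_, length(counts)),
      stringsAsFactors = FALSE
    ),
    n = n,
    total_length_mb = sum(cnvrs$length) / 1e6,
    mean_length_kb = if (n > 0L) mean(cnvrs$length) / 1e3 else NA_real_
  )
}

#' Percentage of the genome covered by CNVRs
#'
#' Union length of CNVRs per chromosome as a percentage of that chromosome,
#' and genome-wide over the total length of all listed chromosomes.
#' Overlapping input intervals are counted once.
#'
#' @param cnvrs CNVR data.frame.
#' @param chrom_lengths data.frame with columns `chrom`, `length` (bp).
#' @return list with `per_chromosome` (chrom, covered_bp, percent) and
#'   `genome_percent`.
#' @export
coverage_percent <- function(cnvrs, chrom_lengths) {
  stopifnot(all(c("chrom", "length") %in% names(chrom_lengths)))
  missing <- setdiff(unique(cnvrs$chrom), chrom_lengths$chrom)
  if (length(missing) > 0L) {
    stop("no length for chromosome(s): ", paste(missing, collapse = ", "))
  }
  covered <- vapply(chrom_lengths$chrom, function(ch) {
    sub <- cnvrs[cnvrs$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0L) return(0)
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(sub$start, sub$end))))
  }, numeric(1))
  per_chrom <- data.frame(
    chrom = chrom_lengths$chrom,
    covered_bp = covered,
    percent = 100 * covered / chrom_lengths$length,
    stringsAsFactors = FALSE
  )
  list(per_chromosome = per_chrom,
       genome_percent = 100 * sum(covered) / sum(chrom_lengths$length))
}

#' Group presence matrix and shared/specific CNVR counts
#'
#' A CNVR is present in a group when at least one of the group's samples
#' contributes a supporting call. "Group-specific" CNVRs are present in
#' exactly one group; "shared" CNVRs are present in every group.
#'
#' @param cnvrs CNVR data.frame carrying the `samples` list-column.
#' @param group_map sample-to-group map.
#' @return list with `presence` (0/1 matrix, CNVR x group), `specific`
#'   (named counts per group), `shared` (count present in all groups).
#' @export
presence_and_specific <- function(cnvrs, group_map) {
  check_group_map(group_map)
  groups <- unique(group_map$group)
  presence <- vapply(groups, function(g) {
    members <- group_map$sample_id[group_map$group == g]
    vapply(cnvrs$samples, function(s) any(s %in% members), logical(1))
  }, logical(nrow(cnvrs)))
  presence <- matrix(as.integer(presence), nrow = nrow(cnvrs),
                     dimnames = list(cnvrs$cnvr_id, groups))
  n_present <- rowSums(presence)
  specific <- vapply(groups, function(g) {
    sum(presence[, g] == 1L & n_present == 1L)
  }, integer(1))
  list(presence = presence,
       specific = stats::setNames(specific, groups),
       shared = sum(n_present == length(groups)))
}

#' Write CNVRs as a BED file (0-based half-open)
#'
#' Name column carries the CNVR id, score column 0, and an extra column the
#' CNVR type.
#'
#' @param cnvrs CNVR data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cnvr_bed <- function(cnvrs, path) {
  bed <- data.frame(chrom = cnvrs$chrom, start = cnvrs$start - 1,
                    end = cnvrs$end, name = cnvrs$cnvr_id, score = 0,
                    type = cnvrs$cnvr_type)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# BED: 0-based half-open; col5 unused; col6 CNVR type", con)
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
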