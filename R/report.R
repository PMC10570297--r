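# Report-table layer: the two summary tables a cohort CNV study prints,
# reproduced from pipeline objects (counts in, percentages out).

#' Percentages of a count vector, table-style
#'
#' Each count as a percentage of the vector's total, rounded half-up to
#' two decimals — the convention of published CNVR summary tables.
#'
#' @param counts non-negative numeric vector.
#' @return numeric vector of percentages (NA if the total is 0).
#' @export
percent_of_total <- function(counts) {
  total <- sum(counts)
  if (total == 0) return(rep(NA_real_, length(counts)))
  round_half_up(100 * counts / total, 2)
}

#' CNVR summary table by type and size (Table-2 layout)
#'
#' Type counts (total / duplication / deletion / both) with percentages,
#' total and mean lengths, and size-bin counts split by type.
#'
#' @param cnvrs CNVR data.frame from [merge_cnv_calls()].
#' @return data.frame with a `statistic` column and one column per type.
#' @export
table2_report <- function(cnvrs) {
  types <- c("duplication", "deletion", "both")
  by_type <- lapply(types, function(t) {
    cnvrs[cnvrs$cnvr_type == t, , drop = FALSE]
  })
  names(by_type) <- types
  counts <- vapply(by_type, nrow, integer(1))
  pct <- percent_of_total(counts)
  fmt_cp <- function(count, p) {
    if (is.na(p)) as.character(count) else sprintf("%d (%.2f%%)", count, p)
  }
  all_sd <- size_distribution(cnvrs)
  row <- function(stat, total, dup, del, both) {
    data.frame(statistic = stat, total = total, duplication = dup,
               deletion = del, both = both, stringsAsFactors = FALSE)
  }
  rows <- list(
    row("Number of CNVRs",
        fmt_cp(nrow(cnvrs), if (nrow(cnvrs) > 0) 100 else NA_real_),
        fmt_cp(counts[["duplication"]], pct[1L]),
        fmt_cp(counts[["deletion"]], pct[2L]),
        fmt_cp(counts[["both"]], pct[3L])),
    row("Total length (Mb)",
        sprintf("%.2f", all_sd$total_length_mb),
        sprintf("%.2f", size_distribution(by_type$duplication)$total_length_mb),
        sprintf("%.2f", size_distribution(by_type$deletion)$total_length_mb),
        sprintf("%.2f", size_distribution(by_type$both)$total_length_mb)),
    row("Average length per CNVR (Kb)",
        sprintf("%.2f", all_sd$mean_length_kb),
        sprintf("%.2f", size_distribution(by_type$duplication)$mean_length_kb),
        sprintf("%.2f", size_distribution(by_type$deletion)$mean_length_kb),
        sprintf("%.2f", size_distribution(by_type$both)$mean_length_kb))
  )
  bin_counts <- function(sub) size_distribution(sub)$bins$count
  bc_all <- all_sd$bins
  bc_type <- lapply(by_type, bin_counts)
  for (i in seq_along(cnvr_size_labels)) {
    rows[[length(rows) + 1L]] <- row(
      cnvr_size_labels[i],
      fmt_cp(bc_all$count[i],
             if (nrow(cnvrs) > 0)
               round_half_up(100 * bc_all$count[i] / nrow(cnvrs), 2)
             else NA_real_),
      as.character(bc_type$duplication[i]),
      as.character(bc_type$deletion[i]),
      as.character(bc_type$both[i]))
  }
  do.call(rbind, rows)
}

#' Per-group CNV and CNVR summary (Table-1 layout)
#'
#' The CNV block comes from [summarize_groups()]; the CNVR block re-runs
#' the merge within each group's samples (group-wise CNVR counts cannot
#' arise from a single global merge) and adds the percentage of the genome
#' covered by each group's CNVRs.
#'
#' @param calls filtered call data.frame.
#' @param group_map sample-to-group map.
#' @param chrom_lengths data.frame `chrom`, `length`.
#' @param min_overlap_frac passed to [merge_cnv_calls()].
#' @return list with data.frames `cnv` and `cnvr`.
#' @export
table1_report <- function(calls, group_map, chrom_lengths,
                          min_overlap_frac = 0) {
  cnv <- summarize_groups(calls, group_map)
  per_group <- merge_by_group(calls, group_map, min_overlap_frac)
  cnvr <- do.call(rbind, lapply(names(per_group), function(g) {
    cr <- per_group[[g]]
    data.frame(
      group = g,
      cnvr_count = nrow(cr),
      duplication = sum(cr$cnvr_type == "duplication"),
      deletion = sum(cr$cnvr_type == "deletion"),
      both = sum(cr$cnvr_type == "both"),
      total_length_mb = sum(cr$length) / 1e6,
      mean_length_kb = if (nrow(cr) > 0) mean(cr$length) / 1e3 else NA_real_,
      genome_percent = coverage_percent(cr, chrom_lengths)$genome_percent,
      stringsAsFactors = FALSE)
  }))
  list(cnv = cnv, cnvr = cnvr)
}
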