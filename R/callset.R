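#' Read a per-sample CNV call file (CNVnator-style dialect)
#'
#' Parses the tab-separated caller output with columns: CNV type
#' (`deletion`/`duplication`), coordinates as `chrom:start-end` (1-based
#' inclusive), CNV size in bp, normalized read depth (diploid = 1.0), four
#' significance columns (`e-val1`..`e-val4`), and `q0`, the fraction of
#' reads with mapping quality zero (`-1` when not computable). The first
#' significance column is taken as the filter p-value; the remaining three
#' are carried through untouched.
#'
#' Lines whose stated size disagrees with `end - start + 1` are corrected
#' to the coordinate-derived size with a warning.
#'
#' @param path path to the call file.
#' @param sample_id sample identifier attached to every record.
#' @return a data.frame with columns `sample_id`, `chrom`, `start`, `end`,
#'   `cnv_type`, `size`, `normalized_rd`, `p_value`, `eval2`, `eval3`,
#'   `eval4`, `q0`. Empty file gives a zero-row frame.
#' @export
read_cnv_calls <- function(path, sample_id) {
  if (!file.exists(path)) stop("call file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_calls())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    stop("line ", which(nf != 9L)[1L], ": expected 9 tab-separated columns, got ",
         nf[which(nf != 9L)[1L]])
  }
  m <- do.call(rbind, fields)
  cnv_type <- m[, 1L]
  bad_type <- !cnv_type %in% c("deletion", "duplication")
  if (any(bad_type)) {
    stop("line ", which(bad_type)[1L], ": unknown CNV type '",
         cnv_type[which(bad_type)[1L]], "'")
  }
  coord <- regmatches(m[, 2L], regexec("^([^:]+):([0-9]+)-([0-9]+)$", m[, 2L]))
  bad_coord <- lengths(coord) != 4L
  if (any(bad_coord)) {
    stop("line ", which(bad_coord)[1L], ": malformed coordinate string '",
         m[which(bad_coord)[1L], 2L], "'")
  }
  coord <- do.call(rbind, coord)
  num <- suppressWarnings(apply(m[, 3:9, drop = FALSE], 2L, as.numeric))
  num <- matrix(num, ncol = 7L)
  if (anyNA(num)) {
    stop("line ", which(rowSums(is.na(num)) > 0)[1L], ": non-numeric field")
  }
  calls <- data.frame(
    sample_id = sample_id,
    chrom = coord[, 2L],
    start = as.numeric(coord[, 3L]),
    end = as.numeric(coord[, 4L]),
    cnv_type = cnv_type,
    size = num[, 1L],
    normalized_rd = num[, 2L],
    p_value = num[, 3L],
    eval2 = num[, 4L],
    eval3 = num[, 5L],
    eval4 = num[, 6L],
    q0 = num[, 7L],
    stringsAsFactors = FALSE
  )
  if (any(calls$start > calls$end)) {
    stop("line ", which(calls$start > calls$end)[1L], ": start > end")
  }
  derived <- calls$end - calls$start + 1
  off <- calls$size != derived
  if (any(off)) {
    warning(sum(off), " record(s) with size != end - start + 1; ",
            "corrected to the coordinate-derived size")
    calls$size[off] <- derived[off]
  }
  calls
}

empty_calls <- function() {
  data.frame(sample_id = character(), chrom = character(), start = numeric(),
             end = numeric(), cnv_type = character(), size = numeric(),
             normalized_rd = numeric(), p_value = numeric(), eval2 = numeric(),
             eval3 = numeric(), eval4 = numeric(), q0 = numeric(),
             stringsAsFactors = FALSE)
}

#' Read all per-sample call files listed in a group map
#'
#' @param dir directory holding `<sample_id>.calls.tsv` files.
#' @param group_map data.frame with columns `sample_id`, `group`.
#' @return row-bound call data.frame across all samples.
#' @export
read_cohort_calls <- function(dir, group_map) {
  check_group_map(group_map)
  parts <- lapply(group_map$sample_id, function(s) {
    read_cnv_calls(file.path(dir, paste0(s, ".calls.tsv")), s)
  })
  do.call(rbind, parts)
}

#' Quality-filter specification for CNV calls
#'
#' Defaults follow the standard read-depth call filter: p-value below 0.01,
#' size above 1 kb, and fraction of zero-mapping-quality reads (q0) below
#' 0.5 — all strict inequalities.
#'
#' @param max_p exclusive upper bound on the p-value.
#' @param min_size exclusive lower bound on call size in bp.
#' @param max_q0 exclusive upper bound on q0.
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(max_p = 0.01, min_size = 1000, max_q0 = 0.5) {
  stopifnot(max_p > 0, min_size > 0, max_q0 > 0)
  structure(list(max_p = max_p, min_size = min_size, max_q0 = max_q0),
            class = "filter_spec")
}

#' Filter CNV calls on significance, size and mapping quality
#'
#' Retains exactly the calls with `p_value < max_p`, `size > min_size` and
#' `q0 < max_q0`. A `q0` of `-1` is the caller's sentinel for "not
#' computable" and is treated as missing, i.e. retained. Input order is
#' preserved; the operation is idempotent.
#'
#' @param calls call data.frame from [read_cnv_calls()].
#' @param spec a [filter_spec()].
#' @return the retained subset of `calls`.
#' @export
filter_calls <- function(calls, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  if (nrow(calls) == 0L) return(calls)
  q0_ok <- calls$q0 == -1 | calls$q0 < spec$max_q0
  keep <- calls$p_value < spec$max_p & calls$size > spec$min_size & q0_ok
  calls[keep, , drop = FALSE]
}

#' Per-group CNV summary (cohort Table-1 style)
#'
#' For each group and for the whole cohort: call count, duplication and
#' deletion counts, total call length in Mb, mean call length in kb, and
#' mean calls per sample. Samples with zero calls still count in the
#' per-sample denominator, which is the group's sample count in the map.
#'
#' @param calls call data.frame.
#' @param group_map data.frame with columns `sample_id`, `group`.
#' @return data.frame with one row per group plus a `Total` row.
#' @export
summarize_groups <- function(calls, group_map) {
  check_group_map(group_map)
  missing <- setdiff(unique(calls$sample_id), group_map$sample_id)
  if (length(missing) > 0L) {
    stop("samples missing from group map: ", paste(missing, collapse = ", "))
  }
  calls$group <- group_map$group[match(calls$sample_id, group_map$sample_id)]
  groups <- unique(group_map$group)
  one <- function(g, sub, n_samples) {
    data.frame(
      group = g,
      n_samples = n_samples,
      cnv_count = nrow(sub),
      duplication = sum(sub$cnv_type == "duplication"),
      deletion = sum(sub$cnv_type == "deletion"),
      total_length_mb = sum(sub$size) / 1e6,
      mean_length_kb = if (nrow(sub) > 0L) mean(sub$size) / 1e3 else NA_real_,
      mean_per_sample = nrow(sub) / n_samples,
      stringsAsFactors = FALSE
    )
  }
  rows <- lapply(groups, function(g) {
    one(g, calls[calls$group == g, , drop = FALSE],
        sum(group_map$group == g))
  })
  rows <- c(rows, list(one("Total", calls, nrow(group_map))))
  do.call(rbind, rows)
}
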