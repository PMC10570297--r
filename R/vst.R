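#' Vst differentiation statistic for copy number
#'
#' `Vst = (V_T - V_S) / V_T`, where `V_T` is the variance of copy number
#' across all individuals and `V_S = sum(n_i * Var_i) / sum(n_i)` is the
#' size-weighted mean within-group variance. By default both variances use
#' the population convention (denominator n), the standard construction
#' for this statistic; set `var_type = "sample"` for n - 1 denominators.
#' When `V_T = 0` (all values equal) Vst is defined as 0. Negative values
#' can occur and are reported as computed, not clamped.
#'
#' @param values numeric vector of per-sample copy numbers.
#' @param labels group label per sample; at least two groups, each with at
#'   least one sample.
#' @param var_type "population" (default) or "sample".
#' @return list with `vst`, `v_total`, `v_within`, and `n_i` (named group
#'   sizes).
#' @export
compute_vst <- function(values, labels, var_type = "population") {
  stopifnot(length(values) == length(labels), all(is.finite(values)))
  labels <- as.character(labels)
  n_i <- table(labels)
  if (length(n_i) < 2L) stop("Vst needs at least two groups")
  if (any(n_i == 0L)) stop("empty group")
  v_total <- variance_of(values, var_type)
  by_group <- split(values, labels)
  var_i <- vapply(by_group, variance_of, numeric(1), var_type = var_type)
  n_vec <- as.numeric(n_i[names(by_group)])
  v_within <- sum(n_vec * var_i) / sum(n_vec)
  vst <- if (v_total == 0) 0 else (v_total - v_within) / v_total
  list(vst = vst, v_total = v_total, v_within = v_within,
       n_i = stats::setNames(as.integer(n_i), names(n_i)))
}

#' Vst scan across a copy-number matrix
#'
#' Applies [compute_vst()] to every CNVR (row) of a copy-number matrix.
#' An optional contrast restricts the scan to two user-defined sides, e.g.
#' high- versus low-altitude groups: samples of groups on neither side are
#' dropped and each side is treated as one population.
#'
#' @param cn_matrix matrix from [genotype_calls()] (rows CNVRs, columns
#'   samples).
#' @param group_map sample-to-group map covering all columns.
#' @param contrast NULL for an all-groups scan, or a list of two character
#'   vectors of group names (`list(A = ..., B = ...)`).
#' @param var_type passed to [compute_vst()].
#' @return data.frame with `cnvr_id`, `contrast`, `v_total`, `v_within`,
#'   `vst`.
#' @export
vst_scan <- function(cn_matrix, group_map, contrast = NULL,
                     var_type = "population") {
  check_group_map(group_map)
  labels <- group_map$group[match(colnames(cn_matrix), group_map$sample_id)]
  if (anyNA(labels)) stop("samples missing from group map")
  contrast_name <- "all-groups"
  if (!is.null(contrast)) {
    stopifnot(is.list(contrast), length(contrast) == 2L)
    side <- ifelse(labels %in% contrast[[1L]], "A",
                   ifelse(labels %in% contrast[[2L]], "B", NA))
    keep <- !is.na(side)
    cn_matrix <- cn_matrix[, keep, drop = FALSE]
    labels <- side[keep]
    contrast_name <- paste(paste(contrast[[1L]], collapse = "+"),
                           paste(contrast[[2L]], collapse = "+"), sep = " vs ")
  }
  recs <- apply(cn_matrix, 1L, compute_vst, labels = labels,
                var_type = var_type)
  data.frame(
    cnvr_id = rownames(cn_matrix),
    contrast = contrast_name,
    v_total = vapply(recs, `[[`, numeric(1), "v_total"),
    v_within = vapply(recs, `[[`, numeric(1), "v_within"),
    vst = vapply(recs, `[[`, numeric(1), "vst"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Select top-quantile Vst candidates
#'
#' Declares as candidates the records whose Vst falls in the top `fraction`
#' of the empirical distribution. The threshold is the nearest-rank upper
#' quantile: with n records, the k-th largest value where
#' `k = max(1, floor(fraction * n))`; all records with `vst >= threshold`
#' are candidates, so ties at the threshold are included.
#'
#' @param vst_records data.frame from [vst_scan()] (needs columns
#'   `cnvr_id`, `vst`).
#' @param fraction top fraction to select, in (0, 1); default 0.01.
#' @return list with `candidates` (rows of `vst_records` sorted by vst
#'   descending) and `threshold`.
#' @export
select_top <- function(vst_records, fraction = 0.01) {
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  n <- nrow(vst_records)
  if (n < 1L) stop("no Vst records")
  k <- max(1L, as.integer(floor(fraction * n)))
  sorted <- sort(vst_records$vst, decreasing = TRUE)
  threshold <- sorted[k]
  cand <- vst_records[vst_records$vst >= threshold, , drop = FALSE]
  cand <- cand[order(cand$vst, decreasing = TRUE), , drop = FALSE]
  rownames(cand) <- NULL
  list(candidates = cand, threshold = threshold)
}

#' Analytic Vst expected under specified per-group state distributions
#'
#' Given a locus's categorical copy-number distribution per group and the
#' group sizes, returns the population-level Vst: `V_T` is the variance of
#' the size-weighted pooled mixture, `V_S` the size-weighted mean of the
#' within-group variances, and `Vst = (V_T - V_S)/V_T` (0 when `V_T = 0`).
#' This is the value an empirical scan converges to as group sizes grow.
#'
#' @param locus a [locus_spec()] (its `dist` field is used).
#' @param group_sizes integer vector of per-group sample counts, aligned
#'   with `names(locus$dist)`; at least two groups.
#' @return expected Vst (scalar).
#' @export
expected_vst <- function(locus, group_sizes) {
  dist <- locus$dist
  if (length(dist) < 2L || length(group_sizes) < 2L) {
    stop("expected_vst needs at least two groups")
  }
  stopifnot(length(group_sizes) == length(dist), all(group_sizes >= 1))
  w <- group_sizes / sum(group_sizes)
  mu <- vapply(dist, function(d) sum(as.numeric(names(d)) * d), numeric(1))
  m2 <- vapply(dist, function(d) sum(as.numeric(names(d))^2 * d), numeric(1))
  var_i <- m2 - mu^2
  v_total <- sum(w * m2) - sum(w * mu)^2
  v_within <- sum(w * var_i)
  if (v_total == 0) 0 else (v_total - v_within) / v_total
}
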