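#' Genotype normalized copy number per CNVR per sample from filtered calls
#'
#' For each CNVR and sample, the copy number is the overlap-length-weighted
#' mean of `normalized_rd` over the sample's calls intersecting the CNVR,
#' with bases not covered by any call contributing the diploid baseline
#' 1.0. A sample with no call touching a CNVR gets exactly 1.0.
#'
#' @param cnvrs CNVR data.frame from [merge_cnv_calls()].
#' @param calls filtered call data.frame.
#' @param samples character vector of sample ids defining the columns
#'   (defaults to the samples present in `calls`).
#' @return numeric matrix, rows = `cnvr_id`, columns = samples,
#'   values >= 0 with diploid = 1.0.
#' @export
genotype_calls <- function(cnvrs, calls, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(calls$sample_id))
  cn <- matrix(1, nrow = nrow(cnvrs), ncol = length(samples),
               dimnames = list(cnvrs$cnvr_id, samples))
  if (nrow(cnvrs) == 0L || nrow(calls) == 0L) return(cn)
  gr_cnvr <- df_to_gr(cnvrs)
  gr_call <- df_to_gr(calls)
  hits <- GenomicRanges::findOverlaps(gr_cnvr, gr_call)
  if (length(hits) == 0L) return(cn)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov_w <- IRanges::width(GenomicRanges::pintersect(gr_cnvr[qi], gr_call[si]))
  samp <- calls$sample_id[si]
  key <- paste(qi, samp, sep = "\r")
  w_rd <- tapply(ov_w * calls$normalized_rd[si], key, sum)
  w <- tapply(ov_w, key, sum)
  parts <- strsplit(names(w), "\r", fixed = TRUE)
  row_i <- as.integer(vapply(parts, `[`, "", 1L))
  col_s <- vapply(parts, `[`, "", 2L)
  keep <- col_s %in% samples
  len <- cnvrs$length[row_i]
  val <- (as.numeric(w_rd) + pmax(len - as.numeric(w), 0)) / len
  cn[cbind(row_i[keep], match(col_s[keep], samples))] <- val[keep]
  cn
}

#' Genotype copy number from a binned read-depth track
#'
#' Copy number for a CNVR is the mean depth over bins overlapping it,
#' divided by the sample's genome-wide mean bin depth, so that a diploid
#' region scores about 1.0.
#'
#' @param cnvrs CNVR data.frame.
#' @param depth data.frame with columns `chrom`, `bin_start` (0-based) and
#'   `depth` for one sample, covering whole chromosomes.
#' @param bin_size bin width in bp.
#' @return numeric vector of copy numbers, one per CNVR row.
#' @export
genotype_depth <- function(cnvrs, depth, bin_size = 100) {
  stopifnot(all(c("chrom", "bin_start", "depth") %in% names(depth)))
  genome_mean <- mean(depth$depth)
  if (genome_mean == 0) stop("depth track has zero genome-wide mean")
  gr_bins <- GenomicRanges::GRanges(
    depth$chrom,
    IRanges::IRanges(start = depth$bin_start + 1, width = bin_size))
  gr_cnvr <- df_to_gr(cnvrs)
  # suppress the seqlevel-mismatch chatter; disjoint chromosomes surface
  # below as an explicit extent error
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_cnvr, gr_bins))
  n_bins <- tabulate(S4Vectors::queryHits(hits), nbins = nrow(cnvrs))
  if (any(n_bins == 0L)) {
    stop("CNVR(s) outside the depth track extent: ",
         paste(cnvrs$cnvr_id[n_bins == 0L], collapse = ", "))
  }
  sums <- tapply(depth$depth[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits), sum)
  means <- rep(NA_real_, nrow(cnvrs))
  means[as.integer(names(sums))] <- as.numeric(sums)
  (means / n_bins) / genome_mean
}

#' Classify a copy number on the Redon scale
#'
#' `deleted` below 0.4, `conserved` in `[0.4, 1.6]`, `duplicated` above
#' 1.6 — an exhaustive, mutually exclusive partition of the non-negative
#' copy-number axis (diploid = 1.0).
#'
#' @param cn numeric vector of normalized copy numbers, all >= 0.
#' @return character vector of classes.
#' @export
classify_cn <- function(cn) {
  if (any(cn < 0)) stop("copy number must be non-negative")
  ifelse(cn < 0.4, "deleted", ifelse(cn <= 1.6, "conserved", "duplicated"))
}

#' Relative quantification by the 2^-ddCt method
#'
#' `ddCt = (Ct_target,test - Ct_ref,test) - (Ct_target,cal - Ct_ref,cal)`;
#' the relative quantity is `2^-ddCt`. Used to express qPCR copy number of
#' a target gene against a reference gene and a calibrator sample.
#'
#' @param ct_target_test,ct_ref_test Ct of target and reference gene in the
#'   test sample.
#' @param ct_target_calibrator,ct_ref_calibrator Ct of target and reference
#'   gene in the calibrator sample.
#' @return relative quantity (1.0 means no change).
#' @export
ddct_quantity <- function(ct_target_test, ct_ref_test,
                          ct_target_calibrator, ct_ref_calibrator) {
  stopifnot(is.finite(ct_target_test), is.finite(ct_ref_test),
            is.finite(ct_target_calibrator), is.finite(ct_ref_calibrator))
  ddct <- (ct_target_test - ct_ref_test) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}
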