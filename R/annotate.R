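#' Read gene models from GFF3
#'
#' Parses `gene` and `exon` features, resolving exon `Parent` chains to
#' their gene (directly or through an intermediate mRNA/transcript
#' feature). Exons of each gene are normalized: sorted and merged when
#' overlapping. A gene without exon children is treated as a single exon
#' spanning the gene body, so any overlap with it is exonic.
#'
#' @param path GFF3 file.
#' @return a `gene_models` list with data.frames `genes` (`gene_id`,
#'   `chrom`, `start`, `end`, `strand`) and `exons` (`gene_id`, `chrom`,
#'   `start`, `end`); 1-based inclusive coordinates.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- gr$Parent  # CharacterList
  is_gene <- type == "gene"
  genes <- data.frame(
    gene_id = ids[is_gene],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
    start = GenomicRanges::start(gr)[is_gene],
    end = GenomicRanges::end(gr)[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene],
    stringsAsFactors = FALSE)
  if (any(!genes$strand %in% c("+", "-"))) {
    bad <- genes$gene_id[!genes$strand %in% c("+", "-")][1L]
    stop("gene without a defined strand: ", bad)
  }
  # map any feature id to its owning gene id (follow one Parent level up)
  parent1 <- vapply(as.list(parents), function(p) {
    if (length(p) == 0L) NA_character_ else p[[1L]]
  }, character(1))
  owner <- function(i) {
    p <- parent1[i]
    if (is.na(p)) return(NA_character_)
    if (p %in% genes$gene_id) return(p)
    j <- match(p, ids)
    if (is.na(j)) return(NA_character_)
    owner(j)
  }
  is_exon <- type == "exon"
  exon_gene <- vapply(which(is_exon), owner, character(1))
  if (anyNA(exon_gene)) {
    bad <- ids[which(is_exon)[is.na(exon_gene)][1L]]
    stop("orphan exon (no gene ancestor): ", bad)
  }
  exons <- data.frame(
    gene_id = exon_gene,
    chrom = as.character(GenomicRanges::seqnames(gr))[is_exon],
    start = GenomicRanges::start(gr)[is_exon],
    end = GenomicRanges::end(gr)[is_exon],
    stringsAsFactors = FALSE)
  # genes without exon children contribute their full span as one exon
  bare <- setdiff(genes$gene_id, exons$gene_id)
  if (length(bare) > 0L) {
    gi <- match(bare, genes$gene_id)
    exons <- rbind(exons, data.frame(
      gene_id = bare, chrom = genes$chrom[gi], start = genes$start[gi],
      end = genes$end[gi], stringsAsFactors = FALSE))
  }
  # normalize: per gene, sort and merge overlapping exons
  parts <- split(exons, exons$gene_id)
  exons <- do.call(rbind, lapply(parts, function(sub) {
    red <- IRanges::reduce(IRanges::IRanges(sub$start, sub$end))
    data.frame(gene_id = sub$gene_id[1L], chrom = sub$chrom[1L],
               start = IRanges::start(red), end = IRanges::end(red),
               stringsAsFactors = FALSE)
  }))
  rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

# Strand-aware upstream/downstream flank intervals of width flank_bp,
# clipped at coordinate 1. Returns GRanges aligned with models$genes.
gene_flanks <- function(models, flank_bp, side = c("upstream", "downstream")) {
  side <- match.arg(side)
  g <- models$genes
  before <- (g$strand == "+") == (side == "upstream")
  start <- ifelse(before, pmax(1, g$start - flank_bp), g$end + 1)
  end <- ifelse(before, g$start - 1, g$end + flank_bp)
  keep <- start <= end
  GenomicRanges::GRanges(g$chrom[keep],
                         IRanges::IRanges(start[keep], end[keep]))
}

#' Classify CNVRs by genomic context against gene models
#'
#' Each CNVR receives exactly one class with precedence
#' exonic > intronic > upstream > downstream > intergenic:
#' exonic when it shares at least one base with an exon; intronic when it
#' overlaps a gene body but no exon; upstream/downstream when it lies
#' within `flank_bp` of a gene start/end on the strand-appropriate side
#' (upstream of a `+` gene is below its start, of a `-` gene above its
#' end); intergenic otherwise. A CNVR that is upstream of one gene and
#' downstream of another is called upstream (precedence).
#'
#' @param cnvrs CNVR data.frame.
#' @param models a `gene_models` object from [read_gene_models()].
#' @param flank_bp flank width in bp; default 1900 (the 1.9 kb convention
#'   of the upstream analysis this package reproduces).
#' @return character vector of classes, one per CNVR row.
#' @export
classify_regions <- function(cnvrs, models, flank_bp = 1900) {
  stopifnot(inherits(models, "gene_models"), flank_bp >= 0)
  n <- nrow(cnvrs)
  if (n == 0L) return(character(0))
  gr <- df_to_gr(cnvrs)
  gr_exon <- df_to_gr(models$exons)
  gr_gene <- df_to_gr(models$genes)
  in_exon <- IRanges::overlapsAny(gr, gr_exon)
  in_gene <- IRanges::overlapsAny(gr, gr_gene)
  in_up <- IRanges::overlapsAny(gr, gene_flanks(models, flank_bp, "upstream"))
  in_down <- IRanges::overlapsAny(gr, gene_flanks(models, flank_bp,
                                                  "downstream"))
  ifelse(in_exon, "exonic",
         ifelse(in_gene, "intronic",
                ifelse(in_up, "upstream",
                       ifelse(in_down, "downstream", "intergenic"))))
}

#' Gene ids overlapping each CNVR
#'
#' All gene ids whose gene span shares at least one base with the CNVR.
#'
#' @param cnvrs CNVR data.frame.
#' @param models a `gene_models` object.
#' @return list of character vectors (possibly empty), one per CNVR.
#' @export
overlap_genes <- function(cnvrs, models) {
  stopifnot(inherits(models, "gene_models"))
  gr <- df_to_gr(cnvrs)
  gr_gene <- df_to_gr(models$genes)
  hits <- GenomicRanges::findOverlaps(gr, gr_gene)
  out <- rep(list(character(0)), nrow(cnvrs))
  by_q <- split(models$genes$gene_id[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
  for (q in names(by_q)) out[[as.integer(q)]] <- sort(unique(by_q[[q]]))
  out
}

#' Fraction of CNVRs per genomic-context class
#'
#' @param cnvrs non-empty CNVR data.frame.
#' @param models a `gene_models` object.
#' @param flank_bp flank width passed to [classify_regions()].
#' @return named numeric vector over the five classes, summing to 1.
#' @export
region_distribution <- function(cnvrs, models, flank_bp = 1900) {
  if (nrow(cnvrs) == 0L) stop("region distribution of an empty CNVR set")
  cls <- classify_regions(cnvrs, models, flank_bp)
  counts <- table(factor(cls, levels = region_classes))
  stats::setNames(as.numeric(counts) / nrow(cnvrs), region_classes)
}
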