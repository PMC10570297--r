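#' Locus specification for the cohort simulator
#'
#' A locus is a genomic interval with, for every group, a categorical
#' distribution over normalized copy-number states (diploid = 1.0; typical
#' states 0.0, 0.5, 1.0, 1.5, 2.0). Group distributions are what the Vst
#' scan is sensitive to: identical distributions give expected Vst 0,
#' disjoint fixed states give 1.
#'
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param dist named list: group name -> named numeric vector of
#'   probabilities whose names are the copy-number states. Probabilities
#'   must sum to 1 (tolerance 1e-9); states must be >= 0.
#' @return a `locus_spec` list with a `locus_id` of the form
#'   `chrom:start-end`.
#' @export
locus_spec <- function(chrom, start, end, dist) {
  stopifnot(start <= end, start >= 1)
  for (g in names(dist)) {
    d <- dist[[g]]
    states <- suppressWarnings(as.numeric(names(d)))
    if (anyNA(states) || any(states < 0)) {
      stop("locus ", chrom, ":", start, "-", end,
           ": states must be non-negative numbers (group ", g, ")")
    }
    if (abs(sum(d) - 1) > 1e-9) {
      stop("locus ", chrom, ":", start, "-", end,
           ": probabilities for group ", g, " sum to ", sum(d), ", not 1")
    }
  }
  structure(list(locus_id = paste0(chrom, ":", start, "-", end),
                 chrom = chrom, start = start, end = end, dist = dist),
            class = "locus_spec")
}

#' Simulation configuration for a multi-group CNV cohort
#'
#' @param chromosomes data.frame with columns `chrom`, `length` (bp).
#' @param groups data.frame with columns `group`, `n_samples` (all >= 1).
#' @param loci list of [locus_spec()]; every locus must lie within its
#'   chromosome and carry a distribution for every group.
#' @param mean_coverage expected reads per bin at the diploid state.
#' @param bin_size bin width in bp (caller-style default 100).
#' @param rd_noise_sd standard deviation of the Gaussian jitter added to
#'   the normalized read depth of emitted calls (truncated at 0).
#' @param junk_call_rate fraction of extra calls, relative to the real
#'   ones, engineered to fail exactly one filter criterion each.
#' @param seed integer seed governing all randomness; per-sample
#'   sub-streams are derived from it deterministically.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(chromosomes, groups, loci,
                              mean_coverage = 20, bin_size = 100,
                              rd_noise_sd = 0.05, junk_call_rate = 0.05,
                              seed = 1) {
  stopifnot(is.data.frame(chromosomes),
            all(c("chrom", "length") %in% names(chromosomes)),
            is.data.frame(groups),
            all(c("group", "n_samples") %in% names(groups)),
            all(groups$n_samples >= 1), bin_size > 0,
            mean_coverage > 0, rd_noise_sd >= 0,
            junk_call_rate >= 0, junk_call_rate < 1)
  for (loc in loci) {
    stopifnot(inherits(loc, "locus_spec"))
    len <- chromosomes$length[match(loc$chrom, chromosomes$chrom)]
    if (is.na(len)) stop("locus on unknown chromosome: ", loc$chrom)
    if (loc$end > len) stop("locus ", loc$locus_id, " exceeds chromosome")
    missing_g <- setdiff(groups$group, names(loc$dist))
    if (length(missing_g) > 0L) {
      stop("locus ", loc$locus_id, " lacks distributions for group(s): ",
           paste(missing_g, collapse = ", "))
    }
  }
  structure(list(chromosomes = chromosomes, groups = groups, loci = loci,
                 mean_coverage = mean_coverage, bin_size = bin_size,
                 rd_noise_sd = rd_noise_sd, junk_call_rate = junk_call_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Sample sheet of a simulation configuration
#'
#' @param config a [simulation_config()].
#' @return data.frame with columns `sample_id`, `group`; sample ids are
#'   `<group>_<i>`.
#' @export
sim_samples <- function(config) {
  rows <- lapply(seq_len(nrow(config$groups)), function(i) {
    g <- config$groups$group[i]
    n <- config$groups$n_samples[i]
    data.frame(sample_id = sprintf("%s_%d", g, seq_len(n)), group = g,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Draw the true copy-number table of a simulated cohort
#'
#' Each (sample, locus) copy number is drawn independently from the
#' sample's group distribution at that locus. The draw for each sample
#' uses its own RNG sub-stream derived from the global seed, so the table
#' is reproducible and insensitive to sample order.
#'
#' @param config a [simulation_config()].
#' @return data.frame with one row per sample x locus: `sample_id`,
#'   `group`, `locus_id`, `chrom`, `start`, `end`, `cn`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  samples <- sim_samples(config)
  loci <- config$loci
  rows <- lapply(seq_len(nrow(samples)), function(j) {
    set.seed(derive_seed(config$seed, j))
    cn <- vapply(loci, function(loc) {
      d <- loc$dist[[samples$group[j]]]
      as.numeric(names(d))[sample.int(length(d), 1L, prob = d)]
    }, numeric(1))
    data.frame(
      sample_id = samples$sample_id[j], group = samples$group[j],
      locus_id = vapply(loci, `[[`, "", "locus_id"),
      chrom = vapply(loci, `[[`, "", "chrom"),
      start = vapply(loci, `[[`, numeric(1), "start"),
      end = vapply(loci, `[[`, numeric(1), "end"),
      cn = cn, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Emit caller-style call files for a simulated cohort
#'
#' For every (sample, locus) with true copy number different from 1.0, one
#' record is written in the caller dialect read by [read_cnv_calls()]:
#' type `deletion` below 1.0 and `duplication` above, normalized read
#' depth equal to the true copy number plus Gaussian jitter (sd
#' `rd_noise_sd`, truncated at 0), and p-value / q0 drawn to pass the
#' default filter. On top, `junk_call_rate` times the number of real calls
#' are emitted as junk records, each engineered to fail exactly one filter
#' criterion (p-value >= 0.01, size <= 1 kb, or q0 >= 0.5), placed at
#' random positions away from no particular care — they never survive the
#' filter. A truth sidecar (`truth_calls.tsv`) flags every record.
#'
#' @param truth table from [generate_truth()].
#' @param config the same [simulation_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the sidecar data.frame (columns `sample_id`,
#'   `chrom`, `start`, `end`, `cnv_type`, `true_cn`, `status`,
#'   `junk_reason`).
#' @export
emit_callset <- function(truth, config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- sim_samples(config)
  junk_reasons <- c("p_value", "size", "q0")
  sidecar <- list()
  for (j in seq_len(nrow(samples))) {
    sid <- samples$sample_id[j]
    set.seed(derive_seed(config$seed, 100000L + j))
    sub <- truth[truth$sample_id == sid & truth$cn != 1.0, , drop = FALSE]
    lines <- character(0)
    side <- list()
    if (nrow(sub) > 0L) {
      rd <- pmax(0, sub$cn + stats::rnorm(nrow(sub), 0, config$rd_noise_sd))
      p <- stats::runif(nrow(sub), 1e-6, 0.009)
      q0 <- stats::runif(nrow(sub), 0, 0.45)
      type <- ifelse(sub$cn < 1.0, "deletion", "duplication")
      lines <- sprintf("%s\t%s:%d-%d\t%d\t%s\t%s\t%s\t%s\t%s\t%s",
                       type, sub$chrom, as.integer(sub$start),
                       as.integer(sub$end),
                       as.integer(sub$end - sub$start + 1),
                       format(rd, digits = 6, trim = TRUE),
                       format(p, digits = 6, trim = TRUE),
                       format(p, digits = 6, trim = TRUE),
                       format(p, digits = 6, trim = TRUE),
                       format(p, digits = 6, trim = TRUE),
                       format(q0, digits = 6, trim = TRUE))
      side[[1L]] <- data.frame(
        sample_id = sid, chrom = sub$chrom, start = sub$start, end = sub$end,
        cnv_type = type, true_cn = sub$cn, status = "real", junk_reason = "",
        stringsAsFactors = FALSE)
    }
    n_junk <- round(config$junk_call_rate * nrow(sub))
    if (n_junk > 0L) {
      ci <- sample.int(nrow(config$chromosomes), n_junk, replace = TRUE)
      reason <- junk_reasons[(seq_len(n_junk) - 1L) %% 3L + 1L]
      size <- ifelse(reason == "size",
                     as.integer(stats::runif(n_junk, 300, 1000)),
                     as.integer(stats::runif(n_junk, 2000, 5000)))
      start <- vapply(seq_len(n_junk), function(k) {
        max_start <- config$chromosomes$length[ci[k]] - size[k]
        as.integer(stats::runif(1, 1, max_start))
      }, numeric(1))
      p <- ifelse(reason == "p_value", stats::runif(n_junk, 0.01, 1),
                  stats::runif(n_junk, 1e-6, 0.009))
      q0 <- ifelse(reason == "q0", stats::runif(n_junk, 0.5, 0.95),
                   stats::runif(n_junk, 0, 0.45))
      rd <- stats::runif(n_junk, 0.2, 2.5)
      type <- ifelse(rd < 1, "deletion", "duplication")
      lines <- c(lines, sprintf(
        "%s\t%s:%d-%d\t%d\t%s\t%s\t%s\t%s\t%s\t%s",
        type, config$chromosomes$chrom[ci], as.integer(start),
        as.integer(start + size - 1), size,
        format(rd, digits = 6, trim = TRUE),
        format(p, digits = 6, trim = TRUE),
        format(p, digits = 6, trim = TRUE),
        format(p, digits = 6, trim = TRUE),
        format(p, digits = 6, trim = TRUE),
        format(q0, digits = 6, trim = TRUE)))
      side[[length(side) + 1L]] <- data.frame(
        sample_id = sid, chrom = config$chromosomes$chrom[ci],
        start = start, end = start + size - 1, cnv_type = type,
        true_cn = NA_real_, status = "junk", junk_reason = reason,
        stringsAsFactors = FALSE)
    }
    writeLines(lines, file.path(dir, paste0(sid, ".calls.tsv")))
    if (length(side) > 0L) sidecar[[sid]] <- do.call(rbind, side)
  }
  sidecar <- if (length(sidecar) > 0L) do.call(rbind, sidecar) else
    data.frame(sample_id = character(), chrom = character(),
               start = numeric(), end = numeric(), cnv_type = character(),
               true_cn = numeric(), status = character(),
               junk_reason = character(), stringsAsFactors = FALSE)
  rownames(sidecar) <- NULL
  write_tsv_commented(
    sidecar, file.path(dir, "truth_calls.tsv"),
    "truth sidecar; coordinates 1-based inclusive; status junk = fails one filter criterion (junk_reason)")
  invisible(sidecar)
}

#' Emit per-sample binned read-depth tracks
#'
#' Depth in each bin is Poisson with mean `mean_coverage * CN`, where CN
#' is the sample's true copy number for bins whose midpoint falls inside a
#' simulated locus and 1.0 elsewhere. One TSV per sample with columns
#' `chrom`, `bin_start` (0-based) and `depth`.
#'
#' @param truth table from [generate_truth()].
#' @param config the same [simulation_config()].
#' @param dir output directory.
#' @return invisibly, the vector of written paths.
#' @export
emit_depth <- function(truth, config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- sim_samples(config)
  bins <- do.call(rbind, lapply(seq_len(nrow(config$chromosomes)), function(i) {
    starts <- seq(0, config$chromosomes$length[i] - config$bin_size,
                  by = config$bin_size)
    data.frame(chrom = config$chromosomes$chrom[i], bin_start = starts,
               stringsAsFactors = FALSE)
  }))
  mid <- bins$bin_start + config$bin_size / 2
  paths <- vapply(seq_len(nrow(samples)), function(j) {
    sid <- samples$sample_id[j]
    set.seed(derive_seed(config$seed, 200000L + j))
    cn <- rep(1.0, nrow(bins))
    sub <- truth[truth$sample_id == sid, , drop = FALSE]
    for (k in seq_len(nrow(sub))) {
      hit <- bins$chrom == sub$chrom[k] & mid >= sub$start[k] &
        mid <= sub$end[k]
      cn[hit] <- sub$cn[k]
    }
    depth <- stats::rpois(nrow(bins), config$mean_coverage * cn)
    path <- file.path(dir, paste0(sid, ".depth.tsv"))
    write_tsv_commented(
      data.frame(chrom = bins$chrom, bin_start = bins$bin_start,
                 depth = depth),
      path, "binned read depth; bin_start 0-based")
    path
  }, character(1))
  invisible(paths)
}

# Planted genomic-context classes cycled over loci by emit_genes().
region_classes <- c("exonic", "intronic", "upstream", "downstream",
                    "intergenic")

#' Emit toy gene models implementing a planted region-class design
#'
#' Cycles the five genomic-context classes (exonic, intronic, upstream,
#' downstream, intergenic) over the configured loci in (chrom, start)
#' order and writes a gene/exon GFF3 realizing each class: an exon across
#' the locus, a two-exon gene whose intron holds the locus, a gene 100 bp
#' beyond the locus so the locus sits in its upstream (resp. downstream)
#' flank, or no gene at all. Strands alternate, and every other gene
#' carries an mRNA layer between gene and exons so both Parent chains
#' occur. The planted class per locus is written to a `truth_regions.tsv`
#' sidecar.
#'
#' The design holds for flank widths between about 150 bp and the locus
#' spacing margin; with the default layout any flank in [200, 5000] bp
#' reproduces the planted classes exactly.
#'
#' @param config a [simulation_config()]; loci should be separated by
#'   at least ~12 kb for the planted classes to be unambiguous.
#' @param dir output directory; writes `genes.gff3` and
#'   `truth_regions.tsv`.
#' @return invisibly, the sidecar data.frame (`locus_id`, `chrom`,
#'   `start`, `end`, `planted_class`).
#' @export
emit_genes <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  loci <- config$loci
  ord <- order(vapply(loci, `[[`, "", "chrom"),
               vapply(loci, `[[`, numeric(1), "start"))
  loci <- loci[ord]
  classes <- region_classes[(seq_along(loci) - 1L) %% 5L + 1L]
  feats <- list()
  gid <- 0L
  add_gene <- function(chrom, gstart, gend, strand, exons, with_mrna) {
    gid <<- gid + 1L
    chr_len <- config$chromosomes$length[
      match(chrom, config$chromosomes$chrom)]
    if (gstart < 1 || gend > chr_len) {
      stop("gene for locus layout exceeds chromosome ", chrom,
           " (overflow)")
    }
    gene_id <- sprintf("gene%03d", gid)
    rows <- data.frame(chrom = chrom, type = "gene", start = gstart,
                       end = gend, strand = strand, id = gene_id,
                       parent = NA_character_, stringsAsFactors = FALSE)
    parent <- gene_id
    if (with_mrna) {
      rows <- rbind(rows, data.frame(
        chrom = chrom, type = "mRNA", start = gstart, end = gend,
        strand = strand, id = paste0(gene_id, ".t1"), parent = gene_id))
      parent <- paste0(gene_id, ".t1")
    }
    for (i in seq_len(nrow(exons))) {
      rows <- rbind(rows, data.frame(
        chrom = chrom, type = "exon", start = exons$start[i],
        end = exons$end[i], strand = strand,
        id = sprintf("%s.e%d", gene_id, i), parent = parent))
    }
    feats[[length(feats) + 1L]] <<- rows
  }
  for (i in seq_along(loci)) {
    loc <- loci[[i]]
    s <- loc$start; e <- loc$end
    strand <- if (i %% 2L == 0L) "-" else "+"
    with_mrna <- i %% 2L == 0L
    cls <- classes[i]
    if (cls == "exonic") {
      add_gene(loc$chrom, max(1, s - 200), e + 200, strand,
               data.frame(start = s, end = e), with_mrna)
    } else if (cls == "intronic") {
      add_gene(loc$chrom, max(1, s - 500), e + 500, strand,
               data.frame(start = c(max(1, s - 500), e + 1),
                          end = c(s - 1, e + 500)), with_mrna)
    } else if (cls == "upstream") {
      if (strand == "+") {
        add_gene(loc$chrom, e + 101, e + 2100, "+",
                 data.frame(start = e + 101, end = e + 2100), with_mrna)
      } else {
        add_gene(loc$chrom, s - 2100, s - 101, "-",
                 data.frame(start = s - 2100, end = s - 101), with_mrna)
      }
    } else if (cls == "downstream") {
      if (strand == "+") {
        add_gene(loc$chrom, s - 2100, s - 101, "+",
                 data.frame(start = s - 2100, end = s - 101), with_mrna)
      } else {
        add_gene(loc$chrom, e + 101, e + 2100, "-",
                 data.frame(start = e + 101, end = e + 2100), with_mrna)
      }
    } # intergenic: no gene
  }
  feat <- if (length(feats) > 0L) do.call(rbind, feats) else
    data.frame(chrom = character(), type = character(), start = numeric(),
               end = numeric(), strand = character(), id = character(),
               parent = character(), stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(
    feat$chrom, IRanges::IRanges(feat$start, feat$end),
    strand = feat$strand)
  S4Vectors::mcols(gr)$type <- feat$type
  S4Vectors::mcols(gr)$ID <- feat$id
  plist <- as.list(feat$parent)
  plist[is.na(feat$parent)] <- list(character(0))
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(plist)
  rtracklayer::export(gr, file.path(dir, "genes.gff3"), format = "gff3")
  sidecar <- data.frame(
    locus_id = vapply(loci, `[[`, "", "locus_id"),
    chrom = vapply(loci, `[[`, "", "chrom"),
    start = vapply(loci, `[[`, numeric(1), "start"),
    end = vapply(loci, `[[`, numeric(1), "end"),
    planted_class = classes, stringsAsFactors = FALSE)
  write_tsv_commented(sidecar, file.path(dir, "truth_regions.tsv"),
                      "planted genomic-context class per locus")
  invisible(sidecar)
}

#' Write the sample-to-group map of a simulation
#'
#' @param config a [simulation_config()].
#' @param path output TSV path (columns `sample_id`, `group`).
#' @return invisibly, the path.
#' @export
emit_group_map <- function(config, path) {
  write_tsv_commented(sim_samples(config), path, "sample to group map")
  invisible(path)
}

#' Study-shaped default simulation: 7 groups of 4 samples
#'
#' Mirrors the cohort geometry of a multi-breed whole-genome study: seven
#' groups of four individuals (28 samples), ~20x diploid coverage, 100-bp
#' bins. Two chromosomes carry 15 loci at least 15 kb apart: shared
#' polymorphic loci (identical distributions in all groups, expected Vst
#' 0), moderately differentiated loci, fully differentiated planted loci
#' (one group fixed for a different state, expected Vst 1), and loci laid
#' out so each genomic-context class receives at least one locus.
#'
#' @param seed integer seed.
#' @return a [simulation_config()].
#' @export
default_sim_config <- function(seed = 1) {
  chroms <- data.frame(chrom = c("chr1", "chr2"),
                       length = c(6e5, 4e5))
  group_names <- c("BD", "GY", "HZ", "OL", "SG1", "SG2", "ZK")
  groups <- data.frame(group = group_names, n_samples = 4L)
  shared <- function() {
    d <- c("0.5" = 0.3, "1" = 0.5, "1.5" = 0.2)
    stats::setNames(rep(list(d), length(group_names)), group_names)
  }
  fixed_in <- function(g, state) {
    d <- stats::setNames(rep(list(c("1" = 1)), length(group_names)),
                         group_names)
    d[[g]] <- stats::setNames(1, as.character(state))
    d
  }
  moderate <- function(gs) {
    d <- stats::setNames(rep(list(c("1" = 1)), length(group_names)),
                         group_names)
    for (g in gs) d[[g]] <- c("0.5" = 0.7, "1" = 0.3)
    d
  }
  mk <- function(chrom, start, len, dist) {
    locus_spec(chrom, start, start + len - 1, dist)
  }
  loci <- list(
    mk("chr1", 20001, 2000, shared()),
    mk("chr1", 60001, 3000, fixed_in("BD", 2.0)),
    mk("chr1", 100001, 2500, moderate(c("GY", "HZ"))),
    mk("chr1", 140001, 2000, shared()),
    mk("chr1", 180001, 4000, fixed_in("ZK", 0.0)),
    mk("chr1", 240001, 2000, shared()),
    mk("chr1", 300001, 3000, moderate("OL")),
    mk("chr1", 360001, 2000, shared()),
    mk("chr1", 420001, 2500, fixed_in("SG1", 0.5)),
    mk("chr1", 480001, 2000, shared()),
    mk("chr2", 20001, 2000, shared()),
    mk("chr2", 60001, 2500, moderate(c("SG2", "ZK"))),
    mk("chr2", 100001, 2000, shared()),
    mk("chr2", 160001, 3000, fixed_in("GY", 1.5)),
    mk("chr2", 220001, 2000, shared())
  )
  simulation_config(chroms, groups, loci, mean_coverage = 20,
                    bin_size = 100, rd_noise_sd = 0.05,
                    junk_call_rate = 0.05, seed = seed)
}

#' Write / read a simulation configuration as YAML
#'
#' @param config a [simulation_config()].
#' @param path YAML file path.
#' @return `write_sim_config` the path invisibly; `read_sim_config` a
#'   [simulation_config()].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  obj <- list(
    chromosomes = lapply(seq_len(nrow(config$chromosomes)), function(i) {
      list(chrom = config$chromosomes$chrom[i],
           length = config$chromosomes$length[i])
    }),
    groups = lapply(seq_len(nrow(config$groups)), function(i) {
      list(group = config$groups$group[i],
           n_samples = config$groups$n_samples[i])
    }),
    loci = lapply(config$loci, function(loc) {
      list(chrom = loc$chrom, start = loc$start, end = loc$end,
           dist = lapply(loc$dist, as.list))
    }),
    mean_coverage = config$mean_coverage, bin_size = config$bin_size,
    rd_noise_sd = config$rd_noise_sd,
    junk_call_rate = config$junk_call_rate, seed = config$seed)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  obj <- yaml::read_yaml(path)
  chroms <- do.call(rbind, lapply(obj$chromosomes, as.data.frame))
  groups <- do.call(rbind, lapply(obj$groups, as.data.frame))
  loci <- lapply(obj$loci, function(l) {
    dist <- lapply(l$dist, function(d) unlist(d))
    locus_spec(l$chrom, l$start, l$end, dist)
  })
  simulation_config(chroms, groups, loci,
                    mean_coverage = obj$mean_coverage,
                    bin_size = obj$bin_size,
                    rd_noise_sd = obj$rd_noise_sd,
                    junk_call_rate = obj$junk_call_rate, seed = obj$seed)
}
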