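#' Coverage-filter a methylome sample
#'
#' Keeps CpGs with read coverage (methylated + unmethylated) of at least
#' `min_reads`; the threshold is inclusive, so coverage exactly 5 is
#' retained under the default.
#'
#' @param sample A `methylome_sample`.
#' @param min_reads Minimum coverage (default 5).
#' @return The filtered `methylome_sample`.
#' @export
filter_coverage <- function(sample, min_reads = 5) {
  keep <- sample$records$meth + sample$records$unmeth >= min_reads
  sample$records <- sample$records[keep, , drop = FALSE]
  rownames(sample$records) <- NULL
  sample
}

#' Threshold-based hypomethylated-region calling
#'
#' A deliberately simple segmenter standing in for an HMM-based HMR
#' caller (externally produced HMR BEDs can be supplied to the rest of
#' the pipeline instead): maximal runs of at least `min_cpg` consecutive
#' CpGs with beta <= `beta_max`, uninterrupted by a higher-methylation
#' CpG and with at most `max_gap` bp between neighbouring CpGs, become
#' HMRs spanning the first to the last CpG of the run.
#'
#' @param sample A coverage-filtered `methylome_sample`.
#' @param beta_max Maximum per-CpG beta inside an HMR (default 0.5).
#' @param min_cpg Minimum CpGs per HMR (default 4).
#' @param max_gap Maximum distance between consecutive CpGs in a run
#'   (default 500 bp).
#' @return data.frame (sample_id, chrom, start, end, n_cpg, mean_beta);
#'   `start`/`end` are the first/last CpG positions (1-based closed).
#' @export
call_hmrs_simple <- function(sample, beta_max = 0.5, min_cpg = 4,
                             max_gap = 500) {
  r <- sample$records
  beta <- beta_values(sample)
  low <- !is.na(beta) & beta <= beta_max
  if (!any(low)) {
    return(data.frame(sample_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_cpg = integer(), mean_beta = numeric(),
                      stringsAsFactors = FALSE))
  }
  new_chrom <- c(TRUE, r$chrom[-1] != r$chrom[-nrow(r)])
  big_gap <- c(TRUE, diff(r$pos) > max_gap) | new_chrom
  # run id increments when leaving a low stretch or jumping a gap
  run <- cumsum(!low | big_gap)
  idx <- which(low)
  per <- split(idx, run[idx])
  per <- per[lengths(per) >= min_cpg]
  if (length(per) == 0) {
    return(data.frame(sample_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_cpg = integer(), mean_beta = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    sample_id = sample$sample_id,
    chrom = vapply(per, function(i) r$chrom[i[1]], character(1)),
    start = as.integer(vapply(per, function(i) r$pos[i[1]], numeric(1))),
    end = as.integer(vapply(per, function(i) r$pos[i[length(i)]],
                            numeric(1))),
    n_cpg = lengths(per),
    mean_beta = vapply(per, function(i) mean(beta[i]), numeric(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Scan for cohort-recurrent hypomethylated regions
#'
#' Focal HMRs (length <= `focal_max`) are projected onto non-overlapping
#' `window`-bp tiles anchored at coordinate 0; a tile qualifies when at
#' least `min_fraction` of samples (inclusive: exactly 5% of samples
#' qualifies under the default) have an HMR overlapping it; maximal runs
#' of adjacent qualifying tiles merge into recurrent regions. Each
#' region's `sample_fraction` is the fraction of samples with any focal
#' HMR overlapping the merged region.
#'
#' @param hmrs data.frame of per-sample HMRs (sample_id, chrom, start,
#'   end), e.g. rbind-ed output of [call_hmrs_simple()].
#' @param n_samples Total number of samples scanned (denominator).
#' @param window Tile width in bp (default 100).
#' @param min_fraction Recurrence threshold (default 0.05).
#' @param focal_max Maximum HMR length in bp; longer HMRs are discarded
#'   before scanning (default 10000).
#' @return data.frame (region_id, chrom, start, end, sample_fraction)
#'   with disjoint, sorted regions; `start`/`end` are the 1-based closed
#'   coordinates of the merged tile run.
#' @export
recurrence_scan <- function(hmrs, n_samples, window = 100,
                            min_fraction = 0.05, focal_max = 10000) {
  if (n_samples <= 0) stop("n_samples must be positive")
  empty <- data.frame(region_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      sample_fraction = numeric(), stringsAsFactors = FALSE)
  if (nrow(hmrs) == 0) return(empty)
  hmrs <- hmrs[hmrs$end - hmrs$start + 1 <= focal_max, , drop = FALSE]
  if (nrow(hmrs) == 0) return(empty)
  # expand each HMR to the tile indices it touches, dedupe per sample
  w0 <- (hmrs$start - 1) %/% window
  w1 <- (hmrs$end - 1) %/% window
  nw <- w1 - w0 + 1
  dt <- data.table::data.table(
    chrom = rep(hmrs$chrom, nw),
    win = unlist(mapply(seq, w0, w1, SIMPLIFY = FALSE), use.names = FALSE),
    sample_id = rep(hmrs$sample_id, nw))
  dt <- unique(dt)
  counts <- dt[, list(n = .N), by = c("chrom", "win")]
  counts <- counts[counts$n / n_samples >= min_fraction, ]
  if (nrow(counts) == 0) return(empty)
  data.table::setorderv(counts, c("chrom", "win"))
  brk <- c(TRUE, counts$chrom[-1] != counts$chrom[-nrow(counts)] |
             diff(counts$win) != 1)
  grp <- cumsum(brk)
  regions <- data.frame(
    chrom = as.vector(tapply(counts$chrom, grp, function(x) x[1])),
    start = as.integer(tapply(counts$win, grp, min) * window + 1),
    end = as.integer((tapply(counts$win, grp, max) + 1) * window),
    stringsAsFactors = FALSE)
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  rgr <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(regions$start, regions$end))
  hgr <- GenomicRanges::GRanges(hmrs$chrom,
                                IRanges::IRanges(hmrs$start, hmrs$end))
  hits <- GenomicRanges::findOverlaps(rgr, hgr, ignore.strand = TRUE)
  frac <- vapply(split(hmrs$sample_id[S4Vectors::subjectHits(hits)],
                       factor(S4Vectors::queryHits(hits),
                              seq_len(nrow(regions)))),
                 function(x) length(unique(x)) / n_samples, numeric(1))
  out <- data.frame(region_id = sprintf("rhmr_%05d", seq_len(nrow(regions))),
                    regions, sample_fraction = as.vector(frac),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

first_overlap_group <- function(gr, annots, labels, default) {
  out <- rep(default, length(gr))
  for (i in rev(seq_along(labels))) {
    ann <- annots[[labels[i]]]
    if (is.null(ann)) next
    out[IRanges::overlapsAny(gr, ann, ignore.strand = TRUE)] <- labels[i]
  }
  out
}

#' Annotate regions by regulatory group and CpG-density context
#'
#' Assigns each region to the first overlapping group in the precedence
#' order promoter > enhancer > dyadic (else `none`), and independently to
#' the CpG context island > shore > shelf (else `open_sea`).
#'
#' @param regions Region data.frame (chrom, start, end).
#' @param annotations Named list of `GRanges`: any of `promoter`,
#'   `enhancer`, `dyadic`, `cgi_island`, `cgi_shore`, `cgi_shelf`.
#' @return `regions` with `annotation_group` and `cgi_context` columns.
#' @export
classify_hmr_context <- function(regions, annotations) {
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start, regions$end))
  regions$annotation_group <- first_overlap_group(
    gr, annotations, c("promoter", "enhancer", "dyadic"), "none")
  regions$cgi_context <- first_overlap_group(
    gr, annotations, c("cgi_island", "cgi_shore", "cgi_shelf"), "open_sea")
  regions
}

#' Region-by-sample methylation matrix
#'
#' Entry (r, s) is the coverage-weighted mean beta of sample s's covered
#' CpGs inside region r: `sum(meth) / sum(meth + unmeth)`. Missing (`NA`)
#' when the sample has no covered CpG in the region; regions with no
#' covered CpG in any sample are dropped with a warning.
#'
#' @param regions Region data.frame (region_id, chrom, start, end).
#' @param samples List of coverage-filtered `methylome_sample`s.
#' @return Numeric matrix regions x samples with region_ids as rownames.
#' @export
region_methylation_matrix <- function(regions, samples) {
  rgr <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(regions$start, regions$end))
  mat <- matrix(NA_real_, nrow(regions), length(samples),
                dimnames = list(regions$region_id,
                                vapply(samples, `[[`, character(1),
                                       "sample_id")))
  for (j in seq_along(samples)) {
    r <- samples[[j]]$records
    pgr <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$pos, r$pos))
    hits <- GenomicRanges::findOverlaps(rgr, pgr, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits); qj <- S4Vectors::subjectHits(hits)
    if (length(qi) == 0) next
    msum <- tapply(r$meth[qj], qi, sum)
    csum <- tapply(r$meth[qj] + r$unmeth[qj], qi, sum)
    i <- as.integer(names(msum))
    mat[i, j] <- as.vector(msum) / as.vector(csum)
  }
  empty <- rowSums(!is.na(mat)) == 0
  if (any(empty)) {
    warning(sum(empty), " region(s) with no covered CpG in any sample dropped")
    mat <- mat[!empty, , drop = FALSE]
  }
  mat
}

#' Differentially methylated region testing
#'
#' Two-sample Student t-test (pooled variance by default) of per-region
#' mean betas between case and control samples, Benjamini-Hochberg
#' adjusted across regions. Regions with fewer than two non-missing
#' values in either group, or zero variance in both groups with equal
#' means, are excluded from testing and counted in
#' `attr(, "n_excluded")`.
#'
#' @param mat Region x sample matrix from [region_methylation_matrix()].
#' @param case_ids,control_ids Column names of the two groups.
#' @param alpha_q BH threshold defining the DMR set (default 0.05).
#' @param var_equal Pooled-variance test (default `TRUE`); `FALSE` gives
#'   Welch.
#' @return data.frame (region_id, mean_beta_case, mean_beta_control,
#'   delta, t_statistic, p, q, direction, is_dmr) for all testable
#'   regions.
#' @export
dmr_test <- function(mat, case_ids, control_ids, alpha_q = 0.05,
                     var_equal = TRUE) {
  x <- mat[, case_ids, drop = FALSE]
  y <- mat[, control_ids, drop = FALSE]
  nx <- rowSums(!is.na(x)); ny <- rowSums(!is.na(y))
  mx <- rowMeans(x, na.rm = TRUE); my <- rowMeans(y, na.rm = TRUE)
  vx <- apply(x, 1, stats::var, na.rm = TRUE)
  vy <- apply(y, 1, stats::var, na.rm = TRUE)
  testable <- nx >= 2 & ny >= 2 & !(vx == 0 & vy == 0 & mx == my)
  n_excluded <- sum(!testable)
  x <- x[testable, , drop = FALSE]; y <- y[testable, , drop = FALSE]
  nx <- nx[testable]; ny <- ny[testable]
  mx <- mx[testable]; my <- my[testable]
  vx <- vx[testable]; vy <- vy[testable]
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  tstat <- (mx - my) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(
    region_id = rownames(mat)[testable],
    mean_beta_case = mx, mean_beta_control = my, delta = mx - my,
    t_statistic = tstat, p = p, q = q,
    direction = ifelse(mx - my < 0, "hypo", "hyper"),
    is_dmr = q <= alpha_q,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Fraction of hypomethylated DMRs
#'
#' @param dmrs data.frame with a `direction` column (typically the
#'   `is_dmr` subset of [dmr_test()] output).
#' @return Fraction of rows with direction `hypo`.
#' @export
hypo_fraction <- function(dmrs) {
  if (nrow(dmrs) == 0) stop("empty DMR list")
  mean(dmrs$direction == "hypo")
}

#' Select recurrent, case-hypomethylated regions
#'
#' Keeps regions whose HMR recurrence exceeds `min_recurrence` (strict,
#' mirroring "in more than 10% of samples") and whose differential
#' methylation is below `max_delta` (strict), sorted by descending
#' recurrence.
#'
#' @param regions data.frame with `sample_fraction` and `delta` columns
#'   (recurrent regions joined with their DMR deltas).
#' @param min_recurrence Recurrence threshold (default 0.10, exclusive).
#' @param max_delta Differential-methylation threshold (default -0.1,
#'   exclusive: delta must be `< max_delta`).
#' @return The selected rows, sorted by `sample_fraction` descending.
#' @export
select_recurrent_differential <- function(regions, min_recurrence = 0.10,
                                          max_delta = -0.1) {
  sel <- regions[regions$sample_fraction > min_recurrence &
                   !is.na(regions$delta) & regions$delta < max_delta, ,
                 drop = FALSE]
  sel <- sel[order(-sel$sample_fraction, sel$chrom, sel$start), ,
             drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Map DMRs to differentially methylated genes
#'
#' A gene is differentially methylated when any of its promoter, exon or
#' intron parts overlaps a DMR; each gene is reported once.
#'
#' @param dmrs Region data.frame (chrom, start, end).
#' @param gene_parts Feature-set `GRanges` whose `feature_class` is one
#'   of `promoter`, `exon`, `intron` and whose `name` is the gene symbol.
#' @return Character vector of unique gene names, sorted.
#' @export
map_dmrs_to_genes <- function(dmrs, gene_parts) {
  parts <- gene_parts[gene_parts$feature_class %in%
                        c("promoter", "exon", "intron")]
  gr <- GenomicRanges::GRanges(dmrs$chrom,
                               IRanges::IRanges(dmrs$start, dmrs$end))
  hits <- GenomicRanges::findOverlaps(gr, parts, ignore.strand = TRUE)
  sort(unique(parts$name[S4Vectors::subjectHits(hits)]))
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test `P(X >= overlap)` of the query gene
#' list against each set (both intersected with the universe first),
#' Benjamini-Hochberg adjusted.
#'
#' @param query Character vector of query genes (subset of `universe`).
#' @param gene_sets Named list of character vectors, e.g. from
#'   [read_gmt()].
#' @param universe Character vector of all assayable genes.
#' @param alpha_q BH significance threshold (default 0.05).
#' @return data.frame (set_id, overlap, set_size, universe_size, n_query,
#'   p, q, significant), sorted by p.
#' @export
geneset_enrichment <- function(query, gene_sets, universe,
                               alpha_q = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  query <- unique(intersect(query, universe))
  sets <- lapply(gene_sets, intersect, universe)
  overlap <- vapply(sets, function(s) length(intersect(s, query)),
                    integer(1))
  set_size <- lengths(sets)
  p <- stats::phyper(overlap - 1, set_size,
                     length(universe) - set_size, length(query),
                     lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(set_id = names(sets), overlap = overlap,
                    set_size = set_size,
                    universe_size = length(universe),
                    n_query = length(query), p = p, q = q,
                    significant = q <= alpha_q,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p, out$set_id), ]
}
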