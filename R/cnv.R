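cnv_granges <- function(calls) {
  GenomicRanges::GRanges(calls$chrom,
                         IRanges::IRanges(calls$start, calls$end))
}

# round half away from zero, deterministically (base round() is banker's)
round_half_up <- function(x) floor(x + 0.5)

#' Two-caller consensus CNV calls
#'
#' Within each sample, pairs same-type calls from caller A and caller B
#' whose reciprocal overlap is at least `min_reciprocal` (greedy
#' best-overlap matching, each call used at most once) and emits one
#' consensus call per pair with the start and end coordinates averaged
#' (rounded half up). Calls supported by a single caller are dropped.
#'
#' @param calls_a,calls_b Call data.frames (sample_id, chrom, start, end,
#'   type) from the two callers.
#' @param min_reciprocal Minimum reciprocal overlap (default 0.5,
#'   inclusive).
#' @return data.frame of consensus calls (sample_id, chrom, start, end,
#'   type), sorted by sample, chrom, start.
#' @export
consensus_intersect <- function(calls_a, calls_b, min_reciprocal = 0.5) {
  gra <- cnv_granges(calls_a); grb <- cnv_granges(calls_b)
  hits <- GenomicRanges::findOverlaps(gra, grb, ignore.strand = TRUE)
  qa <- S4Vectors::queryHits(hits); qb <- S4Vectors::subjectHits(hits)
  same <- calls_a$sample_id[qa] == calls_b$sample_id[qb] &
    calls_a$type[qa] == calls_b$type[qb]
  qa <- qa[same]; qb <- qb[same]
  rof <- reciprocal_overlap_fraction(gra[qa], grb[qb])
  ok <- rof >= min_reciprocal
  qa <- qa[ok]; qb <- qb[ok]; rof <- rof[ok]
  # greedy best-reciprocal matching
  o <- order(-rof, qa, qb)
  used_a <- logical(nrow(calls_a)); used_b <- logical(nrow(calls_b))
  keep <- logical(length(o))
  for (i in o) {
    if (!used_a[qa[i]] && !used_b[qb[i]]) {
      used_a[qa[i]] <- TRUE; used_b[qb[i]] <- TRUE; keep[i] <- TRUE
    }
  }
  qa <- qa[keep]; qb <- qb[keep]
  start <- as.integer(round_half_up((calls_a$start[qa] + calls_b$start[qb]) / 2))
  end <- as.integer(round_half_up((calls_a$end[qa] + calls_b$end[qb]) / 2))
  stopifnot(all(end > start))
  out <- data.frame(sample_id = calls_a$sample_id[qa],
                    chrom = calls_a$chrom[qa], start = start, end = end,
                    type = calls_a$type[qa], stringsAsFactors = FALSE)
  out <- out[order(out$sample_id, out$chrom, out$start, out$end), ]
  rownames(out) <- NULL
  out
}

#' Cross-sample recurrent CNV regions
#'
#' Links same-type consensus calls from different (or the same) samples
#' whose reciprocal overlap is at least `min_reciprocal`; connected
#' components become recurrent regions whose interval is the
#' coordinate-wise mean of the member calls (rounded half up) and whose
#' `patient_frequency` is the number of distinct supporting samples.
#' Output is independent of input row order and sorted by descending
#' frequency, then coordinates.
#'
#' @param consensus Consensus call data.frame from
#'   [consensus_intersect()].
#' @param min_reciprocal Minimum reciprocal overlap (default 0.5).
#' @return data.frame (region_id, chrom, start, end, type,
#'   patient_frequency, length, supporting_samples); `length` is
#'   `end - start` in the BED sense (= width of the 1-based interval).
#' @export
cluster_across_samples <- function(consensus, min_reciprocal = 0.5) {
  n <- nrow(consensus)
  if (n == 0) {
    return(data.frame(region_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      type = character(), patient_frequency = integer(),
                      length = integer(), supporting_samples = character(),
                      stringsAsFactors = FALSE))
  }
  # canonical order first, so components and means ignore input order
  cons <- consensus[order(consensus$chrom, consensus$start, consensus$end,
                          consensus$type, consensus$sample_id), ]
  rownames(cons) <- NULL
  gr <- cnv_granges(cons)
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); qj <- S4Vectors::subjectHits(hits)
  sel <- qi < qj & cons$type[qi] == cons$type[qj]
  qi <- qi[sel]; qj <- qj[sel]
  ok <- reciprocal_overlap_fraction(gr[qi], gr[qj]) >= min_reciprocal
  g <- igraph::make_graph(as.vector(rbind(qi[ok], qj[ok])), n = nrow(cons),
                          directed = FALSE)
  comp <- igraph::components(g)$membership
  agg <- function(f, x) as.vector(tapply(x, comp, f))
  start <- as.integer(round_half_up(agg(mean, cons$start)))
  end <- as.integer(round_half_up(agg(mean, cons$end)))
  out <- data.frame(
    chrom = agg(function(x) x[1], cons$chrom),
    start = start, end = end,
    type = agg(function(x) x[1], cons$type),
    patient_frequency = as.integer(
      agg(function(x) length(unique(x)), cons$sample_id)),
    length = end - start + 1L,
    supporting_samples = agg(function(x)
      paste(sort(unique(x)), collapse = ";"), cons$sample_id),
    stringsAsFactors = FALSE)
  out <- out[order(-out$patient_frequency, out$chrom, out$start, out$end), ]
  out <- data.frame(region_id = sprintf("region_%03d", seq_len(nrow(out))),
                    out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Annotate recurrent regions with overlapping genes
#'
#' Genes overlapping a region by at least one base are listed in genomic
#' order, semicolon-joined, in an `overlapped_genes` column.
#'
#' @param regions Region data.frame (chrom, start, end).
#' @param genes Feature-set `GRanges` with a `name` column.
#' @return `regions` with `overlapped_genes` added.
#' @export
annotate_regions <- function(regions, genes) {
  genes <- sort(genes, ignore.strand = TRUE)
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start, regions$end))
  hits <- GenomicRanges::findOverlaps(gr, genes, ignore.strand = TRUE)
  by_region <- split(genes$name[S4Vectors::subjectHits(hits)],
                     S4Vectors::queryHits(hits))
  regions$overlapped_genes <- ""
  regions$overlapped_genes[as.integer(names(by_region))] <-
    vapply(by_region, paste, character(1), collapse = ";")
  regions
}

#' Case/control comparison of region carrier frequencies
#'
#' One-sided Fisher test (enrichment in cases) of per-region carrier
#' counts, Benjamini-Hochberg adjusted across regions. This is the
#' region-level frequency comparison the pipeline uses in place of a
#' read-depth signal model.
#'
#' @param case_carriers,control_carriers Integer vectors of per-region
#'   carrier counts.
#' @param case_n,control_n Cohort sizes.
#' @param alpha_q BH significance level (default 0.05).
#' @return data.frame (case_carriers, control_carriers, p, q,
#'   significant).
#' @export
compare_region_frequencies <- function(case_carriers, case_n,
                                       control_carriers, control_n,
                                       alpha_q = 0.05) {
  if (control_n <= 0) stop("control_n must be positive")
  p <- fisher_one_sided(case_carriers, case_n - case_carriers,
                        control_carriers, control_n - control_carriers)
  q <- stats::p.adjust(p, method = "BH")
  data.frame(case_carriers = case_carriers,
             control_carriers = control_carriers,
             p = p, q = q, significant = q <= alpha_q)
}

#' Count samples supporting each region in a call set
#'
#' A sample supports a region if any of its same-type consensus calls
#' overlaps the region with reciprocal overlap at least `min_reciprocal`.
#'
#' @param regions Region data.frame (chrom, start, end, type).
#' @param consensus Consensus call data.frame.
#' @param min_reciprocal Minimum reciprocal overlap.
#' @return Integer vector of supporting-sample counts per region.
#' @export
count_region_support <- function(regions, consensus, min_reciprocal = 0.5) {
  if (nrow(consensus) == 0 || nrow(regions) == 0) {
    return(integer(nrow(regions)))
  }
  rgr <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(regions$start, regions$end))
  cgr <- cnv_granges(consensus)
  hits <- GenomicRanges::findOverlaps(rgr, cgr, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); qj <- S4Vectors::subjectHits(hits)
  sel <- regions$type[qi] == consensus$type[qj] &
    reciprocal_overlap_fraction(rgr[qi], cgr[qj]) >= min_reciprocal
  counts <- integer(nrow(regions))
  if (any(sel)) {
    tab <- tapply(consensus$sample_id[qj[sel]], qi[sel],
                  function(x) length(unique(x)))
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  counts
}
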