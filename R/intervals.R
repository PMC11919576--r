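#' Read a BED file as a GRanges
#'
#' Reads BED3/BED4/BED6 into a `GRanges`. BED is 0-based half-open on disk;
#' the returned ranges use the Bioconductor 1-based closed convention, so a
#' line `chr19 15783859 15791329` becomes `chr19:15783860-15791329` with
#' `width()` equal to `end - start` of the BED line (7470 here). Column 4,
#' when present, is kept as `name`. Out-of-order input is sorted.
#'
#' @param path Path to a BED file. May be empty (returns an empty GRanges).
#' @return A sorted `GRanges`, with a `name` metadata column for BED4+.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) {
    return(GenomicRanges::GRanges())
  }
  raw <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  bad <- which(!(raw[[3]] > raw[[2]]))
  if (length(bad) > 0) {
    stop("BED interval with end <= start at line ", bad[1], " of ", path)
  }
  gr <- rtracklayer::import(path, format = "BED")
  GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
  sort(gr, ignore.strand = TRUE)
}

#' Read a fraction-covered coverage track
#'
#' Reads a 4-column bedGraph-style file (`chrom start end fraction`) giving,
#' for each interval, the fraction of cohort samples covered at the required
#' depth. Used to build the callable mask for burden testing.
#'
#' @param path Path to a bedGraph file.
#' @return A sorted `GRanges` with a numeric `score` column in \[0, 1\].
#' @export
read_coverage_track <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (any(gr$score < 0 | gr$score > 1)) {
    stop("coverage fractions must lie in [0, 1]: ", path)
  }
  GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
  sort(gr, ignore.strand = TRUE)
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (set id, description, tab-separated genes).
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Reciprocal overlap fraction of two interval sets
#'
#' For each pair `a[i]`, `b[i]` returns
#' `min(overlap / width(a), overlap / width(b))`, the reciprocal-overlap
#' statistic that governs CNV call merging (the 50% rule). Symmetric in its
#' arguments; 0 for disjoint pairs or pairs on different chromosomes.
#'
#' @param a,b `GRanges` of equal length (or length 1, recycled).
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
reciprocal_overlap_fraction <- function(a, b) {
  if (length(a) == 1 && length(b) > 1) a <- rep(a, length(b))
  if (length(b) == 1 && length(a) > 1) b <- rep(b, length(a))
  stopifnot(length(a) == length(b))
  if (any(GenomicRanges::width(a) < 1) || any(GenomicRanges::width(b) < 1)) {
    stop("reciprocal_overlap_fraction: zero-length interval")
  }
  same <- as.character(GenomicRanges::seqnames(a)) ==
    as.character(GenomicRanges::seqnames(b))
  ov <- pmax(0L, pmin(GenomicRanges::end(a), GenomicRanges::end(b)) -
               pmax(GenomicRanges::start(a), GenomicRanges::start(b)) + 1L)
  ov[!same] <- 0L
  pmin(ov / GenomicRanges::width(a), ov / GenomicRanges::width(b))
}

#' Build a feature set from intervals
#'
#' A feature set is a `GRanges` carrying `id`, `name` and `feature_class`
#' metadata columns, the unit over which burden tests and annotations are
#' computed. `feature_class` is restricted to the classes used by the
#' pipeline (coding genes, regulatory segment types, CpG-density contexts,
#' gene parts).
#'
#' @param gr A `GRanges`.
#' @param id Feature identifiers (recycled if length 1).
#' @param name Display names; defaults to `id`.
#' @param feature_class One of the supported classes, recycled if length 1.
#' @return `GRanges` with `id`, `name`, `feature_class` columns, sorted.
#' @export
feature_set <- function(gr, id, name = id, feature_class = "coding_gene") {
  classes <- c("coding_gene", "promoter", "enhancer", "five_prime_utr",
               "three_prime_utr", "lncRNA", "lncRNA_promoter", "miRNA",
               "smallRNA", "dyadic", "cgi_island", "cgi_shore", "cgi_shelf",
               "exon", "intron")
  if (!all(feature_class %in% classes)) {
    stop("unknown feature_class: ",
         paste(setdiff(feature_class, classes), collapse = ", "))
  }
  mc <- S4Vectors::DataFrame(
    id = rep_len(as.character(id), length(gr)),
    name = rep_len(as.character(name), length(gr)),
    feature_class = rep_len(feature_class, length(gr))
  )
  S4Vectors::mcols(gr) <- mc
  sort(gr, ignore.strand = TRUE)
}

# GRanges for variant positions (1-based VCF pos, width = nchar(ref))
variant_granges <- function(variants) {
  GenomicRanges::GRanges(
    variants$chrom,
    IRanges::IRanges(start = variants$pos,
                     width = nchar(variants$ref))
  )
}
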