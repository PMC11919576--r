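#' INFO key configuration for annotated VCFs
#'
#' The annotation stack that produces population frequencies, consequence
#' classes, deleteriousness calls and site quality differs between studies,
#' so the INFO keys the readers look for are configurable. The defaults
#' match the fields written by [write_case_vcf()] / [write_control_sites()].
#'
#' @param pop_af Key of the per-alternate max population allele frequency
#'   (Number=A, Float).
#' @param consequence Key of the per-alternate consequence class (Number=A,
#'   String; one of `synonymous`, `missense`, `lof`, `noncoding`).
#' @param deleterious Keys of the three per-alternate deleteriousness calls
#'   (Number=A, Integer 0/1), in the order GERP++, GWAVA, CADD.
#' @param qual_metric Key of the site quality-by-depth-like metric
#'   (Number=1, Float).
#' @param ac,an Keys of the control allele count / allele number.
#' @return A named list of keys.
#' @export
vcf_info_keys <- function(pop_af = "POPAF", consequence = "CSQCLASS",
                          deleterious = c("DGERP", "DGWAVA", "DCADD"),
                          qual_metric = "QD", ac = "AC", an = "AN") {
  stopifnot(length(deleterious) == 3)
  list(pop_af = pop_af, consequence = consequence,
       deleterious = deleterious, qual_metric = qual_metric,
       ac = ac, an = an)
}

check_info_keys <- function(vcf, wanted, path) {
  have <- rownames(VariantAnnotation::info(VariantAnnotation::header(vcf)))
  missing <- setdiff(wanted, have)
  if (length(missing) > 0) {
    stop("VCF ", path, " is missing required INFO key(s): ",
         paste(missing, collapse = ", "))
  }
}

# Per-alternate extraction: returns the vector aligned with the biallelic
# expansion defined by (row_idx, alt_idx); scalar INFO fields are recycled.
expand_info <- function(col, row_idx, alt_idx) {
  if (methods::is(col, "List") || is.list(col)) {
    lens <- S4Vectors::elementNROWS(col)
    flat <- unlist(col, use.names = FALSE)
    offs <- cumsum(lens) - lens
    flat[offs[row_idx] + alt_idx]
  } else {
    col[row_idx]
  }
}

#' Read a case-cohort VCF with per-sample genotypes
#'
#' Reads an annotated VCF 4.x with per-sample `GT` into a `case_cohort`
#' object. Multi-allelic sites are split into biallelic records (one per
#' alternate allele), with per-alternate INFO fields taken per allele and
#' the genotype dose of each sample computed for that allele: number of
#' occurrences of the allele index in `GT`, `NA` for missing genotypes.
#'
#' @param path Path to the VCF.
#' @param keys INFO key configuration from [vcf_info_keys()].
#' @param pass_only Keep only records with FILTER `PASS`.
#' @return A `case_cohort`: list with `samples` (character), `variants`
#'   (data.frame: chrom, pos, ref, alt, qual_metric, pass_flag, pop_af,
#'   consequence, del_gerp, del_gwava, del_cadd) and `doses` (integer
#'   matrix, variants x samples, values 0/1/2/NA).
#' @export
read_case_vcf <- function(path, keys = vcf_info_keys(), pass_only = FALSE) {
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) stop("failed to parse VCF ", path, ": ",
                             conditionMessage(e))
  )
  check_info_keys(vcf, c(keys$pop_af, keys$consequence, keys$deleterious,
                         keys$qual_metric), path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_list)
  row_idx <- rep(seq_along(n_alt), n_alt)
  alt_idx <- unlist(lapply(n_alt, seq_len), use.names = FALSE)
  info <- VariantAnnotation::info(vcf)

  variants <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[row_idx],
    pos = GenomicRanges::start(rr)[row_idx],
    ref = as.character(VariantAnnotation::ref(vcf))[row_idx],
    alt = unlist(lapply(alt_list, as.character), use.names = FALSE),
    qual_metric = expand_info(info[[keys$qual_metric]], row_idx, alt_idx),
    pass_flag = (as.character(VariantAnnotation::filt(vcf)) == "PASS")[row_idx],
    pop_af = expand_info(info[[keys$pop_af]], row_idx, alt_idx),
    consequence = expand_info(info[[keys$consequence]], row_idx, alt_idx),
    del_gerp = expand_info(info[[keys$deleterious[1]]], row_idx, alt_idx) == 1,
    del_gwava = expand_info(info[[keys$deleterious[2]]], row_idx, alt_idx) == 1,
    del_cadd = expand_info(info[[keys$deleterious[3]]], row_idx, alt_idx) == 1,
    stringsAsFactors = FALSE
  )

  gt <- VariantAnnotation::geno(vcf)$GT
  samples <- colnames(gt)
  a1 <- suppressWarnings(
    matrix(as.integer(sub("[/|].*$", "", gt)), nrow(gt), ncol(gt)))
  a2 <- suppressWarnings(
    matrix(as.integer(sub("^.*[/|]", "", gt)), nrow(gt), ncol(gt)))
  doses <- (a1[row_idx, , drop = FALSE] == alt_idx) +
    (a2[row_idx, , drop = FALSE] == alt_idx)
  dimnames(doses) <- list(NULL, samples)

  keep <- if (pass_only) variants$pass_flag else rep(TRUE, nrow(variants))
  out <- list(samples = samples,
              variants = variants[keep, , drop = FALSE],
              doses = doses[keep, , drop = FALSE])
  rownames(out$variants) <- NULL
  class(out) <- "case_cohort"
  out
}

#' Read a summary-control site VCF (AC/AN only)
#'
#' Reads a gnomAD-style control VCF that carries cohort summary counts in
#' the `AC`/`AN` INFO fields (no per-sample genotypes), plus the same
#' annotation fields as the case VCF so qualifying-variant selection can be
#' applied to both cohorts identically.
#'
#' @inheritParams read_case_vcf
#' @return A data.frame of control site records with columns chrom, pos,
#'   ref, alt, pop_af, consequence, del_gerp, del_gwava, del_cadd,
#'   control_ac, control_an.
#' @export
read_control_sites <- function(path, keys = vcf_info_keys()) {
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) stop("failed to parse VCF ", path, ": ",
                             conditionMessage(e))
  )
  check_info_keys(vcf, c(keys$ac, keys$an, keys$pop_af, keys$consequence,
                         keys$deleterious), path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_list)
  row_idx <- rep(seq_along(n_alt), n_alt)
  alt_idx <- unlist(lapply(n_alt, seq_len), use.names = FALSE)
  info <- VariantAnnotation::info(vcf)

  an <- expand_info(info[[keys$an]], row_idx, alt_idx)
  if (anyNA(an)) stop("control VCF ", path, ": record missing AN")
  ac <- expand_info(info[[keys$ac]], row_idx, alt_idx)
  if (anyNA(ac)) stop("control VCF ", path, ": record missing AC")
  if (any(ac > an)) {
    stop("control VCF ", path, ": AC > AN at record ",
         which(ac > an)[1])
  }
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[row_idx],
    pos = GenomicRanges::start(rr)[row_idx],
    ref = as.character(VariantAnnotation::ref(vcf))[row_idx],
    alt = unlist(lapply(alt_list, as.character), use.names = FALSE),
    pop_af = expand_info(info[[keys$pop_af]], row_idx, alt_idx),
    consequence = expand_info(info[[keys$consequence]], row_idx, alt_idx),
    del_gerp = expand_info(info[[keys$deleterious[1]]], row_idx, alt_idx) == 1,
    del_gwava = expand_info(info[[keys$deleterious[2]]], row_idx, alt_idx) == 1,
    del_cadd = expand_info(info[[keys$deleterious[3]]], row_idx, alt_idx) == 1,
    control_ac = as.integer(ac),
    control_an = as.integer(an),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

vcf_header_lines <- function(keys, contigs, with_gt) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs),
            as.integer(contigs)),
    sprintf('##INFO=<ID=%s,Number=A,Type=Float,Description="Max population allele frequency">', keys$pop_af),
    sprintf('##INFO=<ID=%s,Number=A,Type=String,Description="Consequence class">', keys$consequence),
    sprintf('##INFO=<ID=%s,Number=A,Type=Integer,Description="GERP++ deleterious call">', keys$deleterious[1]),
    sprintf('##INFO=<ID=%s,Number=A,Type=Integer,Description="GWAVA deleterious call">', keys$deleterious[2]),
    sprintf('##INFO=<ID=%s,Number=A,Type=Integer,Description="CADD deleterious call">', keys$deleterious[3]),
    sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="Quality by depth">', keys$qual_metric),
    sprintf('##INFO=<ID=%s,Number=A,Type=Integer,Description="Alternate allele count">', keys$ac),
    sprintf('##INFO=<ID=%s,Number=1,Type=Integer,Description="Allele number">', keys$an),
    '##FILTER=<ID=LowQual,Description="Low quality">',
    if (with_gt)
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
}

#' Write a case cohort as a VCF
#'
#' Emits one biallelic record per variant row with per-sample `GT`
#' reconstructed from the dose matrix (`NA` doses become `./.`). Inverse of
#' [read_case_vcf()] on the fields that reader retains.
#'
#' @param cohort A `case_cohort`.
#' @param path Output path.
#' @param keys INFO key configuration.
#' @param contigs Named integer vector of contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_case_vcf <- function(cohort, path, keys = vcf_info_keys(),
                           contigs = NULL) {
  v <- cohort$variants
  if (is.null(contigs)) {
    contigs <- vapply(split(v$pos, v$chrom), function(p) max(p) + 1000L,
                      numeric(1))
  }
  gt <- matrix("0/0", nrow(v), length(cohort$samples))
  gt[cohort$doses == 1] <- "0/1"
  gt[cohort$doses == 2] <- "1/1"
  gt[is.na(cohort$doses)] <- "./."
  info <- sprintf("%s=%s;%s=%s;%s=%d;%s=%d;%s=%d;%s=%s",
                  keys$pop_af, formatC(v$pop_af, format = "g", digits = 8),
                  keys$consequence, v$consequence,
                  keys$deleterious[1], as.integer(v$del_gerp),
                  keys$deleterious[2], as.integer(v$del_gwava),
                  keys$deleterious[3], as.integer(v$del_cadd),
                  keys$qual_metric, formatC(v$qual_metric, format = "g",
                                            digits = 8))
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".",
                ifelse(v$pass_flag, "PASS", "LowQual"), info, "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(vcf_header_lines(keys, contigs, TRUE),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", cohort$samples),
                     collapse = "\t"),
               body), path)
  invisible(path)
}

#' Write summary-control sites as a VCF
#'
#' @param sites Control site data.frame as returned by
#'   [read_control_sites()].
#' @inheritParams write_case_vcf
#' @return `path`, invisibly.
#' @export
write_control_sites <- function(sites, path, keys = vcf_info_keys(),
                                contigs = NULL) {
  v <- sites
  if (is.null(contigs)) {
    contigs <- vapply(split(v$pos, v$chrom), function(p) max(p) + 1000L,
                      numeric(1))
  }
  info <- sprintf("%s=%d;%s=%d;%s=%s;%s=%s;%s=%d;%s=%d;%s=%d",
                  keys$ac, v$control_ac, keys$an, v$control_an,
                  keys$pop_af, formatC(v$pop_af, format = "g", digits = 8),
                  keys$consequence, v$consequence,
                  keys$deleterious[1], as.integer(v$del_gerp),
                  keys$deleterious[2], as.integer(v$del_gwava),
                  keys$deleterious[3], as.integer(v$del_cadd))
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info,
                sep = "\t")
  writeLines(c(vcf_header_lines(keys, contigs, FALSE),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO"), collapse = "\t"),
               body), path)
  invisible(path)
}
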