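#' Toy-genome feature layout for the synthetic cohort
#'
#' Tiles `n_genes` gene bodies across the configured contigs and derives
#' regulatory segments (upstream of the first `n_segments` genes, classes
#' cycling over the noncoding segment types), low-complexity intervals and
#' fraction-covered tracks. LCR and low-coverage intervals are placed in
#' gene-free territory so that planted carrier rates stay interpretable;
#' the region filters are exercised by dedicated fixtures in the tests.
#'
#' @param config A [simulation_config()].
#' @return List with `genes`, `segments` (feature-set `GRanges`), `lcr`
#'   (`GRanges`) and `coverage_case` / `coverage_control` (scored
#'   `GRanges` tracks).
#' @export
simulate_feature_layout <- function(config) {
  contigs <- config$contigs
  n_per <- diff(round(seq(0, config$n_genes, length.out = length(contigs) + 1)))
  margin <- 20000L
  chrom <- character(0); start <- integer(0)
  for (i in seq_along(contigs)) {
    k <- n_per[i]
    if (k == 0) next
    spacing <- floor((contigs[i] - 2 * margin) / k)
    stopifnot(spacing > config$gene_length + 2000)
    start <- c(start, margin + (seq_len(k) - 1L) * spacing + 1501L)
    chrom <- c(chrom, rep(names(contigs)[i], k))
  }
  ids <- sprintf("gene_%04d", seq_len(config$n_genes))
  genes <- feature_set(
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start,
                                                   width = config$gene_length)),
    id = ids, feature_class = "coding_gene")
  genes <- genes[order(as.integer(sub("gene_", "", genes$id)))]

  seg_classes <- rep_len(c("promoter", "enhancer", "five_prime_utr",
                           "three_prime_utr", "lncRNA", "lncRNA_promoter",
                           "miRNA", "smallRNA"), config$n_segments)
  seg_idx <- seq_len(config$n_segments)
  segments <- GenomicRanges::GRanges(
    chrom[seg_idx],
    IRanges::IRanges(start[seg_idx] - 1200L, start[seg_idx] - 201L))
  segments <- feature_set(segments, id = sprintf("seg_%04d", seg_idx),
                          feature_class = seg_classes)
  segments <- segments[order(as.integer(sub("seg_", "", segments$id)))]

  lcr <- GenomicRanges::GRanges(
    rep(names(contigs), each = 2),
    IRanges::IRanges(rep(c(1000L, 13000L), length(contigs)),
                     rep(c(4000L, 15000L), length(contigs))))
  cov_track <- function(dip_start, dip_end, level, dip_level) {
    gr <- unlist(GenomicRanges::GRangesList(lapply(
      seq_along(contigs), function(i) {
        ch <- names(contigs)[i]
        GenomicRanges::GRanges(ch, IRanges::IRanges(
          c(1L, dip_start, dip_end + 1L),
          c(dip_start - 1L, dip_end, as.integer(contigs[i]))),
          score = c(level, dip_level, level))
      })))
    sort(gr, ignore.strand = TRUE)
  }
  list(genes = genes, segments = segments, lcr = lcr,
       coverage_case = cov_track(5000L, 8000L, 0.95, 0.50),
       coverage_control = cov_track(9000L, 12000L, 0.93, 0.60))
}

# Candidate-site catalog: positions, annotations and case site quality for
# every rare variant site the carrier model can populate.
build_site_catalog <- function(config, layout) {
  ns <- config$sites_per_class
  genes <- layout$genes
  gpos <- function(offset) {
    as.integer(t(outer(GenomicRanges::start(genes),
                      round(seq_len(ns) * config$gene_length / (ns + 2)) +
                        offset, "+")))
  }
  gene_ids <- rep(genes$id, each = ns)
  gene_chrom <- rep(as.character(GenomicRanges::seqnames(genes)), each = ns)
  cod <- data.frame(
    chrom = gene_chrom, pos = gpos(0L), feature_id = gene_ids,
    class = "coding",
    consequence = rep_len(c("missense", "missense", "lof", "missense",
                            "missense"), length(gene_ids)),
    stringsAsFactors = FALSE)
  syn <- data.frame(
    chrom = gene_chrom, pos = gpos(3L), feature_id = gene_ids,
    class = "syn", consequence = "synonymous", stringsAsFactors = FALSE)
  common <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(genes)),
    pos = GenomicRanges::start(genes) + 17L,
    feature_id = genes$id, class = "common", consequence = "missense",
    stringsAsFactors = FALSE)

  segs <- layout$segments
  spos <- function(k, offset) {
    as.integer(t(outer(GenomicRanges::start(segs),
                      round(seq_len(k) * 1000 / (k + 2)) + offset, "+")))
  }
  nc_del <- data.frame(
    chrom = rep(as.character(GenomicRanges::seqnames(segs)), each = 2),
    pos = spos(2L, 0L), feature_id = rep(segs$id, each = 2),
    class = "nc_del", consequence = "noncoding", stringsAsFactors = FALSE)
  nc_ben <- data.frame(
    chrom = rep(as.character(GenomicRanges::seqnames(segs)), each = ns),
    pos = spos(ns, 3L), feature_id = rep(segs$id, each = ns),
    class = "nc_ben", consequence = "noncoding", stringsAsFactors = FALSE)

  cat <- rbind(cod, syn, common, nc_del, nc_ben)
  cat$ref <- "A"; cat$alt <- "G"
  n <- nrow(cat)
  cat$pop_af <- 10^stats::runif(n, -5, -2.2)
  cat$pop_af[cat$class == "common"] <- stats::runif(sum(cat$class == "common"),
                                                    0.02, 0.5)
  nc <- cat$class %in% c("nc_del", "nc_ben")
  cat$pop_af[nc] <- 10^stats::runif(sum(nc), -5, -3.2)
  cat$del_gerp <- cat$del_gwava <- cat$del_cadd <- FALSE
  cat[cat$class == "nc_del", c("del_gerp", "del_gwava", "del_cadd")] <- TRUE
  # coding sites get scattered single flags (irrelevant to the coding
  # selectors, exercises the three-flag rule)
  cat$del_gerp[cat$class == "coding"] <- stats::runif(sum(cat$class == "coding")) < 0.3
  cat$qual_metric <- pmax(stats::rnorm(n, config$qual_mean, config$qual_sd), 0.5)
  cat$pass_flag <- TRUE
  cat
}

# Per-feature carrier rates for a class, honouring planted risk genes.
class_rates <- function(config, layout, class, cohort) {
  if (class %in% c("nc_del", "nc_ben")) {
    n <- config$n_segments
    base <- if (class == "nc_del") config$noncoding_del_rate else
      config$noncoding_benign_rate
    return(stats::setNames(rep(base, n), layout$segments$id))
  }
  n <- config$n_genes
  base <- switch(class,
                 coding = config$background_carrier_rate,
                 syn = config$syn_carrier_rate,
                 common = config$common_carrier_rate)
  r <- stats::setNames(rep(base, n), layout$genes$id)
  if (class == "coding" && nrow(config$risk_genes) > 0) {
    rg <- config$risk_genes
    r[rg$gene_id] <- if (cohort == "case") rg$case_rate else rg$control_rate
  }
  r
}

# Carrier-level genotype simulation: each carrier receives one het allele
# at one candidate site of the feature/class (rare-variant regime; hom-alt
# genotypes are effectively unobserved at AF <= 0.01).
sim_class_doses <- function(rates, n_samples, cat_rows_by_feature, doses) {
  feats <- names(rates)
  carrier <- matrix(stats::rbinom(length(feats) * n_samples, 1L,
                                  rep(rates, n_samples)),
                    nrow = length(feats))
  hit <- which(carrier == 1L, arr.ind = TRUE)
  if (nrow(hit) > 0) {
    rows_list <- cat_rows_by_feature[feats[hit[, 1]]]
    k <- lengths(rows_list)
    pick <- floor(stats::runif(nrow(hit)) * k) + 1L
    site_row <- unlist(rows_list, use.names = FALSE)[cumsum(k) - k + pick]
    doses[cbind(site_row, hit[, 2])] <- 1L
  }
  doses
}

#' Simulate a case/control burden-testing cohort
#'
#' Generates, in memory, an annotated case cohort with genotype doses, an
#' in-house control cohort with genotypes, a summary-only control cohort
#' (AC/AN), the feature layout and coverage masks. The carrier model is
#' per-feature and per-class: each sample carries a qualifying variant of
#' a class with the configured rate, planted risk genes elevate the coding
#' rate in cases only, and (when `artifact_rate > 0`) a fraction of genes
#' receives a case-only low-quality synonymous site emulating a
#' genotyping-artifact tranche. Summary controls carry
#' `AC =` simulated carrier alleles and `AN = 2 * n_control_summary`.
#'
#' Use [write_burden_cohort()] to materialise the VCF/BED/bedGraph files.
#'
#' @param config A [simulation_config()].
#' @return A `burden_sim` list: `case`, `inhouse` (`case_cohort`
#'   objects), `summary` (control site data.frame), `layout`, and `truth`
#'   (risk genes, artifact sites, full site catalog).
#' @export
simulate_burden_cohort <- function(config) {
  set_substream(config, "burden/layout")
  layout <- simulate_feature_layout(config)
  set_substream(config, "burden/catalog")
  cat <- build_site_catalog(config, layout)

  # artifact sites: case-only synonymous, quality in the extreme low tail
  set_substream(config, "burden/artifacts")
  art <- NULL
  if (config$artifact_rate > 0) {
    g <- layout$genes
    is_art <- stats::runif(length(g)) < config$artifact_gene_fraction
    if (any(is_art)) {
      qcap <- 0.5 * stats::qnorm(config$artifact_quantile, config$qual_mean,
                                 config$qual_sd)
      art <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(g))[is_art],
        pos = GenomicRanges::start(g)[is_art] + 11L,
        feature_id = g$id[is_art], class = "syn_artifact",
        consequence = "synonymous", ref = "A", alt = "G",
        pop_af = 10^stats::runif(sum(is_art), -5, -2.2),
        del_gerp = FALSE, del_gwava = FALSE, del_cadd = FALSE,
        qual_metric = stats::runif(sum(is_art), 0.01, max(qcap, 0.02)),
        pass_flag = TRUE, stringsAsFactors = FALSE)
    }
  }
  cat_all <- rbind(cat, art)
  o <- order(cat_all$chrom, cat_all$pos)
  cat_all <- cat_all[o, , drop = FALSE]
  rownames(cat_all) <- NULL

  rows_by <- function(classes) {
    idx <- which(cat_all$class %in% classes)
    split(idx, cat_all$feature_id[idx])
  }
  sim_cohort <- function(n_samples, cohort, stream, prefix) {
    set_substream(config, stream)
    doses <- matrix(0L, nrow(cat_all), n_samples)
    for (cl in c("coding", "syn", "common", "nc_del", "nc_ben")) {
      doses <- sim_class_doses(class_rates(config, layout, cl, cohort),
                               n_samples, rows_by(cl), doses)
    }
    if (cohort == "case" && !is.null(art)) {
      art_rows <- which(cat_all$class == "syn_artifact")
      art_car <- matrix(stats::rbinom(length(art_rows) * n_samples, 1L,
                                      config$artifact_rate),
                        nrow = length(art_rows))
      doses[art_rows, ] <- pmax(doses[art_rows, , drop = FALSE], art_car)
    }
    keep <- rowSums(doses) > 0
    v <- cat_all[keep, c("chrom", "pos", "ref", "alt", "qual_metric",
                         "pass_flag", "pop_af", "consequence", "del_gerp",
                         "del_gwava", "del_cadd", "feature_id", "class")]
    rownames(v) <- NULL
    samples <- sprintf("%s%03d", prefix, seq_len(n_samples))
    structure(list(samples = samples, variants = v,
                   doses = matrix(doses[keep, ], ncol = n_samples,
                                  dimnames = list(NULL, samples))),
              class = "case_cohort")
  }
  case <- sim_cohort(config$n_case, "case", "burden/case", "ICE")
  inhouse <- sim_cohort(config$n_control_inhouse, "control",
                        "burden/inhouse", "CTL")

  # summary controls: per-feature carrier-allele counts split over sites
  set_substream(config, "burden/summary")
  ac <- integer(nrow(cat_all))
  for (cl in c("coding", "syn", "common", "nc_del", "nc_ben")) {
    rates <- class_rates(config, layout, cl, "control")
    rows <- rows_by(cl)
    counts <- stats::rbinom(length(rates), config$n_control_summary, rates)
    names(counts) <- names(rates)
    for (f in names(rows)[counts[names(rows)] > 0]) {
      r <- rows[[f]]
      ac[r] <- ac[r] + tabulate(
        floor(stats::runif(counts[f]) * length(r)) + 1L, length(r))
    }
  }
  keep <- ac > 0
  summary_sites <- cbind(
    cat_all[keep, c("chrom", "pos", "ref", "alt", "pop_af", "consequence",
                    "del_gerp", "del_gwava", "del_cadd", "feature_id",
                    "class")],
    data.frame(control_ac = ac[keep],
               control_an = 2L * config$n_control_summary))
  rownames(summary_sites) <- NULL

  truth <- list(
    risk_genes = config$risk_genes,
    artifact_sites = art,
    site_catalog = cat_all)
  structure(list(config = config, layout = layout, case = case,
                 inhouse = inhouse, summary = summary_sites,
                 truth = truth),
            class = "burden_sim")
}

write_bed_file <- function(gr, path, name = NULL) {
  df <- data.frame(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
  if (!is.null(name)) df[[4]] <- name
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

write_bedgraph_file <- function(gr, path) {
  data.table::fwrite(
    data.frame(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
               gr$score),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a simulated burden cohort to standard formats
#'
#' Emits `case.vcf`, `inhouse.vcf`, `controls.vcf` (summary AC/AN),
#' `genes.bed`, `segments.bed`, `lcr.bed`, the two coverage bedGraph
#' tracks, and TSV truth tables.
#'
#' @param sim A `burden_sim` from [simulate_burden_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_burden_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  contigs <- sim$config$contigs
  p <- list(
    case_vcf = file.path(dir, "case.vcf"),
    inhouse_vcf = file.path(dir, "inhouse.vcf"),
    control_vcf = file.path(dir, "controls.vcf"),
    genes_bed = file.path(dir, "genes.bed"),
    segments_bed = file.path(dir, "segments.bed"),
    lcr_bed = file.path(dir, "lcr.bed"),
    coverage_case = file.path(dir, "coverage_case.bedgraph"),
    coverage_control = file.path(dir, "coverage_control.bedgraph"),
    risk_genes = file.path(dir, "truth_risk_genes.tsv"))
  write_case_vcf(sim$case, p$case_vcf, contigs = contigs)
  write_case_vcf(sim$inhouse, p$inhouse_vcf, contigs = contigs)
  write_control_sites(sim$summary, p$control_vcf, contigs = contigs)
  write_bed_file(sim$layout$genes, p$genes_bed, sim$layout$genes$id)
  write_bed_file(sim$layout$segments, p$segments_bed,
                 paste(sim$layout$segments$id,
                       sim$layout$segments$feature_class, sep = "|"))
  write_bed_file(sim$layout$lcr, p$lcr_bed)
  write_bedgraph_file(sim$layout$coverage_case, p$coverage_case)
  write_bedgraph_file(sim$layout$coverage_control, p$coverage_control)
  data.table::fwrite(sim$truth$risk_genes, p$risk_genes, sep = "\t")
  invisible(p)
}

#' Simulate genome-wide per-sample variant positions at class-level rates
#'
#' Draws, for every sample and every feature class, a Poisson number of
#' variant positions at the configured per-Mb rate, uniformly placed
#' within the class's intervals. Input for [mutations_per_mb()].
#'
#' @param config A [simulation_config()].
#' @param classes Named `GRangesList`-like list of class intervals
#'   (defaults to the layout's coding genes plus segment classes).
#' @param rates Named per-Mb rates; defaults to
#'   `config$mutation_rates_per_mb`.
#' @return data.frame (sample, class, chrom, pos).
#' @export
simulate_mutation_positions <- function(config, classes = NULL,
                                        rates = NULL) {
  set_substream(config, "burden/mutrates")
  if (is.null(classes)) {
    layout <- simulate_feature_layout(config)
    classes <- split(layout$segments, layout$segments$feature_class)
    classes <- c(list(coding_gene = layout$genes), as.list(classes))
  }
  if (is.null(rates)) rates <- config$mutation_rates_per_mb
  classes <- classes[names(classes) %in% names(rates)]
  out <- list()
  for (cl in names(classes)) {
    gr <- classes[[cl]]
    len <- sum(GenomicRanges::width(gr))
    lambda <- rates[[cl]] * len / 1e6
    counts <- stats::rpois(config$n_case, lambda)
    tot <- sum(counts)
    if (tot == 0) next
    offs <- floor(stats::runif(tot) * len)
    cum <- cumsum(GenomicRanges::width(gr))
    iv <- findInterval(offs, c(0, cum[-length(cum)] ))
    pos <- GenomicRanges::start(gr)[iv] + (offs - c(0, cum)[iv])
    out[[cl]] <- data.frame(
      sample = rep(sprintf("ICE%03d", seq_len(config$n_case)), counts),
      class = cl,
      chrom = as.character(GenomicRanges::seqnames(gr))[iv],
      pos = as.integer(pos), stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
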