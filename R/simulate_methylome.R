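#' Simulate case/control bisulfite methylomes
#'
#' Generates per-CpG methylated/unmethylated counts for
#' `n_meth_case + n_meth_control` samples over a CpG grid on the toy
#' genome. Three kinds of territory are planted in non-overlapping
#' blocks:
#'
#' * background CpGs at `background_beta` (default 0.85);
#' * `n_hmr_blocks` hypomethylated blocks at `hmr_beta` (default 0.10),
#'   each present in a random per-block fraction of samples drawn from
#'   `hmr_presence_range` — these create the recurrent-HMR landscape;
#' * `n_dmr_regions` differential regions at `dmr_base_beta` (0.35) in
#'   every sample (so they are hypomethylated relative to background and
#'   enter the recurrent-region candidate set), with the case-group mean
#'   shifted by `dmr_effect`; each region is hypomethylated in cases with
#'   probability `meth_hypo_fraction`, otherwise the shift flips sign.
#'
#' Per sample and block, a Gaussian biological effect (`region_sd`) is
#' added on the beta scale; per CpG, depth is Poisson(`depth_mean`) and
#' the methylated count is beta-binomial with overdispersion
#' `overdispersion` (0 = binomial).
#'
#' @param config A [simulation_config()].
#' @return A `methylome_sim` list: `case`, `control` (lists of
#'   `methylome_sample`), `truth` (list with `hmr_blocks` and
#'   `dmr_regions` data.frames).
#' @export
simulate_methylomes <- function(config) {
  set_substream(config, "meth/layout")
  chrom <- config$meth_contig
  pos <- as.integer(seq(1001L, config$meth_contig_length - 1000L,
                        by = config$cpg_spacing))
  n_cpg <- length(pos)
  bl_cpg <- config$hmr_block_cpgs
  gap_cpg <- 8L
  slot <- bl_cpg + gap_cpg
  n_slots <- floor(n_cpg / slot)
  n_blocks <- config$n_hmr_blocks + config$n_dmr_regions
  stopifnot(n_blocks <= n_slots)
  chosen <- sort(sample.int(n_slots, n_blocks))
  kind <- sample(rep(c("hmr", "dmr"),
                     c(config$n_hmr_blocks, config$n_dmr_regions)))
  # CpG index ranges of each block (leave the gap at the end of the slot)
  first <- (chosen - 1L) * slot + 1L
  last <- first + bl_cpg - 1L
  block <- integer(n_cpg)  # 0 = background, else block index
  for (b in seq_len(n_blocks)) block[first[b]:last[b]] <- b

  is_hmr <- kind == "hmr"
  presence <- stats::runif(n_blocks, config$hmr_presence_range[1],
                           config$hmr_presence_range[2])
  presence[!is_hmr] <- NA_real_
  hypo <- stats::runif(n_blocks) < config$meth_hypo_fraction
  effect <- ifelse(hypo, config$dmr_effect, -config$dmr_effect)
  effect[is_hmr] <- NA_real_

  # regulatory and CpG-context annotation of each block: most recurrent
  # HMR territory lies outside islands/shores/shelves, and promoters
  # dominate the regulatory groups
  set_substream(config, "meth/annot")
  ann_group <- sample(c("promoter", "enhancer", "dyadic", "none"),
                      n_blocks, replace = TRUE,
                      prob = c(0.40, 0.35, 0.05, 0.20))
  cgi <- sample(c("cgi_island", "cgi_shore", "cgi_shelf", "open_sea"),
                n_blocks, replace = TRUE,
                prob = c(0.15, 0.05, 0.03, 0.77))
  truth_blocks <- data.frame(
    block_id = sprintf("block_%04d", seq_len(n_blocks)),
    kind = kind, chrom = chrom,
    start = pos[first], end = pos[last],
    n_cpg = bl_cpg, presence = presence, effect = effect,
    annotation_group = ann_group, cgi_context = cgi,
    stringsAsFactors = FALSE)
  block_gr <- function(sel) {
    if (!any(sel)) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(chrom, IRanges::IRanges(
      pmax(1L, pos[first[sel]] - 50L), pos[last[sel]] + 50L))
  }
  annotations <- list(
    promoter = block_gr(ann_group == "promoter"),
    enhancer = block_gr(ann_group == "enhancer"),
    dyadic = block_gr(ann_group == "dyadic"),
    cgi_island = block_gr(cgi == "cgi_island"),
    cgi_shore = block_gr(cgi == "cgi_shore"),
    cgi_shelf = block_gr(cgi == "cgi_shelf"))

  # toy gene models: every promoter-annotated block anchors a gene whose
  # exon and intron trail it
  prom_idx <- which(ann_group == "promoter")
  gene_names <- sprintf("mgene_%04d", seq_along(prom_idx))
  gene_parts <- feature_set(
    GenomicRanges::GRanges(chrom, IRanges::IRanges(
      c(pos[first[prom_idx]], pos[last[prom_idx]] + 60L,
        pos[last[prom_idx]] + 261L),
      c(pos[last[prom_idx]] + 50L, pos[last[prom_idx]] + 260L,
        pos[last[prom_idx]] + 460L))),
    id = rep(gene_names, 3), name = rep(gene_names, 3),
    feature_class = rep(c("promoter", "exon", "intron"),
                        each = length(prom_idx)))
  # gene sets over the toy universe: one set concentrated on genes whose
  # promoter block is a planted differential region, the rest random
  dmr_genes <- gene_names[kind[prom_idx] == "dmr"]
  gene_sets <- list(
    planted_hypo_promoters = sample(dmr_genes,
                                    min(40, length(dmr_genes))))
  for (k in 2:10) {
    gene_sets[[sprintf("random_set_%02d", k)]] <-
      sample(gene_names, min(40, length(gene_names)))
  }

  rho <- config$overdispersion
  sim_sample <- function(sid, is_case, stream) {
    set_substream(config, stream)
    # per-block means for this sample
    m_block <- rep(config$background_beta, n_blocks)
    m_block[is_hmr] <- ifelse(stats::runif(sum(is_hmr)) < presence[is_hmr],
                              config$hmr_beta, config$background_beta)
    m_block[!is_hmr] <- config$dmr_base_beta +
      if (is_case) effect[!is_hmr] else 0
    m_block <- m_block + stats::rnorm(n_blocks, 0, config$region_sd)
    m_block <- pmin(pmax(m_block, 0.01), 0.99)
    mu <- rep(config$background_beta, n_cpg)
    mu[block > 0] <- m_block[block[block > 0]]
    depth <- stats::rpois(n_cpg, config$depth_mean)
    if (rho > 0) {
      a <- mu * (1 - rho) / rho
      b <- (1 - mu) * (1 - rho) / rho
      p <- stats::rbeta(n_cpg, a, b)
    } else {
      p <- mu
    }
    meth <- stats::rbinom(n_cpg, depth, p)
    structure(list(sample_id = sid,
                   records = data.frame(chrom = chrom, pos = pos,
                                        meth = meth,
                                        unmeth = depth - meth)),
              class = "methylome_sample")
  }
  case <- lapply(seq_len(config$n_meth_case), function(i)
    sim_sample(sprintf("MCASE%03d", i), TRUE, sprintf("meth/case/%03d", i)))
  control <- lapply(seq_len(config$n_meth_control), function(i)
    sim_sample(sprintf("MCTL%03d", i), FALSE, sprintf("meth/ctl/%03d", i)))

  truth <- list(hmr_blocks = truth_blocks[truth_blocks$kind == "hmr", ],
                dmr_regions = truth_blocks[truth_blocks$kind == "dmr", ])
  rownames(truth$hmr_blocks) <- rownames(truth$dmr_regions) <- NULL
  structure(list(config = config, case = case, control = control,
                 annotations = annotations, gene_parts = gene_parts,
                 gene_sets = gene_sets, truth = truth),
            class = "methylome_sim")
}

#' Write simulated methylomes as Bismark coverage files
#'
#' @param sim A `methylome_sim`.
#' @param dir Output directory; files are named `<sample_id>.cov` and the
#'   truth tables are emitted alongside.
#' @return Named list with `case`, `control` path vectors and truth
#'   paths, invisibly.
#' @export
write_methylomes <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(samples) vapply(samples, function(s) {
    f <- file.path(dir, paste0(s$sample_id, ".cov"))
    write_bismark_cov(s, f)
    f
  }, character(1))
  p <- list(case = emit(sim$case), control = emit(sim$control),
            hmr_truth = file.path(dir, "truth_hmr_blocks.tsv"),
            dmr_truth = file.path(dir, "truth_dmr_regions.tsv"),
            gene_parts = file.path(dir, "gene_parts.bed"),
            gene_sets = file.path(dir, "gene_sets.gmt"))
  data.table::fwrite(sim$truth$hmr_blocks, p$hmr_truth, sep = "\t")
  data.table::fwrite(sim$truth$dmr_regions, p$dmr_truth, sep = "\t")
  for (grp in names(sim$annotations)) {
    f <- file.path(dir, paste0("annot_", grp, ".bed"))
    write_bed_file(sim$annotations[[grp]], f)
    p[[paste0("annot_", grp)]] <- f
  }
  write_bed_file(sim$gene_parts, p$gene_parts,
                 paste(sim$gene_parts$name, sim$gene_parts$feature_class,
                       sep = "|"))
  writeLines(vapply(names(sim$gene_sets), function(s)
    paste(c(s, "synthetic", sim$gene_sets[[s]]), collapse = "\t"),
    character(1)), p$gene_sets)
  invisible(p)
}
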