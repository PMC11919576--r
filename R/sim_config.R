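#' Configuration for the synthetic cohort generator
#'
#' Bundles every tunable of the synthetic case/control cohort: cohort
#' sizes, the toy genome, per-gene carrier rates, planted risk genes,
#' quality-tranche artifacts, CNV truth/noise, and the methylome noise
#' model. Defaults emulate the structure of a rare-disease WGS + methylome
#' cohort study: 51 sequenced cases against 350 in-house controls with
#' genotypes and 9197 summary-level controls (AC/AN only), 48 case vs 45
#' control methylomes, and planted case-hypomethylation making up 90% of
#' differential effects.
#'
#' All randomness flows from `seed` through named substreams (one per
#' generated component), so regenerating one component does not disturb
#' the others and identical configs give byte-identical outputs.
#'
#' @param seed Integer root seed.
#' @param n_case Case samples with genotypes (default 51).
#' @param n_control_inhouse Control samples with genotypes (default 350).
#' @param n_control_summary Summary-only control count (default 9197);
#'   controls of this cohort are never materialised as genotypes, only
#'   AC/AN summaries are emitted.
#' @param contigs Named vector of toy-genome contig lengths.
#' @param n_genes Number of tiled genes.
#' @param gene_length Gene body length in bp.
#' @param n_segments Number of noncoding regulatory segments (classes
#'   cycle over promoter, enhancer, UTRs, lncRNA, lncRNA promoter, miRNA,
#'   small RNA).
#' @param sites_per_class Candidate rare-variant positions per gene and
#'   variant class.
#' @param background_carrier_rate Per-gene per-sample probability of
#'   carrying a rare coding-altering qualifying variant (default 0.01).
#' @param syn_carrier_rate Per-gene rare synonymous carrier rate (default
#'   0.2), the benign class used for inflation calibration.
#' @param noncoding_del_rate,noncoding_benign_rate Per-segment carrier
#'   rates for deleterious (all three algorithms) and benign noncoding
#'   rare variants.
#' @param common_carrier_rate Carrier rate at the one common
#'   (`pop_af > 0.01`) site per gene, identical in both cohorts.
#' @param risk_genes `data.frame(gene_id, case_rate, control_rate)` of
#'   planted risk genes; default plants three genes at case rate 0.3 vs
#'   control rate 0.01.
#' @param artifact_quantile,artifact_rate,artifact_gene_fraction Artifact
#'   model for calibration tests: genes receive (with probability
#'   `artifact_gene_fraction`) one case-only synonymous site carried at
#'   `artifact_rate`, whose site quality falls in the lowest
#'   `artifact_quantile` tail of the genuine quality distribution.
#'   `artifact_rate = 0` (default) disables injection.
#' @param qual_mean,qual_sd Normal parameters of the genuine site
#'   quality-by-depth metric.
#' @param n_cnv_regions,cnv_length,cnv_freq_range,cnv_del_fraction,cnv_control_freq
#'   CNV truth model: region count, length (bp), case carrier-frequency
#'   range, fraction of deletions, control carrier frequency.
#' @param cnv_jitter_sd,cnv_fn_rate,cnv_fp_rate,cnv_fp_length_range CNV
#'   caller noise: boundary jitter sd (bp), per-caller false-negative
#'   rate, Poisson false-positive count per sample per caller, and FP
#'   call length range.
#' @param n_meth_case,n_meth_control Methylome cohort sizes (48 vs 45).
#' @param meth_contig,meth_contig_length,cpg_spacing Methylome toy genome.
#' @param background_beta Background CpG methylation level (default 0.85).
#' @param hmr_beta Methylation level inside hypomethylated blocks (0.10).
#' @param dmr_base_beta Control-group level of planted differential
#'   regions (0.35, low enough that they are HMRs and hence enter the
#'   recurrent-region candidate set).
#' @param overdispersion Beta-binomial overdispersion rho in \[0, 1);
#'   0 degenerates to binomial sampling.
#' @param depth_mean Mean of the Poisson per-CpG read depth.
#' @param n_hmr_blocks,hmr_block_cpgs,hmr_presence_range Planted
#'   null hypomethylated blocks: count, CpGs per block, and the range the
#'   per-block sample-presence fraction is drawn from.
#' @param n_dmr_regions Number of planted differential regions.
#' @param dmr_effect Case-minus-control shift of planted differential
#'   regions (default -0.20).
#' @param meth_hypo_fraction Fraction of planted effects that are
#'   hypomethylation (default 0.90); the rest flip sign.
#' @param region_sd Per-sample per-region biological noise sd on the beta
#'   scale (default 0.05).
#' @param mutation_rates_per_mb Named per-class mutation rates (per Mb)
#'   for [simulate_mutation_positions()].
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    seed = 1L,
    n_case = 51L, n_control_inhouse = 350L, n_control_summary = 9197L,
    contigs = c(chr1 = 5e6, chr2 = 5e6),
    n_genes = 1000L, gene_length = 2000L, n_segments = 200L,
    sites_per_class = 5L,
    background_carrier_rate = 0.01, syn_carrier_rate = 0.2,
    noncoding_del_rate = 0.01, noncoding_benign_rate = 0.1,
    common_carrier_rate = 0.1,
    risk_genes = NULL,
    artifact_quantile = 0.05, artifact_rate = 0,
    artifact_gene_fraction = 0.35,
    qual_mean = 20, qual_sd = 4,
    n_cnv_regions = 30L, cnv_length = 5000L,
    cnv_freq_range = c(0.1, 0.8), cnv_del_fraction = 0.77,
    cnv_control_freq = 0.02,
    cnv_jitter_sd = 50, cnv_fn_rate = 0.1, cnv_fp_rate = 1,
    cnv_fp_length_range = c(2000, 10000),
    n_meth_case = 48L, n_meth_control = 45L,
    meth_contig = "chr1", meth_contig_length = 3e6, cpg_spacing = 60L,
    background_beta = 0.85, hmr_beta = 0.10, dmr_base_beta = 0.35,
    overdispersion = 0.05, depth_mean = 30,
    n_hmr_blocks = 300L, hmr_block_cpgs = 12L,
    hmr_presence_range = c(0.05, 0.8),
    n_dmr_regions = 300L, dmr_effect = -0.2, meth_hypo_fraction = 0.9,
    region_sd = 0.05,
    mutation_rates_per_mb = c(coding_gene = 14.70, promoter = 15.15,
                              enhancer = 16.47, miRNA = 19.83,
                              smallRNA = 20.46)) {
  if (is.null(risk_genes)) {
    risk_genes <- data.frame(
      gene_id = sprintf("gene_%04d", c(101L, 402L, 803L)),
      case_rate = 0.3, control_rate = 0.01)
  }
  cfg <- as.list(environment())
  rates <- c(background_carrier_rate, syn_carrier_rate, noncoding_del_rate,
             noncoding_benign_rate, common_carrier_rate, artifact_rate,
             artifact_quantile, cnv_freq_range, cnv_control_freq,
             cnv_fn_rate, cnv_del_fraction, background_beta, hmr_beta,
             dmr_base_beta, overdispersion, meth_hypo_fraction,
             if (nrow(risk_genes)) c(risk_genes$case_rate,
                                     risk_genes$control_rate))
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  counts <- c(n_case, n_control_inhouse, n_control_summary, n_genes,
              n_segments, sites_per_class, n_meth_case, n_meth_control)
  if (any(counts <= 0)) stop("all cohort/feature counts must be positive")
  class(cfg) <- "simulation_config"
  cfg
}

# Deterministic substream seed derived from the root seed and a name.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587)
}

set_substream <- function(config, name) {
  set.seed(substream_seed(config$seed, name))
}
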