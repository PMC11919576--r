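# internal: fraction of samples whose (focal) HMRs overlap each region
region_hmr_fraction <- function(regions, hmrs, n_samples,
                                focal_max = 10000) {
  if (nrow(regions) == 0) return(numeric(0))
  hmrs <- hmrs[hmrs$end - hmrs$start + 1 <= focal_max, , drop = FALSE]
  if (nrow(hmrs) == 0) return(numeric(nrow(regions)))
  rgr <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(regions$start, regions$end))
  hgr <- GenomicRanges::GRanges(hmrs$chrom,
                                IRanges::IRanges(hmrs$start, hmrs$end))
  hits <- GenomicRanges::findOverlaps(rgr, hgr, ignore.strand = TRUE)
  frac <- vapply(split(hmrs$sample_id[S4Vectors::subjectHits(hits)],
                       factor(S4Vectors::queryHits(hits),
                              seq_len(nrow(regions)))),
                 function(x) length(unique(x)) / n_samples, numeric(1))
  as.vector(frac)
}

#' Run the burden-testing stage on a simulated (or assembled) cohort
#'
#' Applies the callable-mask and low-complexity filters to both cohorts,
#' calibrates the quality tranche on the benign synonymous stratum,
#' applies the chosen tranche and runs the coding and noncoding burden
#' scans, plus the variant-sharing summary.
#'
#' @param sim A `burden_sim` (or a list with the same members).
#' @param tranche_grid Quality-inclusion grid for [calibration_sweep()].
#' @param alpha Family-wise error target for Bonferroni flags.
#' @param required_fraction Callable-mask coverage fraction.
#' @return List: `mask`, `calibration`, `coding`, `noncoding`,
#'   `benign_qq` (QQ table at the chosen tranche), `sharing`.
#' @export
run_burden_stage <- function(sim, tranche_grid = c(0.9, 0.95, 1),
                             alpha = 0.05, required_fraction = 0.9) {
  layout <- sim$layout
  n_sum <- sim$config$n_control_summary
  mask <- build_callable_mask(layout$coverage_case, layout$coverage_control,
                              required_fraction)
  case <- apply_region_filters(sim$case, mask, layout$lcr)
  ctl <- apply_region_filters(sim$summary, mask, layout$lcr)

  calib <- calibration_sweep(case, ctl, layout$genes, n_sum,
                             tranche_grid = tranche_grid, mode = "coding")
  tranche <- if (is.na(calib$chosen_tranche)) 1 else calib$chosen_tranche
  thr <- stats::quantile(case$variants$qual_metric, 1 - tranche, type = 7,
                         names = FALSE)
  kept <- subset_variants(case, case$variants$qual_metric >= thr)

  coding_case <- subset_variants(kept, select_qualifying_coding(kept$variants))
  coding_ctl <- subset_variants(ctl, select_qualifying_coding(ctl))
  coding <- burden_scan(coding_case, coding_ctl, layout$genes, n_sum,
                        alpha = alpha)
  nc_case <- subset_variants(kept, select_qualifying_noncoding(kept$variants))
  nc_ctl <- subset_variants(ctl, select_qualifying_noncoding(ctl))
  noncoding <- burden_scan(nc_case, nc_ctl, layout$segments, n_sum,
                           alpha = alpha)
  benign_case <- subset_variants(kept, select_benign(kept$variants, "coding"))
  benign_ctl <- subset_variants(ctl, select_benign(ctl, "coding"))
  benign <- burden_scan(benign_case, benign_ctl, layout$genes, n_sum)

  list(mask = mask, calibration = calib, tranche = tranche,
       coding = coding, noncoding = noncoding,
       benign_qq = attr(benign, "qq"),
       sharing = variant_sharing_summary(coding_case))
}

#' Run the CNV consensus stage
#'
#' Per-sample two-caller consensus, cross-sample recurrent regions, gene
#' annotation and case/control region-frequency comparison.
#'
#' @param sim A `cnv_sim`.
#' @param genes Feature-set `GRanges` for annotation (defaults to none).
#' @param min_reciprocal Reciprocal-overlap threshold (default 0.5).
#' @return List: `consensus_case`, `consensus_control`, `regions` (the
#'   Table-1-style region table with patient frequency, length, genes,
#'   p/q against controls).
#' @export
run_cnv_stage <- function(sim, genes = NULL, min_reciprocal = 0.5) {
  split_caller <- function(calls) split(calls, calls$caller)
  cc <- split_caller(sim$calls_case)
  consensus_case <- consensus_intersect(cc$A, cc$B, min_reciprocal)
  regions <- cluster_across_samples(consensus_case, min_reciprocal)
  consensus_control <- NULL
  if (!is.null(sim$calls_control)) {
    ctl <- split_caller(sim$calls_control)
    consensus_control <- consensus_intersect(ctl$A, ctl$B, min_reciprocal)
    ctl_support <- count_region_support(regions, consensus_control,
                                        min_reciprocal)
    cmp <- compare_region_frequencies(
      regions$patient_frequency, sim$config$n_case,
      ctl_support, sim$config$n_control_inhouse)
    regions$control_frequency <- ctl_support
    regions$p <- cmp$p; regions$q <- cmp$q
    regions$significant <- cmp$significant
  }
  if (!is.null(genes)) regions <- annotate_regions(regions, genes)
  list(consensus_case = consensus_case,
       consensus_control = consensus_control, regions = regions)
}

#' Run the methylome differential stage
#'
#' Coverage-filters every sample, calls HMRs, scans for recurrent
#' regions (jointly and in cases only), annotates regulatory and CpG
#' context, tests every recurrent region for differential methylation,
#' selects recurrent case-hypomethylated regions, maps DMRs to genes and
#' runs set enrichment.
#'
#' @param sim A `methylome_sim`.
#' @param min_coverage Per-CpG coverage filter (default 5).
#' @param beta_max,min_cpg,max_gap HMR-calling parameters
#'   (see [call_hmrs_simple()]).
#' @param window,min_fraction,focal_max Recurrence-scan parameters.
#' @param alpha_q DMR significance level.
#' @param min_recurrence,max_delta Selection thresholds for recurrent
#'   differential regions.
#' @return List: `hmrs`, `recurrent` (annotated, with case/all
#'   recurrence, deltas and DMR flags), `dmr`, `selected`, `dmgs`,
#'   `enrichment`, `summary` (named numerics: counts and fractions).
#' @export
run_methylome_stage <- function(sim, min_coverage = 5, beta_max = 0.5,
                                min_cpg = 4, max_gap = 500, window = 100,
                                min_fraction = 0.05, focal_max = 10000,
                                alpha_q = 0.05, min_recurrence = 0.10,
                                max_delta = -0.1) {
  all_samples <- c(sim$case, sim$control)
  filtered <- lapply(all_samples, filter_coverage, min_reads = min_coverage)
  case_ids <- vapply(sim$case, `[[`, character(1), "sample_id")
  control_ids <- vapply(sim$control, `[[`, character(1), "sample_id")
  hmrs <- do.call(rbind, lapply(filtered, call_hmrs_simple,
                                beta_max = beta_max, min_cpg = min_cpg,
                                max_gap = max_gap))
  n_all <- length(filtered)
  recurrent <- recurrence_scan(hmrs, n_all, window = window,
                               min_fraction = min_fraction,
                               focal_max = focal_max)
  recurrent <- classify_hmr_context(recurrent, sim$annotations)
  case_hmrs <- hmrs[hmrs$sample_id %in% case_ids, , drop = FALSE]
  recurrent$case_fraction <- region_hmr_fraction(recurrent, case_hmrs,
                                                 length(case_ids),
                                                 focal_max)
  mat <- region_methylation_matrix(recurrent, filtered)
  dmr <- dmr_test(mat, case_ids, control_ids, alpha_q = alpha_q)
  recurrent$delta <- dmr$delta[match(recurrent$region_id, dmr$region_id)]
  recurrent$q <- dmr$q[match(recurrent$region_id, dmr$region_id)]
  recurrent$is_dmr <- recurrent$region_id %in% dmr$region_id[dmr$is_dmr]
  sel_input <- recurrent
  sel_input$sample_fraction <- sel_input$case_fraction
  selected <- select_recurrent_differential(sel_input, min_recurrence,
                                            max_delta)
  dmr_regions <- recurrent[recurrent$is_dmr, , drop = FALSE]
  dmgs <- map_dmrs_to_genes(dmr_regions, sim$gene_parts)
  enrichment <- geneset_enrichment(dmgs, sim$gene_sets,
                                   unique(sim$gene_parts$name))
  dmrs_only <- dmr[dmr$is_dmr, , drop = FALSE]
  summary <- c(
    n_recurrent = nrow(recurrent),
    n_tested = nrow(dmr),
    n_dmr = sum(dmr$is_dmr),
    hypo_fraction = if (nrow(dmrs_only) > 0) hypo_fraction(dmrs_only)
    else NA_real_,
    out_of_cgi_fraction = mean(recurrent$cgi_context == "open_sea"),
    n_selected = nrow(selected),
    n_dmg = length(dmgs))
  list(hmrs = hmrs, recurrent = recurrent, dmr = dmr, selected = selected,
       dmgs = dmgs, enrichment = enrichment, summary = summary)
}

format_tsv_value <- function(v) {
  if (is.numeric(v)) paste(trimws(formatC(v, format = "g", digits = 10)),
                           collapse = ",")
  else paste(v, collapse = ",")
}

#' Write a TSV with a provenance header
#'
#' Prepends `#%`-prefixed provenance lines (package version, seed and
#' every threshold used) to a plain TSV so each output is traceable to
#' its exact run configuration; [read_provenance()] parses them back.
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param params Named list of provenance values.
#' @return `path`, invisibly.
#' @export
write_tsv_prov <- function(df, path, params = list()) {
  params <- c(list(package = "icepipe",
                   version = as.character(utils::packageVersion("icepipe"))),
              params)
  hdr <- sprintf("#%% %s=%s", names(params),
                 vapply(params, format_tsv_value, character(1)))
  con <- file(path, "w")
  writeLines(hdr, con)
  close(con)
  data.table::fwrite(df, path, sep = "\t", append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_tsv_prov
#' @return For `read_provenance`: named character list of the provenance
#'   entries of `path`.
#' @export
read_provenance <- function(path) {
  lines <- readLines(path)
  lines <- lines[startsWith(lines, "#% ")]
  kv <- sub("^#% ", "", lines)
  eq <- regexpr("=", kv, fixed = TRUE)
  stats::setNames(as.list(substring(kv, eq + 1)), substring(kv, 1, eq - 1))
}

pipeline_error <- function(class, message) {
  stop(structure(class = c(class, "icepipe_error", "error", "condition"),
                 list(message = message, call = sys.call(-1))))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Orchestrates the stages in dependency order — `simulate` (cohort
#' generation), `burden`, `cnv`, `methylome` — and writes every output
#' table under `outdir` with a provenance header carrying the seed and
#' all thresholds. Later stages require the simulation products of the
#' first stage; requesting them without `simulate` (and without passing
#' `sims`) raises a missing-input error of class
#' `icepipe_missing_input`.
#'
#' @param config A [simulation_config()].
#' @param outdir Output directory.
#' @param stages Subset of `c("simulate", "burden", "cnv", "methylome")`.
#' @param sims Optional pre-built list (`burden`, `cnv`, `methylome`)
#'   of simulation objects, to reuse instead of regenerating.
#' @param write_inputs Also materialise the simulated VCF/BED/coverage
#'   inputs under `outdir/inputs` (default `FALSE`; the analysis tables
#'   are always written).
#' @return List with the stage results and `files` (paths written),
#'   invisibly.
#' @export
run_pipeline <- function(config = simulation_config(), outdir,
                         stages = c("simulate", "burden", "cnv",
                                    "methylome"),
                         sims = NULL, write_inputs = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!inherits(config, "simulation_config")) {
    pipeline_error("icepipe_validation", "config must be a simulation_config")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(seed = config$seed)
  files <- list()
  out <- list()

  need_sims <- setdiff(stages, "simulate")
  if ("simulate" %in% stages) {
    sims <- list(burden = simulate_burden_cohort(config),
                 cnv = simulate_cnv_callsets(config),
                 methylome = simulate_methylomes(config))
    if (write_inputs) {
      files$inputs <- c(write_burden_cohort(sims$burden,
                                            file.path(outdir, "inputs")),
                        write_cnv_callsets(sims$cnv,
                                           file.path(outdir, "inputs")),
                        write_methylomes(sims$methylome,
                                         file.path(outdir, "inputs")))
    }
  } else if (length(need_sims) > 0 && is.null(sims)) {
    pipeline_error("icepipe_missing_input",
                   paste("stages", paste(need_sims, collapse = "/"),
                         "need simulated inputs: include the simulate",
                         "stage or pass `sims`"))
  }
  out$sims <- sims

  if ("burden" %in% stages) {
    res <- run_burden_stage(sims$burden)
    out$burden <- res
    p <- c(prov, list(tranche_grid = res$calibration$tranche_grid,
                      chosen_tranche = res$tranche,
                      lambda95 = res$calibration$lambda95_by_tranche))
    files$burden_coding <- write_tsv_prov(
      res$coding, file.path(outdir, "burden_coding.tsv"), p)
    files$burden_noncoding <- write_tsv_prov(
      res$noncoding, file.path(outdir, "burden_noncoding.tsv"), p)
    files$calibration <- write_tsv_prov(
      data.frame(tranche = res$calibration$tranche_grid,
                 lambda95 = res$calibration$lambda95_by_tranche),
      file.path(outdir, "calibration.tsv"), prov)
    files$qq <- write_tsv_prov(res$benign_qq,
                               file.path(outdir, "benign_qq.tsv"), p)
  }
  if ("cnv" %in% stages) {
    genes <- if (!is.null(sims$burden)) sims$burden$layout$genes
    res <- run_cnv_stage(sims$cnv, genes = genes)
    out$cnv <- res
    tab <- data.frame(Chr = res$regions$chrom,
                      Start = res$regions$start - 1L,
                      End = res$regions$end,
                      Cnvtype = res$regions$type,
                      Patient_frequency = res$regions$patient_frequency,
                      Cnv_length = res$regions$length,
                      Overlaped_genes = res$regions$overlapped_genes,
                      p = res$regions$p, q = res$regions$q)
    files$cnv_regions <- write_tsv_prov(
      tab, file.path(outdir, "cnv_regions.tsv"),
      c(prov, list(min_reciprocal = 0.5)))
  }
  if ("methylome" %in% stages) {
    res <- run_methylome_stage(sims$methylome)
    out$methylome <- res
    p <- c(prov, list(min_coverage = 5, window = 100, min_fraction = 0.05,
                      focal_max = 10000, alpha_q = 0.05,
                      min_recurrence = 0.10, max_delta = -0.1))
    files$recurrent_hmrs <- write_tsv_prov(
      res$recurrent, file.path(outdir, "recurrent_hmrs.tsv"), p)
    files$dmr <- write_tsv_prov(res$dmr, file.path(outdir, "dmr.tsv"), p)
    files$selected <- write_tsv_prov(
      res$selected, file.path(outdir, "recurrent_differential.tsv"), p)
    files$dmgs <- write_tsv_prov(
      data.frame(gene = res$dmgs), file.path(outdir, "dmgs.tsv"), p)
    files$enrichment <- write_tsv_prov(
      res$enrichment, file.path(outdir, "enrichment.tsv"), p)
  }
  out$files <- files
  invisible(out)
}
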