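test_that("generator output is byte-identical under a fixed seed", {
  cfg <- tiny_burden_config(17)
  d1 <- tempfile(); d2 <- tempfile()
  write_burden_cohort(simulate_burden_cohort(cfg), d1)
  write_burden_cohort(simulate_burden_cohort(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  mcfg <- simulation_config(seed = 17, n_meth_case = 2L,
                            n_meth_control = 2L, meth_contig_length = 2e5,
                            n_hmr_blocks = 10L, n_dmr_regions = 10L)
  m1 <- tempfile(); m2 <- tempfile()
  write_methylomes(simulate_methylomes(mcfg), m1)
  write_methylomes(simulate_methylomes(mcfg), m2)
  for (f in list.files(m1)) {
    expect_identical(unname(tools::md5sum(file.path(m1, f))),
                     unname(tools::md5sum(file.path(m2, f))),
                     info = f)
  }
})

test_that("summary-control carrier counts are binomially calibrated", {
  # background rate 0.01 against 9197 summary controls: per-gene coding
  # AC sums should average 92 within 3 standard errors
  cfg <- simulation_config(seed = 23, n_genes = 150L, n_segments = 24L,
                           n_control_inhouse = 5L, risk_genes = data.frame(
                             gene_id = character(), case_rate = numeric(),
                             control_rate = numeric()))
  sim <- simulate_burden_cohort(cfg)
  coding <- sim$summary[sim$summary$class == "coding", ]
  per_gene <- tapply(coding$control_ac, coding$feature_id, sum)
  per_gene <- c(per_gene, rep(0, cfg$n_genes - length(per_gene)))
  mu <- 9197 * 0.01
  se <- sqrt(9197 * 0.01 * 0.99 / cfg$n_genes)
  expect_lt(abs(mean(per_gene) - mu), 3 * se)
})

test_that("planted risk genes elevate case carriers as configured", {
  cfg <- tiny_burden_config(29, risk_genes = data.frame(
    gene_id = "gene_0050", case_rate = 0.5, control_rate = 0.01))
  sim <- simulate_burden_cohort(cfg)
  v <- sim$case$variants
  rows <- which(v$feature_id == "gene_0050" & v$class == "coding")
  carriers <- sum(colSums(sim$case$doses[rows, , drop = FALSE] >= 1) > 0)
  expect_lt(abs(carriers - 51 * 0.5), 3 * sqrt(51 * 0.25))
})

test_that("noiseless CNV callers reproduce the truth; FN 1 empties them", {
  cfg <- simulation_config(seed = 7, cnv_jitter_sd = 0, cnv_fn_rate = 0,
                           cnv_fp_rate = 0)
  cs <- simulate_cnv_callsets(cfg, include_controls = FALSE)
  a <- cs$calls_case[cs$calls_case$caller == "A", ]
  b <- cs$calls_case[cs$calls_case$caller == "B", ]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a[c("sample_id", "chrom", "start", "end", "type")],
                   b[c("sample_id", "chrom", "start", "end", "type")])
  key <- paste(a$chrom, a$start, a$end, a$type)
  tkey <- paste(cs$truth$chrom, cs$truth$start, cs$truth$end, cs$truth$type)
  expect_true(all(key %in% tkey))
  expect_equal(nrow(a), nrow(cs$carriers_case))

  cfg2 <- simulation_config(seed = 7, cnv_fn_rate = 1, cnv_fp_rate = 0)
  cs2 <- simulate_cnv_callsets(cfg2, include_controls = FALSE)
  expect_equal(nrow(cs2$calls_case), 0)
})

test_that("CNV boundary jitter follows the configured half-normal scale", {
  cfg <- simulation_config(seed = 41, cnv_jitter_sd = 50, cnv_fn_rate = 0,
                           cnv_fp_rate = 0)
  cs <- simulate_cnv_callsets(cfg, include_controls = FALSE)
  calls <- cs$calls_case
  tr <- cs$truth
  i <- match(paste(calls$chrom, calls$type), paste(tr$chrom, tr$type))
  # match each call to the truth region it overlaps
  g1 <- GenomicRanges::GRanges(calls$chrom,
                               IRanges::IRanges(calls$start, calls$end))
  g2 <- GenomicRanges::GRanges(tr$chrom, IRanges::IRanges(tr$start, tr$end))
  ov <- GenomicRanges::findOverlaps(g1, g2, select = "first")
  shift <- c(abs(calls$start - tr$start[ov]), abs(calls$end - tr$end[ov]))
  mu_half <- 50 * sqrt(2 / pi)
  se <- sqrt(50^2 * (1 - 2 / pi) / length(shift))
  expect_lt(abs(mean(shift) - mu_half), 3 * se + 0.5)  # 0.5 for rounding
})

test_that("null methylome configuration has no case/control difference", {
  cfg <- simulation_config(seed = 13, n_meth_case = 10L,
                           n_meth_control = 10L, meth_contig_length = 4e5,
                           n_hmr_blocks = 10L, n_dmr_regions = 20L,
                           dmr_effect = 0, overdispersion = 0,
                           depth_mean = 50, region_sd = 0)
  ms <- simulate_methylomes(cfg)
  mat <- region_methylation_matrix(ms$truth$dmr_regions,
                                   c(ms$case, ms$control))
  case_ids <- vapply(ms$case, `[[`, character(1), "sample_id")
  ctl_ids <- vapply(ms$control, `[[`, character(1), "sample_id")
  diffs <- rowMeans(mat[, case_ids]) - rowMeans(mat[, ctl_ids])
  expect_lt(mean(abs(diffs)), 0.02)
})

test_that("planted direction draws follow the configured hypo fraction", {
  cfg <- simulation_config(seed = 19, n_meth_case = 1L, n_meth_control = 1L,
                           meth_contig_length = 3e6, n_hmr_blocks = 10L,
                           n_dmr_regions = 100L)
  ms <- simulate_methylomes(cfg)
  n_hypo <- sum(ms$truth$dmr_regions$effect < 0)
  expect_lt(abs(n_hypo - 90), 3 * sqrt(100 * 0.9 * 0.1) + 1)
})

test_that("per-CpG mean betas match the configured background level", {
  cfg <- simulation_config(seed = 37, n_meth_case = 4L, n_meth_control = 1L,
                           meth_contig_length = 3e5, n_hmr_blocks = 2L,
                           n_dmr_regions = 2L)
  ms <- simulate_methylomes(cfg)
  planted <- c(ms$truth$hmr_blocks$start, ms$truth$dmr_regions$start)
  bg <- vapply(ms$case, function(s) {
    b <- beta_values(s)
    # restrict to background territory (outside any planted block)
    inside <- rep(FALSE, nrow(s$records))
    for (i in seq_len(nrow(ms$truth$hmr_blocks))) {
      inside <- inside | (s$records$pos >= ms$truth$hmr_blocks$start[i] &
                            s$records$pos <= ms$truth$hmr_blocks$end[i])
    }
    for (i in seq_len(nrow(ms$truth$dmr_regions))) {
      inside <- inside | (s$records$pos >= ms$truth$dmr_regions$start[i] &
                            s$records$pos <= ms$truth$dmr_regions$end[i])
    }
    mean(b[!inside], na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(bg) - 0.85), 0.01)
})

test_that("truth tables identify every planted feature exactly once", {
  cfg <- simulation_config(seed = 3, n_meth_case = 1L, n_meth_control = 1L,
                           meth_contig_length = 5e5, n_hmr_blocks = 12L,
                           n_dmr_regions = 8L)
  ms <- simulate_methylomes(cfg)
  ids <- c(ms$truth$hmr_blocks$block_id, ms$truth$dmr_regions$block_id)
  expect_equal(length(ids), 20)
  expect_false(any(duplicated(ids)))
  cs <- simulate_cnv_callsets(simulation_config(seed = 3),
                              include_controls = FALSE)
  expect_false(any(duplicated(cs$truth$region_id)))
  sim <- simulate_burden_cohort(tiny_burden_config(3))
  expect_false(any(duplicated(
    paste(sim$truth$site_catalog$chrom, sim$truth$site_catalog$pos))))
})
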