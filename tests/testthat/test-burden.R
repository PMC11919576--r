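vdf <- function(pop_af, consequence, flags = c(FALSE, FALSE, FALSE)) {
  data.frame(chrom = "chr1", pos = 100, ref = "A", alt = "G",
             qual_metric = 20, pass_flag = TRUE, pop_af = pop_af,
             consequence = consequence, del_gerp = flags[1],
             del_gwava = flags[2], del_cadd = flags[3],
             stringsAsFactors = FALSE)
}

test_that("qualifying-variant selectors apply rarity and consequence rules", {
  expect_true(select_qualifying_coding(vdf(0.009, "missense")))
  expect_true(select_qualifying_coding(vdf(0.01, "lof")))    # inclusive
  expect_false(select_qualifying_coding(vdf(0.02, "lof")))
  expect_false(select_qualifying_coding(vdf(0.005, "synonymous")))

  expect_true(select_qualifying_noncoding(vdf(5e-4, "noncoding",
                                              c(TRUE, TRUE, TRUE))))
  expect_false(select_qualifying_noncoding(vdf(5e-4, "noncoding",
                                               c(TRUE, TRUE, FALSE))))
  expect_false(select_qualifying_noncoding(vdf(2e-3, "noncoding",
                                               c(TRUE, TRUE, TRUE))))
  expect_true(select_qualifying_noncoding(vdf(0.001, "noncoding",
                                              c(TRUE, TRUE, TRUE))))

  expect_true(select_benign(vdf(0.005, "synonymous"), "coding"))
  expect_false(select_benign(vdf(0.005, "missense"), "coding"))
  expect_true(select_benign(vdf(5e-4, "noncoding"), "noncoding"))
  expect_false(select_benign(vdf(5e-4, "noncoding", c(TRUE, FALSE, FALSE)),
                             "noncoding"))
})

test_that("callable mask requires the coverage fraction in both cohorts", {
  case <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(1, 101, 201), c(100, 200, 300)), score = c(0.95, 0.95, 0.95))
  ctl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(1, 101, 201), c(100, 200, 300)), score = c(0.92, 0.85, 0.90))
  mask <- build_callable_mask(case, ctl)
  # base at 0.95/0.92 in; 0.95/0.85 out; 0.90 boundary in (inclusive)
  expect_true(IRanges::overlapsAny(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 50)),
    mask$intervals))
  expect_false(IRanges::overlapsAny(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(150, 150)),
    mask$intervals))
  expect_true(IRanges::overlapsAny(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(250, 250)),
    mask$intervals))
  expect_length(build_callable_mask(case[0], ctl[0])$intervals, 0)
  ctl2 <- GenomicRanges::GRanges("chr2", IRanges::IRanges(1, 10),
                                 score = 1)
  expect_error(build_callable_mask(case, ctl2), "chromosomes")
})

test_that("region filters keep in-mask, out-of-LCR variants", {
  doses <- matrix(1L, 3, 1, dimnames = list(NULL, "S1"))
  cc <- make_cohort("chr1", c(50, 150, 250), doses)
  mask <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 200))
  lcr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(140, 160))
  out <- apply_region_filters(cc, mask, lcr)
  expect_equal(out$variants$pos, 50)   # 150 in LCR, 250 outside mask
})

test_that("dominant-model carrier counting is per distinct sample", {
  doses <- rbind(c(1L, 0L, 0L), c(0L, 2L, 0L))
  colnames(doses) <- c("s1", "s2", "s3")
  cc <- make_cohort("chr1", c(150, 250), doses)
  genes <- feature_set(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 300)), "gA")
  res <- count_case_carriers(cc, genes)
  expect_equal(res$case_carriers, 2L)
  # carrier fraction worked example: 27 of 51 is 53%
  expect_equal(round(100 * 27 / 51), 53)
  empty <- make_cohort("chr1", integer(0),
                       matrix(0L, 0, 3, dimnames = list(NULL,
                                                        c("a", "b", "c"))))
  expect_equal(count_case_carriers(empty, genes)$case_carriers, 0L)
  # missing genotypes count as non-carriers but are reported
  doses_na <- rbind(c(NA, 1L, 0L))
  colnames(doses_na) <- c("s1", "s2", "s3")
  res2 <- count_case_carriers(make_cohort("chr1", 150, doses_na), genes)
  expect_equal(res2$case_carriers, 1L)
  expect_equal(res2$missing_calls, 1L)
})

test_that("control carriers are summed allele counts capped at N", {
  sites <- data.frame(chrom = "chr1", pos = c(150, 250), ref = "A",
                      alt = "G", control_ac = c(3L, 2L),
                      control_an = 18394L, stringsAsFactors = FALSE)
  genes <- feature_set(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 300)), "gA")
  expect_equal(estimate_control_carriers(sites, genes, 9197)$control_carriers,
               5L)
  sites$control_ac <- c(7000L, 6000L)
  expect_equal(estimate_control_carriers(sites, genes, 9197)$control_carriers,
               9197L)
  expect_equal(estimate_control_carriers(sites[0, ], genes,
                                         9197)$control_carriers, 0L)
})

test_that("one-sided Fisher reproduces printed and enumerated values", {
  expect_sigfig(fisher_one_sided(27, 24, 62, 288), 2.06e-7)
  expect_equal(fisher_one_sided(0, 51, 0, 9197), 1)
  expect_equal(fisher_one_sided(2, 1, 1, 2), 0.5)  # (9+1)/20 by enumeration
  expect_error(fisher_one_sided(-1, 5, 5, 5), "negative")
  expect_error(fisher_one_sided(0, 0, 5, 5), "margin")
})

test_that("fisher matches the enumeration oracle and is monotone in a", {
  set.seed(7)
  for (i in 1:500) {
    n <- sample(4:200, 1)
    k <- sample(1:(n - 1), 1)
    m <- sample(1:(n - 1), 1)
    a <- sample(max(0, k + m - n):min(k, m), 1)
    p <- fisher_one_sided(a, k - a, m - a, n - k - m + a)
    po <- oracle_fisher_tail(a, k - a, m - a, n - k - m + a)
    expect_lt(abs(p - po) / po, 1e-10)
  }
  # monotone: more case carriers, smaller enrichment p
  p_seq <- fisher_one_sided(0:20, 20:0, 50, 450)
  expect_true(all(diff(p_seq) <= 1e-15))
})

test_that("lambda95 is calibrated on uniform p-values and flags deflation", {
  n <- 10000
  grid <- (seq_len(n) - 0.5) / n
  expect_lt(abs(lambda95(grid) - 1), 0.01)
  set.seed(5)
  u <- stats::runif(n)
  expect_true(lambda95(u) > 0.9 && lambda95(u) < 1.1)
  expect_gt(lambda95(u / 2), 1)  # monotone deflation of p inflates chi^2
  expect_equal(lambda95(u), lambda95(sample(u)))  # order invariant
  expect_error(lambda95(rep(0.5, 5)), "at least 20")
  expect_warning(lambda95(c(rep(0.5, 30), 0)), "clipped")
})

test_that("burden scan flags planted genes and ignores feature order", {
  cfg <- tiny_burden_config(53, risk_genes = data.frame(
    gene_id = c("gene_0010", "gene_0060"), case_rate = 0.3,
    control_rate = 0.01))
  sim <- simulate_burden_cohort(cfg)
  coding_case <- subset_variants(sim$case,
                                 select_qualifying_coding(sim$case$variants))
  coding_ctl <- subset_variants(sim$summary,
                                select_qualifying_coding(sim$summary))
  scan <- burden_scan(coding_case, coding_ctl, sim$layout$genes,
                      cfg$n_control_summary)
  top2 <- scan$feature_id[1:2]
  expect_setequal(top2, c("gene_0010", "gene_0060"))
  expect_true(all(scan$significant[1:2]))
  expect_equal(scan$bonferroni_alpha[1], 0.05 / sum(scan$tested))
  # permutation invariance to feature order
  perm <- sample(seq_along(sim$layout$genes))
  scan2 <- burden_scan(coding_case, coding_ctl, sim$layout$genes[perm],
                       cfg$n_control_summary)
  expect_identical(scan, scan2, ignore_attr = TRUE)
  expect_identical(attr(scan, "qq"), attr(scan2, "qq"))
  # single-feature worked example: counts (27,24) vs (62,288)
  one <- burden_scan(
    make_cohort("chr1", 150,
                matrix(c(rep(1L, 27), rep(0L, 24)), 1,
                       dimnames = list(NULL, sprintf("s%02d", 1:51)))),
    data.frame(chrom = "chr1", pos = 150, ref = "A", alt = "G",
               control_ac = 62L, control_an = 700L),
    feature_set(GenomicRanges::GRanges("chr1",
                                       IRanges::IRanges(100, 200)), "gA"),
    control_n = 350)
  expect_true(one$significant)
  expect_sigfig(one$p_one_sided, 2.06e-7)
})

test_that("features without tested variants are reported untested, p = 1", {
  cc <- make_cohort("chr1", 150,
                    matrix(1L, 1, 2, dimnames = list(NULL, c("a", "b"))))
  genes <- feature_set(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(100, 1000), c(200, 1100))), c("gA", "gB"))
  scan <- burden_scan(cc, data.frame(chrom = "chr1", pos = 150, ref = "A",
                                     alt = "G", control_ac = 1L,
                                     control_an = 100L),
                      genes, control_n = 50)
  gB <- scan[scan$feature_id == "gB", ]
  expect_false(gB$tested)
  expect_equal(gB$p_one_sided, 1)
})

test_that("null burden p-values have a calibrated sub-0.05 fraction", {
  cfg <- tiny_burden_config(61, n_genes = 1000L, risk_genes = data.frame(
    gene_id = character(), case_rate = numeric(),
    control_rate = numeric()))
  sim <- simulate_burden_cohort(cfg)
  ben_case <- subset_variants(sim$case,
                              select_benign(sim$case$variants, "coding"))
  ben_ctl <- subset_variants(sim$summary, select_benign(sim$summary,
                                                        "coding"))
  scan <- burden_scan(ben_case, ben_ctl, sim$layout$genes,
                      cfg$n_control_summary)
  frac <- mean(scan$p_mid[scan$tested] < 0.05)
  se <- sqrt(0.05 * 0.95 / sum(scan$tested))
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("calibration sweep accepts full inclusion on clean null data", {
  cfg <- tiny_burden_config(71, n_genes = 400L)
  sim <- simulate_burden_cohort(cfg)
  res <- calibration_sweep(sim$case, sim$summary, sim$layout$genes,
                           cfg$n_control_summary, tranche_grid = 1,
                           tolerance = c(0.85, 1.15))
  expect_equal(res$chosen_tranche, 1)
  expect_true(res$lambda95_by_tranche > 0.85 &&
                res$lambda95_by_tranche < 1.15)
  none <- calibration_sweep(sim$case, sim$summary, sim$layout$genes,
                            cfg$n_control_summary, tranche_grid = 1,
                            tolerance = c(2, 3))
  expect_true(is.na(none$chosen_tranche))
  expect_match(none$diagnostic, "no tranche")
})

test_that("artifact-free cohorts always calibrate at full inclusion", {
  chosen <- vapply(1:20, function(seed) {
    cfg <- simulation_config(seed = seed, n_control_inhouse = 5L)
    sim <- simulate_burden_cohort(cfg)
    calibration_sweep(sim$case, sim$summary, sim$layout$genes,
                      cfg$n_control_summary,
                      tranche_grid = c(0.9, 0.95, 1))$chosen_tranche
  }, numeric(1))
  expect_true(all(chosen == 1))
})

test_that("mutation rates per Mb and the class comparison behave", {
  classes <- list(
    coding_gene = GenomicRanges::GRanges("chr1",
                                         IRanges::IRanges(1, 2e6)),
    promoter = GenomicRanges::GRanges("chr1",
                                      IRanges::IRanges(3e6, 5e6 - 1)))
  pos <- data.frame(sample = "s1", class = "coding_gene", chrom = "chr1",
                    pos = seq(1, 2e6, length.out = 100))
  res <- mutations_per_mb(pos, classes["coding_gene"])
  expect_equal(res$rates$mean_rate, 50)
  expect_error(mutations_per_mb(pos, list(z = GenomicRanges::GRanges())),
               "zero-length")

  set.seed(9)
  n <- 51
  sim_pos <- rbind(
    data.frame(sample = rep(sprintf("s%02d", 1:n),
                            rpois(n, 15 * 2)), class = "coding_gene"),
    data.frame(sample = rep(sprintf("s%02d", 1:n),
                            rpois(n, 20 * 2)), class = "promoter"))
  sim_pos$chrom <- "chr1"; sim_pos$pos <- 1
  res2 <- mutations_per_mb(sim_pos, classes)
  expect_lt(res2$tests$q[res2$tests$class == "promoter"], 0.05)

  # identical per-sample rates in both classes: difference 0
  same <- rbind(
    data.frame(sample = rep(sprintf("s%02d", 1:n), 4),
               class = "coding_gene"),
    data.frame(sample = rep(sprintf("s%02d", 1:n), 4),
               class = "promoter"))
  same$chrom <- "chr1"; same$pos <- 1
  classes_eq <- list(
    coding_gene = classes$coding_gene,
    promoter = GenomicRanges::GRanges("chr1",
                                      IRanges::IRanges(3e6, 5e6 - 1)))
  classes_eq$promoter <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(3e6, 3e6 + 2e6 - 1))
  res3 <- mutations_per_mb(same, classes_eq)
  expect_equal(res3$tests$mean_diff, 0)
  expect_equal(res3$tests$p, 1)
})

test_that("variant sharing summary matches counts and closed form", {
  doses <- matrix(0L, 5, 4, dimnames = list(NULL, letters[1:4]))
  doses[1, 1] <- doses[2, 2] <- doses[3, 3] <- doses[4, 4] <- 1L
  doses[5, c(1, 2)] <- 1L
  cc <- make_cohort("chr1", c(10, 20, 30, 40, 50), doses)
  sh <- variant_sharing_summary(cc)
  expect_equal(sh$fraction_private, 0.8)
  expect_equal(sh$histogram$n_variants[sh$histogram$n_carriers == 2], 1L)
  doses[5, 2] <- 0L
  expect_equal(variant_sharing_summary(
    make_cohort("chr1", c(10, 20, 30, 40, 50), doses))$fraction_private, 1)

  # closed form: per-site carriers ~ Bin(n_case, rate / sites_per_class)
  cfg <- tiny_burden_config(83, n_genes = 800L, risk_genes = data.frame(
    gene_id = character(), case_rate = numeric(),
    control_rate = numeric()))
  sim <- simulate_burden_cohort(cfg)
  coding <- subset_variants(sim$case, sim$case$variants$class == "coding")
  sh2 <- variant_sharing_summary(coding)
  p_site <- 0.01 / 5
  p1 <- stats::dbinom(1, 51, p_site)
  pg1 <- stats::pbinom(0, 51, p_site, lower.tail = FALSE)
  expected <- p1 / pg1
  n_sites <- nrow(coding$variants)
  se <- sqrt(expected * (1 - expected) / n_sites)
  expect_lt(abs(sh2$fraction_private - expected), 3 * se)
})
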