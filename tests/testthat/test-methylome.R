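test_that("coverage filter keeps CpGs at exactly the threshold", {
  s <- make_sample("x", c(100, 200, 300), c(3, 2, 0), c(2, 2, 0))
  f <- filter_coverage(s)
  expect_equal(f$records$pos, 100L)        # coverage 5 kept, 4 and 0 dropped
  expect_equal(nrow(filter_coverage(make_sample("x", integer(0),
                                                integer(0),
                                                integer(0)))$records), 0)
})

test_that("threshold HMR caller finds maximal low-beta runs", {
  pos <- seq(1000, 2900, by = 100)
  beta_low <- c(rep(0.9, 5), rep(0.05, 10), rep(0.9, 5))
  meth <- round(beta_low * 20)
  s <- make_sample("x", pos, meth, 20 - meth)
  h <- call_hmrs_simple(s)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, pos[6])
  expect_equal(h$end, pos[15])
  expect_equal(h$n_cpg, 10L)
  expect_lt(h$mean_beta, 0.1)

  # two low CpGs only: below min_cpg
  s2 <- make_sample("x", c(100, 200), c(0, 0), c(20, 20))
  expect_equal(nrow(call_hmrs_simple(s2)), 0)

  # a 600 bp gap splits the run; each piece tested against min_cpg
  pos3 <- c(100, 200, 300, 400, 1000, 1100, 1200, 1300, 1400)
  s3 <- make_sample("x", pos3, rep(0, 9), rep(20, 9))
  h3 <- call_hmrs_simple(s3)
  expect_equal(nrow(h3), 2)
  expect_equal(h3$start, c(100L, 1000L))
  expect_equal(h3$end, c(400L, 1400L))
})

test_that("recurrence scan handles thresholds and merging as specified", {
  # 1 sample of 20 = exactly 5%: qualifies (inclusive)
  hmr1 <- data.frame(sample_id = "s1", chrom = "chr1", start = 1001,
                     end = 1400, stringsAsFactors = FALSE)
  r1 <- recurrence_scan(hmr1, 20)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$start, 1001)
  expect_equal(r1$end, 1400)
  expect_equal(r1$sample_fraction, 0.05)
  # 1 of 21 is below 5%
  expect_equal(nrow(recurrence_scan(hmr1, 21)), 0)

  # a single 12 kb HMR is discarded as non-focal
  big <- data.frame(sample_id = "s1", chrom = "chr1", start = 1001,
                    end = 13000, stringsAsFactors = FALSE)
  expect_equal(nrow(recurrence_scan(big, 10)), 0)

  # staggered HMRs merge into one contiguous region
  st <- data.frame(sample_id = c("s1", "s2"), chrom = "chr1",
                   start = c(1001, 1201), end = c(1300, 1500),
                   stringsAsFactors = FALSE)
  r2 <- recurrence_scan(st, 20)
  expect_equal(nrow(r2), 1)
  expect_equal(r2$start, 1001)
  expect_equal(r2$end, 1500)
  expect_equal(r2$sample_fraction, 0.1)
  expect_error(recurrence_scan(st, 0), "n_samples")
})

test_that("recurrence scan equals the brute-force window oracle", {
  set.seed(19)
  for (rep in 1:5) {
    n_s <- 12
    hmrs <- do.call(rbind, lapply(1:n_s, function(i) {
      k <- sample(3:8, 1)
      st <- sort(sample(seq(1, 20000, by = 50), k))
      data.frame(sample_id = sprintf("s%02d", i),
                 chrom = sample(c("chr1", "chr2"), k, replace = TRUE),
                 start = st, end = st + sample(c(200, 900, 4000, 12000),
                                               k, replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    got <- recurrence_scan(hmrs, n_s, min_fraction = 0.25)
    want <- oracle_recurrence(hmrs, n_s, min_fraction = 0.25)
    o <- order(want$chrom, want$start)
    want <- want[o, ]
    expect_equal(got$chrom, want$chrom)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$sample_fraction, want$sample_fraction)
    expect_true(all(got$sample_fraction >= 0.25))
  }
})

test_that("context classification follows the stated precedence", {
  ann <- list(
    promoter = GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 200)),
    enhancer = GenomicRanges::GRanges("chr1", IRanges::IRanges(150, 400)),
    dyadic = GenomicRanges::GRanges("chr1", IRanges::IRanges(380, 500)),
    cgi_island = GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 120)),
    cgi_shore = GenomicRanges::GRanges("chr1", IRanges::IRanges(121, 300)))
  regions <- data.frame(chrom = "chr1",
                        start = c(110, 250, 420, 1000),
                        end = c(180, 300, 450, 1100))
  out <- classify_hmr_context(regions, ann)
  expect_equal(out$annotation_group,
               c("promoter", "enhancer", "dyadic", "none"))
  expect_equal(out$cgi_context,
               c("cgi_island", "cgi_shore", "open_sea", "open_sea"))
  # input order of the annotation list is irrelevant
  out2 <- classify_hmr_context(regions, rev(ann))
  expect_identical(out$annotation_group, out2$annotation_group)
  expect_identical(out$cgi_context, out2$cgi_context)
})

test_that("region methylation matrix pools counts, flags missing", {
  s1 <- make_sample("a", c(100, 150), c(5, 10), c(5, 0))
  s2 <- make_sample("b", 500, 3, 7)
  regions <- data.frame(region_id = c("r1", "r2"), chrom = "chr1",
                        start = c(90, 400), end = c(200, 600))
  mat <- region_methylation_matrix(regions, list(s1, s2))
  expect_equal(mat["r1", "a"], 15 / 20)  # coverage-weighted, not mean of betas
  expect_true(is.na(mat["r1", "b"]))
  expect_equal(mat["r2", "b"], 0.3)
  # a region no sample covers is dropped with a warning
  regions3 <- rbind(regions, data.frame(region_id = "r3", chrom = "chr1",
                                        start = 900, end = 1000))
  expect_warning(m3 <- region_methylation_matrix(regions3, list(s1, s2)),
                 "dropped")
  expect_equal(rownames(m3), c("r1", "r2"))

  # brute-force pooling oracle on a seeded fixture
  set.seed(4)
  pos <- sort(sample(1:5000, 200))
  depth <- rpois(200, 20)
  meth <- rbinom(200, depth, 0.4)
  sx <- make_sample("x", pos, meth, depth - meth)
  reg <- data.frame(region_id = sprintf("w%d", 1:5), chrom = "chr1",
                    start = seq(1, 4001, by = 1000),
                    end = seq(1000, 5000, by = 1000))
  got <- region_methylation_matrix(reg, list(sx))
  for (i in 1:5) {
    in_r <- pos >= reg$start[i] & pos <= reg$end[i]
    expect_equal(got[i, "x"], sum(meth[in_r]) / sum(depth[in_r]))
  }
})

test_that("dmr test matches t reference, excludes degenerate regions", {
  set.seed(8)
  mat <- matrix(runif(40 * 12, 0.2, 0.8), 40, 12,
                dimnames = list(sprintf("r%02d", 1:40),
                                c(sprintf("c%d", 1:6), sprintf("k%d", 1:6))))
  res <- dmr_test(mat, sprintf("c%d", 1:6), sprintf("k%d", 1:6))
  for (i in sample(40, 8)) {
    ref <- t.test(mat[i, 1:6], mat[i, 7:12], var.equal = TRUE)
    j <- which(res$region_id == rownames(mat)[i])
    expect_equal(res$p[j], ref$p.value, tolerance = 1e-8)
    expect_equal(res$t_statistic[j], unname(ref$statistic),
                 tolerance = 1e-8)
  }
  # BH q is monotone in p rank
  o <- order(res$p)
  expect_true(all(diff(res$q[o]) >= -1e-12))
  expect_true(all(res$q >= res$p))

  # identical constants in both groups are excluded, not tested
  mat2 <- rbind(mat, const = rep(0.5, 12))
  res2 <- dmr_test(mat2, sprintf("c%d", 1:6), sprintf("k%d", 1:6))
  expect_false("const" %in% res2$region_id)
  expect_equal(attr(res2, "n_excluded"), 1)
})

test_that("dmr test recovers a planted shift at the cohort's sample sizes", {
  set.seed(21)
  n_reg <- 60
  base <- runif(n_reg, 0.3, 0.5)
  case <- sapply(1:48, function(i) pmin(pmax(base - 0.2 +
                                               rnorm(n_reg, 0, 0.05), 0), 1))
  ctl <- sapply(1:45, function(i) pmin(pmax(base +
                                              rnorm(n_reg, 0, 0.05), 0), 1))
  mat <- cbind(case, ctl)
  dimnames(mat) <- list(sprintf("r%02d", 1:n_reg),
                        c(sprintf("c%02d", 1:48), sprintf("k%02d", 1:45)))
  res <- dmr_test(mat, sprintf("c%02d", 1:48), sprintf("k%02d", 1:45))
  expect_gte(mean(res$is_dmr), 0.95)
  expect_lt(max(abs(res$delta + 0.2)), 0.05)
  expect_lt(mean(abs(res$delta + 0.2)), 0.03)
  expect_true(all(res$direction == "hypo"))

  # null matrix: false-positive DMR fraction stays near alpha
  null <- matrix(runif(400 * 20, 0.3, 0.7), 400, 20,
                 dimnames = list(sprintf("n%03d", 1:400),
                                 sprintf("s%02d", 1:20)))
  resn <- dmr_test(null, sprintf("s%02d", 1:10), sprintf("s%02d", 11:20))
  expect_lte(mean(resn$is_dmr), 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("hypo fraction and recurrent-differential selection", {
  d <- data.frame(direction = c("hypo", "hypo", "hyper"))
  expect_equal(hypo_fraction(d), 2 / 3)
  expect_equal(hypo_fraction(data.frame(direction = rep("hypo", 4))), 1)
  expect_error(hypo_fraction(d[0, , drop = FALSE]), "empty")

  regions <- data.frame(chrom = "chr1", start = c(1, 2, 3),
                        end = c(10, 11, 12),
                        sample_fraction = c(0.12, 0.12, 0.08),
                        delta = c(-0.15, -0.05, -0.30))
  sel <- select_recurrent_differential(regions)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$delta, -0.15)
  # boundary: fraction exactly 0.10 and delta exactly -0.1 are excluded
  border <- data.frame(chrom = "chr1", start = 1, end = 10,
                       sample_fraction = 0.10, delta = -0.1)
  expect_equal(nrow(select_recurrent_differential(border)), 0)
})

test_that("DMR-to-gene mapping deduplicates and respects gene parts", {
  parts <- feature_set(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(100, 200, 300, 1000), c(199, 299, 399, 1099))),
    id = c("MAL", "MAL", "MAL", "OTHER"),
    name = c("MAL", "MAL", "MAL", "OTHER"),
    feature_class = c("promoter", "exon", "intron", "exon"))
  expect_equal(map_dmrs_to_genes(
    data.frame(chrom = "chr1", start = 150, end = 160), parts), "MAL")
  expect_equal(map_dmrs_to_genes(
    data.frame(chrom = "chr1", start = 5000, end = 5100), parts),
    character(0))
  # one DMR spanning parts of two genes reports both, once each
  expect_equal(map_dmrs_to_genes(
    data.frame(chrom = "chr1", start = c(150, 250, 1000),
               end = c(260, 320, 1010)), parts), c("MAL", "OTHER"))
})

test_that("hypergeometric set enrichment matches exact values and BH", {
  universe <- sprintf("g%02d", 1:20)
  sets <- list(setA = universe[1:5])
  res <- geneset_enrichment(c(universe[1:4], universe[10]), sets, universe)
  expect_equal(res$overlap, 4L)
  expect_equal(res$p, 76 / 15504, tolerance = 1e-12)
  res0 <- geneset_enrichment(universe[6:10], list(setA = universe[1:5]),
                             universe)
  expect_equal(res0$p, 1)
  expect_error(geneset_enrichment("a", sets, character(0)), "empty universe")
})
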