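#' Qualifying-variant selectors
#'
#' The burden framework tests three variant strata, each defined by a
#' rarity threshold on the maximum population allele frequency plus a
#' functional criterion:
#'
#' * `select_qualifying_coding()`: rare (`pop_af <= af_max`, default 0.01)
#'   coding-altering variants (consequence `missense` or `lof`).
#' * `select_qualifying_noncoding()`: rare (default `af_max = 0.001`)
#'   noncoding variants called deleterious by all three of GERP++, GWAVA
#'   and CADD.
#' * `select_benign()`: the calibration stratum — rare synonymous variants
#'   (`mode = "coding"`, default `af_max = 0.01`), or rare noncoding
#'   variants with *no* deleteriousness call (`mode = "noncoding"`,
#'   default `af_max = 0.001`).
#'
#' Thresholds are inclusive: a variant exactly at `af_max` qualifies.
#'
#' @param variants Variant data.frame (from a `case_cohort` or control
#'   site table).
#' @param af_max Inclusive rarity threshold.
#' @return Logical vector selecting the qualifying rows.
#' @export
select_qualifying_coding <- function(variants, af_max = 0.01) {
  variants$pop_af <= af_max & variants$consequence %in% c("missense", "lof")
}

#' @rdname select_qualifying_coding
#' @export
select_qualifying_noncoding <- function(variants, af_max = 0.001) {
  variants$pop_af <= af_max & variants$del_gerp & variants$del_gwava &
    variants$del_cadd
}

#' @rdname select_qualifying_coding
#' @param mode `"coding"` (rare synonymous) or `"noncoding"` (rare,
#'   zero deleteriousness flags).
#' @export
select_benign <- function(variants, mode = c("coding", "noncoding"),
                          af_max = NULL) {
  mode <- match.arg(mode)
  if (mode == "coding") {
    if (is.null(af_max)) af_max <- 0.01
    variants$pop_af <= af_max & variants$consequence == "synonymous"
  } else {
    if (is.null(af_max)) af_max <- 0.001
    variants$pop_af <= af_max & variants$consequence == "noncoding" &
      !variants$del_gerp & !variants$del_gwava & !variants$del_cadd
  }
}

#' Build the jointly-callable mask from two coverage tracks
#'
#' Because case and control cohorts are not jointly called, burden testing
#' is restricted to bases where at least `required_fraction` of samples
#' are covered in *both* cohorts.
#'
#' @param case_coverage,control_coverage Scored `GRanges` tracks
#'   (fraction of samples covered, see [read_coverage_track()]).
#' @param required_fraction Minimum fraction in each cohort (default 0.9,
#'   inclusive).
#' @return A `CallableMask`: list with `intervals` (disjoint, sorted
#'   `GRanges`) and `required_fraction`.
#' @export
build_callable_mask <- function(case_coverage, control_coverage,
                                required_fraction = 0.9) {
  s1 <- sort(GenomeInfoDb::seqlevels(case_coverage))
  s2 <- sort(GenomeInfoDb::seqlevels(control_coverage))
  if (!identical(s1, s2)) {
    stop("coverage tracks disagree on chromosomes: only in case: [",
         paste(setdiff(s1, s2), collapse = ","), "], only in control: [",
         paste(setdiff(s2, s1), collapse = ","), "]")
  }
  ok1 <- GenomicRanges::reduce(
    case_coverage[case_coverage$score >= required_fraction])
  ok2 <- GenomicRanges::reduce(
    control_coverage[control_coverage$score >= required_fraction])
  mask <- GenomicRanges::intersect(ok1, ok2, ignore.strand = TRUE)
  structure(list(intervals = sort(mask, ignore.strand = TRUE),
                 required_fraction = required_fraction),
            class = "callable_mask")
}

#' Filter variants to the callable mask and away from low-complexity DNA
#'
#' Keeps variants whose position lies inside the callable mask and outside
#' the low-complexity regions.
#'
#' @param x A `case_cohort` or a variant/control-site data.frame.
#' @param mask A `callable_mask` (or `GRanges`); `NULL` skips the check.
#' @param lcr Low-complexity `GRanges`; `NULL` skips the check.
#' @return `x` subset to the retained variants.
#' @export
apply_region_filters <- function(x, mask = NULL, lcr = NULL) {
  variants <- if (inherits(x, "case_cohort")) x$variants else x
  gr <- variant_granges(variants)
  keep <- rep(TRUE, length(gr))
  if (!is.null(mask)) {
    mgr <- if (inherits(mask, "callable_mask")) mask$intervals else mask
    keep <- keep & IRanges::overlapsAny(gr, mgr)
  }
  if (!is.null(lcr)) {
    keep <- keep & !IRanges::overlapsAny(gr, lcr)
  }
  subset_variants(x, keep)
}

#' Subset a cohort (or variant table) by a row predicate
#'
#' @param x A `case_cohort` or data.frame.
#' @param keep Logical or integer row selector.
#' @return Object of the same shape with the selected variants.
#' @export
subset_variants <- function(x, keep) {
  if (inherits(x, "case_cohort")) {
    x$variants <- x$variants[keep, , drop = FALSE]
    rownames(x$variants) <- NULL
    x$doses <- x$doses[keep, , drop = FALSE]
    x
  } else {
    out <- x[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
}

# Map variant rows to feature ids by positional overlap.
assign_features <- function(variants, features) {
  hits <- GenomicRanges::findOverlaps(variant_granges(variants), features,
                                      ignore.strand = TRUE)
  data.frame(row = S4Vectors::queryHits(hits),
             feature_id = features$id[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' Count case carriers per feature (dominant model)
#'
#' A sample is a carrier of a feature if it has alternate dose >= 1 at any
#' of the supplied qualifying variants overlapping the feature. Missing
#' genotypes count as non-carriers but are tallied in a `missing_calls`
#' column.
#'
#' @param cohort A `case_cohort` already subset to qualifying variants.
#' @param features Feature-set `GRanges`.
#' @return data.frame (feature_id, case_carriers, n_variants,
#'   missing_calls); features without variants get zero counts.
#' @export
count_case_carriers <- function(cohort, features) {
  map <- assign_features(cohort$variants, features)
  out <- data.frame(feature_id = features$id, case_carriers = 0L,
                    n_variants = 0L, missing_calls = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(map) > 0) {
    by_feat <- split(map$row, map$feature_id)
    carriers <- vapply(by_feat, function(rows) {
      d <- cohort$doses[rows, , drop = FALSE]
      sum(colSums(d >= 1L, na.rm = TRUE) > 0)
    }, integer(1))
    missing <- vapply(by_feat, function(rows) {
      sum(is.na(cohort$doses[rows, , drop = FALSE]))
    }, integer(1))
    i <- match(names(by_feat), out$feature_id)
    out$case_carriers[i] <- carriers
    out$n_variants[i] <- lengths(by_feat)
    out$missing_calls[i] <- missing
  }
  out
}

#' Estimate control carriers per feature from summary allele counts
#'
#' Sums the control alternate allele counts over each feature's
#' qualifying variants, treating every counted allele as a distinct
#' carrier, and caps the sum at `control_n` to keep the 2x2 table valid.
#'
#' @param sites Control site data.frame already subset to qualifying
#'   variants (columns `control_ac`, `control_an`).
#' @param features Feature-set `GRanges`.
#' @param control_n Number of control individuals.
#' @return data.frame (feature_id, control_carriers, n_variants).
#' @export
estimate_control_carriers <- function(sites, features, control_n) {
  map <- assign_features(sites, features)
  out <- data.frame(feature_id = features$id, control_carriers = 0L,
                    n_variants = 0L, stringsAsFactors = FALSE)
  if (nrow(map) > 0) {
    ac <- vapply(split(map$row, map$feature_id),
                 function(rows) sum(sites$control_ac[rows]), numeric(1))
    i <- match(names(ac), out$feature_id)
    out$control_carriers[i] <- as.integer(pmin(ac, control_n))
    out$n_variants[i] <- as.integer(table(map$feature_id)[names(ac)])
  }
  out
}

#' One-sided Fisher's exact test for case enrichment
#'
#' Exact upper-tail probability `P(X >= a)` of the 2x2 carrier table
#' `[[a, b], [c, d]]` (cases: carriers / non-carriers; controls: carriers
#' / non-carriers) under the hypergeometric null with all margins fixed,
#' computed via [stats::phyper()] (log-space internals, no enumeration).
#' With `midp = TRUE` returns the mid-p variant
#' `P(X > a) + 0.5 P(X = a)`, which removes the discreteness-induced
#' conservativeness and is the quantity the inflation diagnostic
#' [lambda95()] should be fed.
#'
#' All four arguments are vectorised.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param midp Return the mid-p value instead of the exact tail.
#' @return Numeric vector of p-values in \[0, 1\].
#' @export
fisher_one_sided <- function(a, b, c, d, midp = FALSE) {
  if (any(c(a, b, c, d) < 0)) stop("negative count in 2x2 table")
  if (any(a + b == 0) || any(c + d == 0)) stop("empty table margin")
  p <- stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  if (midp) {
    p <- p - 0.5 * stats::dhyper(a, a + c, b + d, a + b)
  }
  pmin(pmax(p, 0), 1)
}

#' Genome-wide burden scan under the dominant model
#'
#' For every feature, builds the 2x2 carrier table (case carriers vs
#' capped control allele-count carriers), computes the one-sided Fisher p
#' (and its mid-p variant, used for calibration), flags significance at
#' the Bonferroni level `alpha / n_features_tested`, and attaches a
#' QQ-plot table (observed vs expected -log10 p).
#'
#' @param cohort A `case_cohort` subset to qualifying case variants.
#' @param control_sites Control site data.frame subset to qualifying
#'   control variants.
#' @param features Feature-set `GRanges`.
#' @param control_n Number of control individuals.
#' @param alpha Family-wise error target (default 0.05).
#' @param bonferroni_n Bonferroni denominator; defaults to the number of
#'   features with at least one tested variant in either cohort.
#' @return data.frame of per-feature results sorted by p (columns
#'   feature_id, case_carriers, case_n, control_carriers, control_n,
#'   p_one_sided, p_mid, odds_ratio, tested, bonferroni_alpha,
#'   significant), with the QQ table in `attr(, "qq")`.
#' @export
burden_scan <- function(cohort, control_sites, features, control_n,
                        alpha = 0.05, bonferroni_n = NULL) {
  case_n <- length(cohort$samples)
  cc <- count_case_carriers(cohort, features)
  ctl <- estimate_control_carriers(control_sites, features, control_n)
  stopifnot(identical(cc$feature_id, ctl$feature_id))
  tested <- cc$n_variants + ctl$n_variants > 0
  a <- cc$case_carriers; b <- case_n - a
  c_ <- ctl$control_carriers; d <- control_n - c_
  p <- fisher_one_sided(a, b, c_, d)
  pm <- fisher_one_sided(a, b, c_, d, midp = TRUE)
  p[!tested] <- 1; pm[!tested] <- 1
  or <- (a * d) / (b * c_)
  if (is.null(bonferroni_n)) bonferroni_n <- max(sum(tested), 1L)
  bon <- alpha / bonferroni_n
  res <- data.frame(
    feature_id = cc$feature_id,
    case_carriers = a, case_n = case_n,
    control_carriers = c_, control_n = control_n,
    p_one_sided = p, p_mid = pm, odds_ratio = or,
    tested = tested, bonferroni_alpha = bon,
    significant = tested & p < bon,
    stringsAsFactors = FALSE)
  res <- res[order(res$p_one_sided, res$feature_id), , drop = FALSE]
  rownames(res) <- NULL
  n <- sum(tested)
  qq <- data.frame(
    expected = -log10((seq_len(n) - 0.5) / n),
    observed = -log10(sort(res$p_one_sided[res$tested])))
  attr(res, "qq") <- qq
  res
}

#' Genomic inflation at the 95th percentile
#'
#' Transforms p-values to 1-df chi-square quantiles
#' `Q(1 - p)` and returns the ratio of their empirical 95th
#' percentile (linear-interpolation quantile) to the theoretical
#' chi-square(1) 95th percentile 3.841459. A value near 1 indicates the
#' p-value distribution follows the null expectation in its upper tail;
#' values above 1 indicate inflation (e.g. case-only genotyping
#' artifacts). Feed this mid-p values for discrete tests — exact
#' one-sided tail p-values are conservative and bias lambda downward.
#'
#' @param p_values Numeric vector of p-values in (0, 1\]; at least 20.
#' @return The lambda95 statistic (positive scalar).
#' @export
lambda95 <- function(p_values) {
  if (length(p_values) < 20) stop("need at least 20 p-values")
  if (any(p_values <= 0)) {
    warning("p-values of 0 clipped to smallest positive double")
    p_values <- pmax(p_values, .Machine$double.xmin)
  }
  chi <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::quantile(chi, 0.95, names = FALSE, type = 7) /
    stats::qchisq(0.95, df = 1)
}

#' Quality-tranche calibration sweep
#'
#' Case and control call sets produced by different pipelines must be
#' quality-matched before burden testing. For each tranche `q` in
#' `tranche_grid`, the sweep keeps the top-`q` fraction of case variants
#' by site quality (cut at the empirical `1 - q` quantile of
#' `qual_metric`), runs a benign-stratum burden scan, and computes
#' [lambda95()] on the resulting mid-p values. The chosen tranche is the
#' largest `q` whose lambda95 lies within `tolerance` (ties broken toward
#' more data); if none qualifies, `chosen_tranche` is `NA` and a
#' diagnostic message is attached.
#'
#' @param cohort Full (unfiltered) `case_cohort`.
#' @param control_sites Full control site data.frame.
#' @param features Feature-set `GRanges`.
#' @param control_n Number of control individuals.
#' @param tranche_grid Quality-inclusion fractions to test.
#' @param mode Benign stratum, `"coding"` or `"noncoding"` (see
#'   [select_benign()]).
#' @param tolerance Accepted lambda95 interval. Default `c(0.9, 1.1)`:
#'   with ~1000 features the lambda95 estimator has sampling sd around
#'   0.03-0.04, so a +-0.05 band would reject well-calibrated cohorts in
#'   a substantial fraction of runs.
#' @return A `calibration_result` list: `tranche_grid`,
#'   `lambda95_by_tranche`, `chosen_tranche`, `tolerance_band`,
#'   `diagnostic`.
#' @export
calibration_sweep <- function(cohort, control_sites, features, control_n,
                              tranche_grid = c(0.9, 0.95, 1),
                              mode = c("coding", "noncoding"),
                              tolerance = c(0.9, 1.1)) {
  mode <- match.arg(mode)
  stopifnot(all(tranche_grid > 0 & tranche_grid <= 1))
  tranche_grid <- sort(tranche_grid)
  ctl_benign <- subset_variants(control_sites,
                                select_benign(control_sites, mode))
  lam <- vapply(tranche_grid, function(q) {
    thr <- stats::quantile(cohort$variants$qual_metric, 1 - q, type = 7,
                           names = FALSE)
    kept <- subset_variants(cohort, cohort$variants$qual_metric >= thr)
    benign <- subset_variants(kept, select_benign(kept$variants, mode))
    scan <- burden_scan(benign, ctl_benign, features, control_n)
    lambda95(scan$p_mid[scan$tested])
  }, numeric(1))
  ok <- lam >= tolerance[1] & lam <= tolerance[2]
  chosen <- if (any(ok)) max(tranche_grid[ok]) else NA_real_
  diagnostic <- if (is.na(chosen)) {
    sprintf("no tranche in [%g, %g]; lambda95 = %s at grid {%s}",
            tolerance[1], tolerance[2],
            paste(round(lam, 3), collapse = ", "),
            paste(tranche_grid, collapse = ", "))
  } else NA_character_
  structure(list(tranche_grid = tranche_grid, lambda95_by_tranche = lam,
                 chosen_tranche = chosen, tolerance_band = tolerance,
                 diagnostic = diagnostic),
            class = "calibration_result")
}

#' Per-class mutation rates per megabase with pairwise tests
#'
#' Computes, per sample and feature class, the variant count divided by
#' the class's total length in Mb; summarises each class as mean +- sd
#' across samples; and tests every class against the reference class with
#' a two-sample t-test, Benjamini-Hochberg adjusted.
#'
#' @param positions data.frame (sample, class, chrom, pos) of per-sample
#'   variant positions, e.g. from [simulate_mutation_positions()].
#' @param classes Named list of class `GRanges` giving total lengths.
#' @param reference Class the others are compared against (default
#'   `"coding_gene"`).
#' @return List with `rates` (per class: mean_rate, sd_rate, length_mb),
#'   `per_sample` (sample x class rate matrix) and `tests` (class,
#'   mean_diff, p, q).
#' @export
mutations_per_mb <- function(positions, classes,
                             reference = "coding_gene") {
  len_mb <- vapply(classes, function(gr) sum(GenomicRanges::width(gr)) / 1e6,
                   numeric(1))
  if (any(len_mb <= 0)) {
    stop("zero-length class: ",
         paste(names(classes)[len_mb <= 0], collapse = ", "))
  }
  samples <- sort(unique(positions$sample))
  counts <- table(factor(positions$sample, samples),
                  factor(positions$class, names(classes)))
  rates <- sweep(unclass(counts), 2, len_mb[colnames(counts)], "/")
  summ <- data.frame(
    class = colnames(rates),
    mean_rate = colMeans(rates),
    sd_rate = apply(rates, 2, stats::sd),
    length_mb = len_mb[colnames(rates)], row.names = NULL)
  others <- setdiff(colnames(rates), reference)
  tests <- data.frame(class = others,
                      mean_diff = rep(NA_real_, length(others)),
                      p = rep(NA_real_, length(others)))
  for (i in seq_along(others)) {
    x <- rates[, others[i]]; y <- rates[, reference]
    if (stats::sd(x - y) == 0 && stats::sd(x) == 0 && stats::sd(y) == 0) {
      tests$mean_diff[i] <- 0; tests$p[i] <- 1
    } else {
      tt <- stats::t.test(x, y)
      tests$mean_diff[i] <- mean(x) - mean(y)
      tests$p[i] <- tt$p.value
    }
  }
  tests$q <- stats::p.adjust(tests$p, method = "BH")
  list(rates = summ, per_sample = rates, tests = tests)
}

#' Variant-sharing summary across unrelated cases
#'
#' Reports the fraction of qualifying variants carried by at most one
#' case sample (private variants) and the full sharing histogram.
#'
#' @param cohort A `case_cohort` subset to the variants of interest.
#' @return List with `fraction_private` and `histogram` (data.frame:
#'   n_carriers, n_variants).
#' @export
variant_sharing_summary <- function(cohort) {
  carriers <- rowSums(cohort$doses >= 1L, na.rm = TRUE)
  tab <- table(carriers)
  list(fraction_private = mean(carriers <= 1),
       histogram = data.frame(n_carriers = as.integer(names(tab)),
                              n_variants = as.integer(tab)))
}
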