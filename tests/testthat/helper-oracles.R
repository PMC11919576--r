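# Independent oracles used across the suite. These deliberately avoid the
# code paths they check (no phyper/dhyper, no window bookkeeping shared
# with recurrence_scan).

# Full hypergeometric enumeration of the one-sided 2x2 tail via log
# binomial coefficients, normalised over the whole support.
oracle_fisher_tail <- function(a, b, c, d) {
  k <- a + b            # draws (cases)
  m <- a + c            # successes (carriers)
  n <- b + d
  lo <- max(0L, k - n)
  hi <- min(k, m)
  xs <- lo:hi
  lp <- lchoose(m, xs) + lchoose(n, k - xs)
  w <- exp(lp - max(lp))
  sum(w[xs >= a]) / sum(w)
}

# Brute-force recurrence scan: enumerate every window explicitly and test
# each sample's HMR list against it.
oracle_recurrence <- function(hmrs, n_samples, window = 100,
                              min_fraction = 0.05, focal_max = 10000) {
  hmrs <- hmrs[hmrs$end - hmrs$start + 1 <= focal_max, , drop = FALSE]
  out <- list()
  for (ch in sort(unique(hmrs$chrom))) {
    h <- hmrs[hmrs$chrom == ch, , drop = FALSE]
    if (nrow(h) == 0) next
    wmax <- (max(h$end) - 1) %/% window
    qual <- logical(wmax + 1)
    for (w in 0:wmax) {
      ws <- w * window + 1
      we <- (w + 1) * window
      samples_in <- unique(h$sample_id[h$start <= we & h$end >= ws])
      qual[w + 1] <- length(samples_in) / n_samples >= min_fraction
    }
    r <- rle(qual)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in which(r$values)) {
      ws <- (starts[i] - 1) * window + 1
      we <- ends[i] * window
      sf <- length(unique(h$sample_id[h$start <= we & h$end >= ws])) /
        n_samples
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = ws, end = we, sample_fraction = sf,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), sample_fraction = numeric()))
  }
  do.call(rbind, out)
}

# A case_cohort built directly from a dose matrix, for counting tests.
make_cohort <- function(chrom, pos, doses, consequence = "missense",
                        pop_af = 1e-4, qual = 20) {
  n <- length(pos)
  structure(list(
    samples = colnames(doses),
    variants = data.frame(
      chrom = rep_len(chrom, n), pos = pos, ref = rep_len("A", n),
      alt = rep_len("G", n),
      qual_metric = rep_len(qual, n), pass_flag = rep_len(TRUE, n),
      pop_af = rep_len(pop_af, n),
      consequence = rep_len(consequence, n),
      del_gerp = rep_len(FALSE, n), del_gwava = rep_len(FALSE, n),
      del_cadd = rep_len(FALSE, n),
      stringsAsFactors = FALSE),
    doses = doses), class = "case_cohort")
}

make_sample <- function(sample_id, pos, meth, unmeth, chrom = "chr1") {
  structure(list(sample_id = sample_id,
                 records = data.frame(chrom = rep_len(chrom, length(pos)),
                                      pos = as.integer(pos),
                                      meth = as.integer(meth),
                                      unmeth = as.integer(unmeth))),
            class = "methylome_sample")
}

tiny_burden_config <- function(seed, n_genes = 100L, n_segments = 24L,
                               n_control_inhouse = 20L,
                               n_control_summary = 2000L, ...) {
  simulation_config(seed = seed, n_genes = n_genes,
                    n_segments = n_segments,
                    n_control_inhouse = n_control_inhouse,
                    n_control_summary = n_control_summary, ...)
}

# agreement with a printed value at its own precision: within one unit in
# the last printed digit (covers both rounding and truncation)
expect_sigfig <- function(x, printed, digits = 3) {
  expect_lt(abs(x - printed),
            10^(floor(log10(abs(printed))) - digits + 1))
}
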