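#' Read a Bismark coverage file
#'
#' Bismark coverage format has six columns: chromosome, start (1-based CpG
#' position), end, percent methylation, methylated count, unmethylated
#' count. The percent column is ignored in favour of the raw counts; if it
#' disagrees with the counts by more than rounding error a warning is
#' issued and the counts win. Zero-coverage records are kept (their beta
#' value is undefined until [filter_coverage()] removes them).
#'
#' @param path Path to a Bismark `.cov` file.
#' @param sample_id Sample identifier to attach.
#' @return A `methylome_sample`: list with `sample_id` and `records`, a
#'   data.frame (chrom, pos, meth, unmeth) sorted by (chrom, pos).
#' @export
read_bismark_cov <- function(path, sample_id = basename(path)) {
  cols <- c("chrom", "pos", "end", "pct", "meth", "unmeth")
  if (file.size(path) == 0) {
    rec <- data.frame(chrom = character(), pos = integer(),
                      meth = integer(), unmeth = integer())
    return(structure(list(sample_id = sample_id, records = rec),
                     class = "methylome_sample"))
  }
  dt <- data.table::fread(path, header = FALSE, col.names = cols)
  cov <- dt$meth + dt$unmeth
  expected <- ifelse(cov > 0, 100 * dt$meth / cov, 0)
  off <- cov > 0 & abs(expected - dt$pct) > 0.51
  if (any(off)) {
    warning(sum(off), " record(s) in ", path,
            " have a methylation % inconsistent with counts; counts win")
  }
  rec <- data.frame(chrom = dt$chrom, pos = as.integer(dt$pos),
                    meth = as.integer(dt$meth),
                    unmeth = as.integer(dt$unmeth))
  rec <- rec[order(rec$chrom, rec$pos), , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(sample_id = sample_id, records = rec),
            class = "methylome_sample")
}

#' Write a methylome sample in Bismark coverage format
#'
#' @param sample A `methylome_sample`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bismark_cov <- function(sample, path) {
  r <- sample$records
  cov <- r$meth + r$unmeth
  pct <- ifelse(cov > 0, round(100 * r$meth / cov, 6), 0)
  data.table::fwrite(
    data.frame(r$chrom, r$pos, r$pos, pct, r$meth, r$unmeth),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Per-CpG beta values of a methylome sample
#'
#' @param sample A `methylome_sample`.
#' @return Numeric vector `meth / (meth + unmeth)`, `NA` at zero coverage.
#' @export
beta_values <- function(sample) {
  cov <- sample$records$meth + sample$records$unmeth
  ifelse(cov > 0, sample$records$meth / cov, NA_real_)
}
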