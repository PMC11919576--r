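#' Simulate dual-caller CNV call sets
#'
#' Plants `n_cnv_regions` non-overlapping truth regions on the toy genome,
#' assigns each case (and control) sample carrier status at the region's
#' configured frequency, and derives two noisy caller call sets: each
#' carried region is reported by each caller with probability
#' `1 - cnv_fn_rate`, with both boundaries jittered by independent
#' Gaussian noise (`cnv_jitter_sd` bp, resampled if the interval would
#' collapse), plus Poisson(`cnv_fp_rate`) false-positive calls per sample
#' per caller at random positions. Types (DEL/DUP) are preserved.
#'
#' @param config A [simulation_config()].
#' @param include_controls Also simulate the in-house control cohort's
#'   call sets (needed for region-frequency comparison).
#' @return A `cnv_sim` list: `truth` (region_id, chrom, start, end, type,
#'   case_frequency, plus per-cohort carrier counts), `calls_case`,
#'   `calls_control` (data.frames: sample_id, chrom, start, end, type,
#'   caller), and `carriers` (sample-level truth assignments).
#' @export
simulate_cnv_callsets <- function(config, include_controls = TRUE) {
  set_substream(config, "cnv/truth")
  contigs <- config$contigs
  n <- config$n_cnv_regions
  # non-overlapping slots of 100 kb, regions placed at a random offset
  slot_size <- 1e5
  slots <- do.call(rbind, lapply(names(contigs), function(ch) {
    k <- floor(contigs[ch] / slot_size)
    data.frame(chrom = ch, slot = seq_len(k) - 1L)
  }))
  pick <- slots[sample.int(nrow(slots), n), ]
  offset <- floor(stats::runif(n, 0, slot_size - config$cnv_length - 2000))
  truth <- data.frame(
    region_id = sprintf("cnv_%03d", seq_len(n)),
    chrom = pick$chrom,
    start = as.integer(pick$slot * slot_size + offset + 1),
    end = as.integer(pick$slot * slot_size + offset + config$cnv_length),
    type = ifelse(stats::runif(n) < config$cnv_del_fraction, "DEL", "DUP"),
    case_frequency = stats::runif(n, config$cnv_freq_range[1],
                                  config$cnv_freq_range[2]),
    control_frequency = config$cnv_control_freq,
    stringsAsFactors = FALSE)
  truth <- truth[order(truth$chrom, truth$start), ]
  truth$region_id <- sprintf("cnv_%03d", seq_len(n))
  rownames(truth) <- NULL

  draw_cohort <- function(n_samples, prefix, freqs, stream) {
    set_substream(config, stream)
    samples <- sprintf("%s%03d", prefix, seq_len(n_samples))
    carrier <- matrix(stats::runif(n * n_samples) < freqs, nrow = n)
    hit <- which(carrier, arr.ind = TRUE)
    carr <- data.frame(region_id = truth$region_id[hit[, 1]],
                       sample_id = samples[hit[, 2]],
                       stringsAsFactors = FALSE)
    calls <- list()
    for (caller in c("A", "B")) {
      seen <- stats::runif(nrow(hit)) >= config$cnv_fn_rate
      idx <- hit[seen, , drop = FALSE]
      m <- nrow(idx)
      s0 <- truth$start[idx[, 1]]; e0 <- truth$end[idx[, 1]]
      js <- round(stats::rnorm(m, 0, config$cnv_jitter_sd))
      je <- round(stats::rnorm(m, 0, config$cnv_jitter_sd))
      bad <- which(e0 + je <= s0 + js)
      while (length(bad) > 0) {
        js[bad] <- round(stats::rnorm(length(bad), 0, config$cnv_jitter_sd))
        je[bad] <- round(stats::rnorm(length(bad), 0, config$cnv_jitter_sd))
        bad <- bad[e0[bad] + je[bad] <= s0[bad] + js[bad]]
      }
      tp <- data.frame(sample_id = samples[idx[, 2]],
                       chrom = truth$chrom[idx[, 1]],
                       start = as.integer(pmax(1, s0 + js)),
                       end = as.integer(e0 + je),
                       type = truth$type[idx[, 1]],
                       caller = rep_len(caller, m),
                       stringsAsFactors = FALSE)
      nfp <- stats::rpois(n_samples, config$cnv_fp_rate)
      tot <- sum(nfp)
      fp <- NULL
      if (tot > 0) {
        ch <- sample(names(contigs), tot, replace = TRUE)
        len <- floor(stats::runif(tot, config$cnv_fp_length_range[1],
                                  config$cnv_fp_length_range[2]))
        st <- floor(stats::runif(tot, 1, contigs[ch] - len))
        fp <- data.frame(sample_id = rep(samples, nfp), chrom = ch,
                         start = as.integer(st),
                         end = as.integer(st + len),
                         type = ifelse(stats::runif(tot) < 0.5, "DEL", "DUP"),
                         caller = rep_len(caller, tot),
                         stringsAsFactors = FALSE)
      }
      calls[[caller]] <- rbind(tp, fp)
    }
    calls <- do.call(rbind, calls)
    calls <- calls[order(calls$caller, calls$sample_id, calls$chrom,
                         calls$start), ]
    rownames(calls) <- NULL
    list(calls = calls, carriers = carr)
  }

  case <- draw_cohort(config$n_case, "ICE", truth$case_frequency,
                      "cnv/case")
  truth$case_carriers <- as.integer(
    table(factor(case$carriers$region_id, truth$region_id)))
  out <- list(config = config, truth = truth, calls_case = case$calls,
              carriers_case = case$carriers)
  if (include_controls) {
    ctl <- draw_cohort(config$n_control_inhouse, "CTL",
                       truth$control_frequency, "cnv/control")
    truth$control_carriers <- as.integer(
      table(factor(ctl$carriers$region_id, truth$region_id)))
    out$truth <- truth
    out$calls_control <- ctl$calls
    out$carriers_control <- ctl$carriers
  }
  class(out) <- "cnv_sim"
  out
}

#' Write simulated CNV call sets
#'
#' Emits one BED-like TSV per caller and cohort (`chrom start end type
#' sample`, 0-based half-open starts) plus the truth table.
#'
#' @param sim A `cnv_sim`.
#' @param dir Output directory.
#' @return Named list of paths, invisibly.
#' @export
write_cnv_callsets <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  emit <- function(calls, stem) {
    for (caller in unique(calls$caller)) {
      f <- file.path(dir, sprintf("%s_caller%s.bed", stem, caller))
      sub <- calls[calls$caller == caller, ]
      data.table::fwrite(
        data.frame(sub$chrom, sub$start - 1L, sub$end, sub$type,
                   sub$sample_id),
        f, sep = "\t", col.names = FALSE)
      paths[[sprintf("%s_%s", stem, caller)]] <<- f
    }
  }
  emit(sim$calls_case, "case")
  if (!is.null(sim$calls_control)) emit(sim$calls_control, "control")
  paths$truth <- file.path(dir, "truth_cnv.tsv")
  data.table::fwrite(sim$truth, paths$truth, sep = "\t")
  invisible(paths)
}

#' Read a CNV call table
#'
#' Reads the BED-like format written by [write_cnv_callsets()]: `chrom
#' start end type sample`, 0-based half-open, one row per call.
#'
#' @param path Path to the file.
#' @param caller Caller label to attach.
#' @return data.frame (sample_id, chrom, start, end, type, caller) with
#'   1-based closed coordinates.
#' @export
read_cnv_calls <- function(path, caller = NA_character_) {
  dt <- data.table::fread(path, header = FALSE,
                          col.names = c("chrom", "start0", "end", "type",
                                        "sample_id"))
  if (any(dt$end <= dt$start0)) {
    stop("CNV call with end <= start at line ",
         which(dt$end <= dt$start0)[1])
  }
  if (!all(dt$type %in% c("DEL", "DUP"))) {
    stop("CNV type must be DEL or DUP")
  }
  data.frame(sample_id = dt$sample_id, chrom = dt$chrom,
             start = as.integer(dt$start0 + 1L), end = as.integer(dt$end),
             type = dt$type, caller = caller, stringsAsFactors = FALSE)
}
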