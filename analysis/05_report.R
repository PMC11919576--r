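#!/usr/bin/env Rscript
# Collate the headline numbers from every stage into one summary table.
#
#   Rscript analysis/05_report.R

suppressMessages(library(icepipe))

tsv <- function(f) utils::read.delim(f, comment.char = "#")
coding <- tsv("results/burden_coding.tsv")
calib <- tsv("results/calibration.tsv")
cnv <- tsv("results/cnv_regions.tsv")
dmr <- tsv("results/dmr.tsv")
rec <- tsv("results/recurrent_hmrs.tsv")
sel <- tsv("results/recurrent_differential.tsv")
dmgs <- tsv("results/dmgs.tsv")
prov <- read_provenance("results/burden_coding.tsv")

dmr_sig <- dmr[dmr$is_dmr, ]
rows <- data.frame(
  quantity = c(
    "seed", "chosen quality tranche (%)",
    "lambda95 at full inclusion",
    "significant burden genes (Bonferroni)",
    "top burden gene", "top burden p",
    "consensus CNV regions", "CNV regions enriched in cases (q<=0.05)",
    "recurrent HMR regions", "DMRs (q<=0.05)",
    "hypomethylated DMR fraction (%)",
    "recurrent differential regions (>10% cases, delta < -0.1)",
    "differentially methylated genes"),
  value = c(
    prov$seed, as.numeric(prov$tranche) * 100,
    calib$lambda95[calib$tranche == 1],
    sum(coding$significant), coding$feature_id[1],
    signif(coding$p_one_sided[1], 3),
    nrow(cnv), sum(cnv$q <= 0.05, na.rm = TRUE),
    nrow(rec), nrow(dmr_sig),
    round(100 * mean(dmr_sig$direction == "hypo"), 1),
    nrow(sel), nrow(dmgs)))
print(rows, right = FALSE, row.names = FALSE)
write_tsv_prov(rows, "results/summary.tsv", list(seed = prov$seed))
message("summary written to results/summary.tsv")
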