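#!/usr/bin/env Rscript
# Generate the synthetic cohort: case/control VCFs, feature and coverage
# tracks, dual-caller CNV call sets and case/control methylomes, together
# with the truth tables downstream scripts score against.
#
#   Rscript analysis/01_simulate.R [seed]

suppressMessages(library(icepipe))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
outdir <- file.path("results", "inputs")

cfg <- simulation_config(seed = seed)
message("simulating burden cohort: ", cfg$n_case, " cases, ",
        cfg$n_control_inhouse, " in-house controls, ",
        cfg$n_control_summary, " summary controls, ",
        cfg$n_genes, " genes")
burden <- simulate_burden_cohort(cfg)
p1 <- write_burden_cohort(burden, outdir)
message("  ", nrow(burden$case$variants), " case variant records -> ",
        p1$case_vcf)

message("simulating CNV call sets: ", cfg$n_cnv_regions,
        " truth regions, jitter sd ", cfg$cnv_jitter_sd, " bp, FN ",
        cfg$cnv_fn_rate, ", FP ", cfg$cnv_fp_rate, "/sample")
cnv <- simulate_cnv_callsets(cfg)
p2 <- write_cnv_callsets(cnv, outdir)
message("  ", nrow(cnv$calls_case), " case caller calls")

message("simulating methylomes: ", cfg$n_meth_case, " case vs ",
        cfg$n_meth_control, " control samples, ",
        cfg$n_hmr_blocks, " HMR blocks, ", cfg$n_dmr_regions,
        " differential regions (", 100 * cfg$meth_hypo_fraction,
        "% hypomethylated, effect ", cfg$dmr_effect, ")")
meth <- simulate_methylomes(cfg)
p3 <- write_methylomes(meth, outdir)
message("  ", length(p3$case) + length(p3$control),
        " Bismark coverage files")

writeLines(as.character(seed), file.path(outdir, "seed.txt"))
message("done; inputs under ", outdir)
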