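#!/usr/bin/env Rscript
# Differential methylome: coverage filtering, HMR calling, 100-bp
# recurrence scanning, context annotation, region t-tests, recurrent
# hypomethylated-region selection, gene mapping and set enrichment.
#
#   Rscript analysis/04_methylome.R

suppressMessages(library(icepipe))
indir <- file.path("results", "inputs")
seed <- as.integer(readLines(file.path(indir, "seed.txt")))

cov_files <- list.files(indir, pattern = "\\.cov$", full.names = TRUE)
ids <- sub("\\.cov$", "", basename(cov_files))
message("reading ", length(cov_files), " Bismark coverage files")
samples <- mapply(read_bismark_cov, cov_files, ids, SIMPLIFY = FALSE)
is_case <- grepl("^MCASE", ids)

ann_files <- list.files(indir, pattern = "^annot_.*\\.bed$",
                        full.names = TRUE)
annotations <- lapply(ann_files, read_bed)
names(annotations) <- sub("^annot_(.*)\\.bed$", "\\1", basename(ann_files))
gp_bed <- read_bed(file.path(indir, "gene_parts.bed"))
gp_meta <- strsplit(gp_bed$name, "|", fixed = TRUE)
gene_parts <- feature_set(gp_bed,
                          id = vapply(gp_meta, `[`, character(1), 1),
                          feature_class = vapply(gp_meta, `[`,
                                                 character(1), 2))
gene_sets <- read_gmt(file.path(indir, "gene_sets.gmt"))

sim <- list(case = samples[is_case], control = samples[!is_case],
            annotations = annotations, gene_parts = gene_parts,
            gene_sets = gene_sets)
res <- run_methylome_stage(sim)

s <- res$summary
message(sprintf(paste0(
  "%d recurrent HMR regions (%.1f%% outside CpG islands/shores/shelves); ",
  "%d tested, %d DMRs (%.1f%% hypomethylated in cases)"),
  s[["n_recurrent"]], 100 * s[["out_of_cgi_fraction"]], s[["n_tested"]],
  s[["n_dmr"]], 100 * s[["hypo_fraction"]]))
message(sprintf(paste0(
  "%d recurrent regions (>10%% of cases) with differential methylation ",
  "< -0.1; %d differentially methylated genes"),
  s[["n_selected"]], s[["n_dmg"]]))
sig_sets <- res$enrichment[res$enrichment$significant, ]
message("enriched gene sets (adjusted p <= 0.05): ",
        if (nrow(sig_sets)) paste(sig_sets$set_id, collapse = ", ")
        else "none")

prov <- list(seed = seed, min_coverage = 5, window = 100,
             min_fraction = 0.05, focal_max = 10000)
write_tsv_prov(res$recurrent, "results/recurrent_hmrs.tsv", prov)
write_tsv_prov(res$dmr, "results/dmr.tsv", prov)
write_tsv_prov(res$selected, "results/recurrent_differential.tsv", prov)
write_tsv_prov(data.frame(gene = res$dmgs), "results/dmgs.tsv", prov)
write_tsv_prov(res$enrichment, "results/enrichment.tsv", prov)
message("methylome tables written under results/")
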