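#!/usr/bin/env Rscript
# Step 1 -- generate the synthetic study: a two-condition, two-replicate
# calibrated CUT&RUN experiment with planted condition-specific and common
# H3K27me3-like domains, an IgG-like background sample pair, a peptidoform
# intensity table with a planted 2x histone-mark change, and a chromatin
# proteome LFQ matrix with a planted differential subset.
#
# Writes fragment BEDs, the peptidoform and proteome tables, and the ground
# truth under results/sim/.

suppressPackageStartupMessages(library(chromaquant))

seed <- 20260928L
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

target_genome <- c(chrT = 10e6)
spikein_genome <- c(chrS = 5e6)

# 60 planted 10-kb domains, 20 per class, fold 4 over background. cond1
# plays the naive-like role: higher global coating (2x) on top of which its
# specific domains sit.
regions <- data.frame(
  chrom = "chrT",
  start = round(seq(1e4, 9.8e6, length.out = 60)),
  class = rep(c("cond1_enriched", "cond2_enriched", "common"), each = 20),
  fold = 4)
regions$end <- regions$start + 1e4
regions <- regions[, c("chrom", "start", "end", "class", "fold")]

params <- cutrun_sim_params(
  target_genome, spikein_genome, n_cells = 50000,
  global_level = c(cond1 = 2, cond2 = 1),
  planted_regions = regions, spikein_rate = 0.4,
  depth_scale = c(c1r1 = 1, c1r2 = 0.8, c2r1 = 1.2, c2r2 = 1),
  conditions = c(c1r1 = "cond1", c1r2 = "cond1",
                 c2r1 = "cond2", c2r2 = "cond2"),
  fragment_length = 100L)
sim <- simulate_cutrun(params, seed = seed)

igg_params <- cutrun_sim_params(
  target_genome, spikein_genome, n_cells = 50000,
  global_level = c(cond1 = 0.4, cond2 = 0.4),
  planted_regions = regions, spikein_rate = 0.4,
  depth_scale = c(igg1 = 1, igg2 = 1),
  conditions = c(igg1 = "cond1", igg2 = "cond2"),
  fragment_length = 150L, igg = TRUE)
igg <- simulate_cutrun(igg_params, seed = seed + 1L)

for (s in names(sim$samples))
  write_fragments(sim$samples[[s]], file.path(out, paste0(s, ".bed")))
for (s in names(igg$samples))
  write_fragments(igg$samples[[s]], file.path(out, paste0(s, ".bed")))
write.table(regions, file.path(out, "truth_regions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# Mark panel in the style of a naive-vs-primed comparison: K27me2/me3 and
# K79me2 up in cond1, K36me2 down (antagonism), K4/K9/K18 unchanged.
marks <- rbind(
  data.frame(histone = "H3", residue = "K27",
             state = c("un", "me2", "me3"),
             prop_cond1 = c(0.15, 0.40, 0.45),
             prop_cond2 = c(0.55, 0.20, 0.25)),
  data.frame(histone = "H3", residue = "K79",
             state = c("un", "me1", "me2"),
             prop_cond1 = c(0.55, 0.10, 0.35),
             prop_cond2 = c(0.75, 0.10, 0.15)),
  data.frame(histone = "H3", residue = "K36",
             state = c("un", "me2", "me3"),
             prop_cond1 = c(0.50, 0.20, 0.30),
             prop_cond2 = c(0.30, 0.45, 0.25)),
  data.frame(histone = "H3", residue = rep(c("K4", "K9", "K18"), each = 2),
             state = rep(c("un", "me2"), 3),
             prop_cond1 = rep(c(0.8, 0.2), 3),
             prop_cond2 = rep(c(0.8, 0.2), 3)))
pf <- simulate_peptidoforms(marks, c(cond1 = 7, cond2 = 5), cv = 0.1,
                            seed = seed + 2L)
write.table(pf$table, file.path(out, "peptidoforms.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(sample = names(pf$design), condition = pf$design),
            file.path(out, "peptidoform_design.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(marks, file.path(out, "truth_marks.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

prot <- simulate_proteome(n_proteins = 1000, n_per_group = c(cond1 = 3, cond2 = 3),
                          frac_differential = 0.1, true_log2fc = 2,
                          sd_log2 = 0.3, detection_limit_quantile = 0.05,
                          seed = seed + 3L)
pm <- prot$matrix
write.table(data.frame(protein_id = rownames(pm$intensities), pm$flags[-1],
                       pm$intensities, check.names = FALSE),
            file.path(out, "proteome_lfq.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(prot$truth$differential, file.path(out, "truth_proteins.txt"))

cat("Simulated", length(sim$samples), "H3K27me3-like and",
    length(igg$samples), "IgG-like samples;",
    sum(vapply(sim$samples, nrow, 0L)), "fragments total.\n")
cat("True global coating ratio cond1/cond2:", sim$truth$global_ratio, "\n")
cat("Peptidoform table:", nrow(pf$table), "peptidoforms x",
    length(pf$design), "samples; proteome:", nrow(pm$intensities),
    "proteins.\n")
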