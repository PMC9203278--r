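#!/usr/bin/env Rscript
# Step 6 -- writer/eraser network integration: join the chromatin-proteome
# fold changes of modifier enzymes with the fold changes of their target
# histone marks over the curated write/erase edge list, and score each edge
# as concordant, discordant, neutral or missing. Because the simulated
# proteome uses synthetic protein ids, modifier fold changes here come from
# a small worked table in the style of a naive-vs-primed comparison; the
# mark fold changes are the measured ones from step 4.

suppressPackageStartupMessages(library(chromaquant))

out <- "results/integration"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

edges <- read_modifier_edges(system.file("extdata",
                                         "writer_eraser_edges.tsv",
                                         package = "chromaquant"))
hptm <- read.delim("results/hptm/hptm_abundance.tsv")
mark_fc <- setNames(hptm$log2fc, hptm$mark)

# worked modifier panel: DOT1L up with its mark; K27me3 erasers also up
# (the decoupling case); an acetyltransferase down with its mark neutral
protein_fc <- c(DOT1L = 1.4, EZH2 = 0.6, KDM6A = 0.9, KDM6B = 0.7,
                EP300 = -0.8, NSD2 = -1.1, SETD2 = 0.2)

tab <- score_concordance(build_network(edges, protein_fc, mark_fc),
                         fc_threshold = 0.5)
write.table(tab, file.path(out, "concordance.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
s <- attr(tab, "summary")
cat("Edge status counts:",
    paste(names(s), as.integer(s), collapse = ", "), "\n")
shown <- tab[tab$status %in% c("concordant", "discordant"), ]
for (i in seq_len(nrow(shown)))
  cat(sprintf("  %-8s %-12s %-10s modifier %+0.2f, mark %+0.2f -> %s\n",
              shown$modifier[i], shown$mark[i], shown$relation[i],
              shown$modifier_fc[i], shown$mark_fc[i], shown$status[i]))
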