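#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study — 50 candidate precursors with
# planted truth, an 8-library count matrix with planted tissue enrichment,
# the 9-tissue x 8-individual Ct design, and three planned qPCR DE runs.

library(mirpost)

seed <- 20L
dir <- "results/simdata"
sim <- write_simulation(seed, dir)

cat("simulated study written to", dir, "\n")
cat(" candidates:", nrow(sim$candidates$candidates),
    "( planted:", paste(names(table(sim$candidates$truth$class)),
                        table(sim$candidates$truth$class), collapse = ", "),
    ")\n")
cat(" count matrix:", paste(dim(sim$counts$counts), collapse = " x "),
    "| library sizes",
    paste(range(colSums(sim$counts$counts)), collapse = " - "), "\n")
cat(" Ct matrix:", paste(dim(sim$ct$ct), collapse = " x "),
    "(9 tissues x 8 individuals)\n")
cat(" qPCR DE plan:", nrow(sim$de_plan), "miRNAs, planted shifts",
    paste(sim$de_plan$shift, collapse = "/"), "cycles\n")
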