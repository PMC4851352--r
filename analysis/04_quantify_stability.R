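#!/usr/bin/env Rscript
# Stage 4: quantify mature miRNAs (perfect matches only), normalize to the
# per-10^4 scale, screen stable (low-RSD) and tissue-enriched candidates,
# then rank the qPCR reference-gene candidates by the model-based stability
# value, including the best two-gene combination.

library(mirpost)

indir <- "results/simdata"
outdir <- "results/quantify"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

matures <- read_fasta(file.path(indir, "matures.fa"))
reads <- read_tsv(file.path(indir, "reads.tsv"))
cm <- count_perfect_matches(reads, matures)
nm <- normalize_counts(cm)
write_tsv_matrix(cm, file.path(outdir, "counts.tsv"))
write_tsv_matrix(round(nm, 4), file.path(outdir, "normalized_counts.tsv"))
cat("counted", sum(cm), "perfectly matching reads over", nrow(cm),
    "matures x", ncol(cm), "libraries\n")
cat("normalized column sums (per-10^4):",
    paste(unique(round(colSums(nm))), collapse = ", "), "\n")

rsd <- compute_rsd(nm)
write_tsv(data.frame(mature_id = names(rsd), rsd = round(rsd, 4)),
          file.path(outdir, "rsd.tsv"))
stable <- screen_reference_candidates(rsd, NULL, 5)
cat("lowest-RSD reference candidates:", paste(stable, collapse = ", "), "\n")

tm <- read_tsv(file.path(indir, "tissue_map.tsv"))
enr <- screen_enriched_candidates(nm, setNames(tm$tissue, tm$sample_id),
                                  min_ratio = 4)
write_tsv(enr, file.path(outdir, "enriched_candidates.tsv"))
cat("tissue-enriched candidates (ratio >= 4):", nrow(enr), "\n")

ct <- read_tsv_matrix(file.path(indir, "ct_matrix.tsv"))
ctm <- read_tsv(file.path(indir, "ct_tissue_map.tsv"))
groups <- ctm$tissue[match(colnames(ct), ctm$sample_id)]
fit <- normfinder_stability(linearize_ct(ct), groups)
pair <- best_pair(linearize_ct(ct), groups)
write_tsv(fit$table, file.path(outdir, "stability.tsv"))
write_tsv(pair$all_pairs, file.path(outdir, "stability_pairs.tsv"))
cat("\nreference-gene stability (lower = more stable):\n")
print(fit$table)
cat("best single:", fit$best_single,
    sprintf("(%.4f)", fit$table$stability[1]), "\n")
cat("best pair:", paste(pair$pair, collapse = " + "),
    sprintf("(%.4f)", pair$stability), "\n")
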