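# Readers/writers for the standard formats the pipeline consumes, plus the
# configuration object and the end-to-end driver.  All genomic coordinates
# are 1-based inclusive on disk (GFF3 convention).

#' Read / write FASTA sequence sets
#'
#' Thin wrappers around Biostrings keeping sequences as a named character
#' vector (the pipeline treats mature and precursor sequences as plain
#' strings).
#'
#' @param path file path.
#' @param seqs named character vector of sequences.
#' @return `read_fasta`: named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read / write annotated gene loci as GFF3
#'
#' Gene tables (`gene_id`, `contig`, `start`, `end`, `strand`, plus any extra
#' attribute columns such as `status` or `cluster_id`) round-trip through
#' GFF3 with `type = miRNA_primary_transcript`. Zero-width or inverted
#' intervals are rejected.
#'
#' @param genes data.frame of gene loci.
#' @param path file path.
#' @param extra_cols names of extra columns to carry as GFF3 attributes.
#' @return `read_gff3`: data.frame with `gene_id`, `contig`, `start`, `end`,
#'   `strand` and any attribute columns found.
#' @export
write_gff3 <- function(genes, path, extra_cols = intersect(
  c("status", "family_annotation", "arm_dominance", "cluster_id"),
  names(genes))) {
  if (any(genes$start > genes$end) || any(genes$start < 1L))
    stop("invalid interval (start > end or start < 1) in gene table")
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$type <- "miRNA_primary_transcript"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$Name <- genes$gene_id
  for (col in extra_cols) S4Vectors::mcols(gr)[[col]] <- genes[[col]]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (any(GenomicRanges::width(gr) < 1L))
    stop("zero-length interval in GFF3: ", path)
  out <- data.frame(
    gene_id = S4Vectors::mcols(gr)$ID,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  for (col in setdiff(names(S4Vectors::mcols(gr)),
                      c("type", "source", "phase", "score", "ID", "Name")))
    out[[col]] <- S4Vectors::mcols(gr)[[col]]
  out
}

BLAST_COLS <- c("query_id", "subject_id", "pident", "length", "mismatch",
                "gapopen", "q_start", "q_end", "s_start", "s_end",
                "e_value", "bit_score")

#' Read a BLAST tabular (outfmt 6 style) hit file
#'
#' Expects the 12 standard columns (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore), optionally followed by a
#' 13th `subject_db` column; alternatively `subject_db` can be supplied for
#' a whole single-database file.
#'
#' @param path file path (no header).
#' @param subject_db optional database label applied to all rows.
#' @return data.frame of hits with a `subject_db` column.
#' @export
read_blast_tab <- function(path, subject_db = NULL) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (!ncol(x) %in% c(12L, 13L))
    stop("BLAST tabular file must have 12 or 13 columns: ", path)
  names(x)[1:12] <- BLAST_COLS
  if (ncol(x) == 13L) names(x)[13L] <- "subject_db"
  if (!is.null(subject_db)) x$subject_db <- subject_db
  if (is.null(x$subject_db))
    stop("subject_db neither in file nor supplied: ", path)
  if (any(x$e_value < 0)) stop("negative E-value in ", path)
  x
}

#' @rdname read_blast_tab
#' @param hits hit data.frame (as produced by [simulate_candidates()]).
#' @export
write_blast_tab <- function(hits, path) {
  utils::write.table(hits[, c(BLAST_COLS, "subject_db")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a numeric matrix as TSV
#'
#' Header row of sample ids, first column of feature ids; values round-trip
#' exactly for integer counts.
#'
#' @param m numeric matrix with row and column names.
#' @param path file path.
#' @return `read_tsv_matrix`: numeric matrix.
#' @export
write_tsv_matrix <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_matrix
#' @export
read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Read / write plain record tables (TSV with header)
#'
#' @param df data.frame.
#' @param path file path.
#' @return `read_tsv`: data.frame.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Assemble and validate a pipeline configuration
#'
#' All tunable thresholds of the pipeline with their defaults; unknown keys
#' are rejected and every threshold is range-checked. `config` may be a list
#' of overrides or the path to a YAML file of overrides.
#'
#' @param config list of overrides or YAML path (optional).
#' @return validated named list of parameters.
#' @export
pipeline_config <- function(config = list()) {
  defaults <- list(
    score_cutoff = 4,        # discovery-score threshold (strictly above)
    e_value_max = 1e-06,     # BLAST significance for all three databases
    max_loci = 5L,           # repeat filter: >max_loci significant loci
    min_samples = 2L,        # novel validation: libraries with reads
    min_arm_reads = 5L,      # novel validation: pooled reads per arm (>)
    consistency_frac = 0.9,  # modal 5'-start fraction per arm
    max_gap = 10000L,        # cluster chaining distance (strictly less)
    gap_mode = "edge",
    min_read_len = 18L,      # quantification length filter (keep >=)
    alpha = 0.05,
    n_tests = 76L,           # Bonferroni denominator
    mean_mode = "geometric", # reference-gene Ct combination
    promotion_rule = "median_below_max",
    seed = 1L)
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  with(cfg, {
    stopifnot(is.finite(score_cutoff), e_value_max > 0, max_loci >= 1,
              min_samples >= 1, min_arm_reads >= 0,
              consistency_frac > 0, consistency_frac <= 1,
              max_gap >= 1, min_read_len >= 1,
              alpha > 0, alpha < 1, n_tests >= 1,
              gap_mode %in% c("edge", "start"),
              mean_mode %in% c("geometric", "arithmetic"),
              promotion_rule %in% c("median_below_max",
                                    "median_below_median"))
  })
  cfg
}

#' Run the whole post-discovery pipeline on a directory of inputs
#'
#' Executes discovery filtering, cluster detection, quantification and RSD
#' screening, reference-gene stability ranking, and delta-delta-Ct
#' differential expression on the files in `input_dir` (the layout written by
#' [write_simulation()]), writing TSV/GFF3 reports and a plain-text log of
#' every decision (one line per rejection, promotion and significance call)
#' to `output_dir`. A failure in any stage halts with an error naming the
#' stage.
#'
#' @param input_dir directory with `candidates.tsv`, `stacks.tsv`,
#'   `blast_hits.tsv`, `matures.fa`, `reads.tsv`, `tissue_map.tsv`,
#'   `ct_matrix.tsv`, `ct_tissue_map.tsv`, `de_plan.tsv`, `qpcr_runs.tsv`.
#' @param output_dir directory for reports (created if missing).
#' @param config overrides passed to [pipeline_config()].
#' @return invisible list of the stage results.
#' @export
run_pipeline <- function(input_dir, output_dir, config = list()) {
  cfg <- pipeline_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  need <- function(f) {
    p <- file.path(input_dir, f)
    if (!file.exists(p)) stop("missing input file: ", f)
    p
  }

  ## discovery filter
  report <- stage("discover-filter", {
    cand <- read_tsv(need("candidates.tsv"))
    stacks <- read_tsv(need("stacks.tsv"))
    hits <- read_blast_tab(need("blast_hits.tsv"))
    classify_candidates(cand, stacks, hits,
                        score_cutoff = cfg$score_cutoff,
                        max_loci = cfg$max_loci,
                        min_samples = cfg$min_samples,
                        min_arm_reads = cfg$min_arm_reads,
                        consistency_frac = cfg$consistency_frac,
                        e_max = cfg$e_value_max)
  })
  for (i in which(report$status == "rejected"))
    say("reject\t", report$gene_id[i], "\t", report$rejection_reason[i])
  say("discovery\tconserved=", sum(report$status == "conserved"),
      " novel=", sum(report$status == "novel"),
      " rejected=", sum(report$status == "rejected"))
  write_tsv(report, file.path(output_dir, "classification.tsv"))
  accepted <- report[report$status != "rejected", , drop = FALSE]
  write_gff3(accepted, file.path(output_dir, "annotated_genes.gff3"))

  ## clusters
  clusters <- stage("cluster", {
    detect_clusters(accepted[, c("gene_id", "contig", "start", "end",
                                 "strand")],
                    max_gap = cfg$max_gap, gap_mode = cfg$gap_mode)
  })
  say("clusters\tn_clusters=", length(unique(clusters$cluster_id)),
      " clustered_genes=", nrow(clusters))
  write_tsv(summarise_clusters(clusters),
            file.path(output_dir, "clusters.tsv"))

  ## quantification
  quant <- stage("quantify", {
    matures <- read_fasta(need("matures.fa"))
    reads <- read_tsv(need("reads.tsv"))
    cm <- count_perfect_matches(reads, matures, min_len = cfg$min_read_len)
    cm <- cm[, colSums(cm) > 0, drop = FALSE]
    nm <- normalize_counts(cm)
    list(cm = cm, nm = nm, rsd = compute_rsd(nm))
  })
  write_tsv_matrix(quant$cm, file.path(output_dir, "counts.tsv"))
  write_tsv_matrix(quant$nm, file.path(output_dir, "normalized_counts.tsv"))
  write_tsv(data.frame(mature_id = names(quant$rsd), rsd = quant$rsd),
            file.path(output_dir, "rsd.tsv"))
  say("quantify\tmirnas=", nrow(quant$cm), " samples=", ncol(quant$cm))

  ## reference-gene stability
  stability <- stage("refgenes", {
    ct <- read_tsv_matrix(need("ct_matrix.tsv"))
    tm <- read_tsv(need("ct_tissue_map.tsv"))
    groups <- tm$tissue[match(colnames(ct), tm$sample_id)]
    fit <- normfinder_stability(linearize_ct(ct), groups)
    pair <- best_pair(linearize_ct(ct), groups)
    list(fit = fit, pair = pair)
  })
  say("refgenes\tbest_single=", stability$fit$best_single,
      " best_pair=", paste(stability$pair$pair, collapse = "+"))
  write_tsv(stability$fit$table, file.path(output_dir, "stability.tsv"))

  ## differential expression
  de <- stage("diffexpr", {
    runs <- read_tsv(need("qpcr_runs.tsv"))
    plan <- read_tsv(need("de_plan.tsv"))
    thr <- bonferroni_alpha(cfg$alpha, cfg$n_tests)
    res <- do.call(rbind, lapply(seq_len(nrow(plan)), function(i) {
      r <- runs[runs$mirna == plan$mirna[i], , drop = FALSE]
      target <- r[r$gene == "target", c("sample_id", "tissue", "ct")]
      refs <- r[r$gene != "target", c("sample_id", "gene", "ct")]
      out <- de_test(target, refs, plan$initial_target[i], thr,
                     mean_mode = cfg$mean_mode, rule = cfg$promotion_rule)
      cbind(data.frame(mirna = plan$mirna[i], stringsAsFactors = FALSE), out)
    }))
    res
  })
  for (i in seq_len(nrow(de))) {
    extra <- setdiff(strsplit(de$target_tissues[i], ",")[[1]], de$mirna[i])
    say("de\t", de$mirna[i], "\tp=", signif(de$p[i], 3),
        "\tfold=", signif(de$fold_change[i], 3),
        "\tsignificant=", de$significant[i])
  }
  write_tsv(de, file.path(output_dir, "de_report.tsv"))

  writeLines(log_lines, file.path(output_dir, "run.log"))
  invisible(list(classification = report, clusters = clusters,
                 quant = quant, stability = stability, de = de,
                 config = cfg, log = log_lines))
}

#' Write a simulated study to the pipeline's input layout
#'
#' Materializes the outputs of the generators as the on-disk formats
#' [run_pipeline()] consumes, plus `truth_*.tsv` files for exact scoring of
#' every stage.
#'
#' @param seed integer seed forwarded to all generators (each stage uses a
#'   distinct derived seed).
#' @param dir output directory (created if missing).
#' @param ... overrides forwarded to [simulate_counts()].
#' @return invisible list of the simulated objects.
#' @export
write_simulation <- function(seed, dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim_c <- simulate_candidates(seed)
  write_tsv(sim_c$candidates, file.path(dir, "candidates.tsv"))
  write_tsv(sim_c$stacks, file.path(dir, "stacks.tsv"))
  write_blast_tab(sim_c$hits, file.path(dir, "blast_hits.tsv"))
  write_fasta(sim_c$precursors, file.path(dir, "precursors.fa"))
  write_tsv(sim_c$truth, file.path(dir, "truth_candidates.tsv"))
  write_tsv(sim_c$truth_clusters, file.path(dir, "truth_clusters.tsv"))

  sim_q <- simulate_counts(seed + 1L, ...)
  # express the count matrix as collapsed reads so quantification is
  # exercised end to end
  matures <- stats::setNames(
    vapply(seq_len(nrow(sim_q$counts)), function(i) .rand_seq(22L),
           character(1)),
    rownames(sim_q$counts))
  reads <- do.call(rbind, lapply(colnames(sim_q$counts), function(s) {
    data.frame(sample_id = s, sequence = unname(matures),
               count = sim_q$counts[, s], stringsAsFactors = FALSE)
  }))
  write_fasta(matures, file.path(dir, "matures.fa"))
  write_tsv(reads, file.path(dir, "reads.tsv"))
  write_tsv(data.frame(sample_id = names(sim_q$tissue_of_sample),
                       tissue = unname(sim_q$tissue_of_sample)),
            file.path(dir, "tissue_map.tsv"))
  write_tsv(sim_q$truth, file.path(dir, "truth_counts.tsv"))

  ref_genes <- data.frame(
    gene = c("ref-a", "ref-b", "ref-c", "ref-d"),
    baseline_ct = c(20, 22, 24, 26),
    inter_sd = c(0.1, 0.15, 0.4, 0.8),
    intra_sd = c(0.2, 0.25, 0.5, 0.9), stringsAsFactors = FALSE)
  sim_ct <- simulate_ct(seed + 2L, ref_genes)
  write_tsv_matrix(round(sim_ct$ct, 4), file.path(dir, "ct_matrix.tsv"))
  write_tsv(data.frame(sample_id = names(sim_ct$tissue_of_sample),
                       tissue = unname(sim_ct$tissue_of_sample)),
            file.path(dir, "ct_tissue_map.tsv"))
  write_tsv(sim_ct$truth, file.path(dir, "truth_ct.tsv"))

  plan <- data.frame(mirna = c("mir-de-1", "mir-de-2", "mir-null"),
                     initial_target = c("liver", "brain", "spleen"),
                     shift = c(5, 3, 0), stringsAsFactors = FALSE)
  runs <- do.call(rbind, lapply(seq_len(nrow(plan)), function(i) {
    run <- simulate_qpcr_run(seed + 2L + i,
                             target_tissue = plan$initial_target[i],
                             shift_cycles = plan$shift[i])
    rbind(cbind(data.frame(mirna = plan$mirna[i], gene = "target"),
                run$target[, c("sample_id", "tissue", "ct")]),
          cbind(data.frame(mirna = plan$mirna[i]),
                run$refs[, c("gene", "sample_id")],
                tissue = NA_character_, ct = run$refs$ct))
  }))
  runs <- runs[, c("mirna", "gene", "sample_id", "tissue", "ct")]
  write_tsv(runs, file.path(dir, "qpcr_runs.tsv"))
  write_tsv(plan[, c("mirna", "initial_target")],
            file.path(dir, "de_plan.tsv"))
  write_tsv(plan, file.path(dir, "truth_de.tsv"))
  invisible(list(candidates = sim_c, counts = sim_q, ct = sim_ct,
                 de_plan = plan))
}
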