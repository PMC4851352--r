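# Seeded generators emulating the study design the pipeline assumes:
# eight deep-sequencing libraries (one per organ) for discovery and
# quantification, and a nine-tissue x eight-individual design for RT-qPCR.
# All generators are deterministic given their seed.

STUDY_TISSUES <- c("head_kidney", "heart", "brain", "gills", "muscle",
                   "liver", "spleen", "skin", "intestine")

.rand_seq <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Read stacks for one candidate.  Reads sit on the mature intervals
# (5p at offset `off5`, 3p at `off3`); `frac_modal` controls which fraction
# of each arm's reads shares the modal 5' start.
.make_stacks <- function(candidate_id, samples, reads5p, reads3p,
                         off5 = 10L, off3 = 38L, frac_modal = 1) {
  spread <- function(total, n) {  # split a read total across n samples
    if (total == 0L) return(integer(n))
    base <- rep(total %/% n, n)
    extra <- total %% n
    if (extra > 0L) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
    base
  }
  rows <- list()
  for (arm in c("5p", "3p")) {
    total <- if (arm == "5p") reads5p else reads3p
    off <- if (arm == "5p") off5 else off3
    modal <- round(total * frac_modal)
    per_sample <- spread(modal, length(samples))
    off_counts <- data.frame(start_offset = off, n = per_sample,
                             sample_id = samples)
    if (total - modal > 0L) {
      off_counts <- rbind(off_counts, data.frame(
        start_offset = off + 1L, n = spread(total - modal, length(samples)),
        sample_id = samples))
    }
    off_counts <- off_counts[off_counts$n > 0L, , drop = FALSE]
    if (nrow(off_counts))
      rows[[arm]] <- data.frame(candidate_id = candidate_id,
                                sample_id = off_counts$sample_id, arm = arm,
                                start_offset = off_counts$start_offset,
                                read_length = 22L, count = off_counts$n,
                                stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate candidate precursors with planted truth labels
#'
#' Generates candidate precursor records, read stacks and BLAST-style hit
#' tables such that each candidate satisfies — or violates in exactly one
#' way — the classification rules: conserved candidates carry a significant
#' miRBase-style hit, repeats hit more than five genomic loci, valid novels
#' have reads in at least two libraries, more than five pooled reads per arm
#' and consistent 5' processing, and each negative class breaks a single
#' criterion. Truth labels are returned alongside for exact scoring.
#'
#' @param seed integer RNG seed.
#' @param class_counts named integer vector over the classes `conserved`,
#'   `novel`, `low_score`, `other_smallrna`, `repeat`,
#'   `insufficient_samples`, `insufficient_arm_reads`,
#'   `inconsistent_5p_end`. The default plants 50 candidates.
#' @param n_samples number of sequencing libraries (default 8).
#' @param score_cutoff score threshold the scores are planted around
#'   (default 4).
#' @param cluster_sizes sizes of gene clusters planted among the conserved
#'   candidates (same contig and strand, neighbour gaps of 2-6 kb), as real
#'   miRNA repertoires keep a share of genes in polycistronic clusters;
#'   default plants clusters of 3, 3 and 2 genes.
#' @return list with `candidates` (manifest data.frame), `stacks`, `hits`,
#'   `matures` (named vector of unique mature sequences), `precursors`
#'   (named vector), `truth` (`candidate_id`, `class`, and the expected
#'   `status`/`rejection_reason`), and `truth_clusters` (`candidate_id`,
#'   `cluster` index for planted cluster members).
#' @export
simulate_candidates <- function(seed,
                                class_counts = c(conserved = 20L, novel = 10L,
                                                 low_score = 5L,
                                                 other_smallrna = 3L,
                                                 `repeat` = 5L,
                                                 insufficient_samples = 3L,
                                                 insufficient_arm_reads = 2L,
                                                 inconsistent_5p_end = 2L),
                                n_samples = 8L, score_cutoff = 4,
                                cluster_sizes = c(3L, 3L, 2L)) {
  set.seed(seed)
  samples <- sprintf("lib%02d", seq_len(n_samples))
  classes <- rep(names(class_counts), class_counts)
  n <- length(classes)
  ids <- sprintf("cand-%03d", seq_len(n))

  precursors <- vapply(seq_len(n), function(i) .rand_seq(70L), character(1))
  names(precursors) <- ids
  m5 <- substr(precursors, 11L, 32L)
  m3 <- substr(precursors, 39L, 60L)

  contigs <- sprintf("contig_%02d", sample.int(20L, n, replace = TRUE))
  start <- sample.int(5e5L, n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  # plant gene clusters among the conserved candidates: consecutive members
  # share a dedicated contig and strand with 2-6 kb gaps
  truth_clusters <- data.frame(candidate_id = character(),
                               cluster = integer(),
                               stringsAsFactors = FALSE)
  conserved_idx <- which(classes == "conserved")
  if (length(cluster_sizes) && sum(cluster_sizes) <= length(conserved_idx)) {
    pick <- sample(conserved_idx, sum(cluster_sizes))
    at <- 0L
    for (ci in seq_along(cluster_sizes)) {
      members <- pick[at + seq_len(cluster_sizes[ci])]
      at <- at + cluster_sizes[ci]
      contigs[members] <- sprintf("contig_cl%02d", ci)
      strand[members] <- sample(c("+", "-"), 1L)
      pos <- 1000L + cumsum(c(0L, sample(2000:6000, cluster_sizes[ci] - 1L,
                                         replace = TRUE)))
      start[members] <- pos
      truth_clusters <- rbind(truth_clusters,
                              data.frame(candidate_id = ids[members],
                                         cluster = ci,
                                         stringsAsFactors = FALSE))
    }
  }
  candidates <- data.frame(
    candidate_id = ids, contig = contigs, start = start, end = start + 69L,
    strand = strand,
    score = ifelse(classes == "low_score",
                   round(stats::runif(n, 0, score_cutoff), 2),
                   round(stats::runif(n, score_cutoff + 1, 100), 2)),
    mature5p_seq = m5, mature3p_seq = m3, stringsAsFactors = FALSE)

  stack_list <- list()
  hit_list <- list()
  blast_row <- function(qid, sid, db, e, bits, s_start = 1L, s_end = 70L)
    data.frame(query_id = qid, subject_id = sid, subject_db = db,
               pident = 98, length = 70L, mismatch = 1L, gapopen = 0L,
               q_start = 1L, q_end = 70L, s_start = s_start, s_end = s_end,
               e_value = e, bit_score = bits, stringsAsFactors = FALSE)

  for (i in seq_len(n)) {
    id <- ids[i]
    cls <- classes[i]
    two <- sample(samples, 2L)
    stack_list[[id]] <- switch(
      cls,
      insufficient_samples = .make_stacks(id, samples[1L], 20L, 15L),
      insufficient_arm_reads = .make_stacks(id, two, 12L, 4L),
      inconsistent_5p_end = .make_stacks(id, two, 20L, 20L,
                                         frac_modal = 0.5),
      .make_stacks(id, sample(samples, sample(2:4, 1L)),
                   sample(8:60, 1L), sample(8:60, 1L)))
    hit_list[[id]] <- switch(
      cls,
      conserved = blast_row(id, sprintf("dre-mir-%d", sample.int(500L, 1L)),
                            "mirbase", 10^stats::runif(1, -30, -6),
                            stats::runif(1, 80, 140)),
      other_smallrna = blast_row(id, sprintf("RF%05d", sample.int(3000L, 1L)),
                                 "rfam", 10^stats::runif(1, -20, -6),
                                 stats::runif(1, 80, 140)),
      `repeat` = do.call(rbind, lapply(seq_len(sample(6:12, 1L)), function(k) {
        s0 <- sample.int(9e5L, 1L)
        blast_row(id, sprintf("contig_%02d", sample.int(20L, 1L)), "genome",
                  10^stats::runif(1, -20, -6), stats::runif(1, 80, 140),
                  s_start = s0, s_end = s0 + 69L)
      })),
      # everyone else: the self-locus genome hit plus a weak mirbase hit
      rbind(blast_row(id, candidates$contig[i], "genome", 1e-30, 140,
                      s_start = candidates$start[i],
                      s_end = candidates$end[i]),
            blast_row(id, sprintf("dre-mir-%d", sample.int(500L, 1L)),
                      "mirbase", 10^stats::runif(1, -4, -1),
                      stats::runif(1, 20, 40))))
  }
  stacks <- do.call(rbind, stack_list)
  hits <- do.call(rbind, hit_list)
  rownames(stacks) <- rownames(hits) <- NULL

  expected_status <- ifelse(classes %in% c("conserved", "novel"),
                            classes, "rejected")
  expected_reason <- ifelse(expected_status == "rejected", classes,
                            NA_character_)
  matures <- c(stats::setNames(m5, paste0(ids, "-5p")),
               stats::setNames(m3, paste0(ids, "-3p")))
  matures <- matures[!duplicated(matures)]
  list(candidates = candidates, stacks = stacks, hits = hits,
       matures = matures, precursors = precursors,
       truth = data.frame(candidate_id = ids, class = classes,
                          status = expected_status,
                          rejection_reason = expected_reason,
                          stringsAsFactors = FALSE),
       truth_clusters = truth_clusters)
}

#' Simulate a mature miRNA x sample read-count matrix
#'
#' Counts follow a negative-binomial model: each miRNA gets a relative
#' abundance (log-normal), per-tissue means are shifted by the planted
#' enrichment fold for enriched miRNAs, and library sizes vary at least
#' five-fold across the samples, as small-RNA libraries do. One library per
#' tissue, emulating the eight-organ deep-sequencing design.
#'
#' @param seed integer RNG seed.
#' @param n_mirna number of mature miRNAs (default 60).
#' @param n_enriched how many miRNAs carry a planted tissue enrichment
#'   (default 10).
#' @param fold planted enrichment fold (default 8).
#' @param dispersion negative-binomial `size` parameter (default 10; larger =
#'   less overdispersed).
#' @param lib_sizes expected total counts per library (default spans
#'   2e5..1e6, a five-fold spread over 8 libraries).
#' @param tissues tissue labels, one library each (default: eight of the
#'   nine study organs).
#' @return list with `counts` (integer matrix miRNAs x samples),
#'   `tissue_of_sample` (named character), and `truth` (`mature_id`,
#'   `enriched_tissue` (NA when none), `fold`).
#' @export
simulate_counts <- function(seed, n_mirna = 60L, n_enriched = 10L, fold = 8,
                            dispersion = 10,
                            lib_sizes = round(seq(2e5, 1e6,
                                                  length.out = 8L)),
                            tissues = setdiff(STUDY_TISSUES, "heart")) {
  stopifnot(fold > 0, n_enriched <= n_mirna,
            length(lib_sizes) == length(tissues))
  set.seed(seed)
  n_s <- length(tissues)
  samples <- sprintf("lib%02d", seq_len(n_s))
  tissue_of_sample <- stats::setNames(tissues, samples)
  ids <- sprintf("mir-%03d", seq_len(n_mirna))

  rel <- stats::rlnorm(n_mirna, meanlog = 0, sdlog = 1.2)
  enriched_tissue <- rep(NA_character_, n_mirna)
  if (n_enriched > 0L)
    enriched_tissue[seq_len(n_enriched)] <-
      sample(tissues, n_enriched, replace = TRUE)

  mu <- outer(rel, rep(1, n_s))
  for (i in seq_len(n_mirna)) {
    if (!is.na(enriched_tissue[i]))
      mu[i, tissues == enriched_tissue[i]] <-
        mu[i, tissues == enriched_tissue[i]] * fold
  }
  mu <- sweep(mu, 2L, colSums(mu), "/")          # per-sample composition
  mu <- sweep(mu, 2L, lib_sizes, "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = dispersion),
                   nrow = n_mirna, dimnames = list(ids, samples))
  storage.mode(counts) <- "integer"
  list(counts = counts, tissue_of_sample = tissue_of_sample,
       truth = data.frame(mature_id = ids,
                          enriched_tissue = enriched_tissue,
                          fold = ifelse(is.na(enriched_tissue), 1, fold),
                          stringsAsFactors = FALSE))
}

#' Simulate a Ct matrix over the tissue x individual qPCR design
#'
#' `Ct = gene baseline + tissue effect + individual noise`, all on the cycle
#' scale: the tissue effect is drawn once per gene and tissue from
#' `N(0, inter_sd)` (the inter-group spread), individual noise is
#' `N(0, intra_sd)` per measurement, and a planted target-tissue shift
#' (`shift_cycles` > 0 lowers the Ct, i.e. raises expression) can be added
#' for differential-expression genes.
#'
#' @param seed integer RNG seed.
#' @param genes data.frame describing the genes: `gene`, `baseline_ct`,
#'   `inter_sd`, `intra_sd`, and optional `shift_tissue`, `shift_cycles`.
#' @param tissues tissue labels (default: the nine study organs).
#' @param n_individuals individuals per tissue (default 8).
#' @return list with `ct` (matrix genes x samples, columns named
#'   `tissue.individual`), `tissue_of_sample`, `individual_of_sample`, and
#'   `truth` (= `genes`).
#' @export
simulate_ct <- function(seed, genes, tissues = STUDY_TISSUES,
                        n_individuals = 8L) {
  stopifnot(is.data.frame(genes),
            all(c("gene", "baseline_ct", "inter_sd", "intra_sd") %in%
                  names(genes)))
  set.seed(seed)
  n_g <- nrow(genes)
  design <- expand.grid(individual = sprintf("ind%d", seq_len(n_individuals)),
                        tissue = tissues, stringsAsFactors = FALSE)
  samples <- paste(design$tissue, design$individual, sep = ".")
  ct <- matrix(NA_real_, n_g, nrow(design),
               dimnames = list(genes$gene, samples))
  for (i in seq_len(n_g)) {
    eff <- stats::rnorm(length(tissues), 0, genes$inter_sd[i])
    names(eff) <- tissues
    if (!is.null(genes$shift_tissue) && !is.na(genes$shift_tissue[i]))
      eff[genes$shift_tissue[i]] <-
        eff[genes$shift_tissue[i]] - genes$shift_cycles[i]
    ct[i, ] <- genes$baseline_ct[i] + eff[design$tissue] +
      stats::rnorm(nrow(design), 0, genes$intra_sd[i])
  }
  list(ct = ct,
       tissue_of_sample = stats::setNames(design$tissue, samples),
       individual_of_sample = stats::setNames(design$individual, samples),
       truth = genes)
}

#' Simulate one RT-qPCR differential-expression run
#'
#' Emulates a single assay run: all individuals from the target tissue plus
#' `n_ref_per_tissue` individuals from each reference tissue, with Ct values
#' for the target miRNA (baseline minus `shift_cycles` in the target tissue)
#' and for the stable reference genes measured on the same samples.
#'
#' @param seed integer RNG seed.
#' @param target_tissue tissue with the planted enrichment.
#' @param shift_cycles planted expression shift in cycles (0 = null miRNA).
#' @param intra_sd per-measurement Ct noise (default 0.5 cycles).
#' @param ref_intra_sd reference-gene Ct noise (default 0.3 cycles).
#' @param n_ref_tissues number of reference tissues sampled (default 7).
#' @param n_individuals individuals in the target tissue (default 8).
#' @param n_ref_per_tissue individuals per reference tissue (default 4).
#' @param ref_genes names of the reference assays (default two).
#' @return list with `target` (`sample_id`, `tissue`, `ct`) and `refs`
#'   (`sample_id`, `gene`, `ct`) ready for [de_test()], plus `truth`.
#' @export
simulate_qpcr_run <- function(seed, target_tissue = "liver",
                              shift_cycles = 5, intra_sd = 0.5,
                              ref_intra_sd = 0.3, n_ref_tissues = 7L,
                              n_individuals = 8L, n_ref_per_tissue = 4L,
                              ref_genes = c("ref-mir-a", "ref-mir-b")) {
  set.seed(seed)
  ref_tissues <- sample(setdiff(STUDY_TISSUES, target_tissue), n_ref_tissues)
  tissue <- c(rep(target_tissue, n_individuals),
              rep(ref_tissues, each = n_ref_per_tissue))
  sample_id <- paste(tissue, stats::ave(tissue, tissue, FUN = seq_along),
                     sep = ".")
  baseline <- 30
  shift <- ifelse(tissue == target_tissue, shift_cycles, 0)
  target <- data.frame(
    sample_id = sample_id, tissue = tissue,
    ct = baseline - shift + stats::rnorm(length(tissue), 0, intra_sd),
    stringsAsFactors = FALSE)
  refs <- do.call(rbind, lapply(seq_along(ref_genes), function(k) {
    data.frame(sample_id = sample_id, gene = ref_genes[k],
               ct = 20 + 2 * (k - 1) +
                 stats::rnorm(length(sample_id), 0, ref_intra_sd),
               stringsAsFactors = FALSE)
  }))
  list(target = target, refs = refs,
       truth = data.frame(target_tissue = target_tissue,
                          shift_cycles = shift_cycles,
                          stringsAsFactors = FALSE))
}
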