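# Significance threshold for BLAST evidence used throughout the
# classification chain (miRBase homology, Rfam exclusion, repeat loci).
EVALUE_SIGNIFICANT <- 1e-06

#' Keep candidate precursors scoring strictly above a cutoff
#'
#' The discovery tool's score threshold is picked from its signal-to-noise
#' table (typically the score giving a 30:1 ratio of real to permuted-genome
#' candidates); precursors with scores *above* that threshold are carried
#' forward, so equality with the cutoff drops a candidate.
#'
#' @param candidates data.frame of candidate precursors with at least
#'   `candidate_id` and numeric `score` columns.
#' @param cutoff finite numeric score threshold.
#' @return The rows of `candidates` with `score > cutoff`, input order kept.
#' @export
apply_score_cutoff <- function(candidates, cutoff) {
  stopifnot(is.data.frame(candidates), length(cutoff) == 1L, is.finite(cutoff))
  if (nrow(candidates) == 0L) return(candidates)
  if (!is.numeric(candidates$score) || any(!is.finite(candidates$score)))
    stop("candidate scores must be finite numerics")
  candidates[candidates$score > cutoff, , drop = FALSE]
}

# Pick the best hit among rows of a BLAST hit table: lowest E-value, ties by
# highest bit score, then lexicographic subject id.  Deterministic.
.best_hit <- function(hits) {
  ord <- order(hits$e_value, -hits$bit_score, hits$subject_id)
  hits[ord[1L], , drop = FALSE]
}

#' Classify a candidate as an evolutionarily conserved miRNA
#'
#' A candidate whose precursor matches a known stem-loop with
#' E-value <= 1e-06 is annotated as the conserved ortholog of the family
#' retrieving the best hit (lowest E-value; ties broken by highest bit score,
#' then alphabetical subject id). The boundary E-value 1e-06 itself counts as
#' a match.
#'
#' @param candidate_id id of the candidate being classified.
#' @param hits BLAST tabular hits (`query_id`, `subject_id`, `e_value`,
#'   `bit_score`) against a miRBase-like stem-loop set; all rows must belong
#'   to `candidate_id`.
#' @param e_max significance threshold on the E-value (default 1e-06).
#' @return The best-hit subject id (family annotation) or `NA_character_`
#'   when no significant hit exists.
#' @export
classify_conserved <- function(candidate_id, hits, e_max = EVALUE_SIGNIFICANT) {
  hits <- .check_hits(hits, candidate_id)
  sig <- hits[hits$e_value <= e_max, , drop = FALSE]
  if (nrow(sig) == 0L) return(NA_character_)
  .best_hit(sig)$subject_id
}

.check_hits <- function(hits, candidate_id) {
  if (is.null(hits) || nrow(hits) == 0L)
    return(data.frame(query_id = character(), subject_id = character(),
                      e_value = numeric(), bit_score = numeric()))
  if (any(hits$query_id != candidate_id))
    stop("BLAST hits supplied for a different query than '", candidate_id, "'")
  if (any(hits$e_value < 0)) stop("negative E-value in BLAST hits")
  hits
}

#' Reject candidates that look like other non-miRNA small RNAs
#'
#' A significant match (E-value <= `e_max`) to an Rfam-style small-RNA family
#' database marks the precursor as some other small RNA class and removes it
#' from the novel-miRNA pool.
#'
#' @inheritParams classify_conserved
#' @return TRUE to keep the candidate, FALSE to reject it.
#' @export
filter_other_smallrna <- function(candidate_id, hits, e_max = EVALUE_SIGNIFICANT) {
  hits <- .check_hits(hits, candidate_id)
  !any(hits$e_value <= e_max)
}

#' Reject candidates hitting too many genomic loci
#'
#' Precursors with significant BLAST hits (E-value <= `e_max`) against more
#' than `max_loci` distinct loci of the reference genome are treated as
#' interspersed or tandem repeats. Distinct loci are counted after merging
#' overlapping hit intervals on the same subject sequence and strand, so HSP
#' fragments of one locus count once.
#'
#' @inheritParams classify_conserved
#' @param hits genome BLAST hits; distinct loci are derived from
#'   `subject_id`, `s_start`, `s_end` when present, otherwise each row is a
#'   locus.
#' @param max_loci maximum tolerated number of significant loci (default 5;
#'   the stricter published variant uses 50).
#' @return TRUE to keep, FALSE to reject as repeat-derived.
#' @export
filter_repeats <- function(candidate_id, hits, max_loci = 5L,
                           e_max = EVALUE_SIGNIFICANT) {
  stopifnot(max_loci >= 1L)
  hits <- .check_hits(hits, candidate_id)
  sig <- hits[hits$e_value <= e_max, , drop = FALSE]
  if (nrow(sig) == 0L) return(TRUE)
  n_loci <- if (all(c("s_start", "s_end") %in% names(sig))) {
    gr <- GenomicRanges::GRanges(
      seqnames = sig$subject_id,
      ranges = IRanges::IRanges(pmin(sig$s_start, sig$s_end),
                                pmax(sig$s_start, sig$s_end)),
      strand = ifelse(sig$s_start <= sig$s_end, "+", "-"))
    length(GenomicRanges::reduce(gr))
  } else {
    length(unique(sig$subject_id))
  }
  n_loci <= max_loci
}

#' Validate a putative novel miRNA from its precursor read stacks
#'
#' Novel miRNA candidates must satisfy, in order: (i) reads observed in at
#' least `min_samples` independent libraries; (ii) pooled perfectly matching
#' reads strictly exceeding `min_arm_reads` on the 5p arm *and* on the 3p
#' arm; (iii) consistent processing of the mature 5' end on each arm,
#' quantified as the modal read start offset carrying at least
#' `consistency_frac` of the arm's reads. The first failing criterion
#' determines the rejection reason.
#'
#' @param stacks data.frame of read stacks for one candidate: `sample_id`,
#'   `arm` ("5p"/"3p"), `start_offset`, `count`.
#' @param min_samples minimum number of distinct libraries with reads
#'   (default 2).
#' @param min_arm_reads pooled per-arm read count that must be exceeded
#'   (default 5: six reads or more pass).
#' @param consistency_frac minimum fraction of an arm's reads sharing the
#'   modal 5' start (default 0.9).
#' @return list with `accepted` (logical) and `reason` (`NA` or one of
#'   `"insufficient_samples"`, `"insufficient_arm_reads"`,
#'   `"inconsistent_5p_end"`).
#' @export
validate_novel <- function(stacks, min_samples = 2L, min_arm_reads = 5L,
                           consistency_frac = 0.9) {
  rejected <- function(reason) list(accepted = FALSE, reason = reason)
  if (is.null(stacks) || nrow(stacks) == 0L)
    return(rejected("insufficient_samples"))
  stopifnot(all(stacks$count >= 0), all(stacks$arm %in% c("5p", "3p")))
  stacks <- stacks[stacks$count > 0, , drop = FALSE]
  if (length(unique(stacks$sample_id)) < min_samples)
    return(rejected("insufficient_samples"))
  arm_tot <- vapply(c("5p", "3p"), function(a)
    sum(stacks$count[stacks$arm == a]), numeric(1))
  if (any(arm_tot <= min_arm_reads))
    return(rejected("insufficient_arm_reads"))
  for (a in c("5p", "3p")) {
    s <- stacks[stacks$arm == a, , drop = FALSE]
    per_start <- tapply(s$count, s$start_offset, sum)
    if (max(per_start) / sum(per_start) < consistency_frac)
      return(rejected("inconsistent_5p_end"))
  }
  list(accepted = TRUE, reason = NA_character_)
}

#' Call 5p/3p arm dominance from pooled read counts
#'
#' The arm contributing the larger pooled read count across all libraries is
#' the dominant arm; exactly equal counts are called codominant.
#'
#' @inheritParams validate_novel
#' @return "5p", "3p" or "codominant".
#' @export
call_arm_dominance <- function(stacks) {
  if (is.null(stacks) || nrow(stacks) == 0L || sum(stacks$count) == 0)
    stop("arm dominance requires at least one aligned read")
  tot5 <- sum(stacks$count[stacks$arm == "5p"])
  tot3 <- sum(stacks$count[stacks$arm == "3p"])
  if (tot5 > tot3) "5p" else if (tot3 > tot5) "3p" else "codominant"
}

#' Collapse mature sequences to the unique set
#'
#' Mature 5p and 3p sequences from all annotated genes are grouped by exact
#' string identity (gene family members often share identical matures), giving
#' the total number of unique mature miRNAs and, per unique sequence, the
#' genes contributing it.
#'
#' @param genes data.frame with `gene_id`, `mature5p_seq`, `mature3p_seq`
#'   (NA or "" entries are skipped).
#' @return data.frame with one row per unique mature sequence: `sequence`,
#'   `n_members`, `members` (comma-joined "gene_id:arm" tags), sorted by
#'   decreasing membership then sequence.
#' @export
collapse_unique_matures <- function(genes) {
  long <- rbind(
    data.frame(gene_id = genes$gene_id, arm = "5p",
               sequence = genes$mature5p_seq, stringsAsFactors = FALSE),
    data.frame(gene_id = genes$gene_id, arm = "3p",
               sequence = genes$mature3p_seq, stringsAsFactors = FALSE))
  long <- long[!is.na(long$sequence) & nzchar(long$sequence), , drop = FALSE]
  if (nrow(long) == 0L)
    return(data.frame(sequence = character(), n_members = integer(),
                      members = character(), stringsAsFactors = FALSE))
  grp <- split(paste0(long$gene_id, ":", long$arm), long$sequence)
  out <- data.frame(
    sequence = names(grp),
    n_members = vapply(grp, length, integer(1)),
    members = vapply(grp, function(x) paste(sort(x), collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$n_members, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full candidate classification chain
#'
#' Applies, in order: the score cutoff (below-or-equal scores are rejected as
#' `low_score`), conserved-miRNA annotation against the miRBase-like hits,
#' the other-small-RNA exclusion (Rfam-like hits), the repeat-locus filter
#' (genome hits), and novel-miRNA read-stack validation. Every candidate ends
#' in exactly one of the states conserved, novel or rejected, and each
#' candidate is classified independently of the others.
#'
#' @param candidates candidate table (`candidate_id`, `contig`, `start`,
#'   `end`, `strand`, `score`, `mature5p_seq`, `mature3p_seq`).
#' @param stacks read-stack table for all candidates (see [validate_novel()]).
#' @param hits BLAST hit table for all candidates with a `subject_db` column
#'   in `c("mirbase", "rfam", "genome")` (other labels are ignored).
#' @param score_cutoff score threshold (see [apply_score_cutoff()]).
#' @param max_loci,min_samples,min_arm_reads,consistency_frac,e_max
#'   thresholds passed to the individual filters.
#' @return data.frame (one row per candidate, input order): `gene_id`,
#'   `status`, `rejection_reason`, `family_annotation`, `arm_dominance`,
#'   plus the location columns of the input.
#' @export
classify_candidates <- function(candidates, stacks, hits,
                                score_cutoff,
                                max_loci = 5L, min_samples = 2L,
                                min_arm_reads = 5L, consistency_frac = 0.9,
                                e_max = EVALUE_SIGNIFICANT) {
  stopifnot(!anyDuplicated(candidates$candidate_id))
  hit_split <- if (nrow(hits)) split(hits, hits$query_id) else list()
  stack_split <- if (nrow(stacks)) split(stacks, stacks$candidate_id) else list()

  one <- function(i) {
    cand <- candidates[i, , drop = FALSE]
    id <- cand$candidate_id
    h <- hit_split[[id]]
    st <- stack_split[[id]]
    status <- "rejected"; reason <- NA_character_; fam <- NA_character_
    if (cand$score <= score_cutoff) {
      reason <- "low_score"
    } else {
      fam <- classify_conserved(id, h[h$subject_db == "mirbase", , drop = FALSE],
                                e_max = e_max)
      if (!is.na(fam)) {
        status <- "conserved"
      } else if (!filter_other_smallrna(id, h[h$subject_db == "rfam", , drop = FALSE],
                                        e_max = e_max)) {
        reason <- "other_smallrna"
      } else if (!filter_repeats(id, h[h$subject_db == "genome", , drop = FALSE],
                                 max_loci = max_loci, e_max = e_max)) {
        reason <- "repeat"
      } else {
        v <- validate_novel(st, min_samples = min_samples,
                            min_arm_reads = min_arm_reads,
                            consistency_frac = consistency_frac)
        if (v$accepted) status <- "novel" else reason <- v$reason
      }
    }
    dom <- if (status != "rejected" && !is.null(st) && sum(st$count) > 0)
      call_arm_dominance(st) else NA_character_
    data.frame(gene_id = id, status = status, rejection_reason = reason,
               family_annotation = fam, arm_dominance = dom,
               contig = cand$contig, start = cand$start, end = cand$end,
               strand = cand$strand,
               mature5p_seq = cand$mature5p_seq,
               mature3p_seq = cand$mature3p_seq,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(candidates)), one))
  rownames(out) <- NULL
  out
}
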