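cand_row <- function(id = "c1", score = 10, contig = "ctg1", start = 100) {
  data.frame(candidate_id = id, contig = contig, start = start,
             end = start + 69L, strand = "+", score = score,
             mature5p_seq = "ACGUACGUACGUACGUACGUAC",
             mature3p_seq = "UGCAUGCAUGCAUGCAUGCAUG",
             stringsAsFactors = FALSE)
}

hit_row <- function(qid, sid, e, bits = 100, db = "mirbase",
                    s_start = NULL, s_end = NULL) {
  out <- data.frame(query_id = qid, subject_id = sid, subject_db = db,
                    e_value = e, bit_score = bits, stringsAsFactors = FALSE)
  if (!is.null(s_start)) { out$s_start <- s_start; out$s_end <- s_end }
  out
}

test_that("score cutoff keeps strictly-above scores and preserves order", {
  cands <- rbind(cand_row("a", 5), cand_row("b", 4), cand_row("c", 4.01))
  kept <- apply_score_cutoff(cands, 4)
  expect_identical(kept$candidate_id, c("a", "c"))  # 4.0 == cutoff dropped
  expect_identical(nrow(apply_score_cutoff(cands[0, ], 4)), 0L)
  # raising the cutoff is monotone in the retained count
  ns <- vapply(c(0, 2, 4, 5, 100),
               function(ct) nrow(apply_score_cutoff(cands, ct)), integer(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("conserved classification honours the E-value boundary and best-hit tie-breaks", {
  expect_identical(classify_conserved("q", hit_row("q", "mir-x", 1e-06)),
                   "mir-x")                       # boundary included
  expect_true(is.na(classify_conserved("q", hit_row("q", "mir-x", 1e-05))))
  two <- rbind(hit_row("q", "mir-92", 1e-08), hit_row("q", "mir-25", 1e-10))
  expect_identical(classify_conserved("q", two), oracle_best_hit(two))
  expect_identical(classify_conserved("q", two), "mir-25")
  # ties resolved by bit score then subject id, matching the oracle
  tie <- rbind(hit_row("q", "mir-b", 1e-09, bits = 90),
               hit_row("q", "mir-a", 1e-09, bits = 90),
               hit_row("q", "mir-c", 1e-09, bits = 95))
  expect_identical(classify_conserved("q", tie), oracle_best_hit(tie))
  expect_identical(classify_conserved("q", tie), "mir-c")
  expect_error(classify_conserved("q", hit_row("other", "mir-x", 1e-10)),
               "different query")
})

test_that("Rfam exclusion rejects on significant hits only", {
  expect_false(filter_other_smallrna("q", hit_row("q", "RF00001", 1e-09, db = "rfam")))
  expect_true(filter_other_smallrna("q", hit_row("q", "RF00001", 0.01, db = "rfam")))
  expect_true(filter_other_smallrna("q", NULL))
})

test_that("repeat filter counts distinct merged loci against the >max_loci rule", {
  mk <- function(n, width_gap = 1000L) {
    do.call(rbind, lapply(seq_len(n), function(k)
      hit_row("q", "ctgR", 1e-09, db = "genome",
              s_start = k * width_gap, s_end = k * width_gap + 70L)))
  }
  expect_false(filter_repeats("q", mk(6), max_loci = 5))
  expect_true(filter_repeats("q", mk(5), max_loci = 5))
  expect_false(filter_repeats("q", mk(60), max_loci = 5))
  expect_false(filter_repeats("q", mk(60), max_loci = 50))  # stricter preset
  # overlapping HSP fragments of one locus count once
  frag <- rbind(hit_row("q", "ctgR", 1e-09, db = "genome", s_start = 100, s_end = 170),
                hit_row("q", "ctgR", 1e-09, db = "genome", s_start = 150, s_end = 220))
  expect_true(filter_repeats("q", rbind(frag, mk(4, 10000L)), max_loci = 5))
  # non-significant hits never count
  weak <- do.call(rbind, lapply(1:10, function(k)
    hit_row("q", paste0("c", k), 1e-03, db = "genome", s_start = 1, s_end = 70)))
  expect_true(filter_repeats("q", weak, max_loci = 5))
})

stack_row <- function(sample, arm, off, count) {
  data.frame(candidate_id = "c1", sample_id = sample, arm = arm,
             start_offset = off, read_length = 22L, count = count,
             stringsAsFactors = FALSE)
}

test_that("novel validation applies its three criteria in order", {
  # one library only, even with plenty of reads on both arms
  one_lib <- rbind(stack_row("s1", "5p", 12, 20), stack_row("s1", "3p", 48, 20))
  expect_identical(validate_novel(one_lib)$reason, "insufficient_samples")
  expect_identical(validate_novel(NULL)$reason, "insufficient_samples")
  # exactly five 3p reads is not "more than five"
  five <- rbind(stack_row("s1", "5p", 12, 10), stack_row("s2", "3p", 48, 5))
  expect_identical(validate_novel(five)$reason, "insufficient_arm_reads")
  # modal 5' start must carry >= 90% of each arm's reads
  ok <- rbind(stack_row("s1", "5p", 12, 9), stack_row("s1", "5p", 13, 1),
              stack_row("s2", "3p", 48, 7))
  expect_true(validate_novel(ok)$accepted)  # 9/10 and 7/7 pass 0.9
  bad <- rbind(stack_row("s1", "5p", 12, 8), stack_row("s1", "5p", 13, 2),
               stack_row("s2", "3p", 48, 7))
  expect_identical(validate_novel(bad)$reason, "inconsistent_5p_end")
  # raising the consistency requirement never rescues an inconsistent one
  for (f in c(0.92, 0.95, 0.99, 1)) {
    expect_false(validate_novel(bad, consistency_frac = f)$accepted)
  }
  expect_true(validate_novel(bad, consistency_frac = 0.8)$accepted)
})

test_that("arm dominance is the larger pooled count, ties codominant", {
  expect_identical(call_arm_dominance(
    rbind(stack_row("s1", "5p", 12, 100), stack_row("s1", "3p", 48, 10))), "5p")
  expect_identical(call_arm_dominance(
    rbind(stack_row("s1", "5p", 12, 10), stack_row("s1", "3p", 48, 10))),
    "codominant")
  multi <- rbind(stack_row("s1", "5p", 12, 7), stack_row("s2", "5p", 12, 3),
                 stack_row("s1", "3p", 48, 6), stack_row("s2", "3p", 48, 5))
  expect_identical(call_arm_dominance(multi), "3p")  # 10 vs 11 pooled
  expect_error(call_arm_dominance(NULL), "at least one")
})

test_that("mature collapsing groups by exact string identity", {
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    mature5p_seq = c("UGGAAUGUAAAGAAGUAUGUAU", "UGGAAUGUAAAGAAGUAUGUAU",
                     "UGGAAUGUAAAGAAGUAUGUAC"),  # one nt off: distinct
    mature3p_seq = c("ACCCGUAGAUCCGAACUUGUGG", "CUUUCAGUCGGAUGUUUGCAGC",
                     "AGCUACAUUGUCUGCUGGGUUU"),
    stringsAsFactors = FALSE)
  u <- collapse_unique_matures(genes)
  expect_identical(nrow(u), 5L)  # 6 matures, one shared
  shared <- u[u$n_members == 2L, ]
  expect_identical(shared$members, "g1:5p,g2:5p")
  # no collapsing: all-distinct matures give 2 entries per gene
  n <- 245L
  distinct <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n)),
    mature5p_seq = sprintf("AAAAAAAAAAAAAAAAAA%04d", seq_len(n)),
    mature3p_seq = sprintf("CCCCCCCCCCCCCCCCCC%04d", seq_len(n)),
    stringsAsFactors = FALSE)
  expect_identical(nrow(collapse_unique_matures(distinct)), 2L * n)
})

test_that("the classification chain is exhaustive, order-independent and recovers planted truth", {
  sim <- simulate_candidates(101)
  rep <- classify_candidates(sim$candidates, sim$stacks, sim$hits,
                             score_cutoff = 4)
  # conservation: every candidate in exactly one state
  expect_identical(nrow(rep), nrow(sim$candidates))
  expect_true(all(rep$status %in% c("conserved", "novel", "rejected")))
  expect_true(all(!is.na(rep$rejection_reason[rep$status == "rejected"])))
  expect_true(all(is.na(rep$rejection_reason[rep$status != "rejected"])))
  expect_true(all(!is.na(rep$family_annotation[rep$status == "conserved"])))
  # planted truth recovered exactly
  expect_identical(rep$status, sim$truth$status)
  expect_identical(rep$rejection_reason, sim$truth$rejection_reason)
  # order independence: classify a shuffled copy
  set.seed(9)
  perm <- sample(nrow(sim$candidates))
  rep2 <- classify_candidates(sim$candidates[perm, ], sim$stacks, sim$hits,
                              score_cutoff = 4)
  expect_identical(rep2[order(rep2$gene_id), ]$status,
                   rep[order(rep$gene_id), ]$status)
})
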