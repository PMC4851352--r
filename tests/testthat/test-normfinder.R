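# A small deterministic Ct toy: 4 genes, 2 tissue groups of 4 samples.
toy_ct <- function(noise_mult = 1) {
  base <- rbind(
    g1 = c(20.0, 20.1, 19.9, 20.0,   20.1, 20.0, 19.9, 20.0),
    g2 = c(22.0, 22.4, 21.8, 22.2,   23.1, 23.4, 22.9, 23.0),
    g3 = c(24.0, 24.8, 23.6, 24.4,   23.2, 22.8, 23.6, 23.4),
    g4 = c(26.0, 26.2, 25.8, 26.1,   26.1, 25.9, 26.0, 26.2))
  if (noise_mult != 1) {
    mean4 <- ave(base["g4", ], rep(1:2, each = 4))
    base["g4", ] <- mean4 + (base["g4", ] - mean4) * noise_mult
  }
  base
}
toy_groups <- rep(c("A", "B"), each = 4)

test_that("Ct linearization doubles per cycle and cancels downstream", {
  ct <- toy_ct()
  lin <- linearize_ct(ct)
  expect_equal(as.numeric(2^(ct[2, 1] - ct[1, 1])),
               as.numeric(lin[1, 1] / lin[2, 1]))  # 1 Ct = 2-fold ratio
  expect_equal(as.numeric(lin[1, 2] / lin[1, 4]),
               as.numeric(2^(ct[1, 4] - ct[1, 2])))
  expect_error(linearize_ct(matrix(c(20, NA), 1, 2)), "finite")
  # global Ct shifts leave every stability value unchanged
  f1 <- normfinder_stability(linearize_ct(ct), toy_groups)
  f2 <- normfinder_stability(linearize_ct(ct + 3), toy_groups)
  expect_equal(f1$table, f2$table)
})

test_that("stability values match the loop-based variance-decomposition oracle", {
  ct <- toy_ct()
  fit <- normfinder_stability(linearize_ct(ct), toy_groups)
  orc <- oracle_stability(log2(linearize_ct(ct)), toy_groups)
  got <- fit$table$stability[match(names(orc$stability), fit$table$gene)]
  expect_equal(got, unname(orc$stability), tolerance = 1e-12)
  expect_equal(fit$gamma2, orc$gamma2, tolerance = 1e-12)
  # groups can be relabelled freely
  relab <- normfinder_stability(linearize_ct(ct),
                                rep(c("zzz", "aaa"), each = 4))
  expect_equal(sort(relab$table$stability), sort(fit$table$stability))
})

test_that("inflating a gene's within-group noise increases its stability value", {
  base <- normfinder_stability(linearize_ct(toy_ct()), toy_groups)
  noisy <- normfinder_stability(linearize_ct(toy_ct(noise_mult = 4)),
                                toy_groups)
  g4_base <- base$table$stability[base$table$gene == "g4"]
  g4_noisy <- noisy$table$stability[noisy$table$gene == "g4"]
  expect_gt(g4_noisy, g4_base)
})

test_that("a constant gene among noisy ones is ranked most stable", {
  genes <- data.frame(
    gene = c("flat", paste0("n", 1:4)),
    baseline_ct = c(20, 22, 24, 26, 28),
    inter_sd = c(0, 0.6, 0.7, 0.8, 0.9),
    intra_sd = c(0, 0.5, 0.6, 0.7, 0.8), stringsAsFactors = FALSE)
  sim <- simulate_ct(42, genes, tissues = c("A", "B", "C"), n_individuals = 4)
  fit <- normfinder_stability(linearize_ct(sim$ct), sim$tissue_of_sample)
  expect_identical(fit$best_single, "flat")
  expect_identical(fit$table$gene[1], "flat")
})

test_that("extra i.i.d. noise does not reduce a gene's stability value on average", {
  set.seed(88)
  deltas <- replicate(120, {
    ct <- toy_ct()
    fit0 <- normfinder_stability(linearize_ct(ct), toy_groups)
    ct["g2", ] <- ct["g2", ] + rnorm(8, 0, 0.8)
    fit1 <- normfinder_stability(linearize_ct(ct), toy_groups)
    fit1$table$stability[fit1$table$gene == "g2"] -
      fit0$table$stability[fit0$table$gene == "g2"]
  })
  expect_gt(mean(deltas), 0)
})

test_that("the least-variable gene is recovered across seeded replicates", {
  genes <- data.frame(
    gene = c("best", paste0("g", 1:5)),
    baseline_ct = c(20, 21, 22, 23, 24, 25),
    inter_sd = c(0.05, 0.5, 0.6, 0.7, 0.8, 0.9),
    intra_sd = c(0.05, 0.4, 0.5, 0.6, 0.7, 0.8), stringsAsFactors = FALSE)
  hits <- vapply(seq_len(200), function(i) {
    sim <- simulate_ct(3000 + i, genes)   # 9 tissues x 8 individuals
    fit <- normfinder_stability(linearize_ct(sim$ct), sim$tissue_of_sample)
    fit$best_single == "best"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("best pair matches the exhaustive oracle and cancellation beats singles", {
  # constructed toy: group biases (centered across genes) are
  # q1 +1.5, q2 -0.5, q3 -1.0, p1 +2, p2 -2 cycles; the shared noise
  # pattern cancels in the per-sample centering, so stability = |bias|/2
  # exactly and the exactly-opposite pair (p1, p2) has pair stability 0
  bias <- c(q1 = 1.5, q2 = -0.5, q3 = -1.0, p1 = 2, p2 = -2)
  noise <- c(0.1, -0.1, 0.05, -0.05)
  ct <- t(vapply(names(bias), function(g)
    25 + c(rep(-bias[g] / 2, 4), rep(bias[g] / 2, 4)) + rep(noise, 2),
    numeric(8)))
  fit_pair <- best_pair(linearize_ct(ct), toy_groups)
  orc <- oracle_best_pair(log2(linearize_ct(ct)), toy_groups)
  expect_setequal(fit_pair$pair, orc$pair)
  expect_equal(fit_pair$stability, orc$stability, tolerance = 1e-12)
  expect_setequal(fit_pair$pair, c("p1", "p2"))
  expect_equal(fit_pair$stability, 0, tolerance = 1e-10)
  expect_equal(fit_pair$single_stability, 0.25)   # q2, the best single
  expect_lt(fit_pair$stability, fit_pair$single_stability)
  # a duplicated copy of the best single gene pairs with itself
  ct2 <- toy_ct()
  base_fit <- normfinder_stability(linearize_ct(ct2), toy_groups)
  ct2 <- rbind(ct2, dup_best = ct2[base_fit$best_single, ])
  dup <- best_pair(linearize_ct(ct2), toy_groups)
  expect_setequal(dup$pair, c(base_fit$best_single, "dup_best"))
  # random 4-gene inputs agree with the exhaustive search
  set.seed(17)
  for (rep in 1:10) {
    m <- matrix(rnorm(4 * 8, 22, 1), 4, 8,
                dimnames = list(paste0("r", 1:4), NULL))
    got <- best_pair(linearize_ct(m), toy_groups)
    want <- oracle_best_pair(log2(linearize_ct(m)), toy_groups)
    expect_setequal(got$pair, want$pair)
    expect_equal(got$stability, want$stability, tolerance = 1e-12)
  }
})

test_that("degenerate inputs are refused with clear errors", {
  ct <- toy_ct()
  expect_error(normfinder_stability(linearize_ct(ct[1:2, ]), toy_groups),
               "3 genes")
  expect_error(normfinder_stability(linearize_ct(ct), rep("A", 8)),
               "2 sample groups")
  expect_error(normfinder_stability(linearize_ct(ct),
                                    c(rep("A", 7), "B")),
               "fewer than 2")
})
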