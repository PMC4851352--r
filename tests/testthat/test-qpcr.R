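test_that("delta-Ct subtracts the geometric mean of the reference Cts", {
  target <- data.frame(sample_id = c("s1", "s2", "s3"),
                       tissue = c("liver", "liver", "brain"),
                       ct = c(25, 24, 30), stringsAsFactors = FALSE)
  refs <- rbind(
    data.frame(sample_id = c("s1", "s2", "s3"), gene = "r1", ct = c(20, 21, 21)),
    data.frame(sample_id = c("s1", "s2", "s3"), gene = "r2", ct = c(22, 21, 21)))
  d <- delta_ct(target, refs)
  expect_equal(d$delta_ct[1], 25 - sqrt(20 * 22))        # 4.0238
  expect_equal(round(d$delta_ct[1], 3), 4.024)
  expect_equal(d$ref_ct[2], 21)                          # equal refs
  expect_equal(d$ref_ct[3], 21)                          # symmetric
  # single reference gene: geometric mean is the identity
  one <- delta_ct(target, refs[refs$gene == "r1", ])
  expect_equal(one$ref_ct, c(20, 21, 21))
  # arithmetic mode on equal refs agrees with geometric
  expect_equal(delta_ct(target, refs, mean_mode = "arithmetic")$ref_ct[2], 21)
  # a sample missing one reference is dropped with a warning
  expect_warning(d2 <- delta_ct(target, refs[-1, ]), "dropped")
  expect_identical(d2$sample_id, c("s2", "s3"))
})

dct_frame <- function(vals) {
  do.call(rbind, lapply(names(vals), function(t)
    data.frame(tissue = t, delta_ct = vals[[t]], stringsAsFactors = FALSE)))
}

test_that("tissue promotion iterates overlap to a fixed point", {
  # clear separation: nothing promoted
  clear <- dct_frame(list(liver = c(4, 5, 6), brain = c(10, 11),
                          gills = c(12, 14)))
  got <- assign_target_tissues(clear, "liver")
  expect_identical(got$target, "liver")
  expect_identical(got$promoted, character(0))
  # one overlapping tissue is promoted
  over <- dct_frame(list(liver = c(4, 5, 6), brain = c(5.5, 5.8),
                         gills = c(12, 14)))
  got <- assign_target_tissues(over, "liver")
  expect_setequal(got$target, c("liver", "brain"))
  # cascade: promoting brain (median 5.9 < liver max 6) extends the target
  # range to 6.8, which then captures heart (median 6.75)
  casc <- dct_frame(list(liver = c(4, 6), brain = c(5, 6.8),
                         heart = c(6.5, 7), gills = c(14, 15)))
  got <- assign_target_tissues(casc, "liver")
  expect_identical(sort(got$target), oracle_promote(casc, "liver"))
  expect_setequal(got$target, c("liver", "brain", "heart"))
  # promotion of everything is an error (no reference group left)
  flat <- dct_frame(list(a = c(5, 5.1, 4.9), b = c(5, 5.05),
                         c = c(4.8, 5.05)))
  expect_error(assign_target_tissues(flat, "a"), "no reference group")
  expect_error(assign_target_tissues(clear, "skin"), "absent")
})

test_that("Welch test reproduces the hand-derived toy and the closed-form oracle", {
  w <- welch_test(c(10.0, 10.5, 11.0), c(15.0, 16.0, 17.0, 18.0))
  expect_equal(round(w$t, 2), -8.49)
  expect_equal(round(w$df, 2), 4.08)
  # identical groups: t = 0, p = 1 (constant case by convention)
  same <- welch_test(c(5, 5), c(5, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # large shift, small variance: overwhelming significance
  expect_lt(welch_test(rnorm(5, 0, 0.01), rnorm(5, 100, 0.01))$p, 1e-6)
  # agreement with the hand-coded formula on random inputs
  set.seed(55)
  for (i in 1:100) {
    x <- rnorm(sample(3:12, 1), rnorm(1, 0, 3), runif(1, 0.2, 3))
    y <- rnorm(sample(3:12, 1), rnorm(1, 0, 3), runif(1, 0.2, 3))
    got <- welch_test(x, y)
    want <- oracle_welch(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("Bonferroni threshold is alpha/m", {
  expect_equal(signif(bonferroni_alpha(0.05, 76), 2), 6.6e-04)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 10), 0.005)
  expect_error(bonferroni_alpha(0.05, 0))
})

test_that("fold change is 2^(reference mean - target mean) and antisymmetric", {
  fc <- fold_change(5, 10)
  expect_equal(fc$ddct, 5)
  expect_equal(fc$fold, 32)
  expect_equal(fold_change(7, 7)$fold, 1)
  expect_equal(fold_change(8.2, 10.7)$fold, 2^2.5)   # ~5.66
  # swapping groups flips the sign and inverts the fold
  swapped <- fold_change(10, 5)
  expect_equal(swapped$ddct, -fc$ddct)
  expect_equal(swapped$fold, 1 / fc$fold)
})

test_that("sequencing fold estimates require full quantifiability", {
  nm <- rbind(ok = c(50, 60, 5, 4, 6), gap = c(50, 60, 0, 4, 6))
  colnames(nm) <- paste0("s", 1:5)
  f <- seq_fold_estimate(nm, c("s1", "s2"), c("s3", "s4", "s5"))
  expect_equal(unname(f["ok"]), 55 / 5)
  expect_true(is.na(f["gap"]))  # a zero sample excludes the miRNA
})

test_that("cross-platform correlation is product-moment on log2 folds", {
  q <- c(2, 4, 8, 16, 32)
  expect_equal(correlate_platforms(q, q * 3), 1)        # proportional
  expect_equal(correlate_platforms(q, rev(q)), -1)      # anti on log scale
  # ten-pair toy against the explicit product-moment formula
  set.seed(4)
  qf <- 2^rnorm(10, 2, 1); sf <- 2^(0.7 * log2(qf) + rnorm(10, 0, 0.5))
  lq <- log2(qf); ls <- log2(sf)
  hand <- sum((lq - mean(lq)) * (ls - mean(ls))) /
    sqrt(sum((lq - mean(lq))^2) * sum((ls - mean(ls))^2))
  expect_equal(correlate_platforms(qf, sf), hand, tolerance = 1e-12)
  expect_warning(r <- correlate_platforms(c(2, 2, 2), c(1, 2, 3)), "zero")
  expect_true(is.na(r))
  expect_error(correlate_platforms(c(1, 2), c(1, 2)), "at least 3")
})

test_that("the end-to-end qPCR pipeline has high power and controlled error", {
  thr <- bonferroni_alpha(0.05, 76)
  shifted <- vapply(seq_len(200), function(i) {
    r <- simulate_qpcr_run(i, shift_cycles = 5)
    de_test(r$target, r$refs, r$truth$target_tissue, thr)$significant
  }, logical(1))
  nulls <- vapply(seq_len(200), function(i) {
    r <- simulate_qpcr_run(20000 + i, shift_cycles = 0)
    de_test(r$target, r$refs, r$truth$target_tissue, thr)$significant
  }, logical(1))
  expect_gte(mean(shifted), 0.95)
  expect_lte(mean(nulls), 0.05)
  # reference-group sizes stay within the study design envelope
  r <- simulate_qpcr_run(7, shift_cycles = 5)
  d <- de_test(r$target, r$refs, r$truth$target_tissue, thr)
  expect_true(d$n_reference >= 20 && d$n_reference <= 32)
  expect_gt(d$fold_change, 0)
})
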