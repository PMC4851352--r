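#' Normalize target Ct values against reference genes (delta-Ct)
#'
#' Per sample, `delta_ct = target Ct - mean of the reference-gene Cts`, with
#' the geometric mean as the default combination (applied to the Ct values
#' themselves, as is conventional in comparative-Ct workflows; an arithmetic
#' mode is available since Cts already live on a log scale). Lower delta-Ct
#' means higher expression. Samples missing any reference Ct are dropped
#' with a warning.
#'
#' @param target data.frame with `sample_id`, `ct` and (optionally) `tissue`.
#' @param refs data.frame with `sample_id`, `gene`, `ct` — one row per
#'   reference gene per sample.
#' @param mean_mode `"geometric"` (default) or `"arithmetic"`.
#' @return `target` with columns `ref_ct` (combined reference Ct) and
#'   `delta_ct` appended; rows without complete references removed.
#' @export
delta_ct <- function(target, refs, mean_mode = c("geometric", "arithmetic")) {
  mean_mode <- match.arg(mean_mode)
  stopifnot(all(target$ct > 0), all(refs$ct > 0))
  n_ref_genes <- length(unique(refs$gene))
  comb <- tapply(refs$ct, refs$sample_id, function(x) {
    if (length(x) < n_ref_genes) return(NA_real_)
    if (mean_mode == "geometric") exp(mean(log(x))) else mean(x)
  })
  target$ref_ct <- as.numeric(comb[as.character(target$sample_id)])
  bad <- is.na(target$ref_ct)
  if (any(bad)) {
    warning(sum(bad), " sample(s) dropped for missing reference Ct values")
    target <- target[!bad, , drop = FALSE]
  }
  target$delta_ct <- target$ct - target$ref_ct
  target
}

#' Promote reference tissues that overlap the target expression range
#'
#' The reference group must show low, non-overlapping expression compared to
#' the target tissue(s). Any reference tissue whose delta-Ct values overlap
#' the target range — by default, tissue median delta-Ct below the maximum
#' per-sample delta-Ct observed in the current target group — is promoted to
#' target, and the check is iterated to a fixed point. (Lower delta-Ct =
#' higher expression, so "below the target maximum" means expression at
#' target-like levels.)
#'
#' @param dct data.frame with `tissue` and `delta_ct` columns (one row per
#'   sample), e.g. [delta_ct()] output.
#' @param initial_target non-empty character vector of tissue names.
#' @param rule `"median_below_max"` (default) or `"median_below_median"`
#'   (stricter: promote only when the tissue median beats the target median).
#' @return list with `target` (final target tissues) and `promoted` (the
#'   tissues added to the initial set). Errors if every tissue ends up
#'   promoted, since no reference group would remain.
#' @export
assign_target_tissues <- function(dct, initial_target,
                                  rule = c("median_below_max",
                                           "median_below_median")) {
  rule <- match.arg(rule)
  stopifnot(length(initial_target) >= 1L)
  tissues <- unique(as.character(dct$tissue))
  if (!all(initial_target %in% tissues))
    stop("initial target tissue(s) absent from the data")
  target <- unique(as.character(initial_target))
  repeat {
    tgt_vals <- dct$delta_ct[dct$tissue %in% target]
    thr <- if (rule == "median_below_max") max(tgt_vals) else
      stats::median(tgt_vals)
    refs <- setdiff(tissues, target)
    if (length(refs) == 0L)
      stop("all tissues promoted to target; no reference group left")
    med <- vapply(refs, function(t)
      stats::median(dct$delta_ct[dct$tissue == t]), numeric(1))
    promote <- refs[med < thr]
    if (length(promote) == 0L) break
    target <- c(target, promote)
  }
  list(target = target, promoted = setdiff(target, initial_target))
}

#' Welch's unequal-variance t-test on delta-Ct groups
#'
#' Two-sided Welch test with Satterthwaite degrees of freedom (wraps
#' `stats::t.test(var.equal = FALSE)`). The degenerate case of two constant
#' groups with equal means is reported as t = 0, p = 1 by convention.
#'
#' @param x,y numeric vectors (each length >= 2).
#' @return list with `t`, `df`, `p`.
#' @export
welch_test <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m number of tests performed (>= 1).
#' @return `alpha / m`; calls are significant when `p < alpha / m` (strict).
#' @export
bonferroni_alpha <- function(alpha = 0.05, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Fold change by the comparative Ct (delta-delta-Ct) method
#'
#' `ddct = mean reference delta-Ct - mean target delta-Ct` (positive when the
#' target tissue expresses more), and the relative increase in the target is
#' `2^ddct`, assuming 100% amplification efficiency.
#'
#' @param mean_target,mean_reference mean delta-Ct of each group.
#' @return list with `ddct` and `fold`.
#' @export
fold_change <- function(mean_target, mean_reference) {
  stopifnot(is.finite(mean_target), is.finite(mean_reference))
  ddct <- mean_reference - mean_target
  list(ddct = ddct, fold = 2^ddct)
}

#' Full delta-delta-Ct differential-expression test for one miRNA
#'
#' Combines [delta_ct()], [assign_target_tissues()], [welch_test()] and
#' [fold_change()]: normalizes the target assay against the reference genes,
#' promotes overlapping tissues into the target set, then tests target vs
#' reference delta-Cts and reports the relative increase.
#'
#' @inheritParams delta_ct
#' @inheritParams assign_target_tissues
#' @param p_threshold significance threshold on the (already adjusted) scale,
#'   e.g. [bonferroni_alpha()] output; strict inequality.
#' @return one-row data.frame: `target_tissues`, `n_target`, `n_reference`,
#'   `mean_dct_target`, `mean_dct_reference`, `ddct`, `fold_change`, `t`,
#'   `df`, `p`, `significant`, and `all_tissues_overlap` (TRUE when the
#'   promotion fallback was taken).
#' @export
de_test <- function(target, refs, initial_target, p_threshold,
                    mean_mode = c("geometric", "arithmetic"),
                    rule = c("median_below_max", "median_below_median")) {
  dct <- delta_ct(target, refs, mean_mode = match.arg(mean_mode))
  # A gene with no tissue enrichment overlaps everywhere, so promotion can
  # cascade until no reference tissue remains; fall back to the initial
  # target set then — the conservative comparison for a flat profile.
  tt <- tryCatch(
    assign_target_tissues(dct, initial_target, rule = match.arg(rule)),
    error = function(e) list(target = unique(as.character(initial_target)),
                             promoted = character(0), all_overlap = TRUE))
  all_overlap <- isTRUE(tt$all_overlap)
  in_target <- dct$tissue %in% tt$target
  x <- dct$delta_ct[in_target]
  y <- dct$delta_ct[!in_target]
  w <- welch_test(x, y)
  fc <- fold_change(mean(x), mean(y))
  data.frame(target_tissues = paste(sort(tt$target), collapse = ","),
             n_target = length(x), n_reference = length(y),
             mean_dct_target = mean(x), mean_dct_reference = mean(y),
             ddct = fc$ddct, fold_change = fc$fold,
             t = w$t, df = w$df, p = w$p,
             significant = w$p < p_threshold,
             all_tissues_overlap = all_overlap,
             stringsAsFactors = FALSE)
}

#' Deep-sequencing fold estimate for cross-platform comparison
#'
#' Ratio of the mean normalized read count over target-tissue samples to the
#' mean over reference-tissue samples. Only miRNAs quantifiable in every
#' sample (normalized count > 0 throughout) are eligible; others return NA
#' and are excluded from correlation analyses.
#'
#' @param nm normalized matrix (miRNAs x samples).
#' @param target_samples,reference_samples column names (or indices) of the
#'   two sample sets.
#' @return named numeric vector of fold estimates (NA where excluded).
#' @export
seq_fold_estimate <- function(nm, target_samples, reference_samples) {
  t_m <- rowMeans(nm[, target_samples, drop = FALSE])
  r_m <- rowMeans(nm[, reference_samples, drop = FALSE])
  ok <- apply(nm > 0, 1L, all)
  ifelse(ok, t_m / r_m, NA_real_)
}

#' Correlate fold changes between qPCR and sequencing platforms
#'
#' Product-moment correlation of paired relative increases, computed on the
#' log2 scale by default (folds are ratios, so log-scale correlation is the
#' natural choice); raw-scale and rank (Spearman) variants are available.
#' Pairs with missing values are dropped; at least 3 complete pairs required.
#'
#' @param qpcr_folds,seq_folds paired numeric vectors of fold changes (> 0).
#' @param scale `"log2"` (default), `"raw"`, or `"rank"`.
#' @return the correlation coefficient; NA (with a warning) when either
#'   vector has zero variance.
#' @export
correlate_platforms <- function(qpcr_folds, seq_folds,
                                scale = c("log2", "raw", "rank")) {
  scale <- match.arg(scale)
  stopifnot(length(qpcr_folds) == length(seq_folds))
  ok <- is.finite(qpcr_folds) & is.finite(seq_folds)
  q <- qpcr_folds[ok]; s <- seq_folds[ok]
  if (length(q) < 3L) stop("need at least 3 paired fold estimates")
  if (scale == "log2") { q <- log2(q); s <- log2(s) }
  if (stats::sd(q) == 0 || stats::sd(s) == 0) {
    warning("zero variance in fold changes; correlation undefined")
    return(NA_real_)
  }
  if (scale == "rank") stats::cor(q, s, method = "spearman")
  else stats::cor(q, s)
}
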