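#' Transform Ct values to linear-scale expression
#'
#' One qPCR cycle is a two-fold difference in template, so linear expression
#' is `2^(C - Ct)` with `C = max(Ct)` in the matrix (the constant only shifts
#' the log scale and cancels in all downstream stability values).
#'
#' @param ct numeric matrix of Ct values (genes x samples), all finite.
#' @return numeric matrix of linear-scale expression, same shape.
#' @export
linearize_ct <- function(ct) {
  if (!all(is.finite(ct))) stop("non-finite Ct values")
  2^(max(ct) - ct)
}

# Shared variance-decomposition engine.
#
# Model on log2 expression: y_igj = mu_i + kappa_gj + d_ig + eps_igj with
# gene-by-group effects d_ig (summing to zero over genes and over groups) and
# intra-group noise eps with variance sigma2_ig.  Sample effects kappa are
# removed by centering each sample across genes; the centering leaks a little
# of every gene's noise into each residual, which the K-based correction
# undoes (needs K >= 3 genes).
#
# Returns per gene x group: d_hat (inter-group difference terms), sigma2
# (intra-group variance estimates, clamped at 0), n_g (group sizes), and
# gamma2 (the inter-group variance component, clamped at 0).
.normfinder_components <- function(y, groups) {
  K <- nrow(y)
  if (K < 3L) stop("the variance decomposition needs at least 3 genes")
  groups <- as.character(groups)
  gl <- unique(groups)
  G <- length(gl)
  if (G < 2L) stop("at least 2 sample groups are required")

  zbar <- matrix(NA_real_, K, G, dimnames = list(rownames(y), gl))
  sigma2 <- zbar
  n_g <- integer(G)
  for (gi in seq_along(gl)) {
    yg <- y[, groups == gl[gi], drop = FALSE]
    n <- ncol(yg)
    if (n < 2L) stop("group '", gl[gi], "' has fewer than 2 samples")
    n_g[gi] <- n
    z <- sweep(yg, 2L, colMeans(yg))      # remove per-sample effects
    zbar[, gi] <- rowMeans(z)
    v <- apply(z, 1L, stats::var)         # n-1 denominator
    # E[v_i] = sigma2_i (1 - 2/K) + S/K^2 with S = sum_i sigma2_i;
    # sum over genes gives S_hat = K/(K-1) * sum(v)
    S_hat <- K / (K - 1) * sum(v)
    sigma2[, gi] <- pmax((v - S_hat / K^2) / (1 - 2 / K), 0)
  }
  d_hat <- zbar - rowMeans(zbar)          # center per gene across groups
  var_dhat <- sweep(sigma2, 2L, n_g, "/") # sampling error of d_hat
  gamma2 <- max((sum(d_hat^2) - sum(var_dhat)) / ((K - 1) * (G - 1)), 0)
  list(d_hat = d_hat, sigma2 = sigma2, var_dhat = var_dhat,
       n_g = n_g, gamma2 = gamma2, groups = gl)
}

# Stability from difference terms and their sampling variances, using the
# empirical-Bayes shrinkage toward zero implied by d_ig ~ N(0, gamma2).
# When gamma2 = 0 all inter-group terms are exactly zero and stability
# reduces to the sampling uncertainty of the group means.
.stability_value <- function(d_hat, var_dhat, gamma2) {
  if (gamma2 > 0) {
    shrink <- gamma2 / (gamma2 + var_dhat)
    rho <- abs(d_hat * shrink) + sqrt(var_dhat * shrink)
  } else {
    rho <- sqrt(var_dhat)
  }
  rowMeans(rho)
}

#' Model-based reference-gene stability (single genes)
#'
#' Re-implementation of the model-based variance-decomposition approach to
#' reference-gene selection: on log2-transformed expression, each candidate
#' gene receives per-group intra-group variance estimates and inter-group
#' difference terms (corrected for sampling error by subtracting the
#' intra-group variance over the group size), which are combined into one
#' non-negative stability value per gene. Lower values indicate more stable
#' expression; the inter-group terms are shrunk toward zero in proportion to
#' how much of their spread is explained by sampling noise.
#'
#' @param expr numeric matrix of *linear-scale* expression (genes x samples),
#'   at least 3 genes; typically [linearize_ct()] output.
#' @param groups tissue/group label per sample (length = ncol(expr)), every
#'   group with at least 2 samples, at least 2 groups.
#' @return object of class `stability_result`: list with `table` (data.frame
#'   `gene`, `stability`, ascending), `best_single`, and the fitted
#'   components (`gamma2`, `d_hat`, `sigma2`, `var_dhat`, `n_g`).
#' @export
normfinder_stability <- function(expr, groups) {
  stopifnot(is.matrix(expr), ncol(expr) == length(groups))
  if (any(expr <= 0)) stop("linear-scale expression must be positive")
  if (is.null(rownames(expr)))
    rownames(expr) <- paste0("gene", seq_len(nrow(expr)))
  y <- log2(expr)
  comp <- .normfinder_components(y, groups)
  stab <- .stability_value(comp$d_hat, comp$var_dhat, comp$gamma2)
  tab <- data.frame(gene = rownames(y), stability = unname(stab),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$stability, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, best_single = tab$gene[1L],
                 gamma2 = comp$gamma2, d_hat = comp$d_hat,
                 sigma2 = comp$sigma2, var_dhat = comp$var_dhat,
                 n_g = comp$n_g),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("Reference-gene stability (lower = more stable)\n")
  print(x$table, ...)
  cat("best single gene:", x$best_single, "\n")
  invisible(x)
}

#' Best two-gene reference combination
#'
#' Evaluates every unordered pair of candidate genes: the pair's inter-group
#' difference terms are the average of the two genes' terms and its
#' intra-group variance is the variance of the average
#' (`(sigma2_a + sigma2_b) / 4`), then the same stability value is computed.
#' Two genes whose group biases cancel can beat every single gene, though a
#' pair is not guaranteed to beat the best single gene — both are reported
#' for comparison.
#'
#' @inheritParams normfinder_stability
#' @return list with `pair` (character(2)), `stability` (the pair's value),
#'   `all_pairs` (data.frame of every pair, ascending stability), and
#'   `best_single`/`single_stability` for comparison.
#' @export
best_pair <- function(expr, groups) {
  fit <- normfinder_stability(expr, groups)
  genes <- rownames(fit$d_hat)
  if (length(genes) < 2L) stop("need at least 2 candidate genes")
  idx <- utils::combn(length(genes), 2L)
  pair_stab <- apply(idx, 2L, function(p) {
    d_p <- (fit$d_hat[p[1L], ] + fit$d_hat[p[2L], ]) / 2
    v_p <- (fit$sigma2[p[1L], ] + fit$sigma2[p[2L], ]) / 4 / fit$n_g
    mean(.stability_value(rbind(d_p), rbind(v_p), fit$gamma2))
  })
  all_pairs <- data.frame(gene_a = genes[idx[1L, ]], gene_b = genes[idx[2L, ]],
                          stability = pair_stab, stringsAsFactors = FALSE)
  all_pairs <- all_pairs[order(all_pairs$stability, all_pairs$gene_a,
                               all_pairs$gene_b), , drop = FALSE]
  rownames(all_pairs) <- NULL
  list(pair = c(all_pairs$gene_a[1L], all_pairs$gene_b[1L]),
       stability = all_pairs$stability[1L],
       all_pairs = all_pairs,
       best_single = fit$best_single,
       single_stability = fit$table$stability[1L])
}
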