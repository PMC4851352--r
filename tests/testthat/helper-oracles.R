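# Independent brute-force oracles used to check the package implementations.
# Each oracle is deliberately written as plain loops, not by calling the
# functions it validates.

# best BLAST hit by minimum E-value (ties: bit score desc, subject id asc)
oracle_best_hit <- function(hits, e_max = 1e-06) {
  best <- NULL
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (h$e_value > e_max) next
    if (is.null(best) ||
        h$e_value < best$e_value ||
        (h$e_value == best$e_value && h$bit_score > best$bit_score) ||
        (h$e_value == best$e_value && h$bit_score == best$bit_score &&
         h$subject_id < best$subject_id))
      best <- h
  }
  if (is.null(best)) NA_character_ else best$subject_id
}

# connected components of the all-pairs "closer than max_gap, same contig
# and strand" graph; returns sorted member lists of components of size >= 2
oracle_clusters <- function(loci, max_gap = 10000) {
  n <- nrow(loci)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- loci[i, ]; b <- loci[j, ]
    if (a$contig != b$contig || a$strand != b$strand) next
    gap <- max(0, max(a$start, b$start) - min(a$end, b$end) - 1)
    if (gap < max_gap) adj[i, j] <- TRUE
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comps <- igraph::components(g)$membership
  out <- lapply(split(loci$gene_id, comps), sort)
  out <- out[vapply(out, length, integer(1)) >= 2L]
  unname(out[order(vapply(out, `[`, character(1), 1L))])
}

# all-vs-all exact string matching of reads to matures
oracle_counts <- function(reads, matures, min_len = 18L) {
  samples <- sort(unique(reads$sample_id))
  cm <- matrix(0, length(matures), length(samples),
               dimnames = list(names(matures), samples))
  for (r in seq_len(nrow(reads))) {
    if (nchar(reads$sequence[r]) < min_len) next
    for (m in seq_along(matures)) {
      if (reads$sequence[r] == matures[[m]])
        cm[m, reads$sample_id[r]] <- cm[m, reads$sample_id[r]] + reads$count[r]
    }
  }
  cm
}

# hand-coded Welch t statistic, Satterthwaite df, two-sided p
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# loop-based re-derivation of the stability components: per-sample centering
# within each group, intra-group variance with the K-gene correction,
# cross-group centered difference terms, shrinkage stability
oracle_stability <- function(y, groups) {
  K <- nrow(y); gl <- unique(groups); G <- length(gl)
  zbar <- matrix(0, K, G); sig2 <- matrix(0, K, G); n_g <- integer(G)
  for (g in seq_along(gl)) {
    yg <- y[, groups == gl[g], drop = FALSE]
    n_g[g] <- ncol(yg)
    z <- yg
    for (j in seq_len(ncol(yg))) z[, j] <- yg[, j] - mean(yg[, j])
    v <- numeric(K)
    for (i in seq_len(K)) {
      zbar[i, g] <- mean(z[i, ])
      v[i] <- sum((z[i, ] - mean(z[i, ]))^2) / (n_g[g] - 1)
    }
    S <- K / (K - 1) * sum(v)
    for (i in seq_len(K)) sig2[i, g] <- max((v[i] - S / K^2) / (1 - 2 / K), 0)
  }
  d <- zbar
  for (i in seq_len(K)) d[i, ] <- zbar[i, ] - mean(zbar[i, ])
  vd <- sig2
  for (g in seq_len(G)) vd[, g] <- sig2[, g] / n_g[g]
  gam <- max((sum(d^2) - sum(vd)) / ((K - 1) * (G - 1)), 0)
  rho <- numeric(K)
  for (i in seq_len(K)) {
    acc <- 0
    for (g in seq_len(G)) {
      if (gam > 0) {
        w <- gam / (gam + vd[i, g])
        acc <- acc + abs(d[i, g] * w) + sqrt(vd[i, g] * w)
      } else acc <- acc + sqrt(vd[i, g])
    }
    rho[i] <- acc / G
  }
  names(rho) <- rownames(y)
  list(stability = rho, d = d, sig2 = sig2, n_g = n_g, gamma2 = gam)
}

# exhaustive best-pair search driven by the oracle components
oracle_best_pair <- function(y, groups) {
  comp <- oracle_stability(y, groups)
  K <- nrow(y); G <- length(comp$n_g)
  best <- NULL
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    acc <- 0
    for (g in seq_len(G)) {
      dp <- (comp$d[a, g] + comp$d[b, g]) / 2
      vp <- (comp$sig2[a, g] + comp$sig2[b, g]) / 4 / comp$n_g[g]
      if (comp$gamma2 > 0) {
        w <- comp$gamma2 / (comp$gamma2 + vp)
        acc <- acc + abs(dp * w) + sqrt(vp * w)
      } else acc <- acc + sqrt(vp)
    }
    stab <- acc / G
    if (is.null(best) || stab < best$stability)
      best <- list(pair = rownames(y)[c(a, b)], stability = stab)
  }
  best
}

# fixed-point promotion oracle: repeatedly promote any reference tissue
# whose median delta-Ct is below the current target maximum
oracle_promote <- function(dct, initial_target) {
  target <- initial_target
  repeat {
    thr <- max(dct$delta_ct[dct$tissue %in% target])
    changed <- FALSE
    for (t in setdiff(unique(dct$tissue), target)) {
      if (median(dct$delta_ct[dct$tissue == t]) < thr) {
        target <- c(target, t); changed <- TRUE
      }
    }
    if (!changed) return(sort(target))
  }
}
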