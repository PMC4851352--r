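#' Count reads matching mature miRNAs exactly
#'
#' A (collapsed) read increments a mature miRNA's count if and only if its
#' sequence is an exact string match to that unique mature sequence; reads
#' with mismatches, reads matching no mature, and reads shorter than
#' `min_len` nucleotides are ignored. Because the mature set is the collapsed
#' unique set (distinct strings), a read can match at most one entry and is
#' counted once regardless of how many gene copies share the sequence.
#'
#' @param reads data.frame of collapsed reads: `sample_id`, `sequence`,
#'   `count` (non-negative integers).
#' @param matures named character vector of unique mature sequences (names =
#'   mature ids); must be non-empty with distinct sequences.
#' @param min_len minimum read length kept (default 18).
#' @return integer matrix (matures x samples) of perfect-match read counts,
#'   with a `sample_total` attribute holding the column sums.
#' @export
count_perfect_matches <- function(reads, matures, min_len = 18L) {
  if (length(matures) == 0L) stop("empty mature miRNA set")
  if (is.null(names(matures)) || anyDuplicated(names(matures)))
    stop("matures must be uniquely named")
  if (anyDuplicated(matures)) stop("mature sequences must be unique strings")
  samples <- sort(unique(as.character(reads$sample_id)))
  cm <- matrix(0L, nrow = length(matures), ncol = length(samples),
               dimnames = list(names(matures), samples))
  keep <- nchar(reads$sequence) >= min_len & reads$count > 0
  reads <- reads[keep, , drop = FALSE]
  idx <- match(reads$sequence, matures)
  hit <- !is.na(idx)
  if (any(hit)) {
    tab <- tapply(reads$count[hit],
                  list(names(matures)[idx[hit]],
                       as.character(reads$sample_id[hit])), sum)
    cm[rownames(tab), colnames(tab)] <-
      ifelse(is.na(tab), 0L, as.integer(tab))
  }
  attr(cm, "sample_total") <- colSums(cm)
  cm
}

#' Normalize read counts to a per-10^4 scale
#'
#' Each count is divided by the total number of miRNA-matching reads in its
#' sample and multiplied by 10^4, making expression comparable across
#' libraries of different depth. With this denominator every column of the
#' normalized matrix sums to 10^4.
#'
#' @param cm numeric matrix of counts (miRNAs x samples); every column sum
#'   must be positive.
#' @return numeric matrix of the same shape on the per-10^4 scale, with the
#'   `sample_total` attribute carrying the denominators used.
#' @export
normalize_counts <- function(cm) {
  totals <- colSums(cm)
  if (any(totals <= 0))
    stop("sample(s) with zero miRNA reads cannot be normalized: ",
         paste(colnames(cm)[totals <= 0], collapse = ", "))
  nm <- sweep(cm, 2L, totals, "/") * 1e4
  attr(nm, "sample_total") <- totals
  nm
}

#' Relative standard deviation of each miRNA across samples
#'
#' RSD (coefficient of variation) = sample standard deviation (n-1
#' denominator) of the normalized counts across samples, divided by their
#' mean. Scale-free, so it ranks stability irrespective of expression level.
#' Undefined (NA) when the mean is zero.
#'
#' @param nm normalized matrix (miRNAs x samples), at least two samples.
#' @return named numeric vector of RSD values (NA where mean is 0).
#' @export
compute_rsd <- function(nm) {
  if (ncol(nm) < 2L) stop("RSD needs at least two samples")
  m <- rowMeans(nm)
  s <- apply(nm, 1L, stats::sd)
  ifelse(m > 0, s / m, NA_real_)
}

#' Greedily screen reference-gene candidates by RSD
#'
#' Candidates are taken in ascending RSD order, skipping any miRNA that
#' shares a gene family or a gene cluster with one already selected, so the
#' chosen set is not internally co-regulated.
#'
#' @param rsd named numeric RSD vector (NAs are ineligible).
#' @param membership data.frame with `mature_id` and optional `family`,
#'   `cluster` columns (NA = no membership).
#' @param k number of candidates wanted.
#' @return character vector of up to `k` mature ids; warns when fewer than
#'   `k` are eligible.
#' @export
screen_reference_candidates <- function(rsd, membership, k) {
  stopifnot(k >= 1)
  ok <- names(rsd)[!is.na(rsd)]
  ord <- ok[order(rsd[ok])]
  fam <- stats::setNames(rep(NA_character_, length(ord)), ord)
  clu <- fam
  if (!is.null(membership)) {
    i <- match(ord, membership$mature_id)
    if ("family" %in% names(membership)) fam[] <- as.character(membership$family[i])
    if ("cluster" %in% names(membership)) clu[] <- as.character(membership$cluster[i])
  }
  sel <- character(0); used_fam <- character(0); used_clu <- character(0)
  for (id in ord) {
    if (!is.na(fam[id]) && fam[id] %in% used_fam) next
    if (!is.na(clu[id]) && clu[id] %in% used_clu) next
    sel <- c(sel, id)
    if (!is.na(fam[id])) used_fam <- c(used_fam, fam[id])
    if (!is.na(clu[id])) used_clu <- c(used_clu, clu[id])
    if (length(sel) == k) break
  }
  if (length(sel) < k)
    warning("only ", length(sel), " eligible reference candidates (asked for ",
            k, ")")
  sel
}

#' Rank tissue-enriched candidates from normalized counts
#'
#' For each miRNA the enrichment ratio is the largest per-tissue mean
#' normalized count divided by the mean of the remaining tissues' means.
#' Zero entries are smoothed to half a read on the count scale (0.5 /
#' sample total x 10^4, using the `sample_total` attribute when present, a
#' flat 0.5 otherwise) before forming the ratio; nonzero values are left
#' untouched. miRNAs reaching `min_ratio` are returned ranked by decreasing
#' ratio — a formalized screen for
#' candidates likely to be expressed preferentially in one or few organs.
#'
#' @param nm normalized matrix (miRNAs x samples).
#' @param tissue_of_sample character vector mapping each column to a tissue
#'   (named by sample or positional); at least two tissues.
#' @param min_ratio minimum enrichment ratio to report (default 4).
#' @return data.frame `mature_id`, `top_tissue`, `ratio`, ranked descending.
#' @export
screen_enriched_candidates <- function(nm, tissue_of_sample, min_ratio = 4) {
  if (!is.null(names(tissue_of_sample)))
    tissue_of_sample <- tissue_of_sample[colnames(nm)]
  tissue_of_sample <- as.character(tissue_of_sample)
  if (length(unique(tissue_of_sample)) < 2L)
    stop("enrichment screening needs at least two tissues")
  totals <- attr(nm, "sample_total")
  pseudo <- if (is.null(totals)) rep(0.5, ncol(nm)) else 0.5 / totals * 1e4
  sm <- nm
  for (j in seq_len(ncol(sm))) sm[sm[, j] == 0, j] <- pseudo[j]
  tiss_mean <- t(apply(sm, 1L, function(x)
    tapply(x, tissue_of_sample, mean)))
  top <- max.col(tiss_mean, ties.method = "first")
  ratio <- vapply(seq_len(nrow(tiss_mean)), function(i) {
    tiss_mean[i, top[i]] / mean(tiss_mean[i, -top[i]])
  }, numeric(1))
  out <- data.frame(mature_id = rownames(nm),
                    top_tissue = colnames(tiss_mean)[top],
                    ratio = ratio, stringsAsFactors = FALSE)
  out <- out[out$ratio >= min_ratio, , drop = FALSE]
  out <- out[order(-out$ratio, out$mature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
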